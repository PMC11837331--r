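# wingclap

Aerodynamics of flapping–folding wings and ventral wing-clap jets.

Bat-sized flyers do not just flap: the handwing (wrist to tip) folds
relative to the armwing during the upstroke, and at large fold
amplitudes the two handwings meet below the body — a ventral *clap* —
squeezing out a downward air jet that generates lift during a phase of
the wingbeat that is normally lift-neutral or worse. `wingclap` is an
analysis package for this regime, aimed at people studying animal
flight or building flapping-wing robots. It implements, as tested
reusable code:

* **Kinematics** — two-degree-of-freedom wing motion (sinusoidal or
  crank-rocker four-bar flap; raised-cosine fold pulse starting at
  t/T = 1/3), realized-motion emulation (fold phase lag, passive
  no-fold wobble), and blade-element states with effective velocity
  and effective angle of attack.
* **Quasi-steady model** — blade-element lift/power with the
  generalized flat-plate law C_L = A_L sin 2α,
  C_D = C_D0 + A_D(1 − cos 2α); instantaneous C_L(t) = F_z/(½ρU²S)
  and C_P(t) = P/(½ρU³S) with S = 2bc; cycle averages and power
  economy C̄_L/C̄_P swept over Strouhal number St = fA/U and fold
  amplitude θ₀.
* **Control-volume analysis** — clap-jet lift from phase-averaged
  planar velocity fields via the three-term momentum budget
  (acceleration + momentum flux + pressure, the pressure recovered by
  line-integrating the inviscid momentum equation along the edges);
  C_L = L/(qc) under the 2b jet-width assumption, and the clap peak
  C_L,clap against the clap Strouhal number St_clap = fθ₀b/U.
* **Signal processing** — zero-phase Butterworth filtering (f_c = 5f),
  wings-off mechanism-inertia subtraction, normalization, 83-bin phase
  averaging with cycle-to-cycle RMS bands.
* **Synthetic data** — generators for every input with analytic ground
  truth (realized kinematics, inertia + aero + noise force traces,
  clap-jet velocity fields), so the whole chain is testable end to end.

## Worked example

Sweep the quasi-steady model over fold amplitude at two Strouhal
numbers (St is realized by varying the freestream U at fixed f and tip
excursion A):

```r
library(wingclap)
g <- wing_geometry()   # armwing 0.1 m, handwing b = 0.1 m, chord 0.2 m
qs_sweep(c(0.21, 0.41), c(0, 30, 60, 100) * pi / 180, g)
#>     St theta0_deg       CL_bar    CP_bar      economy        U f         A
#> 1 0.21          0 6.568638e-17 0.7834638 8.384098e-17 3.969476 3 0.2778633
#> 2 0.21         30 6.256862e-02 0.8479953 7.378417e-02 3.969476 3 0.2778633
#> 3 0.21         60 1.780820e-01 0.8919731 1.996495e-01 3.969476 3 0.2778633
#> 4 0.21        100 2.418983e-01 0.9839692 2.458393e-01 3.969476 3 0.2778633
#> 5 0.41          0 1.114549e-16 3.3045756 3.372745e-17 2.033146 3 0.2778633
#> 6 0.41         30 1.092371e-01 3.6694829 2.976908e-02 2.033146 3 0.2778633
#> 7 0.41         60 3.648681e-01 3.9441885 9.250778e-02 2.033146 3 0.2778633
#> 8 0.41        100 5.114802e-01 4.5167403 1.132410e-01 2.033146 3 0.2778633
```

Without folding the strokes are symmetric and the cycle-averaged lift
is zero; lift rises monotonically with fold amplitude at both Strouhal
numbers. The quasi-steady model contains no wing–wing interaction, so
the extra lift of the clap itself is invisible to it — that is what the
control-volume pipeline measures:

```r
sp <- synthetic_spec(seed = 1)                      # theta0 = 100 deg
jf <- make_jet_fields(sp)                           # 40 cycles at 500 Hz
fs <- phase_average(jf$snapshots, n_bins = 83)
bud <- lift_budget(fs, cv_spec())
clap_peak(bud)
#> $CL_clap
#> [1] 0.5098216
#>
#> $phase
#> [1] 0.7168675
```

The clap registers as a lift-coefficient peak of ~0.51 late in the
upstroke — comparable to the downstroke peak of the folded wing, and
within 6% of the generator's analytic ground truth (0.54; the residual
is dominated by the Savitzky–Golay phase derivative's attenuation at
83 bins, plus this seed's noise realization).

The numbered scripts under `analysis/` run the full study on synthetic
data — kinematics, quasi-steady surfaces, clap-jet scaling, and the
force-processing chain — writing tables under `results/`:

```sh
Rscript analysis/01_kinematics.R
Rscript analysis/02_quasi_steady.R
Rscript analysis/03_clap_jet.R
Rscript analysis/04_force_processing.R
```

For example, `03_clap_jet.R` prints the clap-lift scaling across a
family of fold amplitudes (jet strength tied to the handwing closing
speed fθ₀b):

```
 theta0_deg St_clap CL_clap peak_tT CL_clap_truth
         40  0.0524   0.205   0.717         0.216
         60  0.0785   0.321   0.717         0.324
         80  0.1047   0.424   0.717         0.433
        100  0.1309   0.513   0.717         0.541

CL_clap vs St_clap: slope 3.92, Spearman rho 1.00
```

## Documentation

The methods vignette (`vignettes/clap-jet-methods.Rmd`) describes the
models, their assumptions and limitations, every tunable parameter
with units and defaults, and the numerical choices (filters,
anchoring, tolerances, degenerate-input behaviour).
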