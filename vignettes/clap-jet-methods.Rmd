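---
title: "Models and methods: flapping-folding wing aerodynamics and clap-jet lift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: flapping-folding wing aerodynamics and clap-jet lift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingclap)
```

## The system being modelled

Bats articulate their wings in two broad degrees of freedom: the armwing
(shoulder to wrist) flaps up and down, and the handwing (wrist to tip)
folds relative to the armwing about a chordwise axis through the wrist.
At large fold amplitudes the two handwings meet below the body late in
the upstroke — a ventral *clap* — squeezing out a downward air jet that
produces lift at a point in the wingbeat where flapping wings normally
produce none. `wingclap` models a robotic two-degree-of-freedom
flapping-folding wing platform in a freestream: its kinematics, a
quasi-steady blade-element prediction of lift and power, and a
control-volume estimate of the clap-jet lift from planar velocity
fields, together with the signal-processing chain used to reduce
force-transducer and velocimetry measurements.

Conventions used throughout: x downstream, z up, y spanwise. The phase
origin t/T = 0 is the top of the downstroke (dorsal extreme of the
armwing); up- and down-stroke are defined by the armwing and are equal
in duration. Positive fold angle rotates the handwing ventrally.

## Kinematics

The commanded flap is $\phi(t) = \Phi\cos(2\pi f t)$ at $f = 3$ Hz.
The physical drive is a crank-rocker four-bar; a loop-closure solver
(`commanded_flap(mode = "fourbar")`) is provided for fidelity studies,
but the default generator is the ideal sinusoid because the realized
flap of such drives closely follows the prescribed motion. The flap
half-amplitude default $\Phi = 44^\circ$ makes the no-fold peak-to-peak
tip excursion $A = 2R\sin\Phi \approx 0.28$ m, so that $St = fA/U =
0.21$ at $U = 4\;\mathrm{m\,s^{-1}}$ — the baseline condition of the
study this package emulates.

The commanded fold is idle until $t/T = 1/3$ (late downstroke) and then
executes a single raised-cosine fold-and-return pulse ending with the
cycle,
$$\theta(s) = \frac{\theta_o}{2}\left[1 -
  \cos\!\left(2\pi\,\frac{s - s_0}{1 - s_0}\right)\right],
  \qquad s = t/T \ge s_0 = \tfrac13,$$
which peaks at $\theta_o$ at $t/T = 2/3$ and is $C^1$-continuous at
onset and cycle end. The realized fold lags the commanded fold by 0.1
cycles (`realized_from_commanded()`), placing the realized peak — and
the clap — near $t/T \approx 0.77$–0.8. In the no-fold condition the
handwing is not rigidly held; a passive oscillation bounded in
$[-20^\circ, +5^\circ]$ emulates what the physical wrist does.

Blade elements discretize the half-span. Because both flapping and
folding rotate the wing about chordwise axes, a section's incidence is
set by the flow component normal to its own surface, not by its
vertical velocity: for an armwing element $v_n = r\dot\phi$, and for a
handwing element at radius $r$,
$$v_n = L_a\dot\phi\cos\theta + (r - L_a)\dot\psi,
  \qquad \psi = \phi - \theta,$$
with $L_a$ the armwing length. The effective angle of attack is
$\alpha = \operatorname{atan2}(-v_n, U)$ and the effective speed
$U_{\mathrm{eff}} = \sqrt{U^2 + v_n^2}$. The surface-normal force is
later projected onto the vertical by $\cos\phi$ (armwing) or
$\cos\psi$ (handwing); a fully folded handwing near $\psi = -90^\circ$
"slices" through the air and contributes almost no lift or downforce.
This resolution — rather than a vertical-velocity-only description —
is what produces the two experimentally observed benefits of folding:
extra handwing speed (hence lift) in the late downstroke, and
suppressed negative lift during the upstroke. All angular rates are
obtained by Savitzky–Golay differentiation (order 2, frame length 5),
with a periodic wrap when the series covers whole cycles.

## Quasi-steady blade-element model

Each element carries the generalized translational flat-plate law
$$C_L(\alpha) = A_L \sin 2\alpha, \qquad
  C_D(\alpha) = C_{D0} + A_D\,(1 - \cos 2\alpha),$$
with defaults $A_L = 1.7$, $C_{D0} = 0.05$, $A_D = 1.7$ — the standard
revolving-wing form for flat plates with an attached leading-edge
vortex, all configurable in `aero_model()`. Element lift
$q_{\mathrm{eff}} c\,\mathrm{d}r\,C_L$ acts perpendicular to the
relative wind, drag parallel to it; vertical components are summed over
elements and both (mirror-symmetric) half-wings. Aerodynamic power is
the work rate against the relative wind, $P = \sum \mathrm{d}D\,
U_{\mathrm{eff}}$. Coefficients are normalized by the freestream
dynamic pressure and the reference area $S = 2bc$ (the fabric area of
the two handwings): $C_L = F_z/(qS)$, $C_P = P/(qUS)$. Cycle averages
and the power economy $\bar C_L/\bar C_P$ summarize each condition;
`qs_sweep()` maps them over the $(St, \theta_o)$ plane, realizing $St$
by varying $U$ at fixed $f$ and $A$.

Model scope, stated plainly: the quasi-steady model contains no wake
memory, no leading-edge-vortex shedding, no added-mass or rotational
circulation terms, and — by construction — no wing–wing interaction:
its output is invariant to anything describing wingtip separation. It
therefore *cannot* produce clap-jet lift; that is precisely why the
control-volume analysis below exists. Wing-structure inertia power is
excluded (the handwing is light enough that its inertial power is
negligible next to the mechanism's, which the measurement chain
removes by wings-off subtraction).

With these defaults the model predicts zero net lift without folding
(antisymmetric strokes), cycle-averaged lift increasing monotonically
with $\theta_o$ at every $St$ in [0.16, 0.41], and a power economy
that peaks near $\theta_o \approx 80^\circ$ and dips slightly at full
fold: the model prices the drag of the clap kinematics without the
jet lift that, in measurements, rewards them.

## Control-volume estimate of clap-jet lift

Planar time-resolved velocity fields in the midline plane between the
wings are phase-averaged into $N = 83$ bins per cycle (40 repetitions
per bin in the emulated protocol), with per-bin variance and covariance
fields retained. The vertical force associated with the flow follows
from the momentum budget of a fixed rectangle in the plane:
$$L = \underbrace{\frac{\partial}{\partial t}\int_{CV} \rho\,\tilde w\,
  \mathrm{d}V}_{\text{acceleration}}
  + \underbrace{\oint_{CS} \rho\,\tilde w\,(\vec v\cdot\hat n)\,
  \mathrm{d}A}_{\text{momentum flux}}
  + \underbrace{\int (p_b - p_t)\,\mathrm{d}x}_{\text{pressure}},$$
evaluated per unit depth on the downward-positive vertical momentum
$\tilde w = -w$, so that a downward jet registers as positive lift.
The three terms are assembled exactly (`total` is their sum by
construction). Phase derivatives use the same Savitzky–Golay filter
with periodic wrap-around; quadrature is trapezoidal. The
per-unit-depth force is dimensionalized by the assumed spanwise jet
width $2b$ (the planar measurement cannot see the third dimension; the
jet is taken uniform over the clapping handwings' width), giving
$C_L = L/(qc)$.

Gauge pressure on the top and bottom edges is recovered from the
velocity field by integrating the inviscid streamwise momentum
equation from the upstream corner, where $p = p_\infty$
(`method = "momentum_integration"`); an unsteady Bernoulli closure is
provided as a cross-check. Two numerical choices matter:

* **Anchoring.** By default both corners of each edge are pinned to
  $p_\infty$ and the linear drift between them removed. For a
  disturbance compact within the edge (the clap jet) this is exact,
  and it suppresses the random-walk error that line integration
  otherwise accumulates from measurement noise — without it, the
  control-volume-independence of the peak degrades from <1% to ~6% at
  the default noise level. For flows still disturbed at the downstream
  corner use `anchor = "upstream"`.
* **Closure disagreement.** The Bernoulli closure neglects the
  rotational term $w\,\partial u/\partial z$ and deviates from the
  momentum integration most in the phase bins where the jet core is
  strongest; at the clap-lift peak the two agree to within a few
  percent of the total force.

The turbulent-momentum flux $\oint \rho\langle \tilde w'(\vec
v'\cdot\hat n)\rangle\,\mathrm{d}l$, computed from the per-bin
variance/covariance fields, is reported alongside the budget but not
added to it; with 40-repetition phase averages it is three orders of
magnitude below the mean-flow terms, consistent with a coherent
(non-turbulent) jet. The clap lift coefficient $C_{L,\mathrm{clap}}$
is the peak of $C_L$ within the clap window (default $t/T \in
[0.7, 0.9]$), and scales with the clap Strouhal number
$St_{\mathrm{clap}} = f\theta_o b/U$ — note $\theta_o$ in radians, so
that $f\theta_o b$ is the handwing closing-speed scale.

## Measurement-processing chain

Force (1000 Hz) and motor power (512 Hz) channels are low-pass
filtered by a zero-phase fourth-order Butterworth filter at
$f_c = 5f$ (15 Hz), with odd-reflection padding to suppress end
transients. Mechanism inertia is removed by subtracting a matched
wings-off trial (handwings removed, same drive program). Trials are
hardware-trigger synchronized; an optional cross-correlation alignment
(`subtract_inertia(align = TRUE)`, the default) corrects gross trigger
offsets, with a caveat worth stating: because the wings-on fundamental
is the sum of inertial and aerodynamic components, the estimated lag is
pulled by the aerodynamic phase (about a dozen samples under the
default conditions). The misalignment residual is a circularly shifted
periodic signal with zero mean, so cycle-averaged coefficients are
unaffected; for trace-level work with synchronized trials, set
`align = FALSE`. Net traces are normalized by $\tfrac12\rho U^2 S$
(lift) and $\tfrac12\rho U^3 S$ (power), the power channel being
resampled onto the force clock by linear interpolation first.

Phase-averaged traces report, per bin, the mean and the standard
deviation of *per-cycle bin means* — the cycle-to-cycle spread that
measurement figures shade around the mean trace. A noise-free periodic
signal has a zero band under this definition even when several
distinct phases fall in one bin; this is the resolution adopted for
the ambiguity between "RMS about the mean" and "per-bin standard
deviation".

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground
truth (`synthetic_spec()` and the `make_*` functions), pure functions
of (spec, seed). The generator emulates the study conditions: 3 Hz
flapping, $U = 4\;\mathrm{m\,s^{-1}}$, 40-cycle trials, force/motor
channels at 1000/512 Hz, velocimetry at 500 Hz, 83 phase bins.

* **Kinematics** — commanded series plus realized series with the 0.1
  cycle fold lag and the $[-20^\circ, 5^\circ]$ no-fold wobble.
* **Force traces** — wings-on = mechanism inertia (harmonics at $f$
  and $2f$, amplitudes several times the aerodynamic signal, as for a
  real mechanism) + denormalized quasi-steady truth + Gaussian noise;
  wings-off = the same inertia with independent noise.
* **Jet fields** — uniform freestream plus a clap jet, Gaussian in
  space (core radius $\sigma_j = 0.03$ m) and raised-cosine in phase,
  centred at $t/T = 0.8$ with half-width 0.15 cycles so the jet's
  pressure/acceleration activity spans $t/T \approx 0.65$–0.95, the
  span over which clap signatures are observed to build and decay; the
  pulse is then also well resolved by the 83-bin Savitzky–Golay phase
  derivative. Peak speed $V_j = k_j f\theta_o b$ ($k_j = 7.5$, giving
  $V_j \approx U$ at full fold) ties jet strength to the handwing
  closing speed; the jet tilts $20^\circ$ rearward ("down and to the
  rear"), and a weaker upward pre-clap "scooping" lobe at $t/T
  \approx 0.62$ reproduces the negative-lift trough seen as the
  wingtips approach. The generator's ground-truth budget evaluates the
  same three control-volume terms from the analytic field with dense
  central differences on a refined grid.

What the generator does *not* emulate — and hence what passing tests
do and do not show: the jet blob does not advect or leave the control
volume (its cycle-integrated impulse within the volume is zero); there
is no turbulence, no spatially correlated velocimetry noise, no wake
from the wings themselves, and the quasi-steady truth underlying the
force traces is the model, not a measured force. Tests against this
generator validate the *estimators* — discretization, filtering,
phase-averaging, budget assembly, subtraction — not the fluid
dynamics of a real clap.

## Problem sizes and numerical tolerances

Default problem sizes were chosen so a full run of the test suite and
analysis scripts completes in minutes on one core: 400 kinematic
samples per cycle (20 blade elements), a 61 × 41 field grid at 10 mm
pitch over the 600 × 400 mm field of view, and trial lengths of 6–40
cycles depending on whether a magnitude or only a trend is under test.
Against the analytic ground truth at full study conditions, the
pipeline recovers the clap peak $C_L$ to within ~5% — the residual is
dominated by the prescribed Savitzky–Golay phase derivative's
attenuation — with <1% spread across nested control volumes and <2%
sensitivity to a Galilean shift of the streamwise velocity. Degenerate
inputs error early and loudly: non-Grashof linkages name the violated
inequality, empty phase bins are listed by index, cut-offs at or above
Nyquist, non-integer cycle spans, and control volumes leaving the
measured domain are all rejected rather than silently accommodated.

## Known limitations

The quasi-steady model omits unsteady mechanisms by design and must
not be read as predicting clap lift; the control-volume estimate
assumes spanwise jet uniformity over $2b$ and neglects viscous surface
stresses; pressure recovery assumes inviscid edge dynamics and
freestream anchor points; and the synthetic jet is a stand-in for a
flow that was only ever measured in one plane. Where a measured-robot
magnitude is wanted, this package provides the processing chain, not
the measurement.
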