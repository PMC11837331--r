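# Plain-text interchange formats. Every writer emits a commented metadata
# header ("# key = value") followed by a regular CSV table; readers
# round-trip the metadata. Velocity-field series use a long-format CSV
# (one row per phase bin x grid node) rather than a binary gridded
# container so datasets remain diffable and portable.

write_meta_csv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s = %s", k, format(meta[[k]], digits = 15)), con)
  write.csv(df, con, row.names = FALSE)
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^# ", "", l)
    k <- trimws(sub("=.*$", "", kv))
    v <- trimws(sub("^[^=]*=", "", kv))
    num <- suppressWarnings(as.numeric(v))
    meta[[k]] <- if (is.na(num)) v else num
  }
  df <- read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                              collapse = "\n"))
  list(meta = meta, data = df)
}

#' Read and write kinematic series as CSV
#'
#' Columns `time_s`, `flap_rad`, `fold_rad` with a commented metadata
#' header carrying `f`, `theta0` and the fold onset. Round-trips through
#' [kinematic_series()].
#'
#' @param kin a [kinematic_series()].
#' @param path file path.
#' @return `read_kinematics_csv()` returns a [kinematic_series()].
#' @export
write_kinematics_csv <- function(kin, path) {
  stopifnot(inherits(kin, "kinematic_series"))
  write_meta_csv(data.frame(time_s = kin$time, flap_rad = kin$flap,
                            fold_rad = kin$fold),
                 path,
                 list(f_hz = kin$f, theta0_rad = kin$theta0,
                      fold_onset = kin$fold_onset))
  invisible(path)
}

#' @rdname write_kinematics_csv
#' @export
read_kinematics_csv <- function(path) {
  x <- read_meta_csv(path)
  kinematic_series(x$data$time_s, x$data$flap_rad, x$data$fold_rad,
                   f = x$meta$f_hz, theta0 = x$meta$theta0_rad,
                   fold_onset = x$meta$fold_onset)
}

#' Read and write force/power traces as CSV
#'
#' Two files per trace (`<stem>_force.csv`, `<stem>_power.csv`) because
#' the transducer (1000 Hz) and motor (512 Hz) channels run on different
#' clocks; both carry the trial metadata (condition, f, theta0, U).
#'
#' @param trace a [force_trace()].
#' @param stem path stem; `_force.csv` / `_power.csv` are appended.
#' @return `read_force_trace_csv()` returns a [force_trace()].
#' @export
write_force_trace_csv <- function(trace, stem) {
  stopifnot(inherits(trace, "force_trace"))
  meta <- list(condition = trace$condition, f_hz = trace$f,
               theta0_rad = trace$theta0, U_ms = trace$U)
  write_meta_csv(data.frame(time_s = trace$force$time, Fz_N = trace$force$Fz),
                 paste0(stem, "_force.csv"), meta)
  write_meta_csv(data.frame(time_s = trace$power$time, power_W = trace$power$P),
                 paste0(stem, "_power.csv"), meta)
  invisible(stem)
}

#' @rdname write_force_trace_csv
#' @export
read_force_trace_csv <- function(stem) {
  fx <- read_meta_csv(paste0(stem, "_force.csv"))
  px <- read_meta_csv(paste0(stem, "_power.csv"))
  force_trace(fx$data$time_s, fx$data$Fz_N, px$data$time_s, px$data$power_W,
              condition = fx$meta$condition, f = fx$meta$f_hz,
              theta0 = fx$meta$theta0_rad, U = fx$meta$U_ms)
}

#' Read and write phase-averaged field series as long-format CSV
#'
#' One row per (phase bin, z, x) node with mean velocities and the
#' variance/covariance fields; grid and flow metadata in the header.
#' Text-based so field series stay portable and versionable; intended
#' for the modest grids of phase-averaged data, not raw snapshots.
#'
#' @param fs a [field_series()].
#' @param path file path.
#' @return `read_field_series_csv()` returns a [field_series()].
#' @export
write_field_series_csv <- function(fs, path) {
  stopifnot(inherits(fs, "field_series"))
  idx <- expand.grid(bin = seq_len(fs$n_phase),
                     iz = seq_along(fs$z), ix = seq_along(fs$x))
  df <- data.frame(phase_bin = idx$bin,
                   z_m = fs$z[idx$iz], x_m = fs$x[idx$ix],
                   u_ms = fs$u[cbind(idx$bin, idx$iz, idx$ix)],
                   w_ms = fs$w[cbind(idx$bin, idx$iz, idx$ix)],
                   u_var = fs$u_var[cbind(idx$bin, idx$iz, idx$ix)],
                   w_var = fs$w_var[cbind(idx$bin, idx$iz, idx$ix)],
                   uw_cov = fs$uw_cov[cbind(idx$bin, idx$iz, idx$ix)])
  write_meta_csv(df, path,
                 list(U_ms = fs$U, f_hz = fs$f, rho = fs$rho,
                      n_phase = fs$n_phase, n_reps = fs$n_reps,
                      frame = "x downstream, z up"))
  invisible(path)
}

#' @rdname write_field_series_csv
#' @export
read_field_series_csv <- function(path) {
  r <- read_meta_csv(path)
  df <- r$data
  x <- sort(unique(df$x_m)); z <- sort(unique(df$z_m))
  np <- as.integer(r$meta$n_phase)
  shape <- c(np, length(z), length(x))
  ii <- cbind(df$phase_bin, match(df$z_m, z), match(df$x_m, x))
  mk <- function(col) { a <- array(NA_real_, shape); a[ii] <- col; a }
  field_series(x, z, mk(df$u_ms), mk(df$w_ms),
               U = r$meta$U_ms, f = r$meta$f_hz, rho = r$meta$rho,
               u_var = mk(df$u_var), w_var = mk(df$w_var),
               uw_cov = mk(df$uw_cov),
               n_reps = as.integer(r$meta$n_reps))
}
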