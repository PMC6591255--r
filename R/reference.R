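#' Reference (desired) EEG signal
#'
#' A uniform-grid desired trace `y_d(t)` for the tracking controllers, with
#' provenance `"model_background"` (simulated background state),
#' `"alpha_surrogate"` (band-limited noise standing in for a clinical
#' alpha-band recording) or `"file"` (user-supplied single-channel EEG).
#'
#' @param t uniform time grid (s).
#' @param y_d desired EEG values.
#' @param dt grid step (s).
#' @param provenance one of `"model_background"`, `"alpha_surrogate"`,
#'   `"file"`.
#' @return a `reference_signal` object.
#' @export
reference_signal <- function(t, y_d, dt,
                             provenance = c("model_background",
                                            "alpha_surrogate", "file")) {
  provenance <- match.arg(provenance)
  stopifnot(length(t) == length(y_d), dt > 0)
  structure(list(t = t, y_d = y_d, dt = dt, provenance = provenance),
            class = "reference_signal")
}

#' @export
print.reference_signal <- function(x, ...) {
  cat(sprintf("reference_signal (%s): %.3f s at dt = %g s\n",
              x$provenance, max(x$t), x$dt))
  invisible(x)
}

# reference values on the plant grid 0..nsteps*dt (linear interpolation,
# constant extrapolation at the edges)
resample_reference <- function(ref, dt, nsteps) {
  stopifnot(inherits(ref, "reference_signal"))
  tgrid <- seq(0, by = dt, length.out = nsteps + 1)
  if (max(ref$t) < tgrid[length(tgrid)] - 1e-9)
    stop("reference does not cover the full simulation duration")
  if (isTRUE(all.equal(ref$dt, dt)) && length(ref$y_d) >= nsteps + 1)
    return(ref$y_d[seq_len(nsteps + 1)])
  stats::approx(ref$t, ref$y_d, xout = tgrid, rule = 2)$y
}

#' Background-state reference trace
#'
#' Simulates the model from its stable background (LS) equilibrium with
#' Gaussian background noise on RE and returns the observed EEG as the
#' desired trace — the "normal EEG from an unaffected cortical area" of the
#' tracking formulation.  Errors if no stable low-saturated equilibrium
#' exists at the given parameters.
#'
#' @param params a [tc_params()] object.
#' @param duration trace length (s).
#' @param noise a [noise_spec()] (default sd 1 on RE, seed 1).
#' @param dt grid step (s).
#' @param cfg a [classification_config()] (supplies the LS/HS split level).
#' @return a `reference_signal` with provenance `"model_background"`.
#' @export
generate_background_reference <- function(params, duration,
                                          noise = noise_spec(sd = 1, seed = 1L),
                                          dt = 0.001,
                                          cfg = classification_config()) {
  eq <- find_equilibria(params)
  ls <- eq[eq$stable & eq$y < cfg$ls_hs_split, , drop = FALSE]
  if (!nrow(ls))
    stop("no stable background (LS) equilibrium at these parameters")
  x0 <- unlist(ls[1, c("PY", "IN", "TC", "RE")])
  traj <- simulate_tc(params, x0, duration, dt = dt, noise = noise)
  reference_signal(traj$t, traj$y, dt, "model_background")
}

#' Synthetic alpha-band surrogate reference
#'
#' Band-limited Gaussian noise centred on `center_freq`: seeded white noise
#' is band-pass filtered (4th-order Butterworth, zero-phase) to
#' `center_freq +/- bandwidth/2`, normalized to unit RMS and scaled by
#' `amplitude`.  Stands in for a clinical alpha-band scalp EEG channel so
#' that the alpha-tracking study case runs fully offline.
#'
#' @param duration trace length (s).
#' @param dt grid step (s), default 0.001.
#' @param center_freq centre frequency (Hz), default 12.
#' @param bandwidth full passband width (Hz), default 4; must satisfy
#'   `0 < bandwidth < center_freq`.
#' @param amplitude target RMS of the trace in model EEG units (default
#'   0.05, comparable to the model's oscillation range); doubling it
#'   doubles the RMS exactly.
#' @param seed RNG seed.
#' @return a `reference_signal` with provenance `"alpha_surrogate"`.
#' @export
generate_alpha_surrogate <- function(duration, dt = 0.001, center_freq = 12,
                                     bandwidth = 4, amplitude = 0.05,
                                     seed = 1L) {
  stopifnot(bandwidth > 0, bandwidth < center_freq, duration > 4 * dt)
  n <- as.integer(round(duration / dt)) + 1L
  if (amplitude == 0)
    return(reference_signal(seq(0, by = dt, length.out = n), numeric(n), dt,
                            "alpha_surrogate"))
  w <- with_seed(seed, stats::rnorm(n))
  fs <- 1 / dt
  band <- c(center_freq - bandwidth / 2, center_freq + bandwidth / 2) / (fs / 2)
  bf <- signal::butter(4, band, type = "pass")
  v <- signal::filtfilt(bf, w)
  v <- v - mean(v)
  v <- v / sqrt(mean(v^2)) * amplitude
  reference_signal(seq(0, by = dt, length.out = n), v, dt, "alpha_surrogate")
}

#' Load a reference trace from a single-channel CSV file
#'
#' Reads a two-column plain-text file (time in seconds, amplitude),
#' linearly resamples it to the plant grid step and optionally rescales it
#' to a stated RMS amplitude.
#'
#' @param path CSV file with a time column and an amplitude column.
#' @param resample_to_dt target grid step (s).
#' @param t_col,y_col column names or indices (defaults: first and second).
#' @param rescale_rms optional target RMS in model units (`NULL` keeps the
#'   file's scale).
#' @return a `reference_signal` with provenance `"file"`.
#' @export
load_reference_from_file <- function(path, resample_to_dt = 0.001,
                                     t_col = 1, y_col = 2,
                                     rescale_rms = NULL) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  df <- utils::read.csv(path)
  get_col <- function(col) {
    if (is.character(col) && !col %in% names(df))
      stop("column '", col, "' not found in ", path)
    if (is.numeric(col) && col > ncol(df))
      stop("file ", path, " has fewer than ", col, " columns")
    as.numeric(df[[col]])
  }
  tt <- get_col(t_col)
  vv <- get_col(y_col)
  if (anyNA(tt) || anyNA(vv)) stop("unparseable values in ", path)
  if (is.unsorted(tt)) stop("time column must be increasing in ", path)
  tgrid <- seq(0, max(tt) - min(tt), by = resample_to_dt)
  v <- stats::approx(tt - min(tt), vv, xout = tgrid, rule = 2)$y
  if (!is.null(rescale_rms)) {
    ctr <- v - mean(v)
    v <- ctr / sqrt(mean(ctr^2)) * rescale_rms + 0
  }
  reference_signal(tgrid, v, resample_to_dt, "file")
}

#' Export a reference trace to CSV (columns t, y)
#'
#' @param ref a `reference_signal`.
#' @param path output file.
#' @export
write_reference_csv <- function(ref, path) {
  stopifnot(inherits(ref, "reference_signal"))
  utils::write.csv(data.frame(t = ref$t, y = ref$y_d), path, row.names = FALSE)
  invisible(path)
}
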