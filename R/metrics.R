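#' Trailing-window summary statistics
#'
#' RMS, mean and standard deviation of a series over its trailing window
#' (the controllers' performance indexes are computed over the last 12 s of
#' a run by convention).
#'
#' @param x numeric series.
#' @param dt sampling step (s).
#' @param window trailing window length (s), default 12; must not exceed
#'   the series duration.
#' @return named list `rms`, `mean`, `sd`.
#' @export
summary_stats <- function(x, dt, window = 12) {
  n_win <- as.integer(round(window / dt))
  if (n_win < 1 || n_win > length(x))
    stop("window must be positive and no longer than the series")
  v <- x[(length(x) - n_win + 1):length(x)]
  list(rms = sqrt(mean(v^2)), mean = mean(v), sd = stats::sd(v))
}

#' Averaged-periodogram power spectral density
#'
#' Mean-removed averaged periodogram (Welch-style, rectangular window):
#' the series is split into `segment`-second segments with `overlap`
#' fraction overlap, each segment is demeaned and its one-sided
#' periodogram accumulated.  Normalization contract: the integral of the
#' PSD over frequency equals the series variance to within a few percent.
#'
#' @param y numeric series, at least 4 s long.
#' @param dt sampling step (s).
#' @param segment segment length (s), default 4.
#' @param overlap overlap fraction in [0, 1), default 0.5.
#' @return data.frame with `frequency` (Hz) and `psd` (power per Hz).
#' @export
power_spectral_density <- function(y, dt, segment = 4, overlap = 0.5) {
  n <- length(y)
  if (n * dt < 4) stop("series must be at least 4 s long")
  nseg <- min(as.integer(round(segment / dt)), n)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  nf <- nseg %/% 2
  acc <- numeric(nf)
  for (s0 in starts) {
    v <- y[s0:(s0 + nseg - 1L)]
    v <- v - mean(v)
    X <- stats::fft(v)[2:(nf + 1L)]
    # one-sided density: 2|X|^2 dt / n (Nyquist bin kept unscaled is a
    # negligible end effect at these lengths)
    acc <- acc + 2 * Mod(X)^2 * dt / nseg
  }
  data.frame(frequency = (1:nf) / (nseg * dt), psd = acc / length(starts))
}

#' Four-method controller comparison
#'
#' Runs the closed loop under identical seeds and disturbances for the
#' four control methods (1 feedback, 2 feedback+RBF, 3 feedback+SMC,
#' 4 hybrid) and assembles tracking-error and control-effort statistics
#' plus PSD tables of the EEG before control, after each method, and of
#' the desired trace.  Pure measurement: no assertions are made.
#'
#' @param case a case configuration from [case_config()].
#' @return a `performance_report`: list with `stats` (per-method
#'   data.frame of rms/mean/sd of `e` and `u`), `psd` (named list of PSD
#'   tables), `window` (evaluation window, s) and `case`.
#' @export
compare_methods <- function(case) {
  stopifnot(inherits(case, "swd_case_config"))
  methods <- c("feedback", "feedback+rbf", "feedback+smc", "hybrid")
  runs <- lapply(methods, function(mm) {
    cfg <- case$controller
    cfg$method <- mm
    closed_loop_simulate(case$params, case$initial, case$reference, cfg,
                         noise = case$noise, disturbance = case$disturbance,
                         duration = case$duration, dt = case$dt)
  })
  names(runs) <- methods
  stats_df <- do.call(rbind, lapply(methods, function(mm) {
    r <- runs[[mm]]
    se <- summary_stats(r$e, r$dt, case$window)
    su <- summary_stats(r$u, r$dt, case$window)
    data.frame(method = mm, rms_e = se$rms, mean_e = se$mean, sd_e = se$sd,
               rms_u = su$rms, mean_u = su$mean, sd_u = su$sd)
  }))
  open_loop <- simulate_tc(case$params, case$initial, case$duration,
                           dt = case$dt, noise = case$noise,
                           pulses = if (is.null(case$disturbance)) list()
                                    else case$disturbance)
  n_win <- as.integer(round(case$window / case$dt))
  tail_idx <- function(x) x[(length(x) - n_win + 1):length(x)]
  psd <- c(
    list(before_control = power_spectral_density(tail_idx(open_loop$y),
                                                 case$dt),
         y_d = power_spectral_density(
           tail_idx(resample_reference(case$reference, case$dt,
                                       as.integer(round(case$duration / case$dt)))),
           case$dt)),
    lapply(runs, function(r) power_spectral_density(tail_idx(r$y), case$dt))
  )
  structure(list(stats = stats_df, psd = psd, window = case$window,
                 case = case, runs = runs),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Controller comparison (trailing %g s window):\n", x$window))
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Study-case configuration
#'
#' Bundles everything [compare_methods()] needs: plant parameters, the
#' seizure-state initial condition, the reference trace, controller
#' settings, disturbances and the evaluation window.
#'
#' @param params a [tc_params()] object.
#' @param initial length-4 initial state.
#' @param reference a `reference_signal`.
#' @param controller a [controller_config()].
#' @param noise a [noise_spec()] or `NULL`.
#' @param disturbance pulse trains or `NULL`.
#' @param duration run length (s).
#' @param dt step (s).
#' @param window evaluation window (s), default 12.
#' @return a `swd_case_config` object.
#' @export
case_config <- function(params, initial, reference, controller,
                        noise = NULL, disturbance = NULL, duration = 20,
                        dt = 0.001, window = 12) {
  stopifnot(inherits(params, "tc_params"),
            inherits(reference, "reference_signal"),
            inherits(controller, "controller_config"),
            window <= duration)
  structure(list(params = params, initial = as_state(initial),
                 reference = reference, controller = controller,
                 noise = noise, disturbance = disturbance,
                 duration = duration, dt = dt, window = window),
            class = "swd_case_config")
}

#' Reference seizure-abatement study case
#'
#' Builds the bistable seizure-control setup used throughout the package:
#' plant at `c_tr = 0.6, c_te = 3` started in the SWD basin, Gaussian
#' background noise (sd 1) and a random pulse-train disturbance on RE, and
#' either the model-background reference (`case = 1`) or the alpha-band
#' surrogate (`case = 2`).
#'
#' @param case 1 (background-state reference) or 2 (alpha surrogate).
#' @param duration run length (s), default 20.
#' @param seed master seed; noise, disturbance and reference seeds are
#'   derived from it.
#' @param controller a [controller_config()] (default hybrid, switch-on at
#'   4 s).
#' @param dt step (s).
#' @return a `swd_case_config`.
#' @export
standard_case <- function(case = 1, duration = 20, seed = 1L,
                          controller = controller_config("hybrid"),
                          dt = 0.001) {
  params <- tc_params(c_tr = 0.6, c_te = 3)
  initial <- find_basin_state(params, "SWD", seed = 101L)
  reference <- if (case == 1) {
    generate_background_reference(params, duration,
                                  noise = noise_spec(sd = 1, seed = seed + 1000L),
                                  dt = dt)
  } else {
    generate_alpha_surrogate(duration, dt = dt, seed = seed + 2000L)
  }
  case_config(params, initial, reference, controller,
              noise = noise_spec(sd = 1, seed = seed),
              disturbance = random_pulse_series(duration, seed = seed + 500L),
              duration = duration, dt = dt)
}
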