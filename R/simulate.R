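#' Pulse train specification
#'
#' Rectangular stimulation/disturbance pulses applied additively to one or
#' more populations.  Each pulse holds `amplitude` on its targets while
#' `t` is within `[onset, onset + width)`.
#'
#' @param onset_times numeric vector of pulse onsets (s), non-negative.
#' @param amplitude signed pulse amplitude (dimensionless input units).
#' @param width pulse duration (s), > 0.  Default 0.02 s.
#' @param target populations receiving the pulse, subset of
#'   `c("PY","IN","TC","RE")`; default `"RE"` (the paper's stimulation site).
#' @return a `pulse_train` object.
#' @export
pulse_train <- function(onset_times, amplitude, width = 0.02, target = "RE") {
  stopifnot(is.numeric(onset_times), all(onset_times >= 0),
            !is.unsorted(onset_times), length(amplitude) == 1L,
            is.finite(amplitude), width > 0)
  target <- match.arg(target, c("PY", "IN", "TC", "RE"), several.ok = TRUE)
  structure(list(onset_times = as.numeric(onset_times),
                 amplitude = amplitude, width = width, target = target),
            class = "pulse_train")
}

#' Random pulse-series disturbance
#'
#' Generates the "randomly distributed pulses" used to model unexpected
#' projections from other brain areas: Poisson arrivals, rectangular
#' pulses of random sign, applied to RE by default.
#'
#' @param duration time span (s) over which arrivals are drawn.
#' @param rate Poisson arrival rate (pulses/s), default 0.25.
#' @param amplitude magnitude of each pulse (sign drawn at random), default
#'   25: a 20 ms pulse then displaces RE by ~0.5, enough to cross basin
#'   boundaries at the reference bistable operating point, so disturbances
#'   genuinely re-evoke seizures.
#' @param width pulse width (s), default 0.02.
#' @param target population, default "RE".
#' @param seed integer seed for the arrival/sign draws.
#' @return list of `pulse_train` objects (one per sign realization).
#' @export
random_pulse_series <- function(duration, rate = 0.25, amplitude = 25,
                                width = 0.02, target = "RE", seed = 1L) {
  stopifnot(duration > 0, rate >= 0)
  draws <- with_seed(seed, {
    n <- stats::rpois(1, rate * duration)
    list(times = sort(stats::runif(n, 0, duration)),
         signs = sample(c(-1, 1), n, replace = TRUE))
  })
  if (length(draws$times) == 0) return(list())
  out <- list()
  for (sg in c(-1, 1)) {
    keep <- draws$signs == sg
    if (any(keep))
      out[[length(out) + 1L]] <- pulse_train(draws$times[keep],
                                             sg * amplitude, width, target)
  }
  out
}

#' Gaussian background-noise specification
#'
#' Zero-order-hold Gaussian noise: one draw per integration step, held
#' constant across the step's RK4 stages, entering the target population's
#' derivative additively.  The standard deviation is in input units per
#' step (not scaled by sqrt(dt)), so the effective noise power depends on
#' the step size; with the reference dt = 1 ms and sd = 1 the background
#' state fluctuates weakly around its fixed point.
#'
#' @param sd standard deviation (>= 0), default 1.
#' @param mean mean, default 0.
#' @param target population, default "RE".
#' @param seed integer seed.
#' @return a `noise_spec` object.
#' @export
noise_spec <- function(sd = 1, mean = 0, target = "RE", seed = 1L) {
  stopifnot(sd >= 0, is.finite(mean))
  target <- match.arg(target, c("PY", "IN", "TC", "RE"), several.ok = TRUE)
  structure(list(sd = sd, mean = mean, target = target, seed = as.integer(seed)),
            class = "noise_spec")
}

# evaluate seed-scoped expression without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

pop_index <- c(PY = 1L, IN = 2L, TC = 3L, RE = 4L)

# assemble the 4 x nsteps zero-order-hold exogenous disturbance matrix
build_exogenous <- function(nsteps, dt, pulses = list(), noise = NULL) {
  exo <- matrix(0, nrow = 4, ncol = nsteps)
  if (inherits(pulses, "pulse_train")) pulses <- list(pulses)
  for (pl in pulses) {
    stopifnot(inherits(pl, "pulse_train"))
    tgrid <- (seq_len(nsteps) - 1) * dt
    on <- rep(FALSE, nsteps)
    for (t0 in pl$onset_times)
      on <- on | (tgrid >= t0 & tgrid < t0 + pl$width)
    for (tg in pl$target)
      exo[pop_index[[tg]], on] <- exo[pop_index[[tg]], on] + pl$amplitude
  }
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (noise$sd > 0 || noise$mean != 0) {
      draws <- with_seed(noise$seed, stats::rnorm(nsteps, noise$mean, noise$sd))
      for (tg in noise$target)
        exo[pop_index[[tg]], ] <- exo[pop_index[[tg]], ] + draws
    }
  }
  exo
}

#' One fixed-step RK4 integration step
#'
#' Advances the model one classical fourth-order Runge-Kutta step.  The
#' exogenous additive input is held constant across the four stages
#' (zero-order hold) and enters the derivative directly.
#'
#' @param state length-4 state vector.
#' @param params a [tc_params()] object.
#' @param dt step size (s), > 0.
#' @param exogenous additive input per population (scalar 0 or length 4).
#' @return the advanced state (named length-4 vector).
#' @export
integrate_step <- function(state, params, dt, exogenous = 0) {
  x <- as_state(state)
  stopifnot(inherits(params, "tc_params"), dt > 0)
  w <- if (identical(exogenous, 0)) numeric(4) else as.numeric(exogenous)
  if (length(w) != 4L) stop("exogenous must be scalar 0 or length 4")
  out <- .rk4_step_cpp(x, unclass(params), dt, w)
  if (!all(is.finite(out))) {
    bad <- c("PY", "IN", "TC", "RE")[!is.finite(out)][1]
    stop("integration step diverged: component ", bad, " is non-finite")
  }
  stats::setNames(out, c("PY", "IN", "TC", "RE"))
}

#' Simulate the thalamocortical model
#'
#' Fixed-step RK4 integration on a uniform grid with optional rectangular
#' pulse trains, zero-order-hold Gaussian noise and a precomputed control
#' input.  Identical seeds reproduce trajectories bit-for-bit.
#'
#' @param params a [tc_params()] object.
#' @param initial length-4 initial state.
#' @param duration total simulated time (s), > dt.
#' @param dt integration step (s), default 0.001 (1 ms).
#' @param pulses a `pulse_train` or list of them (default none).
#' @param noise a [noise_spec()] or `NULL`.
#' @param control optional numeric vector of per-step control values (length
#'   `duration/dt`), applied additively to the populations in
#'   `control_targets`; mostly used internally by the closed-loop runner.
#' @param control_targets populations receiving `control`,
#'   default `c("PY","IN")`.
#' @return a `tc_trajectory`: list with uniform grid `t`, state matrix
#'   `states` (columns PY, IN, TC, RE), observed EEG `y`, applied control
#'   `u`, applied RE-disturbance `d`, and step size `dt`.
#' @export
simulate_tc <- function(params, initial, duration, dt = 0.001,
                        pulses = list(), noise = NULL, control = NULL,
                        control_targets = c("PY", "IN")) {
  stopifnot(inherits(params, "tc_params"), duration > dt, dt > 0)
  x0 <- as_state(initial)
  nsteps <- as.integer(round(duration / dt))
  exo <- build_exogenous(nsteps, dt, pulses, noise)
  if (!is.null(control)) {
    stopifnot(length(control) >= nsteps)
    for (tg in control_targets)
      exo[pop_index[[tg]], ] <- exo[pop_index[[tg]], ] + control[seq_len(nsteps)]
  }
  res <- .sim_core_cpp(unclass(params), x0, dt, nsteps, exo,
                       0L, numeric(0), 0, 0, 0, 0, numeric(0), 1, 1,
                       0L, integer(0), numeric(4), numeric(0), 0)
  new_trajectory(res, params, dt, nsteps, exo,
                 u = if (is.null(control)) numeric(nsteps + 1)
                     else c(control[seq_len(nsteps)], control[nsteps]))
}

new_trajectory <- function(res, params, dt, nsteps, exo, u = NULL) {
  states <- res$states
  colnames(states) <- c("PY", "IN", "TC", "RE")
  structure(list(
    t = seq(0, by = dt, length.out = nsteps + 1),
    states = states,
    y = as.numeric(res$y),
    u = if (is.null(u)) as.numeric(res$u) else u,
    d = c(exo[4L, ], exo[4L, nsteps]),
    dt = dt,
    params = params
  ), class = "tc_trajectory")
}

#' @export
print.tc_trajectory <- function(x, ...) {
  cat(sprintf("tc_trajectory: %.3f s at dt = %g s (%d samples)\n",
              max(x$t), x$dt, length(x$t)))
  cat(sprintf("  y range [%.4f, %.4f]\n", min(x$y), max(x$y)))
  invisible(x)
}

#' @export
as.data.frame.tc_trajectory <- function(x, ...) {
  data.frame(t = x$t, PY = x$states[, 1], IN = x$states[, 2],
             TC = x$states[, 3], RE = x$states[, 4],
             y = x$y, u = x$u, d = x$d)
}

#' Export a trajectory to CSV
#'
#' Columns: `t, PY, IN, TC, RE, y, u, d`.
#'
#' @param traj a `tc_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "tc_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Single-pulse state-transition experiment
#'
#' Runs a noise-free simulation with a train of single pulses (on RE by
#' default) and classifies the dynamical regime on each inter-pulse segment,
#' exposing pulse-induced transitions between coexisting attractors
#' (e.g. SWD to background and back).
#'
#' @param params a [tc_params()] object.
#' @param initial length-4 initial state.
#' @param pulses a `pulse_train` or list of them.
#' @param duration total time (s).
#' @param dt step (s), default 0.001.
#' @param cfg a [classification_config()].
#' @param settle time (s) after each pulse excluded from segment
#'   classification (transient re-equilibration), default 2.
#' @return list with the `trajectory` and `segments`, a data.frame of
#'   per-segment start/end times and state labels.
#' @export
single_pulse_experiment <- function(params, initial, pulses, duration,
                                    dt = 0.001, cfg = classification_config(),
                                    settle = 2) {
  traj <- simulate_tc(params, initial, duration, dt = dt, pulses = pulses)
  if (inherits(pulses, "pulse_train")) pulses <- list(pulses)
  onsets <- sort(unique(unlist(lapply(pulses, `[[`, "onset_times"))))
  edges <- c(0, onsets, duration)
  segs <- data.frame(start = utils::head(edges, -1), end = utils::tail(edges, -1))
  labs <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    sel <- traj$t >= segs$start[i] & traj$t <= segs$end[i]
    seg_cfg <- cfg
    seg_cfg$transient_discard <- min(if (i == 1) cfg$transient_discard else settle,
                                     max((segs$end[i] - segs$start[i]) / 2, dt))
    labs[[i]] <- classify_series(traj$y[sel], dt, seg_cfg)
  }
  segs$label <- vapply(labs, format_label, character(1))
  list(trajectory = traj, segments = segs, labels = labs)
}

#' Search for a state-switching single pulse
#'
#' Sweeps a coarse grid of pulse amplitudes (both signs as supplied) and
#' onset phases within one oscillation cycle, returning the first single
#' pulse on RE that converts the running regime into the requested target
#' regime.  Mirrors the single-pulse stimulation protocol: transitions
#' between coexisting attractors depend on both the pulse and its timing.
#'
#' @param params a [tc_params()] object.
#' @param initial initial state (on the source attractor's basin).
#' @param target_kind label kind to reach (`"LS"`, `"SWD"`, `"CO"`, ...).
#' @param target_m spike count to reach (SWD only; `NA` accepts any).
#' @param amplitudes candidate pulse amplitudes (signed).
#' @param onset,onset_span earliest onset (s) and the span over which the
#'   onset phase is swept.
#' @param n_phases number of onset phases tried.
#' @param width pulse width (s).
#' @param duration total simulated time per trial (s).
#' @param dt step (s).
#' @param cfg a [classification_config()].
#' @return list with `pulse` (the successful [pulse_train()]), `label`
#'   (the reached [state_label()]) and `experiment` (the
#'   [single_pulse_experiment()] record); error if no grid point switches.
#' @export
find_switching_pulse <- function(params, initial, target_kind, target_m = NA,
                                 amplitudes = c(-10, -25, -50, 10, 25, 50),
                                 onset = 10, onset_span = 0.4, n_phases = 10,
                                 width = 0.02, duration = 20, dt = 0.001,
                                 cfg = classification_config()) {
  phases <- onset + seq(0, onset_span, length.out = n_phases)
  for (A in amplitudes) for (ph in phases) {
    ex <- tryCatch(
      single_pulse_experiment(params, initial, pulse_train(ph, A, width, "RE"),
                              duration, dt = dt, cfg = cfg),
      error = function(e) NULL)
    if (is.null(ex)) next
    lab <- ex$labels[[length(ex$labels)]]
    if (lab$kind == target_kind &&
        (is.na(target_m) || identical(lab$m, as.integer(target_m))))
      return(list(pulse = pulse_train(ph, A, width, "RE"), label = lab,
                  experiment = ex))
  }
  stop("no pulse on the amplitude/phase grid reaches ", target_kind)
}
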