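#' Controller configuration
#'
#' Settings of the closed-loop tracking controllers that drive the
#' pathological cortical EEG `y` toward a desired normal trace `y_d`.
#' The sliding variable is the tracking error `s = e = y - y_d`; the four
#' controller laws are
#' \itemize{
#'   \item `feedback`: \eqn{u = -\lambda s}
#'   \item `feedback+rbf`: \eqn{u = -\lambda s - \hat\theta^T \phi(s)}
#'     (RBF network approximating the unknown drift, adaptive weights)
#'   \item `feedback+smc`: \eqn{u = -\lambda s - \rho z} (sliding-mode
#'     switching term, low-pass filtered to avoid chattering)
#'   \item `hybrid`: \eqn{u = -\lambda s - \hat\theta^T \phi(s) - \rho z}
#' }
#' The control signal is applied to the PY and IN populations
#' (`u_1 = u_2 = u`, `u_3 = u_4 = 0`), modelling cortical stimulation.
#' A fifth method, `feedback+smc-raw`, replaces the filtered `z` with the
#' raw `sign(s)` and exists to quantify chattering; it is not a primary
#' method.
#'
#' @param method one of `"feedback"`, `"feedback+rbf"`, `"feedback+smc"`,
#'   `"hybrid"`, `"feedback+smc-raw"`.
#' @param lam reaching-law gain \eqn{\lambda \ge 0} (default 1; 0 turns
#'   the feedback term off, giving a null controller for equivalence checks).
#' @param rho switching gain \eqn{\rho \ge 0} (default 1).
#' @param k_c leakage gain of the adaptive law (default 1).
#' @param gamma adaptation rate \eqn{\gamma > 0} (default 10).
#' @param n_nodes RBF node count m (default 11).
#' @param width Gaussian width p of the RBF nodes (default 1).
#' @param centers RBF centers; default `n_nodes` points uniformly spaced on
#'   \eqn{[-1, 1]} of the sliding variable.
#' @param tau_filter time constant of the first-order low-pass filter on
#'   `sign(s)` (s, default 0.01).
#' @param switch_on_time time at which the controller activates (s,
#'   default 4); `u = 0` before.
#' @param targets populations receiving `u` (default PY and IN).
#' @return a `controller_config` object.
#' @export
controller_config <- function(method = c("hybrid", "feedback", "feedback+rbf",
                                         "feedback+smc", "feedback+smc-raw"),
                              lam = 1, rho = 1, k_c = 1, gamma = 10,
                              n_nodes = 11, width = 1, centers = NULL,
                              tau_filter = 0.01, switch_on_time = 4,
                              targets = c("PY", "IN")) {
  method <- match.arg(method)
  stopifnot(lam >= 0, rho >= 0, k_c > 0, gamma > 0, n_nodes >= 1,
            width > 0, tau_filter > 0, switch_on_time >= 0)
  if (is.null(centers)) {
    centers <- if (n_nodes == 1) 0 else seq(-1, 1, length.out = n_nodes)
  }
  stopifnot(length(centers) == n_nodes)
  targets <- match.arg(targets, c("PY", "IN", "TC", "RE"), several.ok = TRUE)
  structure(list(method = method, lam = lam, rho = rho, k_c = k_c,
                 gamma = gamma, n_nodes = as.integer(n_nodes), width = width,
                 centers = as.numeric(centers), tau_filter = tau_filter,
                 switch_on_time = switch_on_time, targets = targets),
            class = "controller_config")
}

method_code <- function(method) {
  c("feedback" = 1L, "feedback+rbf" = 2L, "feedback+smc" = 3L,
    "hybrid" = 4L, "feedback+smc-raw" = 5L)[[method]]
}

#' Sliding surface (tracking error)
#'
#' \eqn{s(e, t) = e = y - y_d}: the sliding variable equals the output
#' tracking error.
#'
#' @param y observed EEG.
#' @param y_d desired EEG.
#' @return `y - y_d` (vectorized).
#' @export
sliding_surface <- function(y, y_d) y - y_d

#' Switching sign law
#'
#' Returns +1 for `s >= 0` and -1 for `s < 0` (the convention fixes
#' `sign(0) = +1`).
#'
#' @param s sliding variable (vectorized).
#' @export
sign_law <- function(s) ifelse(s >= 0, 1, -1)

#' Gaussian RBF basis
#'
#' \eqn{\phi_j(s) = \exp(-(s - c_j)^2 / (2 w^2))}; entries in (0, 1], equal
#' to 1 exactly at the centers.
#'
#' @param s sliding variable (scalar).
#' @param centers node centers.
#' @param width Gaussian width, > 0.
#' @return numeric vector of basis responses.
#' @export
rbf_basis <- function(s, centers, width = 1) {
  stopifnot(width > 0)
  exp(-((s - centers)^2) / (2 * width^2))
}

#' One explicit-Euler step of the adaptive weight law
#'
#' \eqn{\dot{\hat\theta} = \gamma s \phi - k_c \gamma |s| \hat\theta}:
#' gradient adaptation with a sigma-modification leakage term that keeps
#' the weights bounded, discretized by explicit Euler at the plant step.
#' The gradient term carries the stabilizing sign required by the
#' Lyapunov cancellation of the weight-error cross terms (s > 0 grows the
#' weights, which lowers \eqn{u = -\lambda s - \hat\theta^T\phi}).
#'
#' @param theta_hat current weight vector.
#' @param s sliding variable.
#' @param phi RBF basis vector (same length as `theta_hat`).
#' @param gamma adaptation rate.
#' @param k_c leakage gain.
#' @param dt step (s), > 0.
#' @return updated weight vector.
#' @export
update_nn_weights <- function(theta_hat, s, phi, gamma, k_c, dt) {
  stopifnot(dt > 0, length(theta_hat) == length(phi))
  out <- theta_hat + dt * (gamma * s * phi - k_c * gamma * abs(s) * theta_hat)
  if (!all(is.finite(out))) stop("adaptive weight vector became non-finite")
  out
}

#' One step of the switching-term low-pass filter
#'
#' \eqn{\tau \dot z = -z + \mathrm{sign}(s)}, advanced by the exact
#' exponential update \eqn{z \leftarrow \mathrm{sign}(s) + (z -
#' \mathrm{sign}(s)) e^{-dt/\tau}} so that the discretization is stable for
#' any `dt`.
#'
#' @param z current filter state.
#' @param s sliding variable.
#' @param tau_filter filter time constant (s), > 0.
#' @param dt step (s), > 0.
#' @return updated filter state.
#' @export
lpf_step <- function(z, s, tau_filter, dt) {
  stopifnot(tau_filter > 0, dt > 0)
  sgn <- sign_law(s)
  sgn + (z - sgn) * exp(-dt / tau_filter)
}

#' Controller output
#'
#' Evaluates the control law of the configured method from the current
#' controller state (sliding variable `s_value`, weights `theta_hat`,
#' filter state `z`).
#'
#' @param cfg a [controller_config()].
#' @param state list with `s_value`, and `theta_hat` / `z` as required by
#'   the method.
#' @return scalar control value `u`.
#' @export
control_output <- function(cfg, state) {
  stopifnot(inherits(cfg, "controller_config"))
  s <- state$s_value
  u <- -cfg$lam * s
  if (cfg$method %in% c("feedback+rbf", "hybrid")) {
    phi <- rbf_basis(s, cfg$centers, cfg$width)
    u <- u - sum(state$theta_hat * phi)
  }
  if (cfg$method %in% c("feedback+smc", "hybrid")) u <- u - cfg$rho * state$z
  if (cfg$method == "feedback+smc-raw") u <- u - cfg$rho * sign_law(s)
  u
}

#' Closed-loop tracking simulation
#'
#' Runs the plant and controller together on the fixed grid.  Per step:
#' the EEG is measured, `s = y - y_d(t)` is formed, the switching filter
#' and adaptive weights are updated, `u` is computed and injected into the
#' PY and IN derivatives, and the plant advances one RK4 step with `u` and
#' the disturbances held constant across the stages.  Before
#' `switch_on_time` the controller is off (`u = 0`; weights stay at their
#' initial zeros).  All randomness is seeded through the noise and
#' disturbance specifications.
#'
#' @param params a [tc_params()] object.
#' @param initial length-4 initial state (typically an SWD-basin state).
#' @param reference a `reference_signal` covering the full duration.
#' @param cfg a [controller_config()].
#' @param noise a [noise_spec()] or `NULL`.
#' @param disturbance a `pulse_train`, list of them, or `NULL`.
#' @param duration total time (s).
#' @param dt step (s), default 0.001.
#' @param theta0 initial weight vector (default zeros).
#' @return a `closed_loop_result`: the fields of a `tc_trajectory` plus
#'   `y_d`, `e`, `z` and (for adaptive methods) the `theta` history.
#' @export
closed_loop_simulate <- function(params, initial, reference, cfg,
                                 noise = NULL, disturbance = NULL,
                                 duration, dt = 0.001, theta0 = NULL) {
  stopifnot(inherits(params, "tc_params"), inherits(cfg, "controller_config"),
            inherits(reference, "reference_signal"), duration > dt)
  nsteps <- as.integer(round(duration / dt))
  yd <- resample_reference(reference, dt, nsteps)
  exo <- build_exogenous(nsteps, dt,
                         pulses = if (is.null(disturbance)) list() else disturbance,
                         noise = noise)
  mask <- as.numeric(c("PY", "IN", "TC", "RE") %in% cfg$targets)
  if (is.null(theta0)) theta0 <- numeric(cfg$n_nodes)
  res <- .sim_core_cpp(unclass(params), as_state(initial), dt, nsteps, exo,
                       method_code(cfg$method), yd,
                       cfg$lam, cfg$rho, cfg$k_c, cfg$gamma,
                       cfg$centers, cfg$width, cfg$tau_filter,
                       as.integer(round(cfg$switch_on_time / dt)),
                       integer(0), mask, as.numeric(theta0), 0)
  out <- new_trajectory(res, params, dt, nsteps, exo)
  out$u <- as.numeric(res$u)
  out$y_d <- yd
  out$e <- out$y - yd
  out$z <- as.numeric(res$z)
  if (!is.null(res$theta)) out$theta <- res$theta
  out$config <- cfg
  class(out) <- c("closed_loop_result", "tc_trajectory")
  out
}

#' Export a closed-loop result to CSV
#'
#' Columns: `t, y, y_d, e, u, d` (plus `var_window` and `trigger_state`
#' when the result comes from [variance_trigger_control()]).
#'
#' @param result a `closed_loop_result`.
#' @param path output file.
#' @export
write_closed_loop_csv <- function(result, path) {
  stopifnot(inherits(result, "closed_loop_result"))
  df <- data.frame(t = result$t, y = result$y, y_d = result$y_d,
                   e = result$e, u = result$u, d = result$d)
  if (!is.null(result$var_window)) df$var_window <- result$var_window
  if (!is.null(result$trigger_state)) df$trigger_state <- result$trigger_state
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Trigger configuration for on-demand control
#'
#' The moving-window variance of the EEG serves as a seizure indicator:
#' when `Var(y)` exceeds `var_threshold` continuously for at least
#' `sustain` seconds, a seizure is declared and the feedback control is
#' switched on for `action_duration` seconds.
#'
#' @param var_threshold variance threshold (default 0.002).
#' @param window variance window length (s, default 0.5).
#' @param step window sliding step (s, default 0.05).
#' @param sustain minimum above-threshold span before triggering (s,
#'   default 0.1).
#' @param action_duration control-on span per trigger (s, default 1).
#' @return a `trigger_config` object.
#' @export
trigger_config <- function(var_threshold = 0.002, window = 0.5, step = 0.05,
                           sustain = 0.1, action_duration = 1) {
  stopifnot(var_threshold > 0, window > 0, step > 0, sustain > 0,
            action_duration > 0, window > step)
  structure(list(var_threshold = var_threshold, window = window, step = step,
                 sustain = sustain, action_duration = action_duration),
            class = "trigger_config")
}

#' Variance-triggered on-demand feedback control
#'
#' Simulates the plant with disturbances while monitoring the moving-window
#' variance of the EEG; when the variance stays above threshold for the
#' sustain span, the feedback controller (`u = -lambda s`) is enabled for
#' `action_duration` seconds, then disabled again.  Trigger on/off events
#' are logged with timestamps.
#'
#' @param params,initial,reference,cfg,noise,disturbance,duration,dt as in
#'   [closed_loop_simulate()] (`cfg$method` is forced to `"feedback"`).
#' @param trigger a [trigger_config()]; `trigger$window` must be shorter
#'   than `duration`.
#' @return a `closed_loop_result` with additional fields `var_window`
#'   (variance series, evaluated on the step grid; `NA` before the first
#'   full window), `trigger_state` (0/1 control-enabled series) and
#'   `events` (data.frame of trigger times).
#' @export
variance_trigger_control <- function(params, initial, reference, cfg,
                                     trigger = trigger_config(), noise = NULL,
                                     disturbance = NULL, duration, dt = 0.001) {
  stopifnot(inherits(trigger, "trigger_config"), trigger$window < duration)
  cfg$method <- "feedback"
  cfg$switch_on_time <- 0
  nsteps <- as.integer(round(duration / dt))
  yd <- resample_reference(reference, dt, nsteps)
  exo <- build_exogenous(nsteps, dt,
                         pulses = if (is.null(disturbance)) list() else disturbance,
                         noise = noise)
  mask <- as.numeric(c("PY", "IN", "TC", "RE") %in% cfg$targets)

  chunk <- as.integer(round(trigger$step / dt))
  win <- as.integer(round(trigger$window / dt))
  sustain_evals <- max(1L, as.integer(ceiling(trigger$sustain / trigger$step)))
  action_steps <- as.integer(round(trigger$action_duration / dt))

  x <- as_state(initial)
  y_all <- numeric(nsteps + 1)
  u_all <- numeric(nsteps + 1)
  states_all <- matrix(0, nsteps + 1, 4,
                       dimnames = list(NULL, c("PY", "IN", "TC", "RE")))
  var_all <- rep(NA_real_, nsteps + 1)
  trig_all <- integer(nsteps + 1)
  states_all[1, ] <- x
  y_all[1] <- eeg_observation(x, params)
  events <- list()
  streak <- 0L
  off_step <- -1L   # control enabled while step index < off_step
  i <- 0L
  while (i < nsteps) {
    n_sub <- min(chunk, nsteps - i)
    enabled <- i < off_step
    idx <- (i + 1):(i + n_sub)
    res <- .sim_core_cpp(unclass(params), x, dt, n_sub,
                         exo[, idx, drop = FALSE],
                         if (enabled) 1L else 0L, yd[c(idx, i + n_sub + 1)],
                         cfg$lam, cfg$rho, cfg$k_c, cfg$gamma,
                         cfg$centers, cfg$width, cfg$tau_filter,
                         0L, integer(0), mask, numeric(cfg$n_nodes), 0)
    sub_states <- res$states
    states_all[idx + 1, ] <- sub_states[-1, , drop = FALSE]
    y_all[idx + 1] <- res$y[-1]
    u_all[idx] <- if (enabled) res$u[-length(res$u)] else 0
    trig_all[idx] <- as.integer(enabled)
    x <- sub_states[nrow(sub_states), ]
    i <- i + n_sub
    # evaluate the moving-window variance at this chunk boundary
    if (i + 1 >= win) {
      v <- stats::var(y_all[(i + 1 - win + 1):(i + 1)])
      var_all[i + 1] <- v
      if (!enabled) {
        if (v > trigger$var_threshold) streak <- streak + 1L else streak <- 0L
        if (streak >= sustain_evals) {
          off_step <- i + action_steps
          events[[length(events) + 1L]] <-
            data.frame(time = i * dt, event = "trigger_on")
          streak <- 0L
        }
      } else if (i >= off_step) {
        events[[length(events) + 1L]] <-
          data.frame(time = i * dt, event = "trigger_off")
      }
    }
  }
  u_all[nsteps + 1] <- u_all[nsteps]
  out <- structure(list(
    t = seq(0, by = dt, length.out = nsteps + 1),
    states = states_all, y = y_all, u = u_all,
    d = c(exo[4L, ], exo[4L, nsteps]), dt = dt, params = params,
    y_d = yd, e = y_all - yd, var_window = var_all,
    trigger_state = trig_all, config = cfg, trigger = trigger,
    events = if (length(events)) do.call(rbind, events)
             else data.frame(time = numeric(0), event = character(0))
  ), class = c("closed_loop_result", "tc_trajectory"))
  out
}

#' Lyapunov-style diagnostics of a closed-loop run
#'
#' Computes the computable part of the stability certificate: the tracking
#' term \eqn{\frac{1}{2} s^2} and, for adaptive methods, the surrogate
#' \eqn{\hat V(t) = \frac{1}{2} s^2 + \frac{1}{2\gamma}
#' \hat\theta^T\hat\theta} (the true certificate uses the unknowable weight
#' error; the surrogate is used to check eventual boundedness).
#'
#' @param result a `closed_loop_result`.
#' @param cfg the [controller_config()] used (defaults to the one stored in
#'   the result).
#' @return data.frame with `t`, `half_s2` and `V_hat` (equal to `half_s2`
#'   when no weight history is present).
#' @export
lyapunov_diagnostics <- function(result, cfg = result$config) {
  stopifnot(inherits(result, "closed_loop_result"))
  half_s2 <- 0.5 * result$e^2
  V_hat <- half_s2
  if (!is.null(result$theta))
    V_hat <- half_s2 + rowSums(result$theta^2) / (2 * cfg$gamma)
  data.frame(t = result$t, half_s2 = half_s2, V_hat = V_hat)
}
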