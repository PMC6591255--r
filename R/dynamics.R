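set_param <- function(params, axis, value) {
  do.call(update_params, c(list(params), stats::setNames(list(value), axis)))
}

#' Parameterized vector field interface
#'
#' Wraps right-hand side and Jacobian functions of `(x, p)` — state and a
#' scalar bifurcation parameter — for use with [continue_equilibria()],
#' [detect_hopf()] and [estimate_double_cycle()].  [tc_field()] builds the
#' thalamocortical field along one named model parameter; custom fields
#' (e.g. normal forms) can be supplied for validation.
#'
#' @param rhs function(x, p) returning the state derivative.
#' @param jac function(x, p) returning the Jacobian matrix (may be `NULL`,
#'   in which case central finite differences are used).
#' @param dim state dimension.
#' @return a `vector_field` object.
#' @export
vector_field <- function(rhs, jac = NULL, dim) {
  if (is.null(jac)) {
    jac <- function(x, p) num_jacobian(function(z) rhs(z, p), x)
  }
  structure(list(rhs = rhs, jac = jac, dim = as.integer(dim)),
            class = "vector_field")
}

#' @rdname vector_field
#' @param params a [tc_params()] object.
#' @param axis name of the model parameter to vary (e.g. `"c_tr"`).
#' @export
tc_field <- function(params, axis) {
  stopifnot(inherits(params, "tc_params"), axis %in% names(params))
  vector_field(
    rhs = function(x, p) unname(model_rhs(x, set_param(params, axis, p))),
    jac = function(x, p) unname(model_jacobian(x, set_param(params, axis, p))),
    dim = 4L
  )
}

num_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    hp <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hp
    xm <- x; xm[j] <- xm[j] - hp
    J[, j] <- (f(xp) - f(xm)) / (2 * hp)
  }
  J
}

# damped Newton on a general square system
newton_solve <- function(f, jac, x0, tol = 1e-12, maxit = 100) {
  x <- x0
  r <- f(x)
  for (it in seq_len(maxit)) {
    if (sqrt(sum(r^2)) < tol) return(list(x = x, residual = sqrt(sum(r^2)),
                                          converged = TRUE))
    step <- tryCatch(solve(jac(x), -r), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x + lam * step
      rn <- tryCatch(f(xn), error = function(e) rep(Inf, length(r)))
      if (all(is.finite(rn)) &&
          (sqrt(sum(rn^2)) < sqrt(sum(r^2)) || lam < 1e-4)) break
      lam <- lam / 2
    }
    if (!all(is.finite(rn)) || (lam < 1e-4 && sqrt(sum(rn^2)) >= sqrt(sum(r^2))))
      break    # stagnated: bail out instead of burning iterations
    x <- xn; r <- rn
  }
  list(x = x, residual = sqrt(sum(r^2)), converged = sqrt(sum(r^2)) < tol)
}

#' Find an equilibrium of the model
#'
#' Newton iteration with the analytic Jacobian from a supplied guess; the
#' returned point satisfies `||model_rhs|| < 1e-10`.
#'
#' @param params a [tc_params()] object.
#' @param guess length-4 starting state.
#' @param tol residual tolerance (default 1e-12, required < 1e-10).
#' @return named length-4 equilibrium state.
#' @export
find_equilibrium <- function(params, guess, tol = 1e-12) {
  stopifnot(inherits(params, "tc_params"))
  x0 <- as_state(guess)
  sol <- newton_solve(function(x) unname(model_rhs(x, params)),
                      function(x) unname(model_jacobian(x, params)),
                      unname(x0), tol = tol)
  if (!sol$converged && sol$residual > 1e-10)
    stop(sprintf("equilibrium search did not converge (last residual %.3e)",
                 sol$residual))
  stats::setNames(sol$x, c("PY", "IN", "TC", "RE"))
}

#' Locate all equilibria on a deterministic guess grid
#'
#' Exploits the model's triangular structure: given PY, the IN equation is
#' explicit (`IN = h_i + c_ie f[PY]`) and the TC/RE equations are linear, so
#' each PY grid value yields a consistent full-state seed for Newton
#' refinement.  Distinct converged roots are returned with stability flags.
#'
#' @param params a [tc_params()] object.
#' @param py_grid PY seed values.
#' @return data.frame with columns PY, IN, TC, RE, y, stable,
#'   max_re_eigenvalue.
#' @export
find_equilibria <- function(params,
                            py_grid = seq(-2, 2, by = 0.1)) {
  stopifnot(inherits(params, "tc_params"))
  roots <- list()
  for (py in py_grid) {
    fPY <- sigmoid_activation(py, params$epsilon)
    IN <- params$h_i + params$c_ie * fPY
    # linear 2x2 for (TC, RE): TC = h_t + c_te f - c_tr (a RE + b)
    #                          RE = h_r + c_re f + c_rt (a TC + b) - c_rr (a RE + b)
    A <- matrix(c(1, params$c_tr * params$a,
                  -params$c_rt * params$a, 1 + params$c_rr * params$a),
                2, 2, byrow = TRUE)
    rhs2 <- c(params$h_t + params$c_te * fPY - params$c_tr * params$b,
              params$h_r + params$c_re * fPY + params$c_rt * params$b -
                params$c_rr * params$b)
    tcre <- solve(A, rhs2)
    guess <- c(py, IN, tcre[1], tcre[2])
    sol <- tryCatch(find_equilibrium(params, guess), error = function(e) NULL)
    if (is.null(sol)) next
    dup <- any(vapply(roots, function(r) max(abs(r - sol)) < 1e-7, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- sol
  }
  if (!length(roots)) {
    return(data.frame(PY = numeric(0), IN = numeric(0), TC = numeric(0),
                      RE = numeric(0), y = numeric(0), stable = logical(0),
                      max_re_eigenvalue = numeric(0)))
  }
  out <- do.call(rbind, lapply(roots, function(r) {
    ev <- eigen(model_jacobian(r, params), only.values = TRUE)$values
    data.frame(PY = r[["PY"]], IN = r[["IN"]], TC = r[["TC"]], RE = r[["RE"]],
               y = unname(eeg_observation(r, params)),
               stable = all(Re(ev) < 0),
               max_re_eigenvalue = max(Re(ev)))
  }))
  rownames(out) <- NULL
  out[order(out$y), , drop = FALSE]
}

#' Continue an equilibrium branch in one parameter
#'
#' Pseudo-arclength continuation of `rhs(x, p) = 0` from a converged
#' starting equilibrium, with per-point Jacobian eigenvalues and stability
#' flags (all real parts negative).  Branches terminate at the parameter
#' range boundary or when the corrector fails repeatedly (reported via the
#' `termination` attribute, not as an error).
#'
#' @param field a [vector_field()] (or build one with [tc_field()]).
#' @param p_range length-2 parameter interval; continuation starts at
#'   `p_range[1]` and proceeds toward `p_range[2]`.
#' @param start state at `p_range[1]` (will be Newton-refined).
#' @param step initial arclength step (default 0.01).
#' @param max_points maximum branch points.
#' @return an `eq_branch`: data.frame with `param`, state columns,
#'   `stable`, `max_re_pair` (largest real part among complex eigenpairs),
#'   `max_re_real` (largest purely-real eigenvalue), `freq` (|Im|/2pi of the
#'   leading complex pair); attributes `eigenvalues` (list) and `field`.
#' @export
continue_equilibria <- function(field, p_range, start, step = 0.01,
                                max_points = 2000) {
  stopifnot(inherits(field, "vector_field"), length(p_range) == 2)
  d <- field$dim
  dirn <- sign(p_range[2] - p_range[1])
  sol0 <- newton_solve(function(x) field$rhs(x, p_range[1]),
                       function(x) field$jac(x, p_range[1]), as.numeric(start))
  if (!sol0$converged)
    stop("no converged starting equilibrium at the start of the range")
  pts <- list(list(x = sol0$x, p = p_range[1]))
  # first predictor: natural continuation
  tangent <- c(rep(0, d), dirn)
  h <- abs(step)
  fails <- 0
  termination <- "range_end"
  while (length(pts) < max_points) {
    last <- pts[[length(pts)]]
    u0 <- c(last$x, last$p)
    pred <- u0 + h * tangent
    Ffun <- function(u) c(field$rhs(u[1:d], u[d + 1]),
                          sum((u - pred) * tangent))
    Jfun <- function(u) {
      Jx <- field$jac(u[1:d], u[d + 1])
      dp <- 1e-6 * max(1, abs(u[d + 1]))
      Fp <- (field$rhs(u[1:d], u[d + 1] + dp) -
               field$rhs(u[1:d], u[d + 1] - dp)) / (2 * dp)
      rbind(cbind(Jx, Fp), tangent)
    }
    sol <- newton_solve(Ffun, Jfun, pred, tol = 1e-11, maxit = 30)
    if (!sol$converged) {
      h <- h / 2
      fails <- fails + 1
      if (h < 1e-7 || fails > 40) { termination <- "corrector_failure"; break }
      next
    }
    fails <- 0
    u1 <- sol$x
    new_t <- u1 - u0
    nt <- sqrt(sum(new_t^2))
    if (nt > 0) tangent <- new_t / nt
    pts[[length(pts) + 1L]] <- list(x = u1[1:d], p = u1[d + 1])
    if (h < abs(step)) h <- min(abs(step), 2 * h)
    if ((dirn > 0 && u1[d + 1] >= p_range[2]) ||
        (dirn < 0 && u1[d + 1] <= p_range[2])) break
  }
  params_v <- vapply(pts, `[[`, numeric(1), "p")
  X <- t(vapply(pts, `[[`, numeric(d), "x"))
  eigs <- lapply(seq_len(nrow(X)), function(i) {
    eigen(field$jac(X[i, ], params_v[i]), only.values = TRUE)$values
  })
  cplx_re <- vapply(eigs, function(ev) {
    cp <- ev[abs(Im(ev)) > 1e-9]
    if (length(cp)) max(Re(cp)) else -Inf
  }, numeric(1))
  real_re <- vapply(eigs, function(ev) {
    rl <- ev[abs(Im(ev)) <= 1e-9]
    if (length(rl)) max(Re(rl)) else -Inf
  }, numeric(1))
  freq <- vapply(eigs, function(ev) {
    cp <- ev[abs(Im(ev)) > 1e-9]
    if (!length(cp)) return(0)
    abs(Im(cp[which.max(Re(cp))])) / (2 * pi)
  }, numeric(1))
  br <- data.frame(param = params_v, X,
                   stable = vapply(eigs, function(ev) all(Re(ev) < 0), logical(1)),
                   max_re_pair = cplx_re, max_re_real = real_re, freq = freq)
  names(br)[2:(d + 1)] <- if (d == 4) c("PY", "IN", "TC", "RE")
                          else paste0("x", seq_len(d))
  attr(br, "eigenvalues") <- eigs
  attr(br, "field") <- field
  attr(br, "termination") <- termination
  class(br) <- c("eq_branch", "data.frame")
  br
}

#' Detect Hopf bifurcations along an equilibrium branch
#'
#' Scans consecutive branch points for a sign change in the largest real
#' part of a complex-conjugate eigenpair, then bisects (re-solving the
#' equilibrium at each trial parameter, warm-started from the branch
#' state) to a parameter tolerance of 1e-4.  Crossings of purely real
#' eigenvalues are classified separately as `"real_crossing"` and never
#' reported as Hopf points.  A crossing is flagged `dominant` when the
#' branch's overall stability flips there — i.e. the crossing pair is the
#' leading eigenvalue, the textbook Hopf scenario; non-dominant crossings
#' occur on already-unstable (saddle) branch segments near folds.
#' Refinement is skipped on segments where the branch folds back in the
#' parameter (bisection in the parameter is ill-posed there); the segment
#' midpoint is then reported at the branch's own resolution.
#'
#' @param branch an `eq_branch` from [continue_equilibria()] (>= 3 points).
#' @param tol parameter localization tolerance (default 1e-4).
#' @return data.frame of bifurcation points: `kind` ("HB" or
#'   "real_crossing"), `parameter_value`, `frequency` (|Im|/2pi at the
#'   crossing, HB only), `dominant`, `branch_id`.
#' @export
detect_hopf <- function(branch, tol = 1e-4) {
  stopifnot(inherits(branch, "eq_branch"), nrow(branch) >= 3)
  field <- attr(branch, "field")
  d <- field$dim
  state_cols <- 2:(d + 1)
  dp <- diff(branch$param)
  out <- list()
  eig_at <- function(p, xguess) {
    sol <- newton_solve(function(x) field$rhs(x, p),
                        function(x) field$jac(x, p), xguess, tol = 1e-11)
    if (!sol$converged) return(NULL)
    # guard against jumping to a different coexisting root
    if (sqrt(sum((sol$x - xguess)^2)) > 1) return(NULL)
    list(x = sol$x, ev = eigen(field$jac(sol$x, p), only.values = TRUE)$values)
  }
  part <- function(ev, complex_pair) {
    sel <- if (complex_pair) abs(Im(ev)) > 1e-9 else abs(Im(ev)) <= 1e-9
    if (any(sel)) max(Re(ev[sel])) else -Inf
  }
  near_fold <- function(i) {
    lo <- max(1, i - 2); hi <- min(length(dp), i + 2)
    any(sign(dp[lo:hi]) != sign(dp[i])) || dp[i] == 0
  }
  for (what in c(TRUE, FALSE)) {
    vals <- if (what) branch$max_re_pair else branch$max_re_real
    for (i in seq_len(nrow(branch) - 1)) {
      a <- vals[i]; b <- vals[i + 1]
      if (!is.finite(a) || !is.finite(b) || a == 0 || sign(a) == sign(b)) next
      lo <- branch$param[i]; hi <- branch$param[i + 1]
      xlo <- as.numeric(branch[i, state_cols])
      flo <- a
      freq <- branch$freq[i]
      if (!near_fold(i)) {
        while (abs(hi - lo) > tol) {
          mid <- (lo + hi) / 2
          r <- eig_at(mid, xlo)
          if (is.null(r)) break
          fm <- part(r$ev, what)
          if (what) {
            cp <- r$ev[abs(Im(r$ev)) > 1e-9]
            if (length(cp)) freq <- abs(Im(cp[which.max(Re(cp))])) / (2 * pi)
          }
          if (sign(fm) == sign(flo)) { lo <- mid; xlo <- r$x; flo <- fm }
          else hi <- mid
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        kind = if (what) "HB" else "real_crossing",
        parameter_value = (lo + hi) / 2,
        frequency = if (what) freq else NA_real_,
        dominant = branch$stable[i] != branch$stable[i + 1],
        branch_id = 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(0), parameter_value = numeric(0),
                      frequency = numeric(0), dominant = logical(0),
                      branch_id = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$parameter_value), , drop = FALSE]
}

#' Probe multistability by seeded initial-condition search
#'
#' Finds the distinct coexisting attractors at one parameter point.
#' Trajectories are integrated noise-free and classified from three kinds
#' of seeded, deterministic starting points: (1) `n_initials` random states
#' drawn uniformly from `box^4`; (2) every equilibrium located by
#' [find_equilibria()] (minority steady states often have basins too thin
#' for random draws to hit); (3) Gaussian clouds around the orbits of
#' attractors found so far (`cloud_rounds` rounds of
#' `cloud_per_attractor` perturbed states each, emulating the
#' pulse-perturbation experiments that expose coexisting cycles).
#' Attractors are clustered by label kind, spike count, rounded dominant
#' frequency, and (for steady states) mean EEG level.
#'
#' @param params a [tc_params()] object.
#' @param n_initials number of random initial states (>= 10).
#' @param seed RNG seed (random draws and clouds).
#' @param box length-2 interval; initials are drawn uniformly from `box^4`.
#' @param duration probe length (s), default 15.
#' @param dt step (s).
#' @param cfg a [classification_config()].
#' @param include_equilibria seed the probe with all located equilibria.
#' @param cloud_rounds rounds of attractor-neighbourhood cloud probing.
#' @param cloud_per_attractor cloud samples per attractor per round.
#' @param cloud_sd standard deviations of the cloud perturbations, recycled
#'   across rounds (mixing tight and wide clouds reaches both thin adjacent
#'   basins and remote ones).
#' @return list with `labels` (list of distinct [state_label()]s),
#'   `representatives` (matrix of one initial state per attractor),
#'   `counts` (hit counts per attractor), `n_unresolved`.
#' @export
multistability_probe <- function(params, n_initials = 50, seed = 1L,
                                 box = c(-4, 1), duration = 15, dt = 0.001,
                                 cfg = classification_config(),
                                 include_equilibria = TRUE,
                                 cloud_rounds = 3, cloud_per_attractor = 16,
                                 cloud_sd = c(0.3, 0.6, 1.2)) {
  stopifnot(n_initials >= 10)
  keys <- character(0); labels <- list(); reps <- list(); counts <- integer(0)
  orbits <- list()
  n_unres <- 0L
  try_init <- function(x0) {
    traj <- tryCatch(simulate_tc(params, x0, duration, dt = dt),
                     error = function(e) NULL)
    lab <- if (is.null(traj)) state_label("UNRESOLVED")
           else classify_state(traj, cfg)
    if (lab$kind == "UNRESOLVED") { n_unres <<- n_unres + 1L; return(invisible()) }
    key <- format_label(lab)
    if (lab$kind %in% c("LS", "HS")) {
      lvl <- mean(traj$y[(length(traj$y) - round(2 / dt)):length(traj$y)])
      key <- paste0(key, "@", round(lvl / 0.02))
    } else {
      key <- paste0(key, "@", round(2 * lab$dominant_frequency) / 2)
    }
    j <- match(key, keys)
    if (is.na(j)) {
      keys <<- c(keys, key)
      labels[[length(labels) + 1L]] <<- lab
      reps[[length(reps) + 1L]] <<- as_state(x0)
      counts <<- c(counts, 1L)
      orbits[[length(orbits) + 1L]] <<-
        traj$states[seq(nrow(traj$states) %/% 2, nrow(traj$states),
                        length.out = 32), , drop = FALSE]
    } else counts[j] <<- counts[j] + 1L
    invisible()
  }
  inits <- with_seed(seed, matrix(stats::runif(4 * n_initials, box[1], box[2]),
                                  ncol = 4))
  colnames(inits) <- c("PY", "IN", "TC", "RE")
  if (include_equilibria) {
    eq <- tryCatch(find_equilibria(params), error = function(e) NULL)
    if (!is.null(eq) && nrow(eq))
      for (i in seq_len(nrow(eq)))
        try_init(unlist(eq[i, c("PY", "IN", "TC", "RE")]))
  }
  for (i in seq_len(n_initials)) try_init(inits[i, ])
  if (cloud_rounds > 0) {
    with_seed(seed + 7L, {
      for (round in seq_len(cloud_rounds)) {
        sdv <- cloud_sd[((round - 1) %% length(cloud_sd)) + 1]
        base_orbits <- orbits
        for (ob in base_orbits) {
          for (k in seq_len(cloud_per_attractor)) {
            x0 <- ob[sample(nrow(ob), 1), ] + stats::rnorm(4, 0, sdv)
            try_init(x0)
          }
        }
      }
    })
  }
  reps_m <- if (length(reps)) do.call(rbind, reps) else
    matrix(numeric(0), 0, 4, dimnames = list(NULL, c("PY", "IN", "TC", "RE")))
  list(labels = labels, representatives = reps_m,
       counts = stats::setNames(counts, keys), n_unresolved = n_unres)
}

#' Representative initial state for a target regime
#'
#' Searches seeded random initial states until one lands in the basin of
#' the requested regime (used to pin "proper initial conditions" for
#' bistable study setups).
#'
#' @param params a [tc_params()] object.
#' @param kind target label kind (`"SWD"`, `"LS"`, ...).
#' @param m spike count (SWD only; `NA` accepts any m).
#' @param n_initials,seed,box,duration,dt,cfg as in [multistability_probe()].
#' @return a length-4 initial state.
#' @export
find_basin_state <- function(params, kind, m = NA, n_initials = 60, seed = 1L,
                             box = c(-4, 1), duration = 10, dt = 0.001,
                             cfg = classification_config()) {
  inits <- with_seed(seed, matrix(stats::runif(4 * n_initials, box[1], box[2]),
                                  ncol = 4))
  colnames(inits) <- c("PY", "IN", "TC", "RE")
  for (i in seq_len(n_initials)) {
    traj <- tryCatch(simulate_tc(params, inits[i, ], duration, dt = dt),
                     error = function(e) NULL)
    if (is.null(traj)) next
    lab <- classify_state(traj, cfg)
    if (lab$kind == kind && (is.na(m) || identical(lab$m, as.integer(m))))
      return(inits[i, ])
  }
  stop("no initial state found in the basin of ", kind,
       if (!is.na(m)) paste0(" (m = ", m, ")") else "")
}

#' One-parameter regime sweep
#'
#' For each parameter value, simulates from every probe initial state,
#' classifies the outcome, deduplicates coexisting attractors, and records
#' label, dominant frequency and EEG extrema — the tidy analogue of a
#' brute-force one-parameter bifurcation diagram.  Optionally adds up- and
#' down-sweeps with state continuation (reusing the final state at each
#' value) to expose hysteresis.
#'
#' @param params a [tc_params()] object.
#' @param axis parameter name (`"c_tr"` or `"c_te"` are the validated axes).
#' @param values parameter values.
#' @param probe_initials matrix of initial states (rows), or `NULL` for a
#'   seeded default set.
#' @param continuation also run up/down state-continuation sweeps.
#' @param duration,dt,cfg simulation/classification settings.
#' @param n_probes,seed used when `probe_initials` is `NULL`.
#' @return data.frame: `value`, `sweep` ("probe", "up", "down"), `kind`,
#'   `m`, `dominant_frequency`, `y_min`, `y_max`, `n_extrema`.
#' @export
one_param_scan <- function(params, axis, values, probe_initials = NULL,
                           continuation = FALSE, duration = 12, dt = 0.001,
                           cfg = classification_config(), n_probes = 5,
                           seed = 1L) {
  stopifnot(inherits(params, "tc_params"), axis %in% names(params))
  if (!length(values)) {
    return(data.frame(value = numeric(0), sweep = character(0),
                      kind = character(0), m = integer(0),
                      dominant_frequency = numeric(0), y_min = numeric(0),
                      y_max = numeric(0), n_extrema = integer(0)))
  }
  if (is.null(probe_initials))
    probe_initials <- default_probe_initials(n_probes, seed)
  rows <- list()
  add_row <- function(value, sweep, lab, y) {
    ex <- signal_extrema(y, dt, transient_discard = cfg$transient_discard,
                         steady_tol = cfg$steady_amplitude_tol)
    rows[[length(rows) + 1L]] <<- data.frame(
      value = value, sweep = sweep, kind = lab$kind, m = lab$m,
      dominant_frequency = lab$dominant_frequency,
      y_min = min(ex), y_max = max(ex), n_extrema = length(ex))
  }
  for (v in values) {
    pv <- set_param(params, axis, v)
    seen <- character(0)
    for (r in seq_len(nrow(probe_initials))) {
      res <- classify_probe(pv, probe_initials[r, ], duration, dt, cfg)
      if (is.null(res) || res$label$kind == "UNRESOLVED") next
      key <- format_label(res$label)
      if (key %in% seen) next
      seen <- c(seen, key)
      add_row(v, "probe", res$label, res$trajectory$y)
    }
  }
  if (continuation) {
    for (dirn in c("up", "down")) {
      vals <- if (dirn == "up") sort(values) else sort(values, decreasing = TRUE)
      state <- probe_initials[1, ]
      for (v in vals) {
        pv <- set_param(params, axis, v)
        traj <- tryCatch(simulate_tc(pv, state, duration, dt = dt),
                         error = function(e) NULL)
        if (is.null(traj)) next
        state <- traj$states[nrow(traj$states), ]
        lab <- classify_state(traj, cfg)
        if (lab$kind != "UNRESOLVED") add_row(v, dirn, lab, traj$y)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_probe_initials <- function(n = 5, seed = 42L, box = c(-4, 1)) {
  inits <- with_seed(seed, matrix(stats::runif(4 * n, box[1], box[2]), ncol = 4))
  colnames(inits) <- c("PY", "IN", "TC", "RE")
  inits
}

# classify a probe, extending the run (continuing from the final state) when
# the verdict is UNRESOLVED -- long decaying transients settle eventually
classify_probe <- function(params, init, duration, dt, cfg, max_extend = 2) {
  traj <- tryCatch(simulate_tc(params, init, duration, dt = dt),
                   error = function(e) NULL)
  if (is.null(traj)) return(NULL)
  lab <- classify_state(traj, cfg)
  ext <- 0
  while (lab$kind == "UNRESOLVED" && ext < max_extend) {
    traj <- tryCatch(simulate_tc(params, traj$states[nrow(traj$states), ],
                                 duration, dt = dt),
                     error = function(e) NULL)
    if (is.null(traj)) return(NULL)
    lab <- classify_state(traj, cfg)
    ext <- ext + 1
  }
  list(label = lab, trajectory = traj)
}

#' Two-parameter regime map over (c_tr, c_te)
#'
#' Classifies every grid cell from multiple probe initial states, storing
#' the set of coexisting labels per cell.  Stable equilibria located
#' analytically contribute their LS/HS label directly (minority steady
#' basins are too thin for random probes), and probes whose verdict is
#' UNRESOLVED are extended until the transient settles.  Qualitatively
#' distinct regions are derived by merging 4-connected cells with
#' identical label sets; for region identity the spike count of SWD labels
#' is ignored (`merge_m`), since the qualitative partition separates
#' coexistence patterns, not the m-laddering inside the SWD territory.
#'
#' @param params a [tc_params()] object (values of `c_tr`/`c_te` are
#'   overridden by the grid).
#' @param c_tr_values,c_te_values grid axes (each >= 1 value; >= 2 for a
#'   meaningful map).
#' @param probe_initials matrix of probe initial states, or `NULL` for the
#'   seeded default set of `n_probes`.
#' @param duration,dt,cfg,n_probes,seed as in [one_param_scan()].
#' @param include_equilibria add analytic stable-equilibrium labels.
#' @param merge_m ignore SWD spike counts in the region identity key.
#' @return a `region_map`: list with `c_tr`, `c_te`, `label_sets` (list
#'   matrix of per-cell label keys), `label_key` / `region_key` (full and
#'   identity keys), `region_id` (integer matrix), `n_regions` (connected
#'   components), `n_label_sets` (distinct identity keys).
#' @export
two_param_map <- function(params, c_tr_values, c_te_values,
                          probe_initials = NULL, duration = 12, dt = 0.001,
                          cfg = classification_config(), n_probes = 5,
                          seed = 1L, include_equilibria = TRUE,
                          merge_m = TRUE) {
  stopifnot(length(c_tr_values) >= 1, length(c_te_values) >= 1)
  if (is.null(probe_initials))
    probe_initials <- default_probe_initials(n_probes, seed)
  ni <- length(c_tr_values); nj <- length(c_te_values)
  keysets <- matrix(vector("list", ni * nj), ni, nj)
  eq_grid <- seq(-2, 2, by = 0.25)
  for (i in seq_len(ni)) {
    for (j in seq_len(nj)) {
      pv <- update_params(params, c_tr = c_tr_values[i], c_te = c_te_values[j])
      seen <- character(0)
      if (include_equilibria) {
        eq <- tryCatch(find_equilibria(pv, py_grid = eq_grid),
                       error = function(e) NULL)
        if (!is.null(eq) && any(eq$stable)) {
          lv <- eq$y[eq$stable]
          seen <- unique(ifelse(lv < cfg$ls_hs_split, "LS", "HS"))
        }
      }
      for (r in seq_len(nrow(probe_initials))) {
        res <- classify_probe(pv, probe_initials[r, ], duration, dt, cfg)
        if (is.null(res) || res$label$kind == "UNRESOLVED") next
        seen <- unique(c(seen, format_label(res$label)))
      }
      keysets[[i, j]] <- sort(seen)
    }
  }
  keymat <- matrix(vapply(keysets, function(k) paste(k, collapse = "+"),
                          character(1)), ni, nj)
  idmat <- if (merge_m) {
    matrix(vapply(keysets, function(k) {
      paste(sort(unique(sub("^[0-9]+-SWD$", "SWD", k))), collapse = "+")
    }, character(1)), ni, nj)
  } else keymat
  region_id <- label_connected_components(idmat)
  structure(list(c_tr = c_tr_values, c_te = c_te_values,
                 label_sets = keysets, label_key = keymat,
                 region_key = idmat, region_id = region_id,
                 n_regions = max(region_id),
                 n_label_sets = length(unique(as.vector(idmat)))),
            class = "region_map")
}

# connected components (4-neighbourhood) of cells sharing the same key
label_connected_components <- function(keymat) {
  ni <- nrow(keymat); nj <- ncol(keymat)
  id <- matrix(0L, ni, nj)
  cur <- 0L
  for (i0 in seq_len(ni)) for (j0 in seq_len(nj)) {
    if (id[i0, j0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i0, j0))
    id[i0, j0] <- cur
    while (length(stack)) {
      cell <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- cell[1]; j <- cell[2]
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        a <- nb[1]; b <- nb[2]
        if (a >= 1 && a <= ni && b >= 1 && b <= nj && id[a, b] == 0L &&
            keymat[a, b] == keymat[i0, j0]) {
          id[a, b] <- cur
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
  }
  id
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d x %d grid over (c_tr, c_te); %d regions (%d distinct label sets)\n",
              length(x$c_tr), length(x$c_te), x$n_regions, x$n_label_sets))
  invisible(x)
}

#' Tidy export of a region map
#'
#' @param map a `region_map`.
#' @param path optional CSV output file.
#' @return data.frame with `c_tr`, `c_te`, `labels`, `region`.
#' @export
region_map_table <- function(map, path = NULL) {
  stopifnot(inherits(map, "region_map"))
  grid <- expand.grid(i = seq_along(map$c_tr), j = seq_along(map$c_te))
  out <- data.frame(c_tr = map$c_tr[grid$i], c_te = map$c_te[grid$j],
                    labels = map$label_key[cbind(grid$i, grid$j)],
                    region_key = map$region_key[cbind(grid$i, grid$j)],
                    region = map$region_id[cbind(grid$i, grid$j)])
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Locate fold-of-cycles (double cycle) points by hysteresis sweeps
#'
#' Follows the stable limit cycle's peak-to-peak EEG amplitude under slow
#' up- and down-parameter sweeps with state continuation (the final state
#' at one value seeds the next).  A double cycle (dc) point is reported
#' where the cycle disappears abruptly — an amplitude discontinuity larger
#' than `jump_tol` between consecutive values — and each disappearance edge
#' is refined by bisection.  A supercritical Hopf, where the amplitude
#' shrinks continuously to zero, produces no dc point.  Unstable cycles are
#' not tracked; only their consequences (the hysteresis edges) are located.
#'
#' @param params a [tc_params()] object, or a [vector_field()] for custom
#'   test systems (then `sim_dt` integration uses a plain RK4 in R and the
#'   observed signal is the first state component).
#' @param axis parameter name (ignored for a `vector_field`).
#' @param range length-2 parameter interval swept in both directions.
#' @param start initial state seeding the sweep (should lie in the basin of
#'   the cycle somewhere in the range).
#' @param n_values number of sweep values.
#' @param jump_tol amplitude discontinuity threshold (default 0.05).
#' @param tol parameter localization tolerance (default 1e-4).
#' @param settle,measure per-value simulated settle and measurement spans (s).
#' @param sim_dt integration step.
#' @return data.frame of dc candidates: `kind` ("dc"), `parameter_value`,
#'   `direction` of the sweep that lost the cycle, `amplitude_before`;
#'   attribute `sweeps` holds the full amplitude records.
#' @export
estimate_double_cycle <- function(params, axis = NULL, range, start,
                                  n_values = 41, jump_tol = 0.05, tol = 1e-4,
                                  settle = 6, measure = 4, sim_dt = 0.001) {
  run <- make_cycle_prober(params, axis, settle, measure, sim_dt)
  values_up <- seq(range[1], range[2], length.out = n_values)
  sweep <- function(vals) {
    state <- as.numeric(start)
    amp <- numeric(length(vals))
    finals <- vector("list", length(vals))
    for (k in seq_along(vals)) {
      r <- run(vals[k], state)
      amp[k] <- r$amplitude
      state <- r$final
      finals[[k]] <- r$final
    }
    list(values = vals, amplitude = amp, finals = finals)
  }
  up <- sweep(values_up)
  down <- sweep(rev(values_up))
  out <- list()
  refine <- function(p_osc, p_dead, state_osc) {
    # bisect from the oscillating side, continuing the cycle state inward
    repeat {
      if (abs(p_dead - p_osc) <= tol) break
      mid <- (p_osc + p_dead) / 2
      r <- run(mid, state_osc)
      if (r$amplitude > jump_tol) { p_osc <- mid; state_osc <- r$final }
      else p_dead <- mid
    }
    (p_osc + p_dead) / 2
  }
  collect <- function(sw, direction) {
    for (k in seq_len(length(sw$values) - 1)) {
      a <- sw$amplitude[k]; b <- sw$amplitude[k + 1]
      if (a > jump_tol && (a - b) > jump_tol && b < jump_tol) {
        pv <- refine(sw$values[k], sw$values[k + 1], sw$finals[[k]])
        out[[length(out) + 1L]] <<- data.frame(
          kind = "dc", parameter_value = pv, direction = direction,
          amplitude_before = a)
      }
    }
  }
  collect(up, "up")
  collect(down, "down")
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(0), parameter_value = numeric(0),
               direction = character(0), amplitude_before = numeric(0))
  attr(res, "sweeps") <- list(up = up, down = down)
  res
}

make_cycle_prober <- function(params, axis, settle, measure, sim_dt) {
  if (inherits(params, "tc_params")) {
    stopifnot(axis %in% names(params))
    function(value, state) {
      pv <- set_param(params, axis, value)
      traj <- simulate_tc(pv, state, settle + measure, dt = sim_dt)
      sel <- traj$t >= settle
      list(amplitude = diff(range(traj$y[sel])),
           final = traj$states[nrow(traj$states), ])
    }
  } else if (inherits(params, "vector_field")) {
    function(value, state) {
      nst <- round((settle + measure) / sim_dt)
      x <- as.numeric(state)
      obs <- numeric(nst + 1)
      obs[1] <- x[1]
      for (i in seq_len(nst)) {
        k1 <- params$rhs(x, value)
        k2 <- params$rhs(x + sim_dt / 2 * k1, value)
        k3 <- params$rhs(x + sim_dt / 2 * k2, value)
        k4 <- params$rhs(x + sim_dt * k3, value)
        x <- x + sim_dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        obs[i + 1] <- x[1]
      }
      sel <- seq(round(settle / sim_dt) + 1, nst + 1)
      list(amplitude = diff(range(obs[sel])), final = x)
    }
  } else stop("params must be tc_params or a vector_field")
}
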