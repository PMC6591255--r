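#' Thalamocortical model parameters
#'
#' Constructs the parameter set of the four-population thalamocortical
#' neural mass model (cortical pyramidal PY and interneuron IN populations,
#' thalamocortical relay TC and thalamic reticular RE nuclei).  Defaults are
#' the reference values used throughout the package; the cortico-thalamic
#' couplings `c_te` (PY to TC excitation) and `c_tr` (RE to TC feedforward
#' inhibition) are the two axes along which the model's regimes are mapped.
#'
#' The vector field is
#' \deqn{dPY/dt = \tau_e (h_e - PY + c_{ee} f[PY] - c_{ei} f[IN] + c_{et} f[TC])}
#' \deqn{dIN/dt = \tau_i (h_i - IN + c_{ie} f[PY])}
#' \deqn{dTC/dt = \tau_t (h_t - TC + c_{te} f[PY] - c_{tr} s[RE])}
#' \deqn{dRE/dt = \tau_r (h_r - RE + c_{re} f[PY] + c_{rt} s[TC] - c_{rr} s[RE])}
#' with sigmoid cortical activation \eqn{f[x] = 1/(1+\epsilon^{-x})} and
#' linear thalamic activation \eqn{s[x] = a x + b}.  The observed EEG is
#' \eqn{y = c_1 PY + c_2 IN}.
#'
#' Timescale constants `tau_*` are in 1/s (time in seconds), so the
#' spike-and-wave rhythm of the default regime falls in the 2.5-4 Hz band
#' typical of absence seizures.  All state variables are dimensionless
#' fractional firing activities.
#'
#' @param h_e,h_i,h_t,h_r population input offsets (dimensionless).
#' @param tau_e,tau_i,tau_t,tau_r timescale rate constants (1/s), all > 0.
#' @param c_ee,c_ei,c_et,c_ie,c_te,c_tr,c_re,c_rt,c_rr non-negative
#'   connectivity strengths.
#' @param epsilon sigmoid steepness (> 1).
#' @param a,b slope and offset of the linear thalamic activation.
#' @param c1,c2 EEG observation weights; must satisfy `c1 + c2 = 1` with
#'   `c1 >= c2 > 0`.
#' @return An object of class `tc_params` (a validated named list).
#' @examples
#' p <- tc_params()                      # reference parameter set
#' p_swd <- tc_params(c_tr = 0.6, c_te = 3)  # bistable SWD/background regime
#' @export
tc_params <- function(h_e = -0.35, h_i = -3.4, h_t = -2, h_r = -5,
                      tau_e = 26, tau_i = 32.5, tau_t = 2.6, tau_r = 2.6,
                      c_ee = 1.8, c_ei = 1.5, c_et = 1, c_ie = 4,
                      c_te = 3, c_tr = 0.6, c_re = 3, c_rt = 10.5,
                      c_rr = 0.2, epsilon = 2e5, a = 2.8, b = 0.5,
                      c1 = 0.5, c2 = 0.5) {
  p <- list(h_e = h_e, h_i = h_i, h_t = h_t, h_r = h_r,
            tau_e = tau_e, tau_i = tau_i, tau_t = tau_t, tau_r = tau_r,
            c_ee = c_ee, c_ei = c_ei, c_et = c_et, c_ie = c_ie,
            c_te = c_te, c_tr = c_tr, c_re = c_re, c_rt = c_rt,
            c_rr = c_rr, epsilon = epsilon, a = a, b = b, c1 = c1, c2 = c2)
  validate_tc_params(p)
  structure(p, class = "tc_params")
}

validate_tc_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all parameters must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "))
  taus <- unlist(p[c("tau_e", "tau_i", "tau_t", "tau_r")])
  if (any(taus <= 0)) stop("all tau_* must be > 0")
  if (p$epsilon <= 1) stop("epsilon must be > 1")
  cc <- unlist(p[grep("^c_[a-z]{2}$", names(p))])
  if (any(cc < 0)) stop("connectivity strengths must be >= 0")
  if (abs(p$c1 + p$c2 - 1) > 1e-12 || p$c2 <= 0 || p$c1 < p$c2)
    stop("observation weights must satisfy c1 + c2 = 1 and c1 >= c2 > 0")
  invisible(p)
}

#' @export
print.tc_params <- function(x, ...) {
  cat("Thalamocortical model parameters\n")
  cat(sprintf("  couplings: c_tr = %g (RE->TC inhibition), c_te = %g (PY->TC excitation)\n",
              x$c_tr, x$c_te))
  cat("  ", paste(sprintf("%s=%g", names(x), unlist(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Modify a parameter set
#'
#' @param params a [tc_params()] object.
#' @param ... named parameter replacements.
#' @return a new validated `tc_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "tc_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  params[names(repl)] <- repl
  validate_tc_params(params)
  structure(params, class = "tc_params")
}

#' Read / write model parameters as a flat YAML or JSON mapping
#'
#' Parameters serialize to a flat mapping keyed by the model symbol names
#' (`h_e`, `tau_e`, `c_ee`, ...).  The format is chosen from the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param params a [tc_params()] object.
#' @param path file to write to / read from.
#' @return `read_params` returns a `tc_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "tc_params"))
  vals <- lapply(unclass(params), identity)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(tc_params, vals[intersect(names(vals), names(formals(tc_params)))])
}

#' State vector constructor
#'
#' @param PY,IN,TC,RE fractional firing activities (finite reals).
#' @return named numeric vector `c(PY, IN, TC, RE)`.
#' @export
state_vector <- function(PY, IN, TC, RE) {
  x <- c(PY = PY, IN = IN, TC = TC, RE = RE)
  if (!all(is.finite(x))) stop("state components must be finite")
  x
}

as_state <- function(state) {
  if (length(state) != 4L || !is.numeric(state))
    stop("state must be a numeric vector of length 4 (PY, IN, TC, RE)")
  if (!all(is.finite(state))) stop("state components must be finite")
  stats::setNames(as.numeric(state), c("PY", "IN", "TC", "RE"))
}

#' Sigmoid cortical activation
#'
#' \eqn{f[x] = 1/(1+\epsilon^{-x})}, evaluated as
#' \eqn{1/(1+\exp(-x\ln\epsilon))} with the exponent clipped to \eqn{\pm 700}
#' so that the steep default (`epsilon = 2e5`) never overflows.
#'
#' @param x input (finite numeric, vectorized).
#' @param epsilon steepness, > 1.
#' @return values strictly in (0, 1), strictly increasing in `x`.
#' @export
sigmoid_activation <- function(x, epsilon = 2e5) {
  if (!all(is.finite(x))) stop("x must be finite")
  if (!is.numeric(epsilon) || epsilon <= 1) stop("epsilon must be > 1")
  z <- pmin(pmax(-x * log(epsilon), -700), 700)
  1 / (1 + exp(z))
}

#' Linear thalamic activation
#'
#' \eqn{s[x] = a x + b}.
#'
#' @param x input (vectorized).
#' @param a slope.
#' @param b offset.
#' @export
linear_activation <- function(x, a = 2.8, b = 0.5) a * x + b

#' Model vector field
#'
#' Time derivatives of the four population activities, optionally with an
#' additive exogenous input per population (disturbance/control, entering
#' the derivative directly as in the controlled system
#' \eqn{\dot x = F(x) + d + u}).
#'
#' @param state numeric length-4 state `(PY, IN, TC, RE)`.
#' @param params a [tc_params()] object.
#' @param exogenous additive input, scalar 0 or numeric length 4.
#' @return named numeric length-4 derivative.
#' @export
model_rhs <- function(state, params, exogenous = 0) {
  x <- as_state(state)
  stopifnot(inherits(params, "tc_params"))
  f <- sigmoid_activation(x[1:3], params$epsilon)
  sTC <- linear_activation(x[["TC"]], params$a, params$b)
  sRE <- linear_activation(x[["RE"]], params$a, params$b)
  d <- c(
    PY = params$tau_e * (params$h_e - x[["PY"]] + params$c_ee * f[[1]] -
                           params$c_ei * f[[2]] + params$c_et * f[[3]]),
    IN = params$tau_i * (params$h_i - x[["IN"]] + params$c_ie * f[[1]]),
    TC = params$tau_t * (params$h_t - x[["TC"]] + params$c_te * f[[1]] -
                           params$c_tr * sRE),
    RE = params$tau_r * (params$h_r - x[["RE"]] + params$c_re * f[[1]] +
                           params$c_rt * sTC - params$c_rr * sRE)
  )
  if (!identical(exogenous, 0)) {
    if (length(exogenous) != 4L) stop("exogenous must be scalar 0 or length 4")
    d <- d + as.numeric(exogenous)
  }
  d
}

#' EEG observation map
#'
#' \eqn{y = c_1 PY + c_2 IN}: the simulated scalp EEG is a convex
#' combination of the two cortical populations.
#'
#' @param state length-4 state vector, or an n x 4 matrix of states.
#' @param params a [tc_params()] object.
#' @return scalar (or length-n vector) observed EEG.
#' @export
eeg_observation <- function(state, params) {
  stopifnot(inherits(params, "tc_params"))
  if (is.matrix(state)) {
    params$c1 * state[, 1] + params$c2 * state[, 2]
  } else {
    x <- as_state(state)
    params$c1 * x[["PY"]] + params$c2 * x[["IN"]]
  }
}

#' Analytic Jacobian of the model vector field
#'
#' Partial derivatives of [model_rhs()] with respect to the state, using
#' \eqn{f'[x] = \ln(\epsilon) f[x](1-f[x])} and \eqn{s'[x] = a}.  Used for
#' equilibrium continuation, stability flags and Hopf detection.
#'
#' @inheritParams model_rhs
#' @return 4 x 4 numeric matrix with rows/columns ordered (PY, IN, TC, RE).
#' @export
model_jacobian <- function(state, params) {
  x <- as_state(state)
  stopifnot(inherits(params, "tc_params"))
  lneps <- log(params$epsilon)
  fp <- function(v) {
    f <- sigmoid_activation(v, params$epsilon)
    lneps * f * (1 - f)
  }
  dfPY <- fp(x[["PY"]]); dfIN <- fp(x[["IN"]]); dfTC <- fp(x[["TC"]])
  a <- params$a
  J <- matrix(0, 4, 4, dimnames = list(c("PY", "IN", "TC", "RE"),
                                       c("PY", "IN", "TC", "RE")))
  J["PY", "PY"] <- params$tau_e * (-1 + params$c_ee * dfPY)
  J["PY", "IN"] <- -params$tau_e * params$c_ei * dfIN
  J["PY", "TC"] <- params$tau_e * params$c_et * dfTC
  J["IN", "PY"] <- params$tau_i * params$c_ie * dfPY
  J["IN", "IN"] <- -params$tau_i
  J["TC", "PY"] <- params$tau_t * params$c_te * dfPY
  J["TC", "TC"] <- -params$tau_t
  J["TC", "RE"] <- -params$tau_t * params$c_tr * a
  J["RE", "PY"] <- params$tau_r * params$c_re * dfPY
  J["RE", "TC"] <- params$tau_r * params$c_rt * a
  J["RE", "RE"] <- params$tau_r * (-1 - params$c_rr * a)
  J
}
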