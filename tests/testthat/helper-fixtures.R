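# shared fixtures: reference parameter sets and cached basin states
p_default <- tc_params()                      # c_tr = 0.6, c_te = 3 regime
p_case1 <- tc_params(c_tr = 0.6, c_te = 3)

# random finite states for property-style loops
random_states <- function(n, seed = 1, lo = -3, hi = 2) {
  set.seed(seed)
  matrix(runif(4 * n, lo, hi), ncol = 4,
         dimnames = list(NULL, c("PY", "IN", "TC", "RE")))
}

# cached slow fixtures, built once per test run
swd_initial_case1 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- find_basin_state(p_case1, "SWD", seed = 101L)
    val
  }
})

ls_equilibrium <- function(params) {
  eq <- find_equilibria(params)
  eq <- eq[eq$stable & eq$y < classification_config()$ls_hs_split, , drop = FALSE]
  stopifnot(nrow(eq) >= 1)
  unlist(eq[1, c("PY", "IN", "TC", "RE")])
}

# 2-D Hopf normal form: x' = mu x - w y - x (x^2+y^2), y' = w x + mu y - y (x^2+y^2)
hopf_normal_form <- function(omega = 2 * pi) {
  vector_field(
    rhs = function(x, p) {
      r2 <- x[1]^2 + x[2]^2
      c(p * x[1] - omega * x[2] - x[1] * r2,
        omega * x[1] + p * x[2] - x[2] * r2)
    },
    jac = function(x, p) {
      r2 <- x[1]^2 + x[2]^2
      matrix(c(p - 3 * x[1]^2 - x[2]^2, -omega - 2 * x[1] * x[2],
               omega - 2 * x[1] * x[2], p - x[1]^2 - 3 * x[2]^2),
             2, 2, byrow = TRUE)
    },
    dim = 2L
  )
}

set_param_for_test <- function(params, axis, value)
  do.call(update_params, c(list(params), stats::setNames(list(value), axis)))
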