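test_that("sigmoid activation is bounded, monotone, and overflow-safe", {
  expect_equal(sigmoid_activation(0), 0.5)
  # direct closed-form evaluation at two nearby points
  lneps <- log(2e5)
  expect_equal(sigmoid_activation(0.001), 1 / (1 + exp(-0.001 * lneps)))
  expect_lt(sigmoid_activation(0.001), sigmoid_activation(0.002))
  expect_gt(sigmoid_activation(0.001), 0.5)
  # saturation without overflow even at huge |x|
  expect_equal(sigmoid_activation(1e6), 1)
  expect_equal(sigmoid_activation(-1e6), 0)
  x <- seq(-2, 2, length.out = 101)
  f <- sigmoid_activation(x)
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(f) > 0))
  expect_error(sigmoid_activation(Inf), "finite")
  expect_error(sigmoid_activation(0.5, epsilon = 1), "epsilon")
})

test_that("linear activation is exact, including degenerate slope", {
  expect_equal(linear_activation(0), 0.5)
  expect_equal(linear_activation(1), 3.3)
  expect_equal(linear_activation(c(-5, 0, 7), a = 0, b = 0.5), rep(0.5, 3))
  expect_equal(linear_activation(2, a = -1, b = 3), 1)
})

test_that("model vector field matches the hand-written population equations", {
  p <- p_default
  X <- random_states(10, seed = 11)
  f <- function(x) sigmoid_activation(x, p$epsilon)
  s <- function(x) linear_activation(x, p$a, p$b)
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    expected <- c(
      p$tau_e * (p$h_e - x[1] + p$c_ee * f(x[1]) - p$c_ei * f(x[2]) +
                   p$c_et * f(x[3])),
      p$tau_i * (p$h_i - x[2] + p$c_ie * f(x[1])),
      p$tau_t * (p$h_t - x[3] + p$c_te * f(x[1]) - p$c_tr * s(x[4])),
      p$tau_r * (p$h_r - x[4] + p$c_re * f(x[1]) + p$c_rt * s(x[3]) -
                   p$c_rr * s(x[4]))
    )
    expect_equal(unname(model_rhs(x, p)), unname(expected), tolerance = 1e-12)
    # compiled core computes the identical field
    expect_equal(unname(model_rhs(x, p)),
                 as.numeric(swdcontrol:::.model_rhs_cpp(x, unclass(p))),
                 tolerance = 1e-12)
  }
})

test_that("saturated and decoupled limits of the vector field hold", {
  p <- p_default
  # all f-terms saturated: dIN/dt -> tau_i (h_i - IN + c_ie)
  x <- c(PY = 5, IN = 5, TC = 5, RE = 0.1)
  d <- model_rhs(x, p)
  expect_equal(unname(d["IN"]), p$tau_i * (p$h_i - 5 + p$c_ie),
               tolerance = 1e-9)
  # zero connectivity: pure decay to the h offsets
  p0 <- update_params(p, c_ee = 0, c_ei = 0, c_et = 0, c_ie = 0, c_te = 0,
                      c_tr = 0, c_re = 0, c_rt = 0, c_rr = 0)
  x <- c(PY = 0.3, IN = -1, TC = 0.2, RE = 0.9)
  d0 <- model_rhs(x, p0)
  expect_equal(unname(d0),
               unname(c(p0$tau_e, p0$tau_i, p0$tau_t, p0$tau_r) *
                        (c(p0$h_e, p0$h_i, p0$h_t, p0$h_r) - x)),
               tolerance = 1e-12)
  expect_error(model_rhs(c(1, NaN, 0, 0), p), "finite")
})

test_that("EEG observation is the convex cortical combination", {
  p <- p_default
  expect_equal(eeg_observation(c(PY = 1, IN = -1, TC = 0, RE = 0), p), 0)
  expect_equal(eeg_observation(c(PY = 0.2, IN = 0.4, TC = 9, RE = -9), p), 0.3)
  p73 <- update_params(p, c1 = 0.7, c2 = 0.3)
  expect_equal(eeg_observation(c(PY = 0.4, IN = 0.4, TC = 0, RE = 0), p73), 0.4)
  X <- random_states(5, seed = 2)
  expect_equal(eeg_observation(X, p), 0.5 * X[, 1] + 0.5 * X[, 2])
})

test_that("analytic Jacobian matches central finite differences", {
  p <- p_default
  X <- random_states(20, seed = 21, lo = -2, hi = 1.5)
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    J <- model_jacobian(x, p)
    Jnum <- swdcontrol:::num_jacobian(function(z) unname(model_rhs(z, p)), x)
    denom <- pmax(abs(Jnum), 1)
    expect_lt(max(abs(J - Jnum) / denom), 1e-5)
  }
  # structural facts read off the equations
  x <- X[1, ]
  J <- model_jacobian(x, p)
  expect_equal(J["IN", "IN"], -p$tau_i)
  expect_equal(J["PY", "RE"], 0)
  expect_equal(J["IN", "TC"], 0)
  expect_equal(J["TC", "RE"], -p$tau_t * p$c_tr * p$a)
})

test_that("parameter validation and serialization round-trip", {
  expect_error(tc_params(tau_e = -1), "tau")
  expect_error(tc_params(epsilon = 0.5), "epsilon")
  expect_error(tc_params(c_ee = -0.1), "connectivity")
  expect_error(tc_params(c1 = 0.2, c2 = 0.8), "observation")
  expect_error(update_params(p_default, nope = 1), "unknown")
  p <- tc_params(c_tr = 0.45, c_te = 3.1)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("pars.", ext))
    write_params(p, path)
    p2 <- read_params(path)
    expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
  }
})
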