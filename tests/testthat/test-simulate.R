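test_that("one RK4 step has fourth-order accuracy on the decoupled system", {
  # zero connectivity: each population decays exponentially to its offset,
  # so the exact solution is known in closed form
  p0 <- update_params(p_default, c_ee = 0, c_ei = 0, c_et = 0, c_ie = 0,
                      c_te = 0, c_tr = 0, c_re = 0, c_rt = 0, c_rr = 0)
  x0 <- c(PY = 1, IN = -1, TC = 0.5, RE = -2)
  h_off <- c(p0$h_e, p0$h_i, p0$h_t, p0$h_r)
  taus <- c(p0$tau_e, p0$tau_i, p0$tau_t, p0$tau_r)
  err_of <- function(dt) {
    exact <- h_off + (x0 - h_off) * exp(-taus * dt)
    max(abs(integrate_step(x0, p0, dt) - exact))
  }
  e1 <- err_of(0.002)
  e2 <- err_of(0.001)
  expect_lt(e1, 1e-7)
  # local error scales as dt^5: halving the step divides it by ~32
  expect_gt(e1 / e2, 20)
  expect_lt(e1 / e2, 45)
})

test_that("full-model trajectory converges under step halving", {
  x0 <- c(0.1, 0.1, 0.1, 0.1)
  tr1 <- simulate_tc(p_case1, x0, 2, dt = 0.001)
  tr2 <- simulate_tc(p_case1, x0, 2, dt = 1e-4)
  idx <- seq(1, length(tr2$y), by = 10)
  expect_lt(max(abs(tr1$y - tr2$y[idx])), 1e-4)
})

test_that("an equilibrium is a fixed point of the integrator", {
  eq <- find_equilibrium(p_case1, c(0.2, 0.2, -0.1, 0.3))
  stepped <- integrate_step(eq, p_case1, 0.001)
  expect_lt(max(abs(stepped - eq)), 1e-12)
  tr <- simulate_tc(p_case1, eq, 2)
  expect_lt(diff(range(tr$y)), 1e-9)
})

test_that("simulation is bit-reproducible under identical seeds", {
  x0 <- swd_initial_case1()
  args <- list(p_case1, x0, 3, noise = noise_spec(sd = 1, seed = 42L),
               pulses = pulse_train(c(0.5, 1.5), 25))
  tr1 <- do.call(simulate_tc, args)
  tr2 <- do.call(simulate_tc, args)
  expect_identical(tr1$y, tr2$y)
  expect_identical(tr1$states, tr2$states)
  tr3 <- simulate_tc(p_case1, x0, 3, noise = noise_spec(sd = 1, seed = 43L))
  expect_false(identical(tr1$y, tr3$y))
})

test_that("zero-sd noise leaves the trajectory exactly noise-free", {
  x0 <- c(0.1, 0.1, 0.1, 0.1)
  tr_plain <- simulate_tc(p_case1, x0, 2)
  tr_sd0 <- simulate_tc(p_case1, x0, 2, noise = noise_spec(sd = 0, seed = 1L))
  expect_identical(tr_plain$y, tr_sd0$y)
})

test_that("pulse trains enter only over their active windows", {
  p0 <- update_params(p_default, c_ee = 0, c_ei = 0, c_et = 0, c_ie = 0,
                      c_te = 0, c_tr = 0, c_re = 0, c_rt = 0, c_rr = 0)
  eqs <- c(p0$h_e, p0$h_i, p0$h_t, p0$h_r)
  tr <- simulate_tc(p0, eqs, 1, pulses = pulse_train(0.3, 5, width = 0.1,
                                                     target = "RE"))
  expect_equal(unname(tr$d[tr$t >= 0.3 & tr$t < 0.4][1]), 5)
  expect_true(all(tr$d[tr$t < 0.3] == 0))
  # only RE moves; cortical populations stay at their decoupled equilibrium
  expect_lt(max(abs(tr$states[, "PY"] - p0$h_e)), 1e-12)
  expect_gt(max(abs(tr$states[, "RE"] - p0$h_r)), 0.1)
  expect_error(pulse_train(c(2, 1), 1), "sorted|unsorted")
  expect_error(pulse_train(1, 1, width = 0), "width")
})

test_that("trajectories export tidy CSV and report divergence", {
  tr <- simulate_tc(p_case1, c(0.1, 0.1, 0.1, 0.1), 1)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("t", "PY", "IN", "TC", "RE", "y", "u", "d"))
  expect_equal(nrow(df), length(tr$t))
  expect_equal(df$y, tr$y, tolerance = 1e-12)
  # an overflow-scale kick reports the diverging component and time
  expect_error(
    simulate_tc(p_case1, c(0.1, 0.1, 0.1, 0.1), 1,
                pulses = pulse_train(0.1, 1e308, width = 0.5, target = "PY")),
    "diverged.*PY")
})

test_that("zero-amplitude single pulses leave segment labels unchanged", {
  x0 <- swd_initial_case1()
  ex <- single_pulse_experiment(p_case1, x0, pulse_train(10, 0), 20)
  expect_equal(nrow(ex$segments), 2)
  expect_equal(ex$segments$label[1], ex$segments$label[2])
  expect_match(ex$segments$label[1], "SWD")
})

test_that("a properly timed negative pulse abates the 2-SWD state", {
  p <- tc_params(c_tr = 0.45, c_te = 3)
  x0 <- find_basin_state(p, "SWD", m = 2, seed = 1L)
  hit <- find_switching_pulse(p, x0, "LS", amplitudes = c(-10, -25, -50),
                              n_phases = 10)
  expect_s3_class(hit$pulse, "pulse_train")
  expect_lt(hit$pulse$amplitude, 0)
  expect_equal(hit$label$kind, "LS")
})

test_that("the background state is pulse-sensitive in the multistable regime", {
  # from the normal background at a strongly coupled operating point, some
  # single pulse kicks the system into a pathological oscillation
  p <- tc_params(c_tr = 1.5, c_te = 3.5)
  xls <- ls_equilibrium(p)
  hit <- find_switching_pulse(p, xls, "CO", amplitudes = c(-25, 25),
                              onset = 5, n_phases = 2, duration = 15)
  expect_equal(hit$label$kind, "CO")
})
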