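test_that("sliding surface and sign law follow their conventions", {
  expect_equal(sliding_surface(0.3, 0.1), 0.2)
  expect_equal(sliding_surface(0.1, 0.1), 0)
  a <- runif(10); b <- runif(10)
  expect_equal(sliding_surface(a, b), -sliding_surface(b, a))
  expect_identical(sign_law(0), 1)        # sign(0) = +1 by convention
  expect_identical(sign_law(-1e-9), -1)
  expect_identical(sign_law(5), 1)
  expect_equal(sign_law(c(-2, 0, 3)), c(-1, 1, 1))
})

test_that("the Gaussian RBF basis peaks at its centers", {
  centers <- seq(-1, 1, length.out = 11)
  phi <- rbf_basis(centers[4], centers, width = 1)
  expect_equal(phi[4], 1)
  expect_true(all(phi > 0 & phi <= 1))
  expect_lt(max(rbf_basis(100, centers, 1)), 1e-20)  # far field -> 0
  # symmetric centers respond symmetrically at s = 0
  expect_equal(rbf_basis(0, c(-0.5, 0.5), 1)[1],
               rbf_basis(0, c(-0.5, 0.5), 1)[2])
})

test_that("the adaptive weight law has the stabilizing sign and fixed point", {
  th <- rep(0, 5); phi <- rep(0.5, 5)
  expect_identical(update_nn_weights(th, 0, phi, 10, 1, 1e-3), th)
  # s > 0 grows the weights so that -theta'phi pulls u down
  th1 <- update_nn_weights(th, 0.5, phi, 10, 1, 1e-3)
  expect_true(all(th1 > 0))
  expect_equal(th1, 10 * 0.5 * phi * 1e-3)
  # with s held constant the law settles at theta* = phi * sign(s) / k_c
  s <- 0.3; kc <- 2; gam <- 10
  theta <- rep(0, 5)
  for (i in 1:20000) theta <- update_nn_weights(theta, s, phi, gam, kc, 1e-3)
  expect_equal(theta, phi * sign(s) / kc, tolerance = 1e-6)
  expect_error(update_nn_weights(c(Inf, 0), 1, c(1, 1), 1, 1, 1e-3),
               "finite")
})

test_that("the switching-term low-pass filter is an exact exponential", {
  expect_equal(lpf_step(1, 0.2, 0.01, 0.001), 1)   # already at sign(s)
  # step response from 0 toward +1 with time constant tau
  z <- 0; tau <- 0.01; dt <- 1e-3
  for (i in 1:10) z <- lpf_step(z, 1, tau, dt)     # t = tau
  expect_equal(z, 1 - exp(-1), tolerance = 1e-12)
  # monotone approach
  zs <- Reduce(function(z, .) lpf_step(z, 1, tau, dt), 1:50, accumulate = TRUE, 0)
  expect_true(all(diff(zs) > 0))
  expect_error(lpf_step(0, 1, 0, 1e-3), "tau_filter")
})

test_that("controller output composes the law of each method", {
  st <- list(s_value = 0.2, theta_hat = rep(0, 11), z = 0)
  expect_equal(control_output(controller_config("feedback"), st), -0.2)
  expect_equal(control_output(controller_config("hybrid"), st), -0.2)
  # zero state gives zero output for every method
  st0 <- list(s_value = 0, theta_hat = rep(0, 11), z = 0)
  for (m in c("feedback", "feedback+rbf", "feedback+smc", "hybrid"))
    expect_equal(control_output(controller_config(m), st0), 0)
  # hybrid with zero weights reduces to feedback+smc
  st2 <- list(s_value = 0.4, theta_hat = rep(0, 11), z = 0.7)
  expect_equal(control_output(controller_config("hybrid"), st2),
               control_output(controller_config("feedback+smc"), st2))
  # raw switching uses sign(s), not the filter state
  expect_equal(control_output(controller_config("feedback+smc-raw"), st2),
               -0.4 - 1)
  expect_error(controller_config("nope"), "arg")
})

test_that("a null controller reproduces the open loop seed-for-seed", {
  x0 <- swd_initial_case1()
  ref <- generate_background_reference(p_case1, 6,
                                       noise = noise_spec(sd = 1, seed = 9L))
  cfg <- controller_config("feedback", lam = 0, switch_on_time = 0)
  closed <- closed_loop_simulate(p_case1, x0, ref, cfg,
                                 noise = noise_spec(sd = 1, seed = 4L),
                                 duration = 6)
  open <- simulate_tc(p_case1, x0, 6, noise = noise_spec(sd = 1, seed = 4L))
  expect_true(all(closed$u == 0))
  expect_identical(closed$y, open$y)
  expect_identical(closed$states, open$states)
})

test_that("the hybrid controller abates the seizure state", {
  x0 <- swd_initial_case1()
  ref <- generate_background_reference(p_case1, 14,
                                       noise = noise_spec(sd = 1, seed = 9L))
  r <- closed_loop_simulate(p_case1, x0, ref, controller_config("hybrid"),
                            noise = noise_spec(sd = 1, seed = 4L),
                            duration = 14)
  rms_pre <- sqrt(mean(r$e[r$t < 4]^2))
  rms_post <- sqrt(mean(r$e[r$t >= 9]^2))
  expect_lt(rms_post, 0.1 * rms_pre)
  # Lyapunov surrogate: non-negative, and the tracking term collapses
  # after switch-on
  V <- lyapunov_diagnostics(r)
  expect_true(all(V$V_hat >= 0))
  expect_lt(max(V$half_s2[V$t > 9]), max(V$half_s2[V$t >= 4 & V$t < 4.5]))
})

test_that("moving the switch-on time does not change settled performance", {
  x0 <- swd_initial_case1()
  ref <- generate_background_reference(p_case1, 16,
                                       noise = noise_spec(sd = 1, seed = 9L))
  rms_tail <- function(t_on) {
    r <- closed_loop_simulate(p_case1, x0, ref,
                              controller_config("hybrid", switch_on_time = t_on),
                              noise = noise_spec(sd = 1, seed = 4L),
                              duration = 16)
    sqrt(mean(r$e[r$t >= 12]^2))
  }
  r4 <- rms_tail(4); r6 <- rms_tail(6)
  expect_lt(abs(r4 - r6), 0.2 * max(r4, r6))
})

test_that("adaptation-rate choice does not alter the qualitative outcome", {
  x0 <- swd_initial_case1()
  ref <- generate_background_reference(p_case1, 12,
                                       noise = noise_spec(sd = 1, seed = 9L))
  for (g in c(1, 10, 100)) {
    r <- closed_loop_simulate(p_case1, x0, ref,
                              controller_config("hybrid", gamma = g),
                              noise = noise_spec(sd = 1, seed = 4L),
                              duration = 12)
    expect_lt(sqrt(mean(r$e[r$t >= 9]^2)), 0.05,
              label = sprintf("settled rms(e) at gamma = %g", g))
  }
})

test_that("low-pass filtering the switching term removes chattering", {
  x0 <- swd_initial_case1()
  ref <- generate_background_reference(p_case1, 12,
                                       noise = noise_spec(sd = 1, seed = 9L))
  du <- function(method) {
    r <- closed_loop_simulate(p_case1, x0, ref, controller_config(method),
                              noise = noise_spec(sd = 1, seed = 4L),
                              duration = 12)
    mean(abs(diff(r$u[r$t >= 6]))) / r$dt
  }
  expect_lt(du("feedback+smc"), 0.5 * du("feedback+smc-raw"))
})

test_that("the variance trigger stays silent on a quiet plant", {
  xls <- ls_equilibrium(p_case1)
  ref <- generate_background_reference(p_case1, 5,
                                       noise = noise_spec(sd = 0, seed = 1L))
  vt <- variance_trigger_control(p_case1, xls, ref, controller_config("feedback"),
                                 trigger = trigger_config(), duration = 5)
  expect_equal(nrow(vt$events), 0)
  expect_true(all(vt$trigger_state == 0))
  expect_lt(max(vt$var_window, na.rm = TRUE), 1e-6)
  expect_error(trigger_config(window = 0.04, step = 0.05), "window")
})

test_that("an induced seizure trips the trigger and is abated", {
  xls <- ls_equilibrium(p_case1)
  ref <- generate_background_reference(p_case1, 16,
                                       noise = noise_spec(sd = 1, seed = 9L))
  vt <- variance_trigger_control(p_case1, xls, ref, controller_config("feedback"),
                                 trigger = trigger_config(),
                                 noise = noise_spec(sd = 1, seed = 3L),
                                 disturbance = pulse_train(4, 25, 0.02, "RE"),
                                 duration = 16)
  expect_gte(nrow(vt$events), 1)
  expect_equal(vt$events$event[1], "trigger_on")
  expect_gt(vt$events$time[1], 4)            # fires only after the seizure
  # control is bounded to the action windows
  expect_true(any(vt$trigger_state == 1))
  expect_true(all(vt$u[vt$trigger_state == 0] == 0))
  # the plant ends in the background basin
  tail_tr <- simulate_tc(p_case1, vt$states[nrow(vt$states), ], 12)
  expect_equal(classify_state(tail_tr)$kind, "LS")
})
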