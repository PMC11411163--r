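test_that("with no lysis the total density follows the logistic closed form", {
  p <- logistic_params()
  traj <- simulate_dynamics(p, induction_constant(100),
                            initial_state(0.01, 0), t_end = 10, dt = 1e-3,
                            check_convergence = FALSE)
  expected <- logistic_closed_form(traj$t_h, 0.01, p$gamma0, p$rho_s)
  expect_lt(max(abs(traj$total - expected)), 2e-4)
})

test_that("no induction means no toxin and pure logistic growth", {
  p <- ref_params()
  p$beta0 <- 0
  traj <- simulate_dynamics(p, induction_constant(100), initial_state(0.01, 0),
                            t_end = 10, dt = 1e-3, check_convergence = FALSE)
  expect_true(all(traj$p == 0))
  expected <- logistic_closed_form(traj$t_h, 0.01, p$gamma0, p$rho_s)
  expect_lt(max(abs(traj$total - expected)), 2e-4)
})

test_that("extinction of the therapeutic strain is absorbing", {
  traj <- simulate_dynamics(ref_params(), induction_constant(100),
                            c(x = 0, y = 1e-4, p = 0), t_end = 10,
                            check_convergence = FALSE)
  expect_true(all(traj$x == 0))
  expect_true(all(traj$fraction_mutant == 1))
})

test_that("forward Euler converges to the logistic solution at order one", {
  p <- logistic_params(gamma0 = 1.57, rho_s = 0.33)
  dts <- c(0.02, 0.01, 0.005, 0.0025)
  errs <- vapply(dts, function(dt) {
    traj <- simulate_dynamics(p, induction_constant(0),
                              initial_state(0.01, 0), t_end = 8, dt = dt,
                              check_convergence = FALSE)
    max(abs(traj$total - logistic_closed_form(traj$t_h, 0.01, p$gamma0,
                                              p$rho_s)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  slope <- coef(lm(log(errs) ~ log(dts)))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("mutant fraction is non-decreasing along trajectories", {
  for (ahl in c(0, 20, 100)) {
    traj <- simulate_dynamics(ref_params(), induction_constant(ahl),
                              initial_state(0.01, 7e-5), t_end = 24,
                              dt = 2e-3, check_convergence = FALSE)
    expect_true(all(diff(traj$fraction_mutant) > -1e-12))
  }
})

test_that("toxin concentration respects the production bound", {
  p <- ref_params()
  traj <- simulate_dynamics(p, induction_constant(100),
                            initial_state(0.01, 7e-5), t_end = 24, dt = 2e-3,
                            check_convergence = FALSE)
  expect_true(all(traj$p <= beta_of_ahl(100, p) * traj$t_h + 1e-9))
})

test_that("the mutant fraction is invariant to a common density rescaling", {
  p1 <- ref_params()
  s <- 7.3
  p2 <- p1
  p2$rho_s <- p1$rho_s * s
  t1 <- simulate_dynamics(p1, 100, initial_state(0.01, 7e-5), t_end = 20,
                          dt = 2e-3, check_convergence = FALSE)
  t2 <- simulate_dynamics(p2, 100, initial_state(0.01 * s, 7e-5), t_end = 20,
                          dt = 2e-3, check_convergence = FALSE)
  expect_equal(t2$fraction_mutant, t1$fraction_mutant, tolerance = 1e-9)
  expect_equal(t2$total, s * t1$total, tolerance = 1e-9)
})

test_that("trajectory bookkeeping: grid, load monotonicity, attributes", {
  traj <- simulate_dynamics(ref_params(), induction_square_wave(100, 6, 1),
                            initial_state(), t_end = 12, dt = 1e-3,
                            record_every = 10, check_convergence = FALSE)
  expect_true(all(diff(traj$t_h) > 0))
  expect_true(all(diff(traj$released_load) > -1e-15))
  expect_s3_class(traj, "lysim_trajectory")
  expect_identical(attr(traj, "model"), "core")
  expect_equal(traj$ahl_nM[1], 100)
  # OFF segment of the square wave is really off
  expect_equal(traj$ahl_nM[traj$t_h == 3], 0)
  final <- attr(traj, "final_state")
  expect_equal(unname(final[["x"]]), traj$x[nrow(traj)])
})

test_that("a divergent integration reports the offending time", {
  # an (unphysical) production rate near the double-precision ceiling
  # overflows p within one step
  p <- model_params(gamma0 = 1, rho_s = 1, alpha0 = 0, K = 1, n = 1,
                    beta0 = 1e308, k = 1, m = 1, delta = 0)
  expect_error(
    simulate_dynamics(p, 100, initial_state(0.01, 0), t_end = 20, dt = 10,
                      check_convergence = FALSE),
    "non-finite state at t")
})

test_that("the half-step convergence check warns on a too-coarse grid", {
  expect_warning(
    simulate_dynamics(ref_params(), 100, initial_state(), t_end = 24,
                      dt = 0.25, convergence_tol = 1e-4),
    "not converged")
  expect_no_warning(
    simulate_dynamics(ref_params(), 100, initial_state(), t_end = 24,
                      dt = 1e-3, convergence_tol = 0.05))
})

test_that("square-wave and equivalent piecewise programs give identical runs", {
  sq <- induction_square_wave(100, period = 6, on_duration = 1.5)
  pw <- induction_piecewise(c(0, 1.5, 6, 7.5, 12, 13.5),
                            c(100, 0, 100, 0, 100, 0))
  t1 <- simulate_dynamics(ref_params(), sq, initial_state(), t_end = 18,
                          dt = 2e-3, check_convergence = FALSE)
  t2 <- simulate_dynamics(ref_params(), pw, initial_state(), t_end = 18,
                          dt = 2e-3, check_convergence = FALSE)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$released_load, t2$released_load)
})
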