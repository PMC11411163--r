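test_that("induction Hill fit recovers noiseless truth and rejects bad designs", {
  cal <- generate_beta_calibration(6.1, 19, 1, ahl = log_spaced(1, 1000, 8),
                                   noise = no_noise())
  fit <- fit_beta_hill(cal)
  est <- tidy(fit)
  expect_rel_equal(est$estimate, c(6.1, 19, 1), 1e-3)
  expect_true(glance(fit)$converged)
  expect_lt(glance(fit)$ssr, 1e-10)
  aug <- augment(fit)
  expect_equal(aug$.fitted, cal$beta, tolerance = 1e-5)

  expect_error(fit_beta_hill(tibble::tibble(ahl_nM = c(1, 100),
                                            beta = c(0.3, 5))), "4 distinct")
  expect_error(fit_beta_hill(tibble::tibble(ahl_nM = rep(50, 6),
                                            beta = rnorm(6, 3))),
               "4 distinct")
})

test_that("growth-curve fit recovers free parameters from clean curves", {
  withr::local_seed(7)
  p <- ref_params()
  gc <- generate_plate_reader(p, ahl = c(5, 20, 100), f0 = 7e-5,
                              duration = 16, replicates = 1,
                              noise = no_noise(), dt = 2e-3)
  truth <- c(alpha0 = 1.39, K = 3.29)
  fit <- fit_growth_curves(gc, free = c("alpha0", "K"),
                           params = params_preset(),
                           init = c(x0 = 0.01 * (1 - 7e-5), y0 = 0.01 * 7e-5),
                           n_starts = 6, dt = 2e-3)
  expect_rel_equal(tidy(fit)$estimate, unname(truth[tidy(fit)$term]), 0.01)
  expect_true(glance(fit)$converged)
})

test_that("growth-curve fit objective is invariant to record order", {
  withr::local_seed(8)
  p <- ref_params()
  gc <- generate_plate_reader(p, ahl = c(20, 100), f0 = 7e-5, duration = 10,
                              replicates = 2,
                              noise = noise_model(0.03, 0, 0, seed = 3),
                              dt = 5e-3)
  shuffled <- gc[sample(nrow(gc)), ]
  f1 <- fit_growth_curves(gc, free = "alpha0", params = p,
                          init = c(x0 = 0.01 * (1 - 7e-5),
                                   y0 = 0.01 * 7e-5),
                          n_starts = 2, dt = 5e-3)
  f2 <- fit_growth_curves(shuffled, free = "alpha0", params = p,
                          init = c(x0 = 0.01 * (1 - 7e-5),
                                   y0 = 0.01 * 7e-5),
                          n_starts = 2, dt = 5e-3)
  expect_equal(glance(f1)$ssr, glance(f2)$ssr, tolerance = 1e-8)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
})

test_that("growth-curve fit raises estimation errors on degenerate designs", {
  p <- ref_params()
  one_point <- tibble::tibble(time_h = 0, od600 = 0.01, ahl_nM = 100,
                              replicate = 1)
  expect_error(fit_growth_curves(one_point, free = "alpha0", params = p),
               "2 distinct time points")
  expect_error(fit_growth_curves(
    generate_plate_reader(p, 100, duration = 2, replicates = 1,
                          noise = no_noise(), dt = 5e-3),
    free = "bogus", params = p), "subset")
})

test_that("composition estimation recovers the initial mutant fraction", {
  withr::local_seed(9)
  p <- ref_params()
  f0 <- 7e-5
  gc <- generate_plate_reader(p, ahl = 100, f0 = f0, duration = 16,
                              replicates = 1, noise = no_noise(), dt = 2e-3)
  est <- estimate_mutant_fraction(gc, p, n_starts = 6, dt = 2e-3)
  expect_lt(abs(est$f0 - f0) / f0, 0.05)
  expect_false(est$flagged)
})

test_that("composition estimation is monotone in the true mutant fraction", {
  withr::local_seed(10)
  p <- ref_params()
  f0s <- c(1e-6, 1e-4, 1e-2, 1e-1)
  ests <- vapply(f0s, function(f0) {
    gc <- generate_plate_reader(p, ahl = 100, f0 = f0, duration = 16,
                                replicates = 1, noise = no_noise(),
                                dt = 4e-3)
    estimate_mutant_fraction(gc, p, n_starts = 4, dt = 4e-3)$f0
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("a mutant-free culture is flagged with y0 at its lower bound", {
  withr::local_seed(11)
  p <- ref_params()
  gc <- generate_plate_reader(p, ahl = 100, f0 = 0, duration = 16,
                              replicates = 1, noise = no_noise(), dt = 4e-3)
  est <- estimate_mutant_fraction(gc, p, n_starts = 4, dt = 4e-3)
  expect_true(est$flagged)
  expect_lt(est$f0, 1e-6)
  expect_match(est$note, "lower bound|regrowth")
})

test_that("induction-time fraction fit is exact on clean data and errs correctly", {
  t_ind <- c(0.5, 1, 2, 3, 5)
  d <- tibble::tibble(t_ind_h = t_ind,
                      fraction = fraction_constant_alpha(t_ind, 2.1, 4.2e-5))
  est <- tidy(fit_fraction_vs_induction(d))
  expect_equal(est$estimate[est$term == "alpha"], 2.1, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "f0"], 4.2e-5, tolerance = 1e-10)

  expect_error(fit_fraction_vs_induction(d[1:2, ]), "at least 3")
  expect_error(fit_fraction_vs_induction(
    tibble::tibble(t_ind_h = 1:4, fraction = rep(0.3, 4))), "identical")
  expect_error(fit_fraction_vs_induction(
    tibble::tibble(t_ind_h = 1:3, fraction = c(0.1, 0.5, 1))), "strictly")
})

test_that("induction-time fit intervals have near-nominal coverage", {
  alpha_true <- 2.1
  f0_true <- 4.2e-5
  t_ind <- c(0.5, 1, 2, 3, 4, 5, 6)
  clean_logit <- qlogis(fraction_constant_alpha(t_ind, alpha_true, f0_true))
  hits <- vapply(1:200, function(s) {
    f_obs <- withr::with_seed(s, plogis(clean_logit + rnorm(7, 0, 0.3)))
    est <- tidy(fit_fraction_vs_induction(
      tibble::tibble(t_ind_h = t_ind, fraction = f_obs)))
    a <- est$estimate[est$term == "alpha"]
    se <- est$std_error[est$term == "alpha"]
    abs(a - alpha_true) <= qt(0.975, 5) * se
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(hits), 0.99)
})
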