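test_that("noise-free sampling reproduces the simulated density exactly", {
  p <- ref_params()
  gc <- generate_plate_reader(p, ahl = 100, f0 = 7e-5, duration = 12,
                              replicates = 2, noise = no_noise(), dt = 2e-3)
  traj <- simulate_dynamics(p, 100, initial_state(0.01, 7e-5), t_end = 12,
                            dt = 2e-3, check_convergence = FALSE)
  one <- gc[gc$replicate == 1, ]
  expect_equal(one$od600,
               approx(traj$t_h, traj$total, xout = one$time_h)$y,
               tolerance = 1e-12)
  # replicates are identical without noise
  expect_equal(gc$od600[gc$replicate == 2], one$od600)
  # default design bookkeeping
  expect_equal(sort(unique(gc$replicate)), 1:2)
  expect_equal(unique(gc$condition), "ahl_100")
  expect_equal(diff(sort(unique(gc$time_h)))[1], 1 / 6, tolerance = 1e-12)
})

test_that("induced curves crash and regrow; uninduced controls do not", {
  p <- ref_params()
  gc <- generate_plate_reader(p, ahl = c(0, 100), f0 = 7e-5,
                              replicates = 1, noise = no_noise(), dt = 2e-3)
  smooth_diff_signs <- function(od) {
    sm <- stats::filter(od, rep(1 / 7, 7), sides = 2)
    sm <- sm[!is.na(sm)]
    sign(diff(sm))
  }
  signs <- smooth_diff_signs(gc$od600[gc$condition == "ahl_100"])
  signs <- signs[signs != 0]
  expect_gte(sum(diff(signs) != 0), 2)  # growth -> crash -> regrowth
  control <- gc$od600[gc$condition == "ahl_0"]
  expect_true(all(diff(control) > -1e-9))
})

test_that("generation is reproducible by seed with a shared noiseless mean", {
  p <- logistic_params()
  g1 <- generate_plate_reader(p, ahl = 0, duration = 6, replicates = 1,
                              noise = noise_model(0.05, 0.002, 0.04,
                                                  seed = 11), dt = 5e-3)
  g2 <- generate_plate_reader(p, ahl = 0, duration = 6, replicates = 1,
                              noise = noise_model(0.05, 0.002, 0.04,
                                                  seed = 11), dt = 5e-3)
  g3 <- generate_plate_reader(p, ahl = 0, duration = 6, replicates = 1,
                              noise = noise_model(0.05, 0.002, 0.04,
                                                  seed = 12), dt = 5e-3)
  expect_identical(g1, g2)
  expect_false(identical(g1$od600, g3$od600))
})

test_that("the ensemble mean converges to the noiseless curve", {
  p <- logistic_params()
  clean <- generate_plate_reader(p, ahl = 0, duration = 6, interval = 3,
                                 replicates = 1, noise = no_noise(),
                                 dt = 5e-3)
  draws <- vapply(1:60, function(s) {
    generate_plate_reader(p, ahl = 0, duration = 6, interval = 3,
                          replicates = 1,
                          noise = noise_model(0.05, 0, 0, seed = s),
                          dt = 5e-3)$od600
  }, numeric(3))
  expect_rel_equal(rowMeans(draws), clean$od600, 0.03)
})

test_that("growth-curve sets round-trip through the text format exactly", {
  gc <- generate_plate_reader(ref_params(), ahl = c(1, 100), duration = 4,
                              replicates = 2,
                              noise = noise_model(seed = 5), dt = 5e-3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_growth_curves(gc, f)
  back <- read_growth_curves(f)
  expect_identical(back$od600, gc$od600)
  expect_identical(back$time_h, gc$time_h)
  expect_identical(back$replicate, gc$replicate)
  expect_identical(back$condition, gc$condition)
})

test_that("passaging series: single leg equals the plain generator", {
  p <- ref_params()
  sched <- tibble::tibble(duration = 8, ahl = 100)
  pr <- generate_passaging_series(p, sched, dilution_factor = 100, f0 = 7e-5,
                                  replicates = 1, noise = no_noise(),
                                  dt = 2e-3)
  gc <- generate_plate_reader(p, ahl = 100, f0 = 7e-5, duration = 8,
                              replicates = 1, noise = no_noise(), dt = 2e-3)
  expect_equal(pr$od600, gc$od600, tolerance = 1e-12)
})

test_that("a unit dilution factor yields a contiguous trajectory", {
  p <- ref_params()
  sched <- tibble::tibble(duration = c(4, 4), ahl = c(100, 100))
  pr <- generate_passaging_series(p, sched, dilution_factor = 1, f0 = 7e-5,
                                  replicates = 1, noise = no_noise(),
                                  dt = 2e-3)
  gc <- generate_plate_reader(p, ahl = 100, f0 = 7e-5, duration = 8,
                              replicates = 1, noise = no_noise(), dt = 2e-3)
  joined <- dplyr::inner_join(pr, gc, by = "time_h",
                              suffix = c("_leg", "_one"))
  expect_equal(joined$od600_leg, joined$od600_one, tolerance = 1e-6)
})

test_that("mutant-dominated cultures stop crashing after re-induction", {
  p <- ref_params()
  p$alpha0 <- 2.1
  sched <- tibble::tibble(duration = c(23, 23, 23), ahl = c(0, 100, 100))
  pr <- generate_passaging_series(p, sched, dilution_factor = 100, f0 = 7e-5,
                                  replicates = 1, noise = no_noise(),
                                  dt = 2e-3)
  # crash = a drop of >30% below the first local density maximum
  has_crash <- function(od) {
    d <- diff(od)
    turn <- which(d[-length(d)] > 0 & d[-1] <= 0)
    if (length(turn) == 0) return(FALSE)
    pk <- turn[1] + 1
    min(od[pk:length(od)]) < 0.7 * od[pk]
  }
  expect_true(has_crash(pr$od600[pr$leg == 2]))   # first induction: lysis
  expect_false(has_crash(pr$od600[pr$leg == 3]))  # mutants took over
})

test_that("induction-response calibration data behave as specified", {
  cal <- generate_beta_calibration(6.1, 19, 1, ahl = c(1, 10, 19, 100, 1000),
                                   noise = no_noise())
  expect_equal(cal$beta[3], 6.1 / 2)
  expect_equal(cal$beta, 6.1 * hill(cal$ahl_nM, 19, 1))
  # Monte-Carlo: recovery error of the downstream fit is below the noise CV
  errs <- vapply(1:100, function(s) {
    d <- generate_beta_calibration(6.1, 19, 1, ahl = log_spaced(1, 1000, 8),
                                   noise = noise_model(0.05, 0, 0, seed = s))
    est <- tidy(fit_beta_hill(d, n_starts = 2))
    abs(est$estimate[est$term == "beta0"] - 6.1) / 6.1
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
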