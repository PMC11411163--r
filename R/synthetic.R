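#' Plate-reader measurement noise model
#'
#' A simple but realistic description of OD600 measurement error:
#' multiplicative lognormal noise (a constant coefficient of variation),
#' additive Gaussian baseline noise, and a constant blank offset. All three
#' components can be switched off by setting them to zero.
#'
#' @param multiplicative_cv Relative (multiplicative) noise, e.g. 0.03.
#' @param additive_sd Additive baseline noise SD (a.u.).
#' @param baseline_offset Constant blank offset added to every reading
#'   (a.u.); subtract it before fitting.
#' @param seed Integer seed making the generated dataset reproducible, or
#'   `NULL` to use the current RNG state.
#' @return An object of class `lysim_noise`.
#' @examples
#' noise_model(multiplicative_cv = 0.03, seed = 1)
#' @export
noise_model <- function(multiplicative_cv = 0.03, additive_sd = 0.002,
                        baseline_offset = 0.04, seed = NULL) {
  if (multiplicative_cv < 0 || additive_sd < 0) {
    abort("noise magnitudes must be non-negative")
  }
  structure(list(multiplicative_cv = multiplicative_cv,
                 additive_sd = additive_sd,
                 baseline_offset = baseline_offset, seed = seed),
            class = "lysim_noise")
}

apply_noise <- function(values, noise) {
  out <- values
  if (noise$multiplicative_cv > 0) {
    sdlog <- sqrt(log(1 + noise$multiplicative_cv^2))
    out <- out * rlnorm(length(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  if (noise$additive_sd > 0) {
    out <- out + rnorm(length(out), sd = noise$additive_sd)
  }
  pmax(out + noise$baseline_offset, 0)
}

with_noise_seed <- function(noise, expr) {
  if (is.null(noise$seed)) expr else withr::with_seed(noise$seed, expr)
}

#' Generate synthetic plate-reader growth curves
#'
#' Simulates the population model for each AHL condition, starting from a
#' culture diluted to `init_density` of which a fraction `f0` is mutant,
#' samples the total density on the plate-reader grid (every `interval`
#' hours over `duration` hours), and applies the measurement noise model to
#' each replicate independently. The default design mirrors a typical
#' experiment: 10-min sampling over 23 h, technical triplicates, and
#' log-spaced AHL concentrations.
#'
#' @param params A [model_params()] object.
#' @param ahl Vector of AHL concentrations (nM), one condition each.
#' @param f0 Initial mutant fraction of the stock.
#' @param duration Experiment duration (h).
#' @param interval Sampling interval (h); 1/6 h = 10 min.
#' @param replicates Technical replicates per condition.
#' @param noise A [noise_model()].
#' @param init_density Initial total density (a.u.).
#' @param dt Euler step used for the underlying simulation (h).
#' @param ... Passed to [simulate_dynamics()] (`model`, `toxin_dilution`).
#' @return A tibble with columns `time_h`, `od600`, `ahl_nM`, `replicate`,
#'   `condition` — the canonical growth-curve format of
#'   [read_growth_curves()].
#' @examples
#' gc <- generate_plate_reader(params_preset(), ahl = c(0, 100),
#'                             noise = noise_model(seed = 1))
#' dplyr::count(gc, condition)
#' @export
generate_plate_reader <- function(params, ahl = log_spaced(1, 1000, 8),
                                  f0 = 7e-5, duration = 23, interval = 1 / 6,
                                  replicates = 3,
                                  noise = noise_model(), init_density = 0.01,
                                  dt = 1e-3, ...) {
  if (interval <= 0) abort("interval must be positive")
  if (replicates < 1) abort("replicates must be >= 1")
  sample_times <- seq(0, duration, by = interval)
  curves <- purrr::map(ahl, function(a) {
    traj <- simulate_dynamics(params, induction_constant(a),
                              initial_state(init_density, f0),
                              t_end = duration, dt = dt,
                              check_convergence = FALSE, ...)
    clean <- approx(traj$t_h, traj$total, xout = sample_times)$y
    tibble(time_h = sample_times, clean = clean, ahl_nM = a,
           condition = paste0("ahl_", format(a, trim = TRUE)))
  })
  base <- dplyr::bind_rows(curves)
  with_noise_seed(noise, {
    out <- purrr::map(seq_len(replicates), function(r) {
      dplyr::mutate(base, od600 = apply_noise(.data$clean, noise),
                    replicate = r)
    })
    dplyr::select(dplyr::bind_rows(out), "time_h", "od600", "ahl_nM",
                  "replicate", "condition")
  })
}

#' Generate a passaged (serially diluted) growth-curve series
#'
#' Simulates consecutive growth legs under a schedule of (duration, AHL)
#' pairs. At each passage the culture is diluted into fresh medium: the
#' population densities `x` and `y` are divided by `dilution_factor`, while
#' the per-cell toxin concentration `p` is carried over unchanged (dilution
#' of the culture does not change the intracellular concentration).
#'
#' @param params A [model_params()] object.
#' @param schedule Data frame with columns `duration` (h) and `ahl` (nM),
#'   one row per leg.
#' @param dilution_factor Fold dilution applied between legs (>= 1; 1 means
#'   a contiguous trajectory).
#' @param f0 Initial mutant fraction of the stock.
#' @inheritParams generate_plate_reader
#' @return A growth-curve tibble (as [generate_plate_reader()]) with an
#'   additional `leg` column; `time_h` is cumulative across legs and
#'   `condition` labels the leg.
#' @export
generate_passaging_series <- function(params, schedule, dilution_factor = 100,
                                      f0 = 7e-5, interval = 1 / 6,
                                      replicates = 3, noise = noise_model(),
                                      init_density = 0.01, dt = 1e-3, ...) {
  if (!all(c("duration", "ahl") %in% names(schedule))) {
    abort("schedule must have columns duration and ahl")
  }
  if (dilution_factor < 1) abort("dilution_factor must be >= 1")
  state <- initial_state(init_density, f0)
  t_offset <- 0
  legs <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    if (i > 1) {
      state[c("x", "y")] <- state[c("x", "y")] / dilution_factor
      state["s"] <- 1  # fresh medium
    }
    traj <- simulate_dynamics(params, induction_constant(schedule$ahl[i]),
                              state, t_end = schedule$duration[i], dt = dt,
                              check_convergence = FALSE, ...)
    sample_times <- seq(0, schedule$duration[i], by = interval)
    legs[[i]] <- tibble(
      time_h = t_offset + sample_times,
      clean = approx(traj$t_h, traj$total, xout = sample_times)$y,
      ahl_nM = schedule$ahl[i],
      leg = i,
      condition = paste0("leg", i, "_ahl_",
                         format(schedule$ahl[i], trim = TRUE))
    )
    state <- attr(traj, "final_state")
    t_offset <- t_offset + schedule$duration[i]
  }
  base <- dplyr::bind_rows(legs)
  with_noise_seed(noise, {
    out <- purrr::map(seq_len(replicates), function(r) {
      dplyr::mutate(base, od600 = apply_noise(.data$clean, noise),
                    replicate = r)
    })
    dplyr::select(dplyr::bind_rows(out), "time_h", "od600", "ahl_nM",
                  "replicate", "condition", "leg")
  })
}

#' Generate a synthetic induction-response calibration data set
#'
#' Hill-response values of the toxin production rate versus inducer
#' concentration, with multiplicative measurement noise — the kind of data
#' produced by a fluorescent-reporter characterisation of the induction
#' promoter, used downstream by [fit_beta_hill()].
#'
#' @param beta0,k,m True Hill parameters (see [model_params()]).
#' @param ahl AHL concentrations (nM).
#' @param noise A [noise_model()]; only the multiplicative component is
#'   applied (rates are blank-free).
#' @return A tibble with columns `ahl_nM` and `beta` (1/h).
#' @examples
#' generate_beta_calibration(6.1, 19, 1, ahl = log_spaced(1, 1000, 8),
#'                           noise = noise_model(0.05, 0, 0, seed = 1))
#' @export
generate_beta_calibration <- function(beta0, k, m,
                                      ahl = log_spaced(1, 1000, 8),
                                      noise = noise_model()) {
  if (length(ahl) == 0) abort("ahl must be non-empty")
  clean <- beta0 * hill(ahl, k, m)
  with_noise_seed(noise, {
    beta <- if (noise$multiplicative_cv > 0) {
      sdlog <- sqrt(log(1 + noise$multiplicative_cv^2))
      clean * rlnorm(length(clean), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else clean
    tibble(ahl_nM = ahl, beta = beta)
  })
}

#' Read or write growth-curve sets as delimited text
#'
#' The canonical exchange format is tab-separated text with header columns
#' `time_h`, `od600`, `ahl_nM`, `replicate`, `condition` (additional
#' columns such as `leg` are preserved). Numeric columns are written with
#' full precision so a write-read round trip reproduces the data exactly.
#'
#' @param data A growth-curve tibble.
#' @param path File path.
#' @return `read_growth_curves()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_growth_curves <- function(data, path) {
  required <- c("time_h", "od600", "ahl_nM", "replicate", "condition")
  if (!all(required %in% names(data))) {
    abort(paste0("growth-curve data must have columns: ",
                 paste(required, collapse = ", ")))
  }
  write_delim_g17(as.data.frame(data), path)
}

#' @rdname write_growth_curves
#' @export
read_growth_curves <- function(path) {
  out <- read_delim_exact(path)
  required <- c("time_h", "od600", "ahl_nM", "replicate", "condition")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0("file is not a growth-curve set; missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  num <- c("time_h", "od600", "ahl_nM")
  out[num] <- lapply(out[num], as.double)
  out
}
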