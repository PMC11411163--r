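#' Evaluate one induction strategy
#'
#' Integrates the model under the given induction program and reports the
#' released payload accumulated before mutant takeover (the load integral
#' truncated at the first time the mutant fraction reaches `threshold`, or
#' at the horizon if takeover never happens), together with the takeover
#' time itself. Takeover detection and load truncation are done on the full
#' integration grid with in-step linear interpolation.
#'
#' @param params A [model_params()] object.
#' @param program A `lysim_program` or a constant AHL level (nM).
#' @param init Initial state, see [initial_state()].
#' @param horizon Integration horizon (h).
#' @param threshold Takeover threshold(s) on the mutant fraction, in (0, 1).
#'   May be a vector; one result row is returned per threshold.
#' @param dt Euler step (h).
#' @param ... Passed to the integrator (`model`, `toxin_dilution`,
#'   `load_integrand`).
#' @return A tibble with one row per threshold: `threshold`,
#'   `load_before_takeover`, `takeover_h` (`NA` if not reached within the
#'   horizon), `takeover_reached`, `load_total`.
#' @examples
#' evaluate_strategy(params_preset(), induction_constant(100),
#'                   initial_state(), horizon = 48)
#' @export
evaluate_strategy <- function(params, program, init = initial_state(),
                              horizon = 200, threshold = 0.99, dt = 1e-3,
                              ...) {
  if (horizon <= 0) abort("horizon must be positive")
  if (any(threshold <= 0 | threshold >= 1)) {
    abort("threshold must be in (0, 1)")
  }
  if (is.numeric(program) && length(program) == 1) {
    program <- induction_constant(program)
  }
  opts <- list(...)
  thr <- sort(threshold)
  run <- run_engine(params, program, init, t_end = horizon, dt = dt,
                    model = opts$model %||% "core",
                    toxin_dilution = opts$toxin_dilution %||% "net_growth",
                    load_integrand = opts$load_integrand %||% "net_lysis",
                    record_every = max(1L, as.integer(round(0.1 / dt))),
                    thresholds = thr)
  reached <- !is.na(run$takeover_time)
  tibble(
    threshold = thr,
    load_before_takeover = ifelse(reached, run$takeover_load,
                                  run$final_load),
    takeover_h = run$takeover_time,
    takeover_reached = reached,
    load_total = run$final_load
  )
}

#' Sweep square-wave induction strategies over a period x on-duration grid
#'
#' Evaluates [evaluate_strategy()] for every combination of period and
#' on-duration (cells with `on_duration > period` are marked invalid and
#' not simulated), together with the static reference: continuous induction
#' at the same amplitude, truncated by the identical takeover rule. Each
#' square-wave cycle starts with its ON segment.
#'
#' The default grid spans periods log-spaced between 0.5 and 24 h and
#' on-durations log-spaced between 0.1 and 6 h (12 values each) at an
#' amplitude of 100 nM over a 200 h horizon.
#'
#' @inheritParams evaluate_strategy
#' @param periods Square-wave periods (h).
#' @param on_durations ON durations per cycle (h).
#' @param amplitude AHL amplitude of the ON segments (nM).
#' @param threshold Single takeover threshold used for the grid.
#' @return A tibble of class `lysim_strategy_grid` in long format with
#'   columns `period_h`, `on_h`, `valid`, `load`, `takeover_h`, and
#'   attributes `static_load`, `static_takeover_h`, `amplitude`,
#'   `threshold`, `horizon`, `params`.
#' @seealso [best_vs_static()]
#' @export
sweep_strategies <- function(params,
                             periods = log_spaced(0.5, 24, 12),
                             on_durations = log_spaced(0.1, 6, 12),
                             amplitude = 100, init = initial_state(),
                             horizon = 200, threshold = 0.99, dt = 1e-3,
                             ...) {
  if (length(periods) == 0 || length(on_durations) == 0) {
    abort("periods and on_durations must be non-empty")
  }
  static <- evaluate_strategy(params, induction_constant(amplitude), init,
                              horizon, threshold, dt, ...)
  grid <- tidyr::expand_grid(period_h = sort(periods),
                             on_h = sort(on_durations))
  grid$valid <- grid$on_h <= grid$period_h
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    if (!grid$valid[i]) {
      return(tibble(load = NA_real_, takeover_h = NA_real_))
    }
    prog <- induction_square_wave(amplitude, grid$period_h[i], grid$on_h[i])
    ev <- evaluate_strategy(params, prog, init, horizon, threshold, dt, ...)
    tibble(load = ev$load_before_takeover, takeover_h = ev$takeover_h)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  attr(out, "static_load") <- static$load_before_takeover
  attr(out, "static_takeover_h") <- static$takeover_h
  attr(out, "amplitude") <- amplitude
  attr(out, "threshold") <- threshold
  attr(out, "horizon") <- horizon
  attr(out, "params") <- params
  class(out) <- c("lysim_strategy_grid", class(out))
  out
}

#' Best dynamic strategy relative to static induction
#'
#' Picks the grid cell with the largest released load before takeover and
#' reports its load ratio to the static (continuous induction) reference.
#' Ties are broken toward the shortest on-duration, then the shortest
#' period.
#'
#' @param grid A `lysim_strategy_grid` from [sweep_strategies()].
#' @return A one-row tibble: `best_period_h`, `best_on_h`, `best_load`,
#'   `best_takeover_h`, `static_load`, `ratio`.
#' @export
best_vs_static <- function(grid) {
  stopifnot(inherits(grid, "lysim_strategy_grid"))
  valid <- dplyr::filter(grid, .data$valid & !is.na(.data$load))
  if (nrow(valid) == 0) abort("the grid contains no valid evaluated cells")
  best <- dplyr::arrange(valid, dplyr::desc(.data$load), .data$on_h,
                         .data$period_h)[1, ]
  static_load <- attr(grid, "static_load")
  tibble(
    best_period_h = best$period_h,
    best_on_h = best$on_h,
    best_load = best$load,
    best_takeover_h = best$takeover_h,
    static_load = static_load,
    ratio = best$load / static_load
  )
}

#' @rdname sweep_strategies
#' @param from,to,length Range and length of a log-spaced sequence.
#' @export
log_spaced <- function(from, to, length) {
  exp(seq(log(from), log(to), length.out = length))
}

#' Write a strategy grid as delimited text
#'
#' Long format with columns `period_h`, `on_h`, `load`, `takeover_h`
#' (invalid cells carry `NA`), suitable for external plotting.
#'
#' @param grid A `lysim_strategy_grid`.
#' @param path File path.
#' @export
write_strategy_grid <- function(grid, path) {
  write_delim_g17(as.data.frame(grid)[, c("period_h", "on_h", "load",
                                          "takeover_h")], path)
}
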