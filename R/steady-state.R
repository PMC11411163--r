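#' Locate a steady state by long-horizon integration
#'
#' Integrates the chosen model variant in chunks until every derivative is
#' small relative to its state (\eqn{|\dot z_i| < tol\,(1 + |z_i|)} for all
#' components), or until the horizon cap is reached. Useful mainly for the
#' dilution variant, where washout and coexistence fixed points organise
#' the long-term behaviour, but works for any variant.
#'
#' @param params A [model_params()] object.
#' @param ahl External AHL (nM), or the AHL supply rate (nM/h) for
#'   `model = "dilution"`.
#' @param init Initial state, see [initial_state()].
#' @param model Model variant, see [rhs()].
#' @param tol Relative derivative tolerance declaring stationarity.
#' @param t_max Horizon cap (h).
#' @param chunk Integration chunk length (h) between stationarity checks.
#' @param dt Euler step (h); steady-state location does not need the fine
#'   step used for transient shapes.
#' @param ... Passed to the integrator (`toxin_dilution`).
#' @return A list with `converged` (logical), `status` (`"converged"`,
#'   `"divergent"`, `"oscillatory_or_slow"`), `state` (named vector),
#'   `fraction_mutant`, `residual_norm` (largest relative derivative) and
#'   `t_reached` (h).
#' @examples
#' p <- params_preset()
#' p$d <- 2
#' find_steady_state(p, ahl = 100, model = "dilution")
#' @export
find_steady_state <- function(params, ahl, init = initial_state(),
                              model = c("core", "substrate", "mutation",
                                        "dilution"),
                              tol = 1e-8, t_max = 1e4, chunk = 100,
                              dt = 1e-2, ...) {
  model <- match.arg(model)
  if (tol <= 0) abort("tol must be positive")
  check_variant_params(params, model)
  opts <- list(...)
  toxdil <- opts$toxin_dilution %||% "net_growth"
  program <- induction_constant(ahl)
  state <- init
  t_done <- 0
  res_hist <- numeric(0)
  status <- "oscillatory_or_slow"
  repeat {
    run <- run_engine(params, program, state, t_end = chunk, dt = dt,
                      model = model, toxin_dilution = toxdil,
                      load_integrand = "net_lysis",
                      record_every = max(1L, as.integer(chunk / dt)),
                      thresholds = numeric(0))
    state <- run$final
    t_done <- t_done + chunk
    deriv <- rhs(state, params, ahl, model = model, toxin_dilution = toxdil)
    used <- used_components(model)
    rel <- abs(deriv) / (1 + abs(state[used]))
    res <- max(rel)
    res_hist <- c(res_hist, res)
    if (res < tol) {
      status <- "converged"
      break
    }
    if (any(!is.finite(state)) || max(abs(state)) > 1e9) {
      status <- "divergent"
      break
    }
    if (t_done >= t_max) {
      # distinguish a residual that has stopped shrinking (cycling) from one
      # still slowly decaying
      status <- if (length(res_hist) >= 5 &&
                    res_hist[length(res_hist)] >=
                      0.5 * res_hist[length(res_hist) - 4]) {
        "oscillatory_or_slow"
      } else "not_converged_within_horizon"
      break
    }
  }
  total <- state[["x"]] + state[["y"]]
  list(
    converged = status == "converged",
    status = status,
    state = state,
    fraction_mutant = if (total > 0) state[["y"]] / total else NA_real_,
    residual_norm = res,
    t_reached = t_done
  )
}

used_components <- function(model) {
  switch(model,
         core = c("x", "y", "p"),
         mutation = c("x", "y", "p"),
         substrate = c("x", "y", "p", "s"),
         dilution = c("x", "y", "p", "a"))
}
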