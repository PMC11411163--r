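#' Hill activation function
#'
#' `hill(v, threshold, coefficient)` returns
#' \eqn{v^h / (\theta^h + v^h)}, the saturating response used both for
#' toxin-triggered lysis (argument: per-cell toxin) and for AHL induction
#' (argument: inducer concentration). It is 0 at `v = 0`, exactly 1/2 at
#' `v = threshold` for any coefficient, strictly increasing, and tends to 1
#' as `v` grows.
#'
#' @param v Non-negative input value(s).
#' @param threshold Positive half-maximum threshold \eqn{\theta}.
#' @param coefficient Hill coefficient \eqn{h \ge 1}.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' hill(c(0, 19, 100), threshold = 19, coefficient = 1)
#' @export
hill <- function(v, threshold, coefficient) {
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("hill(): input values must be finite and non-negative")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("hill(): threshold must be positive")
  }
  if (coefficient < 1) abort("hill(): coefficient must be >= 1")
  r <- (v / threshold)^coefficient
  out <- r / (1 + r)
  out[v == 0] <- 0
  out
}

#' AHL-dependent toxin production rate
#'
#' The per-cell toxin production rate as a Hill function of the external
#' inducer concentration: \eqn{\beta([\mathrm{AHL}]) = \beta_0\,
#' [\mathrm{AHL}]^m / (k^m + [\mathrm{AHL}]^m)}.
#'
#' @param ahl AHL concentration(s) in nM, non-negative.
#' @param params A [model_params()] object supplying `beta0`, `k`, `m`.
#' @return Production rate(s) in a.u./h.
#' @examples
#' beta_of_ahl(c(0, 19, 100), params_preset())
#' @export
beta_of_ahl <- function(ahl, params) {
  stopifnot(inherits(params, "lysim_params"))
  if (any(!is.finite(ahl)) || any(ahl < 0)) {
    abort("beta_of_ahl(): ahl must be finite and non-negative")
  }
  params$beta0 * hill(ahl, params$k, params$m)
}

#' Time derivatives of the population model
#'
#' Evaluates the right-hand side of the model at one state, for the core
#' model or one of its variants. This is the reference (pure R) definition
#' of the dynamics; [simulate_dynamics()] integrates the identical equations
#' with a compiled fixed-step Euler scheme.
#'
#' Variants: `"substrate"` multiplies growth by a Monod factor
#' \eqn{s/(K_s+s)} and consumes substrate at rate \eqn{r_s (x+y) s/(K_s+s)};
#' `"mutation"` moves mass from `x` to `y` at rate `mu`; `"dilution"` adds
#' chemostat washout `-d x`, `-d y` and treats AHL as a state `a` with
#' `da/dt = supply - d a` (the `ahl` argument is then the supply rate in
#' nM/h and `beta` is evaluated at `state["a"]`).
#'
#' @param state Named numeric vector with `x`, `y`, `p` and, for variants,
#'   optionally `s` (normalised substrate) and `a` (AHL, nM).
#' @param params A [model_params()] object.
#' @param ahl External AHL concentration (nM); for `model = "dilution"`, the
#'   AHL supply rate (nM/h).
#' @param model One of `"core"`, `"substrate"`, `"mutation"`, `"dilution"`.
#' @param toxin_dilution Positive-part convention for the toxin dilution
#'   term: `"net_growth"` uses \eqn{(\gamma-\alpha)^+ p} (default),
#'   `"growth"` uses \eqn{(\gamma)^+ p}.
#' @return Named numeric vector of derivatives (`dx`, `dy`, `dp`, and `ds`,
#'   `da` where applicable).
#' @examples
#' rhs(c(x = 0.01, y = 1e-6, p = 0), params_preset(), ahl = 100)
#' @export
rhs <- function(state, params, ahl, model = c("core", "substrate", "mutation",
                                              "dilution"),
                toxin_dilution = c("net_growth", "growth")) {
  model <- match.arg(model)
  toxin_dilution <- match.arg(toxin_dilution)
  stopifnot(inherits(params, "lysim_params"))
  check_variant_params(params, model)
  x <- state[["x"]]; y <- state[["y"]]; p <- state[["p"]]
  if (any(c(x, y, p) < 0)) abort("state values must be non-negative")

  growth_factor <- 1 - (x + y) / params$rho_s
  if (model == "substrate") {
    s <- state[["s"]]
    growth_factor <- growth_factor * s / (params$K_s + s)
  }
  gamma <- params$gamma0 * growth_factor
  alpha <- params$alpha0 * hill(p, params$K, params$n)
  ahl_now <- if (model == "dilution") state[["a"]] else ahl
  beta <- beta_of_ahl(ahl_now, params)

  dil <- if (toxin_dilution == "net_growth") max(gamma - alpha, 0)
         else max(gamma, 0)
  out <- c(dx = (gamma - alpha) * x,
           dy = gamma * y,
           dp = beta - dil * p - params$delta * p)
  if (model == "mutation") {
    out[["dx"]] <- out[["dx"]] - params$mu * x
    out[["dy"]] <- out[["dy"]] + params$mu * x
  }
  if (model == "substrate") {
    s <- state[["s"]]
    out <- c(out, ds = -params$r_s * (x + y) * s / (params$K_s + s))
  }
  if (model == "dilution") {
    out[["dx"]] <- out[["dx"]] - params$d * x
    out[["dy"]] <- out[["dy"]] - params$d * y
    out <- c(out, da = ahl - params$d * state[["a"]])
  }
  out
}

check_variant_params <- function(params, model) {
  need <- switch(model,
                 core = character(0),
                 substrate = c("r_s", "K_s"),
                 mutation = "mu",
                 dilution = "d")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    abort(paste0("model variant '", model, "' requires parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
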