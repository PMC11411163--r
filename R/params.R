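#' Model parameters for the lysis-circuit population model
#'
#' Bundles the rate constants and Hill parameters of the coupled ODE system
#' describing a therapeutic (lysing) strain `x`, a non-lysing mutant strain
#' `y`, and the per-cell intracellular toxin concentration `p`:
#'
#' \deqn{\dot x = (\gamma - \alpha)\,x, \quad \dot y = \gamma\,y, \quad
#'       \dot p = \beta([\mathrm{AHL}]) - (\gamma - \alpha)^{+} p - \delta p}
#' with logistic crowding \eqn{\gamma = \gamma_0 (1 - (x+y)/\rho_s)}, a Hill
#' lysis response \eqn{\alpha = \alpha_0\, p^n / (K^n + p^n)} and a Hill
#' induction response \eqn{\beta = \beta_0\,[\mathrm{AHL}]^m / (k^m +
#' [\mathrm{AHL}]^m)}.
#'
#' Optional fields parameterise the model variants: `mu` (adaptive mutation
#' rate, used by `model = "mutation"`), `r_s` and `K_s` (Monod substrate
#' uptake, `model = "substrate"`), and `d` (chemostat-style dilution rate,
#' `model = "dilution"`).
#'
#' @param gamma0 Maximum per-capita growth rate (1/h).
#' @param rho_s Carrying capacity of the culture (a.u. density, > 0).
#' @param alpha0 Maximum lysis rate (1/h).
#' @param K Lysis Hill threshold (a.u. toxin, > 0).
#' @param n Lysis Hill cooperativity (>= 1).
#' @param beta0 Maximum toxin production rate (a.u./h).
#' @param k Induction Hill threshold (nM AHL, > 0).
#' @param m Induction Hill cooperativity (>= 1).
#' @param delta Intracellular toxin degradation rate (1/h).
#' @param mu Adaptive mutation rate (1/h), optional.
#' @param r_s Substrate utilisation rate (1/h), optional.
#' @param K_s Monod half-saturation constant (normalised substrate units),
#'   optional.
#' @param d Dilution rate (1/h), optional.
#'
#' @return An object of class `lysim_params`: a named list of the parameters
#'   above.
#' @seealso [params_preset()] for the shipped default set,
#'   [simulate_dynamics()] for integration.
#' @examples
#' pars <- params_preset("fitted_means")
#' pars$gamma0
#' model_params(gamma0 = 1.2, rho_s = 0.5, alpha0 = 2, K = 4, n = 2,
#'              beta0 = 5, k = 20, m = 1, delta = 0.1)
#' @export
model_params <- function(gamma0, rho_s, alpha0, K, n, beta0, k, m, delta,
                         mu = NULL, r_s = NULL, K_s = NULL, d = NULL) {
  p <- list(gamma0 = gamma0, rho_s = rho_s, alpha0 = alpha0, K = K, n = n,
            beta0 = beta0, k = k, m = m, delta = delta, mu = mu, r_s = r_s,
            K_s = K_s, d = d)
  p[vapply(p, is.null, logical(1))] <- NULL
  validate_params(p)
  structure(p, class = "lysim_params")
}

validate_params <- function(p) {
  required <- c("gamma0", "rho_s", "alpha0", "K", "n", "beta0", "k", "m",
                "delta")
  missing <- setdiff(required, names(p))
  if (length(missing) > 0) {
    abort(paste0("missing model parameters: ", paste(missing, collapse = ", ")))
  }
  num <- p[!vapply(p, is.null, logical(1))]
  bad <- names(num)[!vapply(num, function(v) is.numeric(v) && length(v) == 1 &&
                              is.finite(v), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("parameters must be finite scalars: ",
                 paste(bad, collapse = ", ")))
  }
  neg <- names(num)[vapply(num, function(v) v < 0, logical(1))]
  if (length(neg) > 0) {
    abort(paste0("parameters must be non-negative: ",
                 paste(neg, collapse = ", ")))
  }
  if (p$rho_s <= 0) abort("rho_s must be positive")
  if (p$K <= 0) abort("K must be positive")
  if (p$k <= 0) abort("k must be positive")
  if (p$n < 1) abort("n must be >= 1")
  if (p$m < 1) abort("m must be >= 1")
  invisible(p)
}

#' Named parameter presets
#'
#' `"fitted_means"` is the default parameter set of the package: the mean
#' values estimated from plate-reader growth curves of an AHL-inducible
#' lysis circuit (growth and lysis parameters), the independently calibrated
#' induction Hill response, a slow a-priori toxin degradation rate, and the
#' variant parameters (substrate utilisation rate, adaptive mutation rate).
#'
#' @param name Preset name; currently `"fitted_means"`.
#' @return A [model_params()] object.
#' @examples
#' params_preset()
#' @export
params_preset <- function(name = "fitted_means") {
  presets <- list(
    fitted_means = model_params(
      gamma0 = 1.57, rho_s = 0.33, alpha0 = 1.39, K = 3.29, n = 4.46,
      beta0 = 6.1, k = 19, m = 1, delta = 0.1,
      mu = 1e-7, r_s = 4.17, K_s = 0.1, d = 0
    )
  )
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

# Pack into the fixed positional layout euler_engine() expects.
pack_params <- function(p) {
  c(p$gamma0, p$rho_s, p$alpha0, p$K, p$n, p$beta0, p$k, p$m, p$delta,
    p$mu %||% 0, p$r_s %||% 0, p$K_s %||% 0.1, p$d %||% 0)
}

#' @export
print.lysim_params <- function(x, ...) {
  cat("<lysim_params>\n")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals)), " = ", format(vals, digits = 6),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Read or write a model parameter set as a flat JSON file
#'
#' Parameter files are flat key-value JSON objects so they can be edited by
#' hand and shared between the R functions and the command-line interface.
#'
#' @param path File path.
#' @param params A [model_params()] object.
#' @return `read_params()` returns a [model_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_params(params_preset(), f)
#' read_params(f)
#' @export
read_params <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, as.list(vals))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "lysim_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
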