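#' Closed-form mutant fraction under lysis-driven selection
#'
#' Along any trajectory of the model the mutant fraction `f = y/(x+y)` obeys
#' the replicator-type equation \eqn{df/dt = \alpha(t)\, f (1-f)}: only the
#' lysis rate \eqn{\alpha} acting on the therapeutic strain separates the
#' two subpopulations, because both share the same growth rate. Its solution
#' is \eqn{f(t) = 1 / (\exp(C - \int_0^t \alpha\,dt') + 1)} with
#' \eqn{C = \ln(f_0^{-1} - 1)}; for constant \eqn{\alpha} this reduces to
#' \eqn{f(t) = e^{\alpha t} / (f_0^{-1} - 1 + e^{\alpha t})}.
#'
#' `fraction_constant_alpha()` evaluates the constant-rate form;
#' `fraction_general()` evaluates the general form with the integral
#' computed by cumulative trapezoidal quadrature on the supplied grid.
#'
#' @param t Time(s) in hours, non-negative. For `fraction_general()` the
#'   evaluation times must lie inside the range of `alpha$t_h`.
#' @param alpha Constant lysis rate (1/h) for
#'   `fraction_constant_alpha()`; for `fraction_general()` a data frame with
#'   columns `t_h` and `alpha` giving the lysis-rate time series (such as
#'   [alpha_series()] of a trajectory).
#' @param f0 Initial mutant fraction, strictly inside (0, 1).
#' @return Mutant fraction(s) in \[0, 1\].
#' @examples
#' fraction_constant_alpha(5, alpha = 2.1, f0 = 4.2e-5)
#' @export
fraction_constant_alpha <- function(t, alpha, f0) {
  check_f0(f0)
  if (alpha < 0) abort("alpha must be non-negative")
  if (any(t < 0)) abort("t must be non-negative")
  # logistic form, computed via plogis for numerical stability at large t
  plogis(alpha * t - log(1 / f0 - 1))
}

#' @rdname fraction_constant_alpha
#' @export
fraction_general <- function(t, alpha, f0) {
  check_f0(f0)
  if (!is.data.frame(alpha) || !all(c("t_h", "alpha") %in% names(alpha))) {
    abort("alpha must be a data frame with columns t_h and alpha")
  }
  if (any(t < min(alpha$t_h)) || any(t > max(alpha$t_h))) {
    abort("the alpha series does not cover all requested times")
  }
  cum <- cumtrapz(alpha$t_h, alpha$alpha)
  int_t <- approx(alpha$t_h, cum, xout = t)$y
  plogis(int_t - log(1 / f0 - 1))
}

check_f0 <- function(f0) {
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0 || f0 >= 1) {
    abort("f0 must lie strictly inside (0, 1)")
  }
  invisible(f0)
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

#' Lysis-rate and growth-rate time series of a trajectory
#'
#' Reconstructs \eqn{\alpha(t) = \alpha_0\,p^n/(K^n+p^n)} and
#' \eqn{\gamma(t) = \gamma_0(1 - (x+y)/\rho_s)} from the stored state
#' columns of a trajectory, using the parameter set the trajectory was
#' integrated with.
#'
#' @param traj A `lysim_trajectory`.
#' @return A tibble with columns `t_h`, `alpha`, `gamma`.
#' @export
alpha_series <- function(traj) {
  stopifnot(inherits(traj, "lysim_trajectory"))
  params <- attr(traj, "params")
  growth_factor <- 1 - traj$total / params$rho_s
  if (attr(traj, "model") == "substrate") {
    growth_factor <- growth_factor * traj$s / (params$K_s + traj$s)
  }
  tibble(t_h = traj$t_h,
         alpha = params$alpha0 * hill(traj$p, params$K, params$n),
         gamma = params$gamma0 * growth_factor)
}

#' Cumulative released-payload proxy of a trajectory
#'
#' The total payload released by lysis is proportional to the cumulative
#' number of therapeutic bacteria lysed,
#' \eqn{\int_0^t (\alpha - \gamma)^{+}\, x\, dt'} (default), or
#' optionally \eqn{\int_0^t \alpha\, x\, dt'}. The proportionality constant
#' is not identifiable from fluorescence-proxy measurements and is fixed at
#' one; comparisons between strategies are therefore made as ratios. The
#' integral is evaluated by cumulative trapezoidal quadrature on the
#' trajectory grid.
#'
#' @param traj A `lysim_trajectory`.
#' @param integrand `"net_lysis"` for \eqn{(\alpha-\gamma)^{+}x} (default)
#'   or `"alpha_x"` for \eqn{\alpha x}.
#' @return A tibble with columns `t_h` and `load` (non-decreasing).
#' @export
released_load <- function(traj, integrand = c("net_lysis", "alpha_x")) {
  integrand <- match.arg(integrand)
  ag <- alpha_series(traj)
  rate <- if (integrand == "net_lysis") {
    pmax(ag$alpha - ag$gamma, 0) * traj$x
  } else {
    ag$alpha * traj$x
  }
  tibble(t_h = traj$t_h, load = cumtrapz(traj$t_h, rate))
}

#' Mutant takeover time of a trajectory
#'
#' The first time at which the mutant fraction reaches a threshold,
#' linearly interpolated between grid points. Takeover marks the loss of
#' the therapeutic reservoir: past it, essentially no further payload can
#' be released.
#'
#' @param traj A `lysim_trajectory`.
#' @param threshold Mutant fraction defining takeover, in (0, 1);
#'   default 0.99.
#' @return Takeover time in hours, or `NA` if the threshold is not reached
#'   within the trajectory.
#' @export
takeover_time <- function(traj, threshold = 0.99) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  f <- traj$fraction_mutant
  t <- traj$t_h
  ok <- !is.na(f)
  f <- f[ok]; t <- t[ok]
  if (length(f) == 0) return(NA_real_)
  if (f[1] >= threshold) return(t[1])
  hit <- which(f >= threshold)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  w <- (threshold - f[i - 1]) / (f[i] - f[i - 1])
  t[i - 1] + w * (t[i] - t[i - 1])
}
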