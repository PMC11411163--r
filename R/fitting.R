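#' Fit the induction Hill response to calibration data
#'
#' Least-squares fit of \eqn{\beta([\mathrm{AHL}]) = \beta_0\,
#' [\mathrm{AHL}]^m/(k^m + [\mathrm{AHL}]^m)} to measured production rates,
#' with bounds \eqn{\beta_0 > 0}, \eqn{k > 0}, \eqn{m \ge 1}. Uses
#' Levenberg-Marquardt with a handful of perturbed restarts; standard
#' errors come from the Gauss-Newton covariance at the optimum.
#'
#' @param data Data frame with columns `ahl_nM` and `beta` (as produced by
#'   [generate_beta_calibration()]).
#' @param n_starts Number of optimizer starts.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A `lysim_fit` object; see [tidy.lysim_fit()].
#' @examples
#' cal <- generate_beta_calibration(6.1, 19, 1,
#'                                  noise = noise_model(0, 0, 0))
#' tidy(fit_beta_hill(cal))
#' @export
fit_beta_hill <- function(data, n_starts = 5, maxiter = 200) {
  if (!all(c("ahl_nM", "beta") %in% names(data))) {
    abort("data must have columns ahl_nM and beta")
  }
  ahl <- data$ahl_nM
  beta <- data$beta
  if (length(unique(ahl)) < 4) {
    abort("need at least 4 distinct AHL concentrations to fit (beta0, k, m)")
  }
  resid_fn <- function(par) {
    beta - par[1] * (ahl / par[2])^par[3] / (1 + (ahl / par[2])^par[3])
  }
  lower <- c(1e-9, 1e-9, 1)
  upper <- c(Inf, Inf, 20)
  k_guess <- stats::approx(beta / max(beta), ahl, xout = 0.5, ties = mean,
                           rule = 2)$y
  s0 <- c(max(beta), max(k_guess, 1e-3), 1)
  starts <- matrix(s0, nrow = 1)
  if (n_starts > 1) {
    jit <- t(vapply(seq_len(n_starts - 1),
                    function(i) s0 * exp(stats::runif(3, -0.7, 0.7)),
                    numeric(3)))
    starts <- rbind(starts, jit)
  }
  starts[, 3] <- pmax(starts[, 3], 1)
  best <- multistart_lm(resid_fn, starts, lower, upper, maxiter)
  new_lysim_fit(
    method = "beta_hill",
    terms = c("beta0", "k", "m"),
    best = best, resid_fn = resid_fn, data = as_tibble(data),
    fitted = data$beta - resid_fn(best$par),
    fixed = list()
  )
}

#' Fit the population model to plate-reader growth curves
#'
#' Minimises the summed squared residuals between observed density and the
#' simulated total density `x + y` across all AHL conditions simultaneously
#' (shared parameters, per-condition AHL forcing). Replicates are stacked,
#' not averaged. Optimisation is bounded Levenberg-Marquardt from a
#' Latin-hypercube set of starting points, because the crash-time landscape
#' is multi-modal in the lysis Hill parameters; `x0` and `y0` are optimised
#' on a log10 scale.
#'
#' The induction parameters `beta0`, `k`, `m` are always taken from
#' `params` (they are calibrated independently, see [fit_beta_hill()]), as
#' is `delta`.
#'
#' @param data Growth-curve data frame with columns `time_h`, `od600`,
#'   `ahl_nM`, `replicate`. `od600` must be blank-corrected (no offset).
#' @param free Character vector of parameters to estimate, a subset of
#'   `c("gamma0", "rho_s", "alpha0", "K", "n", "x0", "y0")`.
#' @param params A [model_params()] object supplying every fixed rate and
#'   the starting values of free rates.
#' @param init Named vector with `x0` and `y0` supplying initial densities
#'   when they are not free (and their starting values when they are).
#' @param n_starts Number of optimizer starts (first start = supplied
#'   values, remainder Latin hypercube over the bounds).
#' @param dt Euler step used inside the objective (h).
#' @param bounds Named list of `c(lower, upper)` bounds; see defaults in
#'   `fit_bounds()`.
#' @param log_residuals If `TRUE`, residuals are computed on
#'   `log(density + 1e-4)`, balancing the post-crash regime.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param toxin_dilution Positive-part convention, see [rhs()].
#' @return A `lysim_fit` object.
#' @export
fit_growth_curves <- function(data,
                              free = c("gamma0", "rho_s", "alpha0", "K", "n"),
                              params = params_preset(),
                              init = c(x0 = 0.01, y0 = 1e-6),
                              n_starts = 16, dt = 2e-3, bounds = fit_bounds(),
                              log_residuals = FALSE, maxiter = 100,
                              toxin_dilution = "net_growth") {
  check_gc_columns(data)
  allowed <- c("gamma0", "rho_s", "alpha0", "K", "n", "x0", "y0")
  if (length(free) == 0 || !all(free %in% allowed)) {
    abort(paste0("free must be a non-empty subset of: ",
                 paste(allowed, collapse = ", ")))
  }
  conds <- split(data, data$ahl_nM)
  for (cd in conds) {
    if (length(unique(cd$time_h)) < 2) {
      abort("each AHL condition needs at least 2 distinct time points")
    }
  }
  if (nrow(data) <= length(free)) {
    abort("fewer observations than free parameters")
  }

  base_vals <- c(unlist(params[c("gamma0", "rho_s", "alpha0", "K", "n")]),
                 x0 = unname(init[["x0"]]), y0 = unname(init[["y0"]]))
  resid_fn <- make_gc_residual(conds, free, params, base_vals, dt,
                               toxin_dilution, log_residuals)

  tr <- gc_transform(free, bounds)
  s0 <- tr$to_internal(pmin(pmax(base_vals[free], tr$lower_nat * 1.0001),
                            tr$upper_nat * 0.9999))
  starts <- matrix(s0, nrow = 1)
  if (n_starts > 1) {
    u <- lhs::randomLHS(n_starts - 1, length(free))
    more <- sweep(sweep(u, 2, tr$upper_int - tr$lower_int, "*"), 2,
                  tr$lower_int, "+")
    starts <- rbind(starts, more)
  }
  best <- multistart_lm(function(th) resid_fn(tr$from_internal(th)),
                        starts, tr$lower_int, tr$upper_int, maxiter)
  est_nat <- tr$from_internal(best$par)

  fit <- new_lysim_fit(
    method = "growth_curves",
    terms = free,
    best = best, resid_fn = function(v) resid_fn(v), data = as_tibble(data),
    fitted = NULL, fixed = c(as.list(params)[setdiff(names(params), free)],
                             as.list(base_vals[setdiff(c("x0", "y0"), free)])),
    estimates_nat = est_nat,
    se_fn = function() gc_nat_se(resid_fn, est_nat, tr, best)
  )
  fit
}

check_gc_columns <- function(data) {
  required <- c("time_h", "od600", "ahl_nM", "replicate")
  if (!all(required %in% names(data))) {
    abort(paste0("growth-curve data must have columns: ",
                 paste(required, collapse = ", ")))
  }
  if (any(data$time_h < 0) || any(data$od600 < 0)) {
    abort("times and densities must be non-negative")
  }
  invisible(data)
}

# Natural <-> internal (optimizer) scales: x0/y0 on log10, the rest linear.
gc_transform <- function(free, bounds) {
  log_pars <- intersect(free, c("x0", "y0"))
  lower_nat <- vapply(free, function(p) bounds[[p]][1], numeric(1))
  upper_nat <- vapply(free, function(p) bounds[[p]][2], numeric(1))
  to_internal <- function(v) {
    v <- v[free]
    v[log_pars] <- log10(v[log_pars])
    v
  }
  from_internal <- function(th) {
    names(th) <- free
    th[log_pars] <- 10^th[log_pars]
    th
  }
  lo <- lower_nat; hi <- upper_nat
  lo[log_pars] <- log10(lo[log_pars]); hi[log_pars] <- log10(hi[log_pars])
  list(to_internal = to_internal, from_internal = from_internal,
       lower_nat = lower_nat, upper_nat = upper_nat,
       lower_int = lo, upper_int = hi)
}

#' @rdname fit_growth_curves
#' @export
fit_bounds <- function() {
  list(gamma0 = c(1e-6, 5), rho_s = c(1e-6, 2), alpha0 = c(0, 10),
       K = c(1e-6, 20), n = c(1, 10), x0 = c(1e-12, 1), y0 = c(1e-12, 1))
}

make_gc_residual <- function(conds, free, params, base_vals, dt,
                             toxin_dilution, log_residuals) {
  obs <- purrr::map(conds, function(cd) {
    list(ahl = cd$ahl_nM[1], t = cd$time_h, od = cd$od600,
         t_end = max(cd$time_h))
  })
  n_tot <- sum(vapply(obs, function(o) length(o$t), integer(1)))
  function(vals) {
    full <- base_vals
    full[names(vals)] <- vals
    p2 <- params
    p2[c("gamma0", "rho_s", "alpha0", "K", "n")] <-
      as.list(unname(full[c("gamma0", "rho_s", "alpha0", "K", "n")]))
    init <- c(x = unname(full[["x0"]]), y = unname(full[["y0"]]), p = 0,
              s = 1, a = 0)
    res <- tryCatch({
      unlist(purrr::map(obs, function(o) {
        run <- run_engine(p2, induction_constant(o$ahl), init,
                          t_end = max(o$t_end, dt), dt = dt, model = "core",
                          toxin_dilution = toxin_dilution,
                          load_integrand = "net_lysis", record_every = 1L,
                          thresholds = numeric(0))
        sim <- approx(run$t, run$x + run$y, xout = o$t, rule = 2)$y
        if (log_residuals) log(o$od + 1e-4) - log(sim + 1e-4)
        else o$od - sim
      }))
    }, error = function(e) rep(1e6, n_tot))
    res[!is.finite(res)] <- 1e6
    res
  }
}

# Gauss-Newton standard errors on the natural scale (finite-difference
# Jacobian at the optimum; delta-method factor for log10-scaled parameters).
gc_nat_se <- function(resid_fn, est_nat, tr, best) {
  se_int <- gn_se(function(th) resid_fn(tr$from_internal(th)), best$par,
                  best$ssr)
  log_pars <- intersect(names(est_nat), c("x0", "y0"))
  se_nat <- se_int
  names(se_nat) <- names(est_nat)
  se_nat[log_pars] <- se_int[match(log_pars, names(est_nat))] *
    est_nat[log_pars] * log(10)
  se_nat
}

gn_se <- function(resid_fn, par, ssr) {
  r0 <- resid_fn(par)
  n <- length(r0); p <- length(par)
  J <- matrix(NA_real_, n, p)
  h <- pmax(abs(par), 1e-4) * 1e-5
  for (j in seq_len(p)) {
    pj <- par; pj[j] <- pj[j] + h[j]
    J[, j] <- (resid_fn(pj) - r0) / h[j]
  }
  sigma2 <- ssr / max(n - p, 1)
  V <- tryCatch(sigma2 * solve(crossprod(J)),
                error = function(e) matrix(NA_real_, p, p))
  sqrt(pmax(diag(V), 0))
}

multistart_lm <- function(resid_fn, starts, lower, upper, maxiter) {
  runs <- purrr::map(seq_len(nrow(starts)), function(i) {
    st <- pmin(pmax(starts[i, ], lower), upper)
    out <- tryCatch(
      withCallingHandlers(
        minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                           upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter)),
        # the iteration cap is deliberate; exhausting it on some restarts is
        # reported through the convergence flag, not as a warning
        warning = function(w) {
          if (grepl("lmdif|maxiter", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    if (is.null(out)) return(NULL)
    list(par = out$par, ssr = sum(out$fvec^2),
         converged = out$info %in% 1:4, info = out$info)
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (length(runs) == 0) {
    abort("estimation failed: no optimizer start converged")
  }
  ssrs <- vapply(runs, function(r) r$ssr, numeric(1))
  best <- runs[[which.min(ssrs)]]
  best$start_ssr <- ssrs
  best$n_obs <- length(resid_fn(best$par))
  best
}

#' Estimate the initial mutant fraction from a growth curve
#'
#' Implements the composition-inference protocol: a culture of interest is
#' refreshed to a known density and grown under a fixed inducer
#' concentration; the resulting growth-crash-regrowth curve is fitted with
#' the full model in which every rate parameter is fixed and only the
#' initial densities `x0` (therapeutic) and `y0` (mutant) are free. The
#' post-crash regrowth timing pins down `y0`, and hence the mutant fraction
#' `f0 = y0 / (x0 + y0)` of the original culture.
#'
#' Uncertainty on `f0` is the dispersion (standard error of the mean)
#' across per-replicate fits. Curves lacking a regrowth signature leave
#' `y0` undetermined at its lower bound; the result is then flagged.
#'
#' @param data Growth-curve data at a single AHL condition (columns
#'   `time_h`, `od600`, `ahl_nM`, `replicate`); blank-corrected.
#' @param params A [model_params()] object fixing all rates.
#' @param n_starts,dt,maxiter Optimiser settings, see [fit_growth_curves()].
#' @return An object of class `lysim_mutant_estimate`: a list with `x0`,
#'   `y0`, `f0`, `f0_se`, `f0_replicates`, `flagged`, `note` and the
#'   underlying joint `fit`.
#' @export
estimate_mutant_fraction <- function(data, params, n_starts = 8, dt = 2e-3,
                                     maxiter = 100) {
  check_gc_columns(data)
  if (length(unique(data$ahl_nM)) != 1) {
    abort("composition estimation expects a single AHL condition")
  }
  first_od <- mean(data$od600[data$time_h == min(data$time_h)])
  init <- c(x0 = max(first_od, 1e-6), y0 = max(first_od * 1e-5, 1e-11))
  fit <- fit_growth_curves(data, free = c("x0", "y0"), params = params,
                           init = init, n_starts = n_starts, dt = dt,
                           maxiter = maxiter)
  est <- fit$estimates_nat
  f0 <- est[["y0"]] / (est[["x0"]] + est[["y0"]])

  reps <- unique(data$replicate)
  f0_reps <- if (length(reps) > 1) {
    vapply(reps, function(r) {
      fr <- tryCatch(
        fit_growth_curves(data[data$replicate == r, , drop = FALSE],
                          free = c("x0", "y0"), params = params, init = init,
                          n_starts = max(4, n_starts / 2), dt = dt,
                          maxiter = maxiter),
        error = function(e) NULL)
      if (is.null(fr)) return(NA_real_)
      e <- fr$estimates_nat
      e[["y0"]] / (e[["x0"]] + e[["y0"]])
    }, numeric(1))
  } else NA_real_
  f0_se <- if (all(is.na(f0_reps))) NA_real_ else {
    sd(f0_reps, na.rm = TRUE) / sqrt(sum(!is.na(f0_reps)))
  }

  at_lower <- est[["y0"]] <= 10^(-11.5)
  regrowth <- has_regrowth(data)
  note <- character(0)
  if (at_lower) note <- c(note, "y0 estimate at its lower bound")
  if (!regrowth) note <- c(note, "no post-crash regrowth signature in data")
  structure(list(x0 = est[["x0"]], y0 = est[["y0"]], f0 = f0, f0_se = f0_se,
                 f0_replicates = f0_reps,
                 flagged = at_lower || !regrowth,
                 note = paste(note, collapse = "; "), fit = fit),
            class = "lysim_mutant_estimate")
}

# Regrowth signature: does the replicate-averaged, lightly smoothed curve
# rise appreciably after its post-peak minimum?
has_regrowth <- function(data) {
  avg <- dplyr::summarise(dplyr::group_by(data, .data$time_h),
                          od = mean(.data$od600), .groups = "drop")
  od <- stats::filter(avg$od, rep(1 / 5, 5), sides = 2)
  od[is.na(od)] <- avg$od[is.na(od)]
  ipk <- which.max(od[seq_len(ceiling(length(od) / 2))])
  tail_od <- od[ipk:length(od)]
  itr <- which.min(tail_od)
  if (itr == length(tail_od)) return(FALSE)
  max(tail_od[itr:length(tail_od)]) > 1.2 * tail_od[itr]
}

#' @export
print.lysim_mutant_estimate <- function(x, ...) {
  cat("<lysim_mutant_estimate>\n")
  cat(sprintf("  x0 = %.4g  y0 = %.4g\n", x$x0, x$y0))
  cat(sprintf("  f0 = %.4g (se %.2g)%s\n", x$f0, x$f0_se,
              if (x$flagged) "  [FLAGGED]" else ""))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
tidy.lysim_mutant_estimate <- function(x, ...) {
  tibble(term = c("x0", "y0", "f0"),
         estimate = c(x$x0, x$y0, x$f0),
         std_error = c(NA_real_, NA_real_, x$f0_se))
}

#' Fit the constant-rate mutant-fraction law to induction-time data
#'
#' Fits \eqn{f(t) = e^{\alpha t}/(f_0^{-1} - 1 + e^{\alpha t})} to measured
#' mutant fractions versus induction time. On the logit scale this law is
#' exactly linear, \eqn{\mathrm{logit}\,f = \alpha t + \mathrm{logit}\,f_0},
#' so the fit is ordinary least squares there; standard errors for `f0`
#' follow by the delta method.
#'
#' @param data Data frame with columns `t_ind_h` (induction times, h) and
#'   `fraction` (mutant fractions strictly inside (0, 1)).
#' @return A `lysim_fit` with terms `alpha` (1/h) and `f0`.
#' @examples
#' d <- tibble::tibble(t_ind_h = c(1, 2, 4, 6),
#'                     fraction = fraction_constant_alpha(c(1, 2, 4, 6),
#'                                                        2.1, 4.2e-5))
#' tidy(fit_fraction_vs_induction(d))
#' @export
fit_fraction_vs_induction <- function(data) {
  if (!all(c("t_ind_h", "fraction") %in% names(data))) {
    abort("data must have columns t_ind_h and fraction")
  }
  t <- data$t_ind_h
  f <- data$fraction
  if (length(t) < 3) abort("need at least 3 induction times")
  if (any(f <= 0 | f >= 1)) abort("fractions must lie strictly in (0, 1)")
  if (sd(f) == 0) abort("all fractions identical; alpha is not identifiable")
  ml <- lm(qlogis(f) ~ t)
  alpha <- unname(coef(ml)[2])
  f0 <- plogis(unname(coef(ml)[1]))
  # standard errors computed directly (a noiseless design fits perfectly,
  # where summary.lm would warn)
  sigma2 <- sum(ml$residuals^2) / ml$df.residual
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, t))))
  ses <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  se_alpha <- ses[2]
  se_f0 <- f0 * (1 - f0) * ses[1]
  structure(list(
    method = "fraction_vs_induction",
    estimates = tibble(term = c("alpha", "f0"),
                       estimate = c(alpha, f0),
                       std_error = c(se_alpha, se_f0)),
    ssr = sum(ml$residuals^2), n_obs = length(t),
    df_residual = ml$df.residual, converged = TRUE, start_ssr = NA_real_,
    fixed = list(), data = as_tibble(data),
    fitted = plogis(stats::fitted(ml)), lm = ml
  ), class = "lysim_fit")
}

new_lysim_fit <- function(method, terms, best, resid_fn, data, fitted, fixed,
                          estimates_nat = NULL, se_fn = NULL) {
  if (is.null(estimates_nat)) {
    estimates_nat <- best$par
    names(estimates_nat) <- terms
  }
  se <- if (is.null(se_fn)) {
    gn_se(resid_fn, best$par, best$ssr)
  } else se_fn()
  structure(list(
    method = method,
    estimates = tibble(term = terms,
                       estimate = unname(estimates_nat[terms]),
                       std_error = unname(se)),
    estimates_nat = estimates_nat,
    ssr = best$ssr, n_obs = best$n_obs,
    df_residual = best$n_obs - length(terms),
    converged = best$converged, start_ssr = best$start_ssr,
    fixed = fixed, data = data, fitted = fitted
  ), class = "lysim_fit")
}

#' Broom-style accessors for `lysim_fit` objects
#'
#' `tidy()` returns one row per estimated parameter with its standard
#' error; `glance()` returns a one-row model summary; `augment()` (where
#' fitted values are available) returns the data with `.fitted` and
#' `.resid` columns.
#'
#' @param x A `lysim_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lysim_fit <- function(x, ...) x$estimates

#' @rdname tidy.lysim_fit
#' @export
glance.lysim_fit <- function(x, ...) {
  tibble(method = x$method, ssr = x$ssr, n_obs = x$n_obs,
         df_residual = x$df_residual, converged = x$converged,
         n_starts = length(x$start_ssr),
         start_ssr_spread = if (all(is.na(x$start_ssr))) NA_real_ else {
           max(x$start_ssr) - min(x$start_ssr)
         })
}

#' @rdname tidy.lysim_fit
#' @export
augment.lysim_fit <- function(x, ...) {
  if (is.null(x$fitted)) {
    abort("fitted values are not stored for this fit method")
  }
  out <- x$data
  out$.fitted <- as.numeric(x$fitted)
  obs_col <- if (x$method == "beta_hill") "beta" else "fraction"
  out$.resid <- out[[obs_col]] - out$.fitted
  out
}

#' @export
print.lysim_fit <- function(x, ...) {
  cat("<lysim_fit>", x$method, "\n")
  print(as.data.frame(x$estimates), row.names = FALSE)
  cat(sprintf("  SSR %.4g on %d observations; converged: %s\n", x$ssr,
              x$n_obs, x$converged))
  invisible(x)
}
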