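#' Initial population state
#'
#' Convenience constructor mirroring the standard plate-reader refresh: a
#' culture diluted to a given total density, of which a (usually tiny)
#' fraction is non-lysing mutant, with no intracellular toxin.
#'
#' @param total Initial total density `x + y` (a.u.).
#' @param fraction_mutant Initial mutant fraction `f0 = y/(x+y)`.
#' @param p Initial per-cell toxin concentration (a.u.); cells freshly
#'   diluted from an uninduced stock start at 0.
#' @param s Initial normalised substrate (substrate variant only).
#' @param a Initial AHL concentration in nM (dilution variant only).
#' @return Named numeric vector with components `x`, `y`, `p`, `s`, `a`.
#' @examples
#' initial_state(total = 0.01, fraction_mutant = 7e-5)
#' @export
initial_state <- function(total = 0.01, fraction_mutant = 7e-5, p = 0,
                          s = 1, a = 0) {
  if (total < 0 || fraction_mutant < 0 || fraction_mutant > 1) {
    abort("total must be >= 0 and fraction_mutant in [0, 1]")
  }
  c(x = total * (1 - fraction_mutant), y = total * fraction_mutant,
    p = p, s = s, a = a)
}

#' Integrate the population model forward in time
#'
#' Fixed-step forward Euler integration of the lysis-circuit model (or a
#' variant) under an arbitrary induction program, with states hard-clamped
#' at zero after every step. The cumulative released-load proxy
#' \eqn{\int (\alpha - \gamma)^{+} x\, dt} is accumulated by trapezoidal
#' quadrature on the full integration grid, so it is exact to the order of
#' the integrator even when the output is thinned via `record_every`.
#'
#' When `check_convergence = TRUE` the integration is repeated at half the
#' step size and the scalar summaries of the crash (peak density and time,
#' trough time, final mutant fraction) are compared; a warning is raised if
#' any differs by more than `convergence_tol` (relative).
#'
#' @param params A [model_params()] object.
#' @param program A `lysim_program` (see [induction_constant()]), or a
#'   single number interpreted as a constant AHL concentration in nM. For
#'   `model = "dilution"` the program levels are AHL *supply rates* (nM/h).
#' @param init Named state vector, see [initial_state()].
#' @param t_end End time (h).
#' @param dt Euler step (h), default 0.001.
#' @param model Model variant, see [rhs()].
#' @param toxin_dilution Positive-part convention for toxin dilution, see
#'   [rhs()].
#' @param load_integrand Released-load integrand: `"net_lysis"` for
#'   \eqn{(\alpha-\gamma)^{+}x} (default) or `"alpha_x"` for \eqn{\alpha x}.
#' @param record_every Record every this-many Euler steps (default 1 =
#'   every step); the final state is always recorded.
#' @param check_convergence Run the half-step check (default `TRUE`).
#' @param convergence_tol Relative tolerance of the half-step check.
#' @return A tibble of class `lysim_trajectory` with columns `t_h`,
#'   `ahl_nM`, `x`, `y`, `p`, `total`, `fraction_mutant`, `released_load`
#'   (plus `s` and/or `a` for the variants), and attributes `params`,
#'   `program`, `model`, `dt`, `final_state`, `n_clamped`.
#' @examples
#' traj <- simulate_dynamics(params_preset(), induction_constant(100),
#'                           initial_state(), t_end = 24)
#' crash_summary(traj)
#' @export
simulate_dynamics <- function(params, program, init = initial_state(),
                              t_end, dt = 1e-3,
                              model = c("core", "substrate", "mutation",
                                        "dilution"),
                              toxin_dilution = c("net_growth", "growth"),
                              load_integrand = c("net_lysis", "alpha_x"),
                              record_every = 1L,
                              check_convergence = TRUE,
                              convergence_tol = 0.01) {
  model <- match.arg(model)
  toxin_dilution <- match.arg(toxin_dilution)
  load_integrand <- match.arg(load_integrand)
  stopifnot(inherits(params, "lysim_params"))
  check_variant_params(params, model)
  if (is.numeric(program) && length(program) == 1) {
    program <- induction_constant(program)
  }
  stopifnot(inherits(program, "lysim_program"))
  if (dt <= 0) abort("dt must be positive")
  if (t_end <= 0) abort("t_end must be positive")
  if (any(init[c("x", "y", "p")] < 0)) abort("init must be non-negative")

  run <- run_engine(params, program, init, t_end, dt, model, toxin_dilution,
                    load_integrand, record_every, thresholds = numeric(0))

  traj <- engine_to_tibble(run, model)
  attr(traj, "params") <- params
  attr(traj, "program") <- program
  attr(traj, "model") <- model
  attr(traj, "toxin_dilution") <- toxin_dilution
  attr(traj, "load_integrand") <- load_integrand
  attr(traj, "dt") <- dt
  attr(traj, "final_state") <- run$final
  attr(traj, "n_clamped") <- run$n_clamped
  class(traj) <- c("lysim_trajectory", class(traj))

  if (isTRUE(check_convergence)) {
    half <- run_engine(params, program, init, t_end, dt / 2, model,
                       toxin_dilution, load_integrand,
                       record_every = 2L * record_every,
                       thresholds = numeric(0))
    s1 <- summary_scalars(run)
    s2 <- summary_scalars(half)
    relerr <- abs(s1 - s2) / pmax(abs(s2), 1e-8)
    if (any(relerr > convergence_tol, na.rm = TRUE)) {
      bad <- names(relerr)[which(relerr > convergence_tol)]
      warn(paste0("Euler half-step check: summaries not converged at dt = ",
                  format(dt), " (", paste(bad, collapse = ", "),
                  "); consider a smaller dt"))
    }
  }
  if (run$n_clamped > 0) {
    attr(traj, "clamp_note") <- paste0(run$n_clamped,
                                       " state value(s) clamped at bounds")
  }
  traj
}

run_engine <- function(params, program, init, t_end, dt, model,
                       toxin_dilution, load_integrand, record_every,
                       thresholds) {
  seg <- program_segments(program, t_end)
  run <- euler_engine(
    pack_params(params),
    model = match(model, c("core", "substrate", "mutation", "dilution")) - 1L,
    toxin_dilution = match(toxin_dilution, c("net_growth", "growth")) - 1L,
    load_integrand = match(load_integrand, c("net_lysis", "alpha_x")) - 1L,
    seg_ends = seg$ends, seg_levels = seg$levels,
    x0 = init[["x"]], y0 = init[["y"]], p0 = init[["p"]],
    s0 = if ("s" %in% names(init)) init[["s"]] else 1,
    a0 = if ("a" %in% names(init)) init[["a"]] else 0,
    t_end = t_end, dt = dt, save_every = as.integer(record_every),
    thresholds = thresholds
  )
  if (!isTRUE(run$ok)) {
    abort(paste0("integration produced a non-finite state at t = ",
                 format(run$bad_time), " h"))
  }
  run
}

engine_to_tibble <- function(run, model) {
  total <- run$x + run$y
  out <- tibble(
    t_h = run$t, ahl_nM = run$ahl, x = run$x, y = run$y, p = run$p,
    total = total,
    fraction_mutant = ifelse(total > 0, run$y / total, NA_real_),
    released_load = run$load
  )
  if (model == "substrate") out$s <- run$s
  if (model == "dilution") out$a <- run$a
  out
}

summary_scalars <- function(run) {
  total <- run$x + run$y
  cs <- crash_indices(total)
  f_final <- if (total[length(total)] > 0) {
    run$y[length(run$y)] / total[length(total)]
  } else NA_real_
  c(peak_density = total[cs$peak],
    peak_time = run$t[cs$peak],
    trough_time = if (is.na(cs$trough)) NA_real_ else run$t[cs$trough],
    final_fraction = f_final,
    final_load = run$final_load)
}

# First local maximum of the density series (the pre-crash peak) and the
# minimum that follows it. Falls back to the global maximum when the series
# is monotone (no crash).
crash_indices <- function(total) {
  d <- diff(total)
  turn <- which(d[-length(d)] > 0 & d[-1] <= 0)
  peak <- if (length(turn) > 0) turn[1] + 1L else which.max(total)
  trough <- if (peak < length(total)) {
    peak + which.min(total[peak:length(total)]) - 1L
  } else NA_integer_
  if (!is.na(trough) && trough == peak) trough <- NA_integer_
  list(peak = peak, trough = trough)
}

#' Summaries of the growth-crash-regrowth shape of a trajectory
#'
#' Locates the pre-crash density peak (the first local maximum of the total
#' density), the post-crash trough (the minimum after the peak), and reports
#' the relative peak-to-trough drop together with the final mutant fraction
#' and cumulative released load.
#'
#' @param traj A `lysim_trajectory` from [simulate_dynamics()].
#' @return A one-row tibble with `peak_time_h`, `peak_density`,
#'   `trough_time_h`, `trough_density`, `drop_pct`, `final_fraction`,
#'   `final_load`.
#' @export
crash_summary <- function(traj) {
  stopifnot(inherits(traj, "lysim_trajectory"))
  cs <- crash_indices(traj$total)
  peak <- cs$peak
  trough <- cs$trough
  tibble(
    peak_time_h = traj$t_h[peak],
    peak_density = traj$total[peak],
    trough_time_h = if (is.na(trough)) NA_real_ else traj$t_h[trough],
    trough_density = if (is.na(trough)) NA_real_ else traj$total[trough],
    drop_pct = if (is.na(trough)) NA_real_ else {
      100 * (traj$total[peak] - traj$total[trough]) / traj$total[peak]
    },
    final_fraction = traj$fraction_mutant[nrow(traj)],
    final_load = traj$released_load[nrow(traj)]
  )
}

#' Read or write a trajectory as delimited text
#'
#' Trajectories are exchanged as tab-separated text with the canonical
#' column header `t_h, ahl_nM, x, y, p, total, fraction_mutant,
#' released_load` (plus variant columns when present).
#'
#' @param traj A `lysim_trajectory` (or any data frame with those columns).
#' @param path File path.
#' @return `read_trajectory()` returns a tibble; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_delim_g17(as.data.frame(traj), path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- read_delim_exact(path)
  num <- intersect(names(out), c("t_h", "ahl_nM", "x", "y", "p", "s", "a",
                                 "total", "fraction_mutant", "released_load"))
  out[num] <- lapply(out[num], as.double)
  out
}

# read.delim is used (rather than readr) because R's strtod parsing is
# correctly rounded, making the %.17g write -> read round trip bit-exact.
read_delim_exact <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

# Tab-separated writer formatting doubles with %.17g so numeric round-trips
# are bit-identical.
write_delim_g17 <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
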