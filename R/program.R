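#' Induction programs: the external AHL forcing \[AHL\](t)
#'
#' An induction program describes the externally imposed inducer
#' concentration as a function of time. Three kinds are supported:
#' a constant level, a square wave (each cycle starts with the ON segment),
#' and a piecewise-constant profile given by breakpoints.
#'
#' @param amplitude AHL concentration in nM (the ON level for square waves).
#' @param period Square-wave period (h).
#' @param on_duration Duration of the ON segment per cycle (h); must not
#'   exceed `period`.
#' @param breakpoints For `induction_piecewise()`: increasing vector of times
#'   (h) at which the level changes, starting at 0.
#' @param levels AHL levels (nM), one per breakpoint; level `levels[i]`
#'   applies on `[breakpoints[i], breakpoints[i + 1])`.
#' @return An object of class `lysim_program`.
#' @examples
#' prog <- induction_square_wave(100, period = 6, on_duration = 1)
#' ahl_at(prog, c(0, 0.5, 1, 3, 6, 6.5))
#' @export
induction_constant <- function(amplitude) {
  check_levels(amplitude)
  structure(list(kind = "constant", amplitude = amplitude),
            class = "lysim_program")
}

#' @rdname induction_constant
#' @export
induction_square_wave <- function(amplitude, period, on_duration) {
  check_levels(amplitude)
  if (period <= 0) abort("period must be positive")
  if (on_duration < 0 || on_duration > period) {
    abort("on_duration must lie in [0, period]")
  }
  structure(list(kind = "square_wave", amplitude = amplitude, period = period,
                 on_duration = on_duration), class = "lysim_program")
}

#' @rdname induction_constant
#' @export
induction_piecewise <- function(breakpoints, levels) {
  check_levels(levels)
  if (length(breakpoints) != length(levels)) {
    abort("breakpoints and levels must have the same length")
  }
  if (breakpoints[1] != 0) abort("the first breakpoint must be 0")
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    abort("breakpoints must be strictly increasing")
  }
  structure(list(kind = "piecewise", breakpoints = breakpoints,
                 levels = levels), class = "lysim_program")
}

check_levels <- function(levels) {
  if (any(!is.finite(levels)) || any(levels < 0)) {
    abort("AHL levels must be finite and non-negative")
  }
  invisible(levels)
}

#' @rdname induction_constant
#' @param program A `lysim_program`.
#' @param t Time(s) in hours, non-negative.
#' @export
ahl_at <- function(program, t) {
  stopifnot(inherits(program, "lysim_program"))
  if (any(t < 0)) abort("t must be non-negative")
  switch(program$kind,
    constant = rep(program$amplitude, length(t)),
    square_wave = ifelse(t %% program$period < program$on_duration,
                         program$amplitude, 0),
    piecewise = program$levels[findInterval(t, program$breakpoints)]
  )
}

# Reduce any program to piecewise-constant segments covering [0, t_end]:
# level seg_levels[j] applies for t < seg_ends[j].
program_segments <- function(program, t_end) {
  switch(program$kind,
    constant = list(ends = t_end, levels = program$amplitude),
    square_wave = {
      n_cycles <- ceiling(t_end / program$period)
      starts <- (seq_len(n_cycles) - 1) * program$period
      ends <- as.vector(rbind(starts + program$on_duration,
                              starts + program$period))
      levels <- rep(c(program$amplitude, 0), n_cycles)
      keep <- c(TRUE, ends[-length(ends)] < t_end)
      ends <- pmin(ends[keep], t_end)
      # drop zero-length segments (on_duration 0 or period-aligned horizon)
      lens <- diff(c(0, ends))
      list(ends = ends[lens > 0], levels = levels[keep][lens > 0])
    },
    piecewise = {
      starts <- program$breakpoints
      ends <- c(starts[-1], Inf)
      keep <- starts < t_end
      list(ends = pmin(ends[keep], t_end), levels = program$levels[keep])
    }
  )
}

#' @export
print.lysim_program <- function(x, ...) {
  cat("<lysim_program>", x$kind, "\n")
  if (x$kind == "constant") {
    cat("  amplitude:", x$amplitude, "nM\n")
  } else if (x$kind == "square_wave") {
    cat("  amplitude:", x$amplitude, "nM, period:", x$period,
        "h, on:", x$on_duration, "h\n")
  } else {
    cat("  breakpoints (h):", paste(x$breakpoints, collapse = ", "), "\n")
    cat("  levels (nM):    ", paste(x$levels, collapse = ", "), "\n")
  }
  invisible(x)
}
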