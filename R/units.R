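#' Convert a Snellen denominator to logMAR
#'
#' Acuity notation used throughout the package: a Snellen fraction 20/x is
#' stored by its denominator x, and logMAR = log10(x / 20), so 20/20 is
#' logMAR 0.0 and 20/200 is logMAR 1.0. Lower logMAR is better vision.
#'
#' @param denominator Positive Snellen denominator(s), e.g. `40` for 20/40.
#' @return logMAR value(s).
#' @seealso [logmar_to_snellen()], [chart_ladder()]
#' @examples
#' snellen_to_logmar(c(20, 40, 200))
#' @export
snellen_to_logmar <- function(denominator) {
  if (!is.numeric(denominator) || length(denominator) == 0 ||
      any(!is.finite(denominator)) || any(denominator <= 0)) {
    stop("Snellen denominator must be a positive finite number", call. = FALSE)
  }
  log10(denominator / 20)
}

#' Convert logMAR to a Snellen denominator
#'
#' Exact inverse of [snellen_to_logmar()]; use [snap_to_ladder()] to round
#' onto a chart line.
#'
#' @param logmar logMAR value(s).
#' @return Snellen denominator(s).
#' @export
logmar_to_snellen <- function(logmar) {
  if (!is.numeric(logmar) || any(!is.finite(logmar))) {
    stop("logmar must be finite numeric", call. = FALSE)
  }
  20 * 10^logmar
}

#' The tumbling-E chart ladder
#'
#' Ordered Snellen denominators, largest first, defining the letter sizes a
#' session can present. The default is the standard clinical progression from
#' 20/400 down to 20/20. The test floor is the first (largest) line; a
#' subject unable to match it is recorded as "worse than 20/400".
#'
#' @param sizes Strictly decreasing positive denominators.
#' @return A `chart_ladder` numeric vector.
#' @examples
#' chart_ladder()
#' @export
chart_ladder <- function(sizes = c(400, 200, 100, 80, 60, 50, 40, 30, 25, 20)) {
  if (!is.numeric(sizes) || length(sizes) < 2 || any(sizes <= 0)) {
    stop("ladder needs at least two positive sizes", call. = FALSE)
  }
  if (any(diff(sizes) >= 0)) {
    stop("ladder sizes must be strictly decreasing", call. = FALSE)
  }
  structure(as.numeric(sizes), class = "chart_ladder")
}

#' Snap a Snellen denominator to the nearest ladder line at or above it
#'
#' @param denominator Positive denominator.
#' @param ladder A [chart_ladder()].
#' @return The smallest ladder line whose denominator is >= `denominator`.
#' @export
snap_to_ladder <- function(denominator, ladder = chart_ladder()) {
  stopifnot(is.numeric(denominator), length(denominator) == 1L, denominator > 0)
  eligible <- unclass(ladder)[unclass(ladder) >= denominator - 1e-9]
  if (length(eligible) == 0) {
    stop("denominator beyond the largest ladder line", call. = FALSE)
  }
  min(eligible)
}

#' A recorded visual acuity
#'
#' A Snellen fraction with its logMAR value and an explicit "below floor"
#' flag for subjects unable to match the largest letter (recorded clinically
#' as "less than 20/400"). Below-floor records keep the floor denominator but
#' must be excluded or capped by any numeric summary; comparisons treat them
#' as strictly worse than the floor.
#'
#' @param denominator Positive Snellen denominator.
#' @param below_floor If `TRUE` the subject failed the largest line;
#'   `denominator` is then the floor value.
#' @return A `visual_acuity` object with fields `denominator`, `logmar`,
#'   `below_floor`.
#' @examples
#' visual_acuity(40)
#' visual_acuity(400, below_floor = TRUE)
#' @export
visual_acuity <- function(denominator = 400, below_floor = FALSE) {
  stopifnot(is.logical(below_floor), length(below_floor) == 1L)
  d <- denominator
  stopifnot(is.numeric(d), length(d) == 1L, d > 0)
  structure(
    list(
      denominator = as.numeric(d),
      logmar = snellen_to_logmar(d),
      below_floor = isTRUE(below_floor)
    ),
    class = "visual_acuity"
  )
}

#' @export
print.visual_acuity <- function(x, ...) {
  if (x$below_floor) {
    cat(sprintf("< 20/%g (below floor)\n", x$denominator))
  } else {
    cat(sprintf("20/%g (logMAR %.2f)\n", x$denominator, x$logmar))
  }
  invisible(x)
}

#' @export
format.visual_acuity <- function(x, ...) {
  if (x$below_floor) sprintf("<20/%g", x$denominator) else sprintf("20/%g", x$denominator)
}

#' Is an acuity at or worse than a Snellen cutoff?
#'
#' The protocol's pinhole-retest rule triggers at "20/30 or worse"; the
#' referral rule uses "worse than 20/30". Below-floor records are worse than
#' every cutoff.
#'
#' @param acuity A [visual_acuity()].
#' @param cutoff_denominator Snellen denominator of the cutoff line.
#' @param strict If `TRUE`, "strictly worse than" instead of "at or worse".
#' @return Logical.
#' @export
acuity_worse_than <- function(acuity, cutoff_denominator, strict = FALSE) {
  stopifnot(inherits(acuity, "visual_acuity"))
  if (acuity$below_floor) return(TRUE)
  if (strict) {
    acuity$denominator > cutoff_denominator + 1e-9
  } else {
    acuity$denominator >= cutoff_denominator - 1e-9
  }
}

# round half away from zero (R's round() is banker's rounding)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with the package's reporting convention
#'
#' Computes `100 * numerator / denominator` rounded half-away-from-zero to
#' the requested number of decimals. This single rounding convention is used
#' for every reported rate (prevalence, sensitivity, specificity, percent
#' improvement) so printed summaries are reproducible.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Non-negative number of decimal places (default 0).
#' @return The rounded percentage.
#' @examples
#' round_percent(2, 204)      # 1   -- e.g. a 1% prevalence
#' round_percent(1, 121, 2)   # 0.83
#' @export
round_percent <- function(numerator, denominator, decimals = 0) {
  stopifnot(is.numeric(numerator), is.numeric(denominator), is.numeric(decimals))
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  if (decimals < 0) stop("decimals must be >= 0", call. = FALSE)
  round_half_away(100 * numerator / denominator, decimals)
}

# evaluate fn() under a scoped seed without touching the caller's RNG state
run_seeded <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
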