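#' Bland-Altman agreement between two paired measurements
#'
#' Computes the mean difference d, the sample standard deviation (n-1
#' denominator) of the paired differences, and the limits of agreement
#' d +/- `multiplier` * SD. The 2-SD convention (not 1.96) is the default,
#' matching how agreement between acuity charts is usually summarised:
#' about 95% of differences are expected inside the limits.
#'
#' @param first,second Equal-length numeric vectors (e.g. logMAR acuities
#'   of the same eyes by two methods); differences are `first - second`.
#' @param multiplier SD multiplier for the limits (default 2).
#' @return An `agreement` object: `n`, `d`, `sd`, `lower`, `upper`, plus
#'   the per-pair `differences` and `means` for plotting.
#' @examples
#' bland_altman(c(0.1, 0.2, 0.0, 0.3), c(0.1, 0.1, 0.1, 0.2))
#' @export
bland_altman <- function(first, second, multiplier = 2) {
  if (!is.numeric(first) || !is.numeric(second)) {
    stop("inputs must be numeric", call. = FALSE)
  }
  if (length(first) != length(second)) {
    stop("paired series must have equal length", call. = FALSE)
  }
  if (length(first) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(first)) || any(!is.finite(second))) {
    stop("inputs must be finite (exclude below-floor records first)",
         call. = FALSE)
  }
  diffs <- first - second
  d <- mean(diffs)
  s <- stats::sd(diffs)
  lims <- agreement_limits(d, s, multiplier)
  structure(
    list(n = length(diffs), d = d, sd = s,
         lower = lims[["lower"]], upper = lims[["upper"]],
         multiplier = multiplier,
         differences = diffs, means = (first + second) / 2),
    class = "agreement"
  )
}

#' Limits of agreement from a printed summary
#'
#' @param d Mean difference.
#' @param sd Standard deviation of the differences.
#' @param multiplier SD multiplier (default 2).
#' @return Named vector `c(lower, upper)` = `d -/+ multiplier * sd`.
#' @examples
#' agreement_limits(0.04, 0.14)  # c(-0.24, 0.32)
#' @export
agreement_limits <- function(d, sd, multiplier = 2) {
  stopifnot(is.numeric(d), is.numeric(sd), sd >= 0)
  c(lower = d - multiplier * sd, upper = d + multiplier * sd)
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("<Bland-Altman, n = %d pairs>\n", x$n))
  cat(sprintf("  d = %.4f, SD = %.4f, limits d %+g SD: [%.4f, %.4f]\n",
              x$d, x$sd, x$multiplier, x$lower, x$upper))
  invisible(x)
}

#' Percent improvement of a summary statistic
#'
#' `100 * (before - after) / before`, rounded half-away-from-zero to the
#' requested decimals — the convention used to report, e.g., the
#' improvement in mean logMAR acuity when the pinhole is added.
#'
#' @param before,after Positive `before` and its improved value.
#' @param decimals Decimal places (default 0, integer percent).
#' @return The rounded percentage.
#' @examples
#' percent_improvement(0.11, 0.05)  # 55
#' @export
percent_improvement <- function(before, after, decimals = 0) {
  stopifnot(is.numeric(before), is.numeric(after))
  if (before <= 0) stop("'before' must be positive", call. = FALSE)
  round_half_away(100 * (before - after) / before, decimals)
}

#' Bland-Altman agreement from screening sessions
#'
#' Pairs per-eye logMAR acuities between two measures and delegates to
#' [bland_altman()]. Eyes are the pairing unit; below-floor or missing
#' records are excluded and counted in `n_excluded`. With a single record
#' list the two measures are taken from the same sessions (e.g. `"unaided"`
#' vs `"pinhole"`); with `records_b` the same measure (or `measure_b`) is
#' paired across two parallel record sets, e.g. the same cohort measured by
#' two protocol variants with independent seeds.
#'
#' @param records A list of `subject_record`s.
#' @param records_b Optional second list, paired with `records` by position.
#' @param measure_a,measure_b `"unaided"` or `"pinhole"`.
#' @param multiplier SD multiplier for the limits.
#' @return An `agreement` object with an extra `n_excluded` field.
#' @export
agreement_from_sessions <- function(records, records_b = NULL,
                                    measure_a = "unaided",
                                    measure_b = if (is.null(records_b))
                                      "pinhole" else measure_a,
                                    multiplier = 2) {
  measure_a <- match.arg(measure_a, c("unaided", "pinhole"))
  measure_b <- match.arg(measure_b, c("unaided", "pinhole"))
  if (!is.null(records_b) && length(records_b) != length(records)) {
    stop("records_b must pair with records by position", call. = FALSE)
  }
  pull <- function(r, measure, eye) {
    if (is.null(r$acuity)) return(NA_real_)
    va <- r$acuity[[eye]][[measure]]
    if (is.null(va) || va$below_floor) NA_real_ else va$logmar
  }
  a <- c(); b <- c()
  src_b <- records_b %||% records
  for (i in seq_along(records)) {
    for (eye in c("OD", "OS")) {
      a <- c(a, pull(records[[i]], measure_a, eye))
      b <- c(b, pull(src_b[[i]], measure_b, eye))
    }
  }
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2L) {
    stop("fewer than 2 usable eye pairs after exclusions", call. = FALSE)
  }
  res <- bland_altman(a[ok], b[ok], multiplier)
  res$n_excluded <- sum(!ok)
  res
}
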