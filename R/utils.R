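#' Rounded count percentage for reporting
#'
#' Formats a count out of a total as a whole-number percentage, the rounding
#' convention used in clinical tables ("12/43 (28%)").
#'
#' @param count Numerator count (non-negative).
#' @param total Denominator count (positive).
#' @return Integer percentage, `round(100 * count / total)`.
#' @examples
#' pct_count(12, 43) # 28
#' pct_count(41, 43) # 95
#' @export
pct_count <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0), all(count >= 0))
  round(100 * count / total)
}

#' Percent reduction between a baseline and a follow-up value
#'
#' @param pre Baseline value (nonzero).
#' @param post Follow-up value.
#' @return `100 * (pre - post) / pre`; positive when the value decreased.
#' @examples
#' percent_reduction(114, 82) # ~28.07
#' @export
percent_reduction <- function(pre, post) {
  out <- 100 * (pre - post) / pre
  out[pre == 0] <- NA_real_
  out
}

#' Myocardial tissue density used for mass/volume conversion (g/mL)
#' @keywords internal
MYO_DENSITY <- 1.05

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single value strictly between 0 and 1", name),
         call. = FALSE)
  }
  invisible(x)
}
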