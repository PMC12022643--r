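#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cmr_cormat <- function(x, ...) {
  vars <- x$vars
  pairs <- expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE)
  tibble::tibble(
    var1 = pairs$var1, var2 = pairs$var2,
    r = as.vector(x$r), p_value = as.vector(x$p), n = as.vector(x$n))
}

#' @export
tidy.cmr_stepwise <- function(x, ...) x$coefficients

#' @export
glance.cmr_stepwise <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    outcome = x$outcome,
    n_selected = length(x$selected),
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    durbin_watson = x$durbin_watson$statistic,
    durbin_watson_p = x$durbin_watson$p_value,
    n_flagged = sum(x$influence$flagged),
    nobs = stats::nobs(x$fit))
}

#' @export
tidy.cmr_cohort_results <- function(x, ...) x$change_table

#' @export
glance.cmr_cohort_results <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(unique(x$paired$subject_id)),
    n_metrics = length(unique(x$paired$metric)),
    n_significant = sum(x$change_table$significant),
    alpha_adjusted = bonferroni_alpha(x$config$alpha, x$config$family))
}
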