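#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Familywise significance level.
#' @param m Number of tests in the family (>= 1).
#' @return `alpha / m`; with the conventional 20-test change table this is
#'   0.05 / 20 = 0.0025.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 20) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Wilcoxon signed-rank test (exact, zero-drop, midranks)
#'
#' Signed-rank test of the hypothesis that paired differences are symmetric
#' about zero. Zero differences are dropped (Wilcoxon's original rule), ties
#' among absolute differences receive midranks. For `n <= exact_limit`
#' (default 25) the two-sided p-value is computed from the exact null
#' distribution of the positive-rank sum over all 2^n sign assignments
#' (evaluated by generating-function convolution); beyond that a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param d Numeric vector of paired differences.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return One-row tibble: `statistic` (positive-rank sum V), `p_value`,
#'   `n` (after zero removal), `method` (`"exact"`/`"normal"`).
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; degenerate test reported with p = 1",
            call. = FALSE)
    return(tibble::tibble(statistic = 0, p_value = 1, n = 0L,
                          method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- wsr_exact_p(v, r)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  tibble::tibble(statistic = v, p_value = p, n = as.integer(n), method = method)
}

# Exact two-sided p for the positive-rank sum given the (mid)ranks.
# Works on doubled ranks so midranks (k/2) become integers; the null
# distribution is the coefficient vector of prod_i (1 + x^(2 r_i)) / 2^n.
wsr_exact_p <- function(v, r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  coef <- numeric(total + 1)
  coef[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), coef[seq_len(total + 1 - ri)])
    coef <- coef + shifted
  }
  coef <- coef / sum(coef)
  v2 <- round(2 * v)
  p_le <- sum(coef[seq_len(v2 + 1)])                 # P(V2 <= v2)
  p_ge <- sum(coef[seq.int(v2 + 1, total + 1)])      # P(V2 >= v2)
  min(1, 2 * min(p_le, p_ge))
}

#' Normality-gated paired comparison
#'
#' Tests whether a metric changed within person between two timepoints. The
#' paired differences are first checked for normality with the Shapiro-Wilk
#' test at level 0.05: if not rejected, a paired Student's t-test is used,
#' otherwise the Wilcoxon signed-rank test ([wilcoxon_signed_rank()]).
#' Significance is judged against the Bonferroni-adjusted threshold
#' `alpha / m`.
#'
#' @param data Optional data frame holding the paired columns.
#' @param pre,post Numeric vectors (or column names in `data`) of equal
#'   length >= 3, no missing pairs.
#' @param alpha Familywise significance level. @param m Family size.
#' @param force `NULL` (gate on Shapiro-Wilk) or `"t"`/`"wilcoxon"` to force
#'   a branch.
#' @param metric Optional metric name carried into the result.
#' @return One-row tibble: `metric`, `n`, `test`, `statistic`, `p_value`,
#'   `normality_p`, `alpha_adjusted`, `significant`.
#' @export
paired_compare <- function(data = NULL, pre, post, alpha = 0.05, m = 1,
                           force = NULL, metric = NA_character_) {
  if (!is.null(data)) {
    pre <- data[[rlang::as_name(rlang::enquo(pre))]]
    post <- data[[rlang::as_name(rlang::enquo(post))]]
  }
  stopifnot(length(pre) == length(post), length(pre) >= 3,
            !anyNA(pre), !anyNA(post))
  d <- post - pre
  thresh <- bonferroni_alpha(alpha, m)

  if (all(d == 0)) {
    warning("all differences are zero; degenerate result with p = 1",
            call. = FALSE)
    return(tibble::tibble(metric = metric, n = length(d), test = "degenerate",
                          statistic = 0, p_value = 1, normality_p = NA_real_,
                          alpha_adjusted = thresh, significant = FALSE))
  }

  normality_p <- if (stats::sd(d) == 0) 0 else stats::shapiro.test(d)$p.value
  use_t <- if (is.null(force)) normality_p >= 0.05 else identical(force, "t")
  if (use_t) {
    tt <- stats::t.test(post, pre, paired = TRUE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
    test <- "paired-t"
  } else {
    w <- wilcoxon_signed_rank(d)
    stat <- w$statistic
    p <- w$p_value
    test <- "wilcoxon-signed-rank"
  }
  tibble::tibble(metric = metric, n = length(d), test = test, statistic = stat,
                 p_value = p, normality_p = normality_p,
                 alpha_adjusted = thresh, significant = p < thresh)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson correlations between all pairs of the selected numeric columns,
#' pairwise-complete, with two-sided p-values from the t distribution.
#' Zero-variance columns yield `NA` correlations.
#'
#' @param data Data frame.
#' @param vars Columns to correlate (character); default: all numeric.
#' @return An object of class `cmr_cormat` with matrices `r`, `p`, `n`;
#'   [generics::tidy()] gives the long form, [ggplot2::autoplot()] a heatmap.
#' @export
correlation_matrix <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(vars) < 2) stop("need at least two variables", call. = FALSE)
  x <- as.matrix(data[, vars])
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- r
  nm <- matrix(NA_integer_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- stats::complete.cases(x[, i], x[, j])
      nn <- sum(ok)
      nm[i, j] <- nn
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (nn < 3 || stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) next
      ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nm, vars = vars), class = "cmr_cormat")
}

#' @export
print.cmr_cormat <- function(x, digits = 2, ...) {
  cat("<cmr_cormat> Pearson correlations (pairwise complete)\n")
  print(round(x$r, digits))
  invisible(x)
}
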