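#' Restricted cubic spline basis
#'
#' Truncated-power restricted (natural) cubic spline basis in Harrell's
#' parameterization: linear in the tails beyond the outer knots, `k - 1`
#' columns for `k` knots (the first column is the linear term). Nonlinear
#' columns are scaled by the squared outer-knot span for numerical balance.
#'
#' @param x Numeric vector.
#' @param knots Knot locations; if a single integer (3, 4 or 5), knots are
#'   placed at the conventional quantiles (3: 10/50/90; 4: 5/35/65/95;
#'   5: 5/27.5/50/72.5/95 percent).
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots = 4) {
  if (length(knots) == 1) {
    k <- as.integer(knots)
    qs <- switch(as.character(k),
                 "3" = c(0.10, 0.50, 0.90),
                 "4" = c(0.05, 0.35, 0.65, 0.95),
                 "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                 stop("knot count must be 3, 4 or 5", call. = FALSE))
    knots <- unname(stats::quantile(x, qs, na.rm = TRUE, type = 7))
  }
  knots <- sort(knots)
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots", call. = FALSE)
  if (any(diff(knots) <= 0)) {
    stop("too few distinct covariate values for knot placement", call. = FALSE)
  }
  span2 <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2), function(j) {
    (pos3(x - knots[j]) -
       pos3(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
       pos3(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) /
      span2
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("linear", paste0("nonlin", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}

#' Restricted-cubic-spline nonlinearity test
#'
#' Fits the outcome on a restricted cubic spline of the covariate and tests
#' whether all nonlinear basis coefficients are jointly zero (F-test of the
#' spline fit against the plain linear fit). A small p-value indicates a
#' nonlinear association.
#'
#' @param data Data frame.
#' @param outcome,covariate Column names (character).
#' @param knots Number of knots (3, 4 or 5; default 4) or explicit locations.
#' @return One-row tibble: `outcome`, `covariate`, `n_knots`,
#'   `nonlinearity_p`.
#' @export
rcs_nonlinearity <- function(data, outcome, covariate, knots = 4) {
  stopifnot(outcome %in% names(data), covariate %in% names(data))
  x <- data[[covariate]]
  y <- data[[outcome]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 20) stop("need at least 20 observations", call. = FALSE)
  basis <- rcs_basis(x, knots)
  n_knots <- length(attr(basis, "knots"))
  if (stats::sd(y) == 0) {
    return(tibble::tibble(outcome = outcome, covariate = covariate,
                          n_knots = n_knots, nonlinearity_p = 1))
  }
  lin <- stats::lm(y ~ x)
  full <- stats::lm(y ~ basis)
  a <- stats::anova(lin, full)
  p <- a[["Pr(>F)"]][2]
  if (is.na(p)) p <- 1  # spline adds no explanatory power (e.g. perfect linear fit)
  tibble::tibble(outcome = outcome, covariate = covariate,
                 n_knots = n_knots, nonlinearity_p = p)
}
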