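#' Durbin-Watson statistic of a residual sequence
#'
#' `DW = sum((e_t - e_{t-1})^2) / sum(e_t^2)`; values near 2 indicate
#' independent residuals. For the p-value of the test on a fitted model use
#' the `durbin_watson` field of [stepwise_multivariable()] results (computed
#' with `lmtest::dwtest`).
#'
#' @param residuals Numeric vector (length >= 2).
#' @return The DW statistic.
#' @export
durbin_watson <- function(residuals) {
  stopifnot(length(residuals) >= 2)
  sum(diff(residuals)^2) / sum(residuals^2)
}

lm_term_row <- function(fit, term, level = 0.95) {
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = level)
  tibble::tibble(
    term = term,
    beta = s[term, "Estimate"],
    conf_low = ci[term, 1],
    conf_high = ci[term, 2],
    p_value = s[term, "Pr(>|t|)"])
}

#' Univariable linear-regression screen
#'
#' Fits one simple linear regression of the outcome on each candidate
#' predictor and reports the coefficient, 95% CI and p-value; candidates
#' with p below `alpha` form the retained set that feeds the multivariable
#' stage. Constant predictors are skipped with a warning.
#'
#' @param data Data frame.
#' @param outcome Outcome column name (character).
#' @param predictors Character vector of candidate predictor columns.
#' @param alpha Retention threshold (default 0.05).
#' @return Tibble: `term`, `beta`, `conf_low`, `conf_high`, `p_value`,
#'   `retained`.
#' @export
univariable_screen <- function(data, outcome, predictors, alpha = 0.05) {
  stopifnot(outcome %in% names(data))
  if (!length(predictors)) {
    return(tibble::tibble(term = character(), beta = numeric(),
                          conf_low = numeric(), conf_high = numeric(),
                          p_value = numeric(), retained = logical()))
  }
  rows <- purrr::map(predictors, function(p) {
    x <- data[[p]]
    if (stats::sd(x, na.rm = TRUE) == 0) {
      warning(sprintf("predictor '%s' is constant; skipped", p), call. = FALSE)
      return(NULL)
    }
    fit <- stats::lm(stats::reformulate(p, outcome), data = data)
    lm_term_row(fit, p)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  out$retained <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Stepwise multivariable linear regression with diagnostics
#'
#' Bidirectional stepwise selection starting from the empty model using
#' p-value criteria: at each round the candidate with the smallest
#' coefficient p-value enters if it is `<= p_enter`, then any included term
#' whose p-value exceeds `p_remove` is removed (worst first). With
#' `criterion = "aic"` base [stats::step()] selection is used instead. The
#' final model is refit and reported with 95% CIs, the Durbin-Watson test,
#' and per-observation studentized residuals and Cook's distances;
#' observations with `|studentized residual| > 3` or `Cook's D > 0.5` are
#' flagged and a refit excluding them is reported alongside.
#'
#' @param data Data frame.
#' @param outcome Outcome column (character).
#' @param predictors Character vector of screened candidate predictors.
#' @param p_enter,p_remove Entry/removal p-value thresholds (0.05/0.10).
#' @param criterion `"p"` (default) or `"aic"`.
#' @param resid_threshold,cooks_threshold Influence flags (3 and 0.5).
#' @return An object of class `cmr_stepwise`: `selected`, `coefficients`
#'   (tibble), `fit` (the final `lm`), `durbin_watson` (statistic + p),
#'   `influence` (per-observation tibble with flags), `refit_excluding`
#'   (coefficients after dropping flagged points, or `NULL`).
#' @export
stepwise_multivariable <- function(data, outcome, predictors,
                                   p_enter = 0.05, p_remove = 0.10,
                                   criterion = c("p", "aic"),
                                   resid_threshold = 3, cooks_threshold = 0.5) {
  criterion <- match.arg(criterion)
  if (!length(predictors)) stop("no screened predictors supplied", call. = FALSE)
  predictors <- drop_collinear(data, predictors)

  if (criterion == "aic") {
    null_fit <- stats::lm(stats::reformulate("1", outcome), data = data)
    scope <- stats::reformulate(predictors)
    fit <- stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                       direction = "both", trace = 0)
    selected <- setdiff(names(stats::coef(fit)), "(Intercept)")
  } else {
    selected <- character(0)
    repeat {
      changed <- FALSE
      remaining <- setdiff(predictors, selected)
      if (length(remaining)) {
        entry <- purrr::map_dbl(remaining, function(cand) {
          f <- stats::lm(stats::reformulate(c(selected, cand), outcome), data = data)
          s <- summary(f)$coefficients
          if (!cand %in% rownames(s)) return(NA_real_)  # rank-deficient
          s[cand, "Pr(>|t|)"]
        })
        if (any(!is.na(entry)) && min(entry, na.rm = TRUE) <= p_enter) {
          selected <- c(selected, remaining[which.min(entry)])
          changed <- TRUE
        }
      }
      if (length(selected) > 1) {
        f <- stats::lm(stats::reformulate(selected, outcome), data = data)
        pv <- summary(f)$coefficients[selected, "Pr(>|t|)"]
        if (max(pv) > p_remove) {
          selected <- setdiff(selected, selected[which.max(pv)])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!length(selected)) {
      warning("no predictor met the entry criterion; returning intercept-only model",
              call. = FALSE)
    }
    fit <- stats::lm(stats::reformulate(if (length(selected)) selected else "1",
                                        outcome), data = data)
  }

  coefs <- if (length(selected)) {
    dplyr::bind_rows(purrr::map(selected, ~lm_term_row(fit, .x)))
  } else {
    tibble::tibble(term = character(), beta = numeric(), conf_low = numeric(),
                   conf_high = numeric(), p_value = numeric())
  }

  dw <- lmtest::dwtest(fit)
  infl <- tibble::tibble(
    observation = seq_len(stats::nobs(fit)),
    studentized_residual = unname(stats::rstudent(fit)),
    cooks_distance = unname(stats::cooks.distance(fit)))
  infl$flagged <- abs(infl$studentized_residual) > resid_threshold |
    infl$cooks_distance > cooks_threshold

  refit <- NULL
  if (any(infl$flagged) && length(selected)) {
    sub <- data[-infl$observation[infl$flagged], , drop = FALSE]
    f2 <- stats::lm(stats::reformulate(selected, outcome), data = sub)
    keep <- intersect(selected, rownames(summary(f2)$coefficients))
    refit <- dplyr::bind_rows(purrr::map(keep, ~lm_term_row(f2, .x)))
  }

  structure(list(outcome = outcome, selected = selected, coefficients = coefs,
                 fit = fit,
                 durbin_watson = list(statistic = unname(dw$statistic),
                                      p_value = dw$p.value),
                 influence = infl, refit_excluding = refit),
            class = "cmr_stepwise")
}

# Drop predictors that are exact duplicates/linear combinations of earlier
# ones (perfect collinearity), with a warning.
drop_collinear <- function(data, predictors) {
  x <- as.matrix(data[, predictors, drop = FALSE])
  keep <- character(0)
  for (p in predictors) {
    m <- cbind(1, x[, c(keep, p), drop = FALSE])
    if (qr(m)$rank == ncol(m)) {
      keep <- c(keep, p)
    } else {
      warning(sprintf("predictor '%s' is collinear with earlier predictors; dropped", p),
              call. = FALSE)
    }
  }
  keep
}

#' @export
print.cmr_stepwise <- function(x, ...) {
  cat(sprintf("<cmr_stepwise> outcome: %s; selected: %s\n", x$outcome,
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"))
  print(x$coefficients)
  cat(sprintf("Durbin-Watson %.3f (p = %.3f); %d flagged observation(s)\n",
              x$durbin_watson$statistic, x$durbin_watson$p_value,
              sum(x$influence$flagged)))
  invisible(x)
}
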