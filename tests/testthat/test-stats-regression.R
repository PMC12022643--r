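test_that("univariable screen recovers a strong linear predictor", {
  set.seed(1)
  n <- 100
  d <- tibble::tibble(x = stats::rnorm(n), noise = stats::rnorm(n))
  d$y <- 2 * d$x + stats::rnorm(n, 0, 0.01)
  res <- univariable_screen(d, "y", c("x", "noise"))
  expect_true(res$retained[res$term == "x"])
  expect_equal(res$beta[res$term == "x"], 2, tolerance = 0.01)
  expect_true(res$conf_low[res$term == "x"] <= 2 &
                res$conf_high[res$term == "x"] >= 2)
  expect_equal(nrow(univariable_screen(d, "y", character(0))), 0)
  d$flat <- 1
  expect_warning(res2 <- univariable_screen(d, "y", c("x", "flat")),
                 "constant")
  expect_false("flat" %in% res2$term)
})

test_that("stepwise selection recovers planted predictors among decoys", {
  set.seed(2)
  n <- 200
  x <- matrix(stats::rnorm(n * 7), n, 7,
              dimnames = list(NULL, paste0("x", 1:7)))
  d <- tibble::as_tibble(x)
  d$y <- 3 * d$x1 - 2 * d$x2 + stats::rnorm(n, 0, 0.5)
  fit <- stepwise_multivariable(d, "y", paste0("x", 1:7))
  expect_true(all(c("x1", "x2") %in% fit$selected))
  co <- fit$coefficients
  expect_equal(co$beta[co$term == "x1"], 3, tolerance = 0.1)
  expect_equal(co$beta[co$term == "x2"], -2, tolerance = 0.1)
  g <- generics::glance(fit)
  expect_gt(g$r_squared, 0.9)
})

test_that("Durbin-Watson statistic matches the definitional sum", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3.0)
  e <- c(0.3, -0.2, 0.5, 0.1, -0.4)
  expect_equal(durbin_watson(e), sum(diff(e)^2) / sum(e^2))
})

test_that("the fitted model carries a Durbin-Watson test p-value", {
  set.seed(3)
  d <- tibble::tibble(x = stats::rnorm(50))
  d$y <- d$x + stats::rnorm(50)
  fit <- stepwise_multivariable(d, "y", "x")
  expect_true(fit$durbin_watson$p_value >= 0 && fit$durbin_watson$p_value <= 1)
  expect_equal(fit$durbin_watson$statistic,
               durbin_watson(stats::residuals(fit$fit)), tolerance = 1e-10)
})

test_that("influence diagnostics flag outliers and spare on-line points", {
  set.seed(4)
  d <- tibble::tibble(x = c(seq(-2, 2, length.out = 40)))
  d$y <- d$x + stats::rnorm(40, 0, 0.1)
  d$y[40] <- d$y[40] + 5     # gross outlier
  fit <- stepwise_multivariable(d, "y", "x")
  expect_true(fit$influence$flagged[40])
  expect_false(any(fit$influence$flagged[1:39]))
  expect_false(is.null(fit$refit_excluding))
  # an average-leverage point near the fitted line has negligible Cook's D
  mid <- which.min(abs(d$x - stats::median(d$x)))
  expect_lt(fit$influence$cooks_distance[mid], 0.05)
})

test_that("perfectly collinear predictors are dropped with a warning", {
  set.seed(5)
  d <- tibble::tibble(x1 = stats::rnorm(60))
  d$x2 <- 2 * d$x1
  d$y <- d$x1 + stats::rnorm(60, 0, 0.1)
  expect_warning(fit <- stepwise_multivariable(d, "y", c("x1", "x2")),
                 "collinear")
  expect_identical(fit$selected, "x1")
})

test_that("AIC-based selection mode is available", {
  set.seed(6)
  n <- 150
  d <- tibble::tibble(x1 = stats::rnorm(n), x2 = stats::rnorm(n),
                      x3 = stats::rnorm(n))
  d$y <- 2 * d$x1 + stats::rnorm(n, 0, 0.3)
  fit <- stepwise_multivariable(d, "y", c("x1", "x2", "x3"),
                                criterion = "aic")
  expect_true("x1" %in% fit$selected)
})

test_that("weak candidate sets fall back to the intercept-only model", {
  set.seed(7)
  d <- tibble::tibble(x = stats::rnorm(40), y = stats::rnorm(40))
  expect_warning(fit <- stepwise_multivariable(d, "y", "x", p_enter = 1e-6),
                 "entry criterion")
  expect_length(fit$selected, 0)
})
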