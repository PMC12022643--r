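test_that("the paired-t branch matches the closed-form t statistic", {
  res <- paired_compare(pre = c(0, 0, 0), post = c(2, 3, 4), force = "t")
  expect_equal(res$statistic, 3 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$p_value, 2 * stats::pt(-3 * sqrt(3), df = 2),
               tolerance = 1e-10)
  expect_equal(res$test, "paired-t")
  # spec of the closed form: t = mean(d) / (sd(d)/sqrt(n))
  d <- c(1.2, -0.5, 2.2, 0.3, 1.1, 0.8)
  res2 <- paired_compare(pre = rep(0, 6), post = d, force = "t")
  expect_equal(res2$statistic, mean(d) / (stats::sd(d) / sqrt(6)),
               tolerance = 1e-12)
})

test_that("five concordant pairs give the classic exact signed-rank p", {
  res <- paired_compare(pre = rep(0, 5), post = c(1, 2, 3, 4, 5),
                        force = "wilcoxon")
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.0625)
})

test_that("identical timepoints degenerate to p = 1", {
  expect_warning(res <- paired_compare(pre = c(1, 2, 3), post = c(1, 2, 3)),
                 "zero")
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("exact signed-rank p equals full 2^n enumeration", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    d <- round(stats::rnorm(n, 0.3, 1), sample(c(0, 1), 1))
    d <- d[d != 0]
    if (length(d) < 3) next
    ours <- wilcoxon_signed_rank(d)
    expect_equal(ours$p_value, enumerate_wilcoxon_p(d), tolerance = 1e-10)
  }
})

test_that("tie-free exact p agrees with the reference implementation", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    d <- stats::rnorm(n, 0.4, 1)  # continuous: no ties, no zeros
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("large-sample branch approximates the exact p", {
  set.seed(9)
  d <- stats::rnorm(40, 0.3, 1)
  approx <- wilcoxon_signed_rank(d)           # n > 25: normal approximation
  exact <- wilcoxon_signed_rank(d, exact_limit = 50)
  expect_equal(approx$method, "normal")
  expect_lt(abs(approx$p_value - exact$p_value), 0.01)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_alpha(0.05, 20), 0.0025)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.10, 4), 0.025)
})

test_that("the normality gate routes Gaussian and skewed differences", {
  set.seed(10)
  gauss <- stats::rnorm(30)
  res_g <- paired_compare(pre = rep(0, 30), post = gauss + 1)
  expect_equal(res_g$test, "paired-t")
  skew <- stats::rexp(30)^3
  res_s <- paired_compare(pre = rep(0, 30), post = skew)
  expect_equal(res_s$test, "wilcoxon-signed-rank")
})

test_that("type-I error of the gated test is near nominal on Gaussian nulls", {
  set.seed(11)
  reject <- vapply(1:500, function(i) {
    d <- stats::rnorm(20)
    paired_compare(pre = rep(0, 20), post = d, alpha = 0.05, m = 1)$significant
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.085)
})

test_that("Pearson correlations match the definitional formula", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(2, 1, 3))
  cm <- correlation_matrix(d)
  expect_equal(cm$r["x", "y"], 0.5)
  expect_equal(cm$r["x", "y"], pearson_r_oracle(d$x, d$y))
  d2 <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10))
  cm2 <- correlation_matrix(d2)
  expect_equal(cm2$r["x", "y"], 1)
  expect_equal(cm2$r["x", "z"], -1)
  expect_true(all(diag(cm2$r) == 1))
  expect_equal(cm2$r, t(cm2$r))
  # zero-variance column: undefined, reported missing
  d3 <- tibble::tibble(x = 1:5, c = rep(3, 5))
  expect_true(is.na(correlation_matrix(d3)$r["x", "c"]))
  td <- generics::tidy(cm2)
  expect_equal(nrow(td), 9)
})
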