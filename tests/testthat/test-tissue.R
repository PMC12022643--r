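test_that("the 6-SD threshold uses mean + 6 sample SDs, strict inequality", {
  img <- matrix(c(98, 100, 102, 100, 100, 110, 108, 90), 1, 8)
  band <- matrix(TRUE, 1, 8)
  roi_mask <- matrix(c(rep(TRUE, 5), rep(FALSE, 3)), 1, 8)
  roi <- suppressWarnings(reference_roi(img, roi_mask, band))
  expect_equal(roi$mean, 100)
  expect_equal(roi$sd, sqrt(2))
  # threshold 100 + 6*sqrt(2) = 108.485...
  mask <- lge_threshold(img, band, roi)
  expect_true(mask[1, 6])    # 110 enhanced
  expect_false(mask[1, 7])   # 108 not
  expect_false(any(mask[1, 1:5]))
})

test_that("a constant reference region degenerates to a strict mean threshold", {
  img <- matrix(c(rep(100, 6), 100.001, 99.9), 1, 8)
  band <- matrix(TRUE, 1, 8)
  roi_mask <- matrix(c(rep(TRUE, 6), FALSE, FALSE), 1, 8)
  roi <- suppressWarnings(reference_roi(img, roi_mask))
  expect_equal(roi$sd, 0)
  mask <- lge_threshold(img, band, roi)
  expect_identical(which(mask), 7L)
})

test_that("reference ROI validation catches degenerate and misplaced ROIs", {
  img <- matrix(100, 2, 10)
  expect_error(reference_roi(img, matrix(c(TRUE, rep(FALSE, 19)), 2, 10)),
               "at least 2")
  band <- matrix(FALSE, 2, 10)
  roi_mask <- matrix(c(rep(TRUE, 4), rep(FALSE, 16)), 2, 10)
  expect_error(reference_roi(img, roi_mask, band), "outside")
  expect_warning(reference_roi(img, roi_mask), "20 voxels")
})

test_that("LGE volume, mass and percent follow the voxel bookkeeping", {
  band <- matrix(TRUE, 10, 40)            # 400 voxels
  lge <- matrix(FALSE, 10, 40); lge[1:10, 1:10] <- TRUE   # 100 voxels
  res <- lge_quantify(lge, band, voxel_spacing = 1, slice_thickness = 8)
  expect_equal(res$lge_volume, 0.8)       # 100 * 8 mm3 = 0.8 mL
  expect_equal(res$lge_mass, 0.84)        # x 1.05 g/mL
  expect_equal(res$lge_percent, 25)

  empty <- lge_quantify(matrix(FALSE, 10, 40), band, 1, 8)
  expect_equal(empty$lge_mass, 0)
  expect_equal(empty$lge_percent, 0)

  full <- lge_quantify(band, band, 1, 8)
  expect_equal(full$lge_percent, 100)
  expect_error(lge_quantify(lge, matrix(FALSE, 10, 40), 1, 8), "empty")
})

test_that("ECV formula matches hand arithmetic and its limits", {
  expect_equal(ecv_from_t1(1300, 600, 1900, 400, 0.40), 0.2728,
               tolerance = 5e-4)
  # myocardium behaving like blood: partition coefficient 1, ECV = 1 - Hct
  expect_equal(ecv_from_t1(1000, 500, 1000, 500, 0.40), 0.600)
  # hematocrit -> 1 drives ECV -> 0
  expect_lt(ecv_from_t1(1300, 600, 1900, 400, 0.999), 0.001)
  # percentage hematocrit is normalized
  expect_equal(ecv_from_t1(1300, 600, 1900, 400, 40),
               ecv_from_t1(1300, 600, 1900, 400, 0.40))
  expect_error(ecv_from_t1(1300, 600, 1900, 1900, 0.4), "contrast")
  expect_error(ecv_from_t1(600, 1300, 1900, 400, 0.4), "non-physical")
  expect_error(ecv_from_t1(-1, 600, 1900, 400, 0.4), "positive")
})

test_that("ECV is strictly decreasing in hematocrit and scale invariant", {
  hcts <- seq(0.1, 0.9, by = 0.1)
  vals <- ecv_from_t1(1300, 600, 1900, 400, hcts)
  expect_true(all(diff(vals) < 0))
  # scaling all T1s by a common factor scales both delta-R1 terms equally
  expect_equal(ecv_from_t1(1300, 600, 1900, 400, 0.4),
               ecv_from_t1(2 * 1300, 2 * 600, 2 * 1900, 2 * 400, 0.4))
})

test_that("global ECV is the area-weighted mean over LGE-free segments", {
  expect_equal(global_ecv(c(0.25, 0.35), c(300, 100), c(1, 2))$value, 0.275)
  g <- global_ecv(rep(0.282, 16), runif(16, 50, 300), 1:16,
                  segments_with_lge = c(2, 3, 8, 9))
  expect_equal(g$value, 0.282)
  expect_false(any(c(2, 3, 8, 9) %in% g$included_segments))

  vals <- c(0.2, 0.3, 0.9, 0.9)
  g2 <- global_ecv(vals, c(100, 100, 100, 100), 1:4,
                   segments_with_lge = c(3, 4))
  expect_equal(g2$value, 0.25)
  expect_error(global_ecv(vals, rep(100, 4), 1:4, 1:4), "excluded")
})

test_that("the 6-SD mask equals the brute-force voxel comparison", {
  set.seed(42)
  for (i in 1:100) {
    d <- c(sample(4:9, 1), sample(4:9, 1))
    img <- matrix(rnorm(prod(d), 100, 10), d[1], d[2])
    band <- matrix(runif(prod(d)) < 0.7, d[1], d[2])
    roi_vals <- rnorm(sample(5:30, 1), 100, 5)
    roi <- list(n = length(roi_vals), mean = mean(roi_vals),
                sd = stats::sd(roi_vals))
    class(roi) <- "reference_roi"
    expect_identical(lge_threshold(img, band, roi),
                     brute_force_lge(img, band, roi_vals))
  }
})

test_that("per-segment LGE presence honours the minimum-fraction rule", {
  seg <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 2, 4)
  lge <- matrix(c(TRUE, FALSE, FALSE, FALSE, rep(FALSE, 4)), 2, 4)
  expect_identical(segments_with_lge(lge, seg), 1L)
  expect_identical(segments_with_lge(lge, seg, min_fraction = 0.5), integer(0))
  expect_identical(segments_with_lge(lge, seg, min_fraction = 0.25), 1L)
})
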