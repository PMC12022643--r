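test_that("myocardial band reproduces the analytic annulus area", {
  ct <- annulus_contours(20, 30)
  band <- myocardial_band(ct)
  analytic <- pi * (30^2 - 20^2)
  # rasterization error scales with the combined contour perimeter
  expect_lt(abs(sum(band) - analytic), 0.02 * analytic)
})

test_that("band follows set semantics and rejects degenerate contours", {
  ct <- annulus_contours(20, 30)
  expect_identical(myocardial_band(ct), ct$epi_mask & !ct$endo_mask)
  same <- annulus_contours(20, 20.4)
  same$endo_mask <- same$epi_mask
  expect_error(myocardial_band(same), "empty")

  # translated endo disc: band is still epi minus endo
  ct2 <- annulus_contours(12, 20, endo_offset = c(6, 0))
  band2 <- myocardial_band(ct2)
  expect_identical(band2, ct2$epi_mask & !ct2$endo_mask)
  expect_equal(sum(band2), sum(ct2$epi_mask) - sum(ct2$epi_mask & ct2$endo_mask))
})

test_that("10% radial offset retains the analytic core ring", {
  ct <- annulus_contours(20, 30)
  band <- myocardial_band(ct)
  core <- radial_offset(band, ct, 0.10)
  rr <- mask_radii(core)
  expect_gt(min(rr), 21 - 0.5)
  expect_lt(max(rr), 29 + 0.5)
  # zero offset is the identity
  expect_identical(radial_offset(band, ct, 0), band)
})

test_that("near-limit offset keeps a central voxel on every ray", {
  ct <- annulus_contours(20, 30)
  band <- myocardial_band(ct)
  core <- radial_offset(band, ct, 0.49)
  expect_true(any(core))
  rr <- mask_radii(core)
  expect_true(all(rr > 23.5 & rr < 26.5))
})

test_that("offset bands are nested as the fraction grows", {
  ct <- annulus_contours(18, 31)
  band <- myocardial_band(ct)
  prev <- band
  for (f in c(0.05, 0.1, 0.2, 0.3, 0.45)) {
    cur <- radial_offset(band, ct, f)
    expect_true(all(!cur | prev))  # cur subset of prev
    prev <- cur
  }
})

test_that("thin walls trigger a warning but keep one voxel per ray", {
  ct <- annulus_contours(20, 22)
  band <- myocardial_band(ct)
  expect_warning(core <- radial_offset(band, ct, 0.10), "thinner")
  expect_true(any(core))
})

test_that("basal and mid slices get six near-equal sectors, apical four", {
  for (lv in c("basal", "mid")) {
    ct <- annulus_contours(20, 30, level = lv)
    model <- assign_segments(myocardial_band(ct), ct)
    expected <- if (lv == "basal") 1:6 else 7:12
    expect_setequal(model$segment_area$segment, expected)
    areas <- model$segment_area$area_mm2
    expect_lt((max(areas) - min(areas)) / mean(areas), 0.02)
  }
  ct <- annulus_contours(14, 23, level = "apical")
  model <- assign_segments(myocardial_band(ct), ct)
  expect_setequal(model$segment_area$segment, 13:16)
})

test_that("segment labels partition the band exactly", {
  ct <- annulus_contours(20, 30, level = "basal")
  band <- myocardial_band(ct)
  core <- radial_offset(band, ct, 0.10)
  model <- assign_segments(core, ct)
  expect_identical(model$segment_map > 0, core)
  expect_identical(sum(model$segment_area$n_voxels), sum(core))
})

test_that("a voxel on the anterior-insertion ray starts segment 1", {
  grid <- 61
  ctr <- 30
  g <- expand.grid(row = seq_len(grid) - 1, col = seq_len(grid) - 1)
  r <- sqrt((g$row - ctr)^2 + (g$col - ctr)^2)
  endo <- matrix(r <= 10, grid, grid)
  epi <- matrix(r <= 20, grid, grid)
  ct <- slice_contours(endo, epi, rv_insertion_anterior = c(ctr + 20, ctr),
                       rv_insertion_inferior = NULL, level = "basal")
  model <- assign_segments(myocardial_band(ct), ct)
  # voxel straight along the insertion ray (sweep angle exactly 0)
  expect_equal(model$segment_map[ctr + 1 + 15, ctr + 1], 1L)
})

test_that("segment assignment is equivariant under a 90-degree rotation", {
  ct <- annulus_contours(18, 29, level = "basal",
                         anterior = c((96 - 1) / 2 + 29 * cos(2.2),
                                      (96 - 1) / 2 + 29 * sin(2.2)))
  model <- assign_segments(myocardial_band(ct), ct)
  rot <- function(m) t(m)[, rev(seq_len(nrow(m)))]   # 90 deg rotation
  rot_pt <- function(p, n = 96) c(p[2], n - 1 - p[1])
  ct2 <- slice_contours(rot(ct$endo_mask), rot(ct$epi_mask),
                        rot_pt(ct$rv_insertion_anterior),
                        rot_pt(ct$rv_insertion_inferior), level = "basal")
  model2 <- assign_segments(myocardial_band(ct2), ct2)
  a1 <- model$segment_area[order(model$segment_area$segment), ]
  a2 <- model2$segment_area[order(model2$segment_area$segment), ]
  expect_equal(a1$segment, a2$segment)
  expect_true(all(abs(a1$n_voxels - a2$n_voxels) <=
                    pmax(2, 0.02 * a1$n_voxels)))
})

test_that("segment statistics average per segment and flag empty segments", {
  ct <- annulus_contours(20, 30, level = "mid")
  model <- assign_segments(myocardial_band(ct), ct)
  const <- matrix(1300, 96, 96)
  st <- segment_stats(const, model)
  expect_true(all(st$mean == 1300))

  toy <- structure(list(
    segment_map = matrix(c(1L, 1L, 2L), 1, 3),
    segment_area = tibble::tibble(segment = c(1L, 2L, 3L), level = "mid",
                                  n_voxels = c(2L, 1L, 0L),
                                  area_mm2 = c(2, 1, 0)),
    vox_area_mm2 = 1), class = "segment_model")
  vals <- matrix(c(1, 3, 5), 1, 3)
  st2 <- segment_stats(vals, toy)
  expect_equal(st2$mean[st2$segment == 1], 2)
  expect_equal(st2$mean[st2$segment == 2], 5)
  expect_equal(st2$area_mm2[1:2], c(2, 1))
  expect_true(is.na(st2$mean[st2$segment == 3]))
  expect_error(segment_stats(matrix(0, 2, 2), toy), "dimensions")
})

test_that("segmentation needs the anterior insertion and an interior centroid", {
  ct <- annulus_contours(20, 30)
  ct$rv_insertion_anterior <- NULL
  expect_error(assign_segments(myocardial_band(ct), ct), "anterior")
})
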