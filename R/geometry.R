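#' Per-slice short-axis contours
#'
#' Bundles the binary endocardial and epicardial rasters for one short-axis
#' slice together with the right-ventricular (RV) insertion points, the AHA
#' level of the slice, and the voxel geometry. Masks are logical matrices in
#' which `TRUE` marks voxels inside the respective contour: `endo_mask` is the
#' cavity disc, `epi_mask` the full disc out to the epicardium, so the
#' myocardium is their set difference.
#'
#' @param endo_mask,epi_mask Logical matrices of identical dimension;
#'   `endo_mask` must be a subset of `epi_mask`.
#' @param rv_insertion_anterior,rv_insertion_inferior In-plane voxel
#'   coordinates `c(row, col)` (0-based, voxel centers) of the anterior and
#'   inferior RV insertion points; the inferior point may be `NULL` on apical
#'   slices.
#' @param level One of `"basal"`, `"mid"`, `"apical"`.
#' @param voxel_spacing In-plane voxel size, mm.
#' @param slice_thickness Slice thickness, mm.
#' @return An object of class `slice_contours`.
#' @export
slice_contours <- function(endo_mask, epi_mask,
                           rv_insertion_anterior = NULL,
                           rv_insertion_inferior = NULL,
                           level = c("mid", "basal", "apical"),
                           voxel_spacing = 1,
                           slice_thickness = 8) {
  level <- match.arg(level)
  stopifnot(is.matrix(endo_mask), is.matrix(epi_mask),
            all(dim(endo_mask) == dim(epi_mask)))
  endo_mask <- endo_mask > 0
  epi_mask <- epi_mask > 0
  if (any(endo_mask & !epi_mask)) {
    stop("endocardial mask must be contained in the epicardial mask", call. = FALSE)
  }
  structure(
    list(endo_mask = endo_mask, epi_mask = epi_mask,
         rv_insertion_anterior = rv_insertion_anterior,
         rv_insertion_inferior = rv_insertion_inferior,
         level = level, voxel_spacing = voxel_spacing,
         slice_thickness = slice_thickness),
    class = "slice_contours")
}

# Voxel-center coordinate grids (0-based indices) for a matrix of given dim.
voxel_grid <- function(d) {
  list(row = matrix(rep(seq_len(d[1]) - 1L, d[2]), d[1], d[2]),
       col = matrix(rep(seq_len(d[2]) - 1L, each = d[1]), d[1], d[2]))
}

# Centroid of a mask in 0-based voxel coordinates.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot take the centroid of an empty mask", call. = FALSE)
  c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
}

# Polar coordinates (radius mm, angle deg in [0, 360)) of every voxel center
# about `center` (0-based voxel coords).
slice_polar <- function(d, center, spacing) {
  g <- voxel_grid(d)
  dr <- g$row - center[1]
  dc <- g$col - center[2]
  list(radius = sqrt(dr^2 + dc^2) * spacing,
       theta = (atan2(dc, dr) * 180 / pi) %% 360)
}

# Edge radius of `mask` along each of 360 1-degree rays from `center`: the
# largest voxel-center radius among mask voxels within a small angular
# window of the ray, plus a quarter-voxel bias correction (voxel centers sit
# strictly inside the contour, so the estimate can never overshoot the true
# edge by more than the correction). The window widens adaptively at small
# radii where a 1-degree sector is narrower than a voxel. Rays that never
# enter the mask are filled from the nearest populated ray (circular).
edge_radius_by_ray <- function(mask, center, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(rep(NA_real_, 360))
  dr <- idx[, 1] - 1 - center[1]
  dc <- idx[, 2] - 1 - center[2]
  rad <- sqrt(dr^2 + dc^2) * spacing
  th <- (atan2(dc, dr) * 180 / pi) %% 360
  bin <- floor(th) %% 360
  M <- rep(NA_real_, 360)
  mx <- tapply(rad, bin, max)
  M[as.integer(names(mx)) + 1L] <- as.numeric(mx)

  win_max <- function(i, w) {
    v <- M[((i - w - 1):(i + w - 1)) %% 360 + 1]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }
  r <- vapply(seq_len(360), function(i) {
    r0 <- if (is.na(M[i])) win_max(i, 3) else M[i]
    if (is.na(r0) || r0 == 0) return(win_max(i, 3))
    w <- ceiling(min(8, max(2, atan2(1.2 * spacing, r0) * 180 / pi)))
    win_max(i, w)
  }, numeric(1))

  if (anyNA(r)) {
    filled <- which(!is.na(r))
    if (!length(filled)) return(r)
    for (i in which(is.na(r))) {
      dist <- pmin(abs(filled - i), 360 - abs(filled - i))
      r[i] <- r[filled[which.min(dist)]]
    }
  }
  r + 0.25 * spacing
}

#' Myocardial band of a slice
#'
#' The myocardium is the set difference between the epicardial and
#' endocardial rasters.
#'
#' @param contours A [slice_contours()] object.
#' @return Logical matrix: `epi_mask & !endo_mask`.
#' @export
myocardial_band <- function(contours) {
  stopifnot(inherits(contours, "slice_contours"))
  band <- contours$epi_mask & !contours$endo_mask
  if (!any(band)) {
    stop("degenerate contours: the myocardial band is empty", call. = FALSE)
  }
  band
}

#' Radial offset of the myocardial band
#'
#' Shrinks the band away from both contours to reduce partial-volume
#' contamination: along each 1-degree ray from the cavity centroid, voxels
#' within `fraction` of the local wall thickness from either the endocardial
#' or the epicardial edge are removed. A 10% offset is the conventional
#' default for T1/ECV measurement.
#'
#' @param band Logical matrix, typically from [myocardial_band()].
#' @param contours The [slice_contours()] the band came from.
#' @param fraction Offset as a fraction of local wall thickness, in
#'   `[0, 0.5)`; `0` returns the band unchanged.
#' @return Logical matrix, the retained core band. Rays whose wall is thinner
#'   than 3 voxels keep their single most central voxel (with a warning).
#' @export
radial_offset <- function(band, contours, fraction = 0.10) {
  stopifnot(inherits(contours, "slice_contours"),
            is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction < 0.5)
  if (!any(band)) stop("cannot offset an empty band", call. = FALSE)
  if (fraction == 0) return(band)

  sp <- contours$voxel_spacing
  center <- mask_centroid(contours$endo_mask)
  polar <- slice_polar(dim(band), center, sp)
  r_in <- edge_radius_by_ray(contours$endo_mask, center, sp)
  r_out <- edge_radius_by_ray(contours$epi_mask, center, sp)
  wall <- pmax(r_out - r_in, 0)
  if (any(wall < 3 * sp, na.rm = TRUE)) {
    warning("wall thinner than 3 voxels on some rays; keeping their central voxel",
            call. = FALSE)
  }

  idx <- which(band)
  bin <- floor(polar$theta[idx]) %% 360 + 1L
  rad <- polar$radius[idx]
  lo <- r_in[bin] + fraction * wall[bin]
  hi <- r_out[bin] - fraction * wall[bin]
  keep <- rad >= lo & rad <= hi

  # Rays whose retained window is thinner than one voxel (near-limit offsets
  # or very thin walls) keep their single most central voxel instead of
  # vanishing.
  width <- r_out - r_in - 2 * fraction * wall
  thin <- which(width < sp)
  kept_bins <- unique(bin[keep])
  for (b in setdiff(intersect(thin, unique(bin)), kept_bins)) {
    in_bin <- which(bin == b)
    mid <- (r_in[b] + r_out[b]) / 2
    cand <- in_bin[which.min(abs(rad[in_bin] - mid))]
    if (abs(rad[cand] - mid) <= 0.75 * sp) keep[cand] <- TRUE
  }

  out <- matrix(FALSE, nrow(band), ncol(band))
  out[idx[keep]] <- TRUE
  out
}

# AHA label lookup: sector index (1-based, counted from the anterior RV
# insertion sweeping through the free wall) -> segment label, per level.
aha_labels <- function(level) {
  switch(level,
         basal = c(1L, 6L, 5L, 4L, 3L, 2L),
         mid = c(7L, 12L, 11L, 10L, 9L, 8L),
         apical = c(13L, 16L, 15L, 14L))
}

# Sweep angle (deg in [0,360)) of `theta` given the anterior-insertion angle
# and sweep direction (+1 counterclockwise in array coordinates).
sweep_angle <- function(theta, theta_anterior, dir) {
  (dir * (theta - theta_anterior)) %% 360
}

#' Assign AHA segments to the myocardial band of one slice
#'
#' Partitions band voxels into AHA 16-segment-model sectors by angle about
#' the cavity centroid. Angles start at the anterior RV insertion point and
#' sweep through the LV free wall: basal/mid slices get six 60-degree sectors
#' (anterior, anterolateral, inferolateral, inferior, inferoseptal,
#' anteroseptal), apical slices four 90-degree sectors (anterior, lateral,
#' inferior, septal). A voxel exactly on a sector boundary belongs to the
#' sector that starts there.
#'
#' @param band Logical matrix of band voxels to label.
#' @param contours A [slice_contours()]; the anterior insertion point is
#'   required, the inferior one fixes the sweep direction (it must fall in the
#'   inferior half of the sweep). Without it, a counterclockwise sweep is
#'   assumed.
#' @return A `segment_model` list: `segment_map` (integer matrix, 0 outside
#'   the band), `segment_area` (tibble with `segment`, `level`, `n_voxels`,
#'   `area_mm2`), `level`.
#' @export
assign_segments <- function(band, contours) {
  stopifnot(inherits(contours, "slice_contours"))
  if (!any(band)) stop("cannot segment an empty band", call. = FALSE)
  ant <- contours$rv_insertion_anterior
  if (is.null(ant)) stop("anterior RV insertion point is required", call. = FALSE)
  center <- mask_centroid(contours$endo_mask)
  r0 <- round(center[1]) + 1L
  c0 <- round(center[2]) + 1L
  if (r0 < 1 || c0 < 1 || r0 > nrow(band) || c0 > ncol(band) ||
      !contours$endo_mask[r0, c0]) {
    stop("cavity centroid falls outside the endocardial mask", call. = FALSE)
  }

  theta_ant <- (atan2(ant[2] - center[2], ant[1] - center[1]) * 180 / pi) %% 360
  dir <- 1
  inf <- contours$rv_insertion_inferior
  if (!is.null(inf)) {
    theta_inf <- (atan2(inf[2] - center[2], inf[1] - center[1]) * 180 / pi) %% 360
    # pick the direction placing the inferior insertion near 240 deg of sweep
    cand <- vapply(c(1, -1), function(d) {
      s <- sweep_angle(theta_inf, theta_ant, d)
      min(abs(s - 240), 360 - abs(s - 240))
    }, numeric(1))
    dir <- c(1, -1)[which.min(cand)]
  }

  polar <- slice_polar(dim(band), center, contours$voxel_spacing)
  labels <- aha_labels(contours$level)
  width <- 360 / length(labels)
  idx <- which(band)
  sw <- sweep_angle(polar$theta[idx], theta_ant, dir)
  sector <- pmin(floor(sw / width) + 1L, length(labels))
  seg <- labels[sector]

  segment_map <- matrix(0L, nrow(band), ncol(band))
  segment_map[idx] <- seg
  counts <- table(factor(seg, levels = sort(labels)))
  area <- tibble::tibble(
    segment = as.integer(names(counts)),
    level = contours$level,
    n_voxels = as.integer(counts),
    area_mm2 = as.integer(counts) * contours$voxel_spacing^2)
  structure(list(segment_map = segment_map, segment_area = area,
                 level = contours$level, sweep_dir = dir,
                 theta_anterior = theta_ant,
                 vox_area_mm2 = contours$voxel_spacing^2),
            class = "segment_model")
}

#' Per-segment summary of a voxel map
#'
#' Arithmetic mean of voxel values within each segment of a segment model,
#' with the segment area. Segments that ended up empty (e.g. after the radial
#' offset) are reported with `NA` mean, never zero.
#'
#' @param values_map Numeric matrix aligned with the model's `segment_map`.
#' @param model A `segment_model` from [assign_segments()].
#' @return Tibble with `segment`, `mean`, `n_voxels`, `area_mm2`.
#' @export
segment_stats <- function(values_map, model) {
  stopifnot(inherits(model, "segment_model"))
  if (!all(dim(values_map) == dim(model$segment_map))) {
    stop("values map and segment map have different dimensions", call. = FALSE)
  }
  labs <- sort(unique(model$segment_area$segment))
  idx <- which(model$segment_map > 0)
  seg <- model$segment_map[idx]
  vals <- values_map[idx]
  means <- tapply(vals, factor(seg, levels = labs), mean)
  counts <- tapply(vals, factor(seg, levels = labs), length)
  counts[is.na(counts)] <- 0L
  vox_area <- model$vox_area_mm2
  tibble::tibble(
    segment = labs,
    mean = as.numeric(means),
    n_voxels = as.integer(counts),
    area_mm2 = as.integer(counts) * vox_area)
}

#' Build per-slice contours from a label-map stack
#'
#' Converts the integer label maps of a subject bundle (0 background, 1 blood
#' pool, 2 myocardium, 3 reference ROI) into a list of [slice_contours()].
#'
#' @param labels 3D integer array `[row, col, slice]`.
#' @param insertions Tibble with columns `slice`, `anterior_row`,
#'   `anterior_col`, `inferior_row`, `inferior_col` (0-based voxel coords).
#' @param levels Character vector of per-slice AHA levels.
#' @param voxel_spacing,slice_thickness Voxel geometry, mm.
#' @return List of `slice_contours`, ordered base to apex.
#' @export
contours_from_labels <- function(labels, insertions, levels,
                                 voxel_spacing = 1, slice_thickness = 8) {
  n <- dim(labels)[3]
  stopifnot(length(levels) == n)
  lapply(seq_len(n), function(s) {
    sl <- labels[, , s]
    ins <- insertions[insertions$slice == s, , drop = FALSE]
    ant <- if (nrow(ins)) c(ins$anterior_row[1], ins$anterior_col[1]) else NULL
    inf <- if (nrow(ins) && !is.na(ins$inferior_row[1])) {
      c(ins$inferior_row[1], ins$inferior_col[1])
    } else NULL
    slice_contours(endo_mask = sl == 1L,
                   epi_mask = sl >= 1L,
                   rv_insertion_anterior = ant,
                   rv_insertion_inferior = inf,
                   level = levels[s],
                   voxel_spacing = voxel_spacing,
                   slice_thickness = slice_thickness)
  })
}
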