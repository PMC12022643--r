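#' Reference-region statistics for LGE thresholding
#'
#' Summarizes the remote (non-enhanced) myocardial reference region of
#' interest on the LGE image: its mean and sample standard deviation set the
#' enhancement threshold.
#'
#' @param lge_image Numeric matrix or 3D array of LGE signal intensity.
#' @param roi_mask Logical mask of reference-ROI voxels, same dimension.
#' @param band Optional logical mask of the myocardial band; if given, every
#'   ROI voxel must lie inside it.
#' @return A `reference_roi` list: `n`, `mean`, `sd` (n-1 denominator).
#' @export
reference_roi <- function(lge_image, roi_mask, band = NULL) {
  stopifnot(all(dim(lge_image) == dim(roi_mask)))
  roi_mask <- roi_mask > 0
  if (!is.null(band) && any(roi_mask & !(band > 0))) {
    stop("reference ROI extends outside the myocardial band", call. = FALSE)
  }
  v <- lge_image[roi_mask]
  if (length(v) < 2) {
    stop("reference ROI needs at least 2 voxels for a standard deviation",
         call. = FALSE)
  }
  if (length(v) < 20) {
    warning("reference ROI has fewer than 20 voxels; threshold may be unstable",
            call. = FALSE)
  }
  structure(list(n = length(v), mean = mean(v), sd = stats::sd(v)),
            class = "reference_roi")
}

#' Threshold late gadolinium enhancement at k standard deviations
#'
#' Marks band voxels whose LGE intensity is strictly greater than the
#' reference-region mean plus `k` sample standard deviations; `k = 6` is the
#' conventional threshold for focal fibrosis.
#'
#' @param lge_image Numeric matrix/array of LGE intensity.
#' @param band Logical myocardial-band mask, same dimension.
#' @param roi A [reference_roi()] object.
#' @param k SD multiplier (default 6).
#' @return Logical mask of enhanced voxels within the band.
#' @export
lge_threshold <- function(lge_image, band, roi, k = 6) {
  stopifnot(inherits(roi, "reference_roi"), all(dim(lge_image) == dim(band)))
  (band > 0) & (lge_image > roi$mean + k * roi$sd)
}

#' Quantify an LGE mask
#'
#' @param lge_mask Logical mask of enhanced voxels.
#' @param band Logical myocardial-band mask (nonempty).
#' @param voxel_spacing In-plane voxel size, mm.
#' @param slice_thickness Slice thickness, mm.
#' @param density Myocardial density, g/mL (default 1.05).
#' @param segment_map Optional integer segment-label array aligned with the
#'   masks, used to report which AHA segments contain enhancement.
#' @param min_fraction Minimum enhanced fraction of a segment's band voxels
#'   for the segment to count as LGE-positive (default 0: any voxel).
#' @return One-row tibble: `lge_volume` (mL), `lge_mass` (g), `lge_percent`
#'   (% of myocardial volume), and `segments_with_lge` (list column of
#'   labels).
#' @export
lge_quantify <- function(lge_mask, band, voxel_spacing, slice_thickness,
                         density = MYO_DENSITY, segment_map = NULL,
                         min_fraction = 0) {
  band <- band > 0
  if (!any(band)) stop("empty myocardial band", call. = FALSE)
  lge_mask <- (lge_mask > 0) & band
  vox_ml <- voxel_spacing^2 * slice_thickness / 1000
  vol <- sum(lge_mask) * vox_ml
  band_vol <- sum(band) * vox_ml
  segs <- integer(0)
  if (!is.null(segment_map)) {
    segs <- segments_with_lge(lge_mask, segment_map, min_fraction)
  }
  tibble::tibble(
    lge_volume = vol,
    lge_mass = vol * density,
    lge_percent = 100 * vol / band_vol,
    segments_with_lge = list(segs))
}

#' AHA segments containing enhancement
#'
#' @param lge_mask Logical enhanced-voxel mask.
#' @param segment_map Integer segment-label array (0 outside the band).
#' @param min_fraction A segment is LGE-positive when the enhanced fraction
#'   of its labeled voxels exceeds this value (0 means any enhanced voxel).
#' @return Sorted integer vector of segment labels.
#' @export
segments_with_lge <- function(lge_mask, segment_map, min_fraction = 0) {
  stopifnot(all(dim(lge_mask) == dim(segment_map)))
  labs <- sort(unique(segment_map[segment_map > 0]))
  if (!length(labs)) return(integer(0))
  hit <- vapply(labs, function(l) {
    in_seg <- segment_map == l
    frac <- sum(lge_mask & in_seg) / sum(in_seg)
    if (min_fraction <= 0) frac > 0 else frac >= min_fraction
  }, logical(1))
  as.integer(labs[hit])
}

#' Extracellular volume fraction from T1 relaxation times
#'
#' Computes ECV from native and post-contrast T1 of myocardium and blood and
#' the hematocrit:
#' `ECV = (1 - Hct) * (1/T1_myo_post - 1/T1_myo_native) /
#'        (1/T1_blood_post - 1/T1_blood_native)`.
#'
#' @param t1_myo_native,t1_myo_post,t1_blood_native,t1_blood_post T1, ms
#'   (all positive); vectors are recycled elementwise.
#' @param hematocrit Fraction in (0, 1); values > 1 are treated as
#'   percentages and divided by 100.
#' @return ECV as a fraction.
#' @export
ecv_from_t1 <- function(t1_myo_native, t1_myo_post,
                        t1_blood_native, t1_blood_post, hematocrit) {
  if (any(c(t1_myo_native, t1_myo_post, t1_blood_native, t1_blood_post) <= 0)) {
    stop("all T1 values must be positive", call. = FALSE)
  }
  hematocrit <- ifelse(hematocrit > 1, hematocrit / 100, hematocrit)
  if (any(hematocrit <= 0 | hematocrit >= 1)) {
    stop("hematocrit must lie strictly between 0 and 1", call. = FALSE)
  }
  dr1_myo <- 1 / t1_myo_post - 1 / t1_myo_native
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_native
  if (any(dr1_blood == 0)) {
    stop("blood delta-R1 is zero: no contrast effect", call. = FALSE)
  }
  ecv <- (1 - hematocrit) * dr1_myo / dr1_blood
  if (any(ecv < 0)) {
    stop("non-physical ECV: myocardial post-contrast T1 exceeds native T1",
         call. = FALSE)
  }
  ecv
}

#' Area-weighted global value over LGE-free segments
#'
#' Global ECV (and, with the same contract, global native T1) is the
#' area-weighted mean over segments, excluding segments that contain LGE.
#'
#' @param segment_values Numeric per-segment values (NA allowed for empty
#'   segments; they are dropped).
#' @param segment_area Matching per-segment areas (mm2).
#' @param segment_labels Segment labels matching `segment_values`.
#' @param segments_with_lge Labels to exclude.
#' @return List: `value` (area-weighted mean) and `included_segments`.
#' @export
global_ecv <- function(segment_values, segment_area, segment_labels,
                       segments_with_lge = integer(0)) {
  stopifnot(length(segment_values) == length(segment_area),
            length(segment_labels) == length(segment_values))
  keep <- !(segment_labels %in% segments_with_lge) & !is.na(segment_values) &
    segment_area > 0
  if (!any(keep)) {
    stop("all segments excluded: no LGE-free segment left to average",
         call. = FALSE)
  }
  list(value = sum(segment_values[keep] * segment_area[keep]) /
         sum(segment_area[keep]),
       included_segments = as.integer(segment_labels[keep]))
}
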