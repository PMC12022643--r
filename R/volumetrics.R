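#' Volume from a stack of per-slice masks
#'
#' Slice-summation (Simpson) volume: the masked area of each slice times the
#' slice thickness, summed over slices.
#'
#' @param masks List of logical matrices (one per slice) or a 3D logical
#'   array `[row, col, slice]`.
#' @param voxel_spacing In-plane voxel size, mm.
#' @param slice_thickness Slice thickness, mm (slices are contiguous).
#' @return Volume in mL.
#' @export
volume_from_masks <- function(masks, voxel_spacing, slice_thickness) {
  if (is.array(masks) && length(dim(masks)) == 3) {
    masks <- lapply(seq_len(dim(masks)[3]), function(s) masks[, , s])
  }
  if (!length(masks)) stop("no slices provided", call. = FALSE)
  if (any(vapply(masks, is.null, logical(1)))) {
    stop("missing slice in mask stack", call. = FALSE)
  }
  n_vox <- sum(vapply(masks, function(m) sum(m > 0), numeric(1)))
  n_vox * voxel_spacing^2 * slice_thickness / 1000
}

#' Stroke volume, ejection fraction and cardiac output
#'
#' @param edv,esv End-diastolic and end-systolic volumes, mL (`edv >= esv`).
#' @param heart_rate bpm.
#' @return One-row tibble: `sv` (mL), `ef` (%), `co` (L/min).
#' @export
lv_function <- function(edv, esv, heart_rate) {
  if (edv <= 0) stop("end-diastolic volume must be positive", call. = FALSE)
  if (esv > edv) stop("end-systolic volume exceeds end-diastolic volume", call. = FALSE)
  sv <- edv - esv
  tibble::tibble(sv = sv, ef = 100 * sv / edv, co = sv * heart_rate / 1000)
}

#' Myocardial mass from volume
#'
#' @param myo_volume Myocardial volume, mL.
#' @param density Tissue density, g/mL (default 1.05).
#' @return Mass in g.
#' @export
mass_from_volume <- function(myo_volume, density = MYO_DENSITY) {
  stopifnot(all(myo_volume >= 0))
  myo_volume * density
}

#' Body surface area
#'
#' @param height cm. @param weight kg.
#' @param formula `"mosteller"` (default, `sqrt(h*w/3600)`) or `"dubois"`
#'   (`0.007184 * h^0.725 * w^0.425`).
#' @return BSA in m2.
#' @export
bsa <- function(height, weight, formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  stopifnot(all(height > 0), all(weight > 0))
  switch(formula,
         mosteller = sqrt(height * weight / 3600),
         dubois = 0.007184 * height^0.725 * weight^0.425)
}

#' Maximal wall thickness across a contour stack
#'
#' For each slice, the wall thickness along every 1-degree ray from the
#' cavity centroid is the epicardial minus the endocardial edge radius; the
#' maximum over rays and slices (end-diastole) is reported.
#'
#' @param contours List of [slice_contours()] (or a single one).
#' @return Maximal wall thickness, mm.
#' @export
max_wall_thickness <- function(contours) {
  if (inherits(contours, "slice_contours")) contours <- list(contours)
  if (!length(contours)) stop("no slices provided", call. = FALSE)
  mwt <- vapply(contours, function(ct) {
    band <- ct$epi_mask & !ct$endo_mask
    if (!any(band)) stop("degenerate band on a slice", call. = FALSE)
    center <- mask_centroid(ct$endo_mask)
    r_in <- edge_radius_by_ray(ct$endo_mask, center, ct$voxel_spacing)
    r_out <- edge_radius_by_ray(ct$epi_mask, center, ct$voxel_spacing)
    # smooth the per-ray wall over a +-8 degree window to suppress the
    # rasterization zigzag of the voxelized contours before taking the max
    wall <- r_out - r_in
    sm <- vapply(seq_along(wall), function(i) {
      mean(wall[((i - 9):(i + 7)) %% 360 + 1], na.rm = TRUE)
    }, numeric(1))
    max(sm, na.rm = TRUE)
  }, numeric(1))
  max(mwt)
}

#' Full volumetric profile of a subject
#'
#' Computes cavity volumes at both phases, function, myocardial volume and
#' mass, maximal wall thickness, BSA and all indexed values from a subject's
#' label masks and metadata.
#'
#' @param subject A `cmr_subject` bundle.
#' @param density Myocardial density, g/mL.
#' @param bsa_formula BSA formula, see [bsa()].
#' @return One-row tibble of volumetric metrics (unindexed and indexed).
#' @export
volumetrics <- function(subject, density = MYO_DENSITY,
                        bsa_formula = "mosteller") {
  stopifnot(inherits(subject, "cmr_subject"))
  sp <- subject$voxel_spacing
  th <- subject$slice_thickness
  ed <- subject$masks$labels_ed
  es <- subject$masks$labels_es
  edv <- volume_from_masks(ed == 1L, sp, th)
  esv <- volume_from_masks(es == 1L, sp, th)
  myo_vol <- volume_from_masks(ed >= 2L, sp, th)
  fun <- lv_function(edv, esv, subject$meta$heart_rate)
  mass <- mass_from_volume(myo_vol, density)
  contours <- contours_from_labels(ed, subject$insertions, subject$levels, sp, th)
  mwt <- max_wall_thickness(contours)
  b <- bsa(subject$meta$height, subject$meta$weight, bsa_formula)
  tibble::tibble(
    edv = edv, esv = esv, sv = fun$sv, ef = fun$ef, co = fun$co,
    myo_volume_ed = myo_vol, mass = mass, mwt = mwt, bsa = b,
    edvi = edv / b, esvi = esv / b, svi = fun$sv / b, lvmi = mass / b)
}
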