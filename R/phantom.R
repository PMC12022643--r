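#' Parameters of a synthetic short-axis subject
#'
#' Describes one synthetic subject: a stack of short-axis slices in which the
#' LV is a concentric annulus (myocardium) around a disc (blood pool), with
#' tissue T1 values before and after contrast, hematocrit, optional focal
#' hyperenhancing lesions on the LGE image, and additive Gaussian noise.
#' Slices are ordered base to apex and labeled basal/mid/apical in thirds;
#' no apex cap is generated (the segment model excludes the LV apex).
#'
#' Default geometry and tissue values describe a hypertrophied LV at 3T:
#' 9 slices of 8 mm, tapered cavity radii, ~11.6 mm wall, native myocardial
#' T1 1313 ms, post-contrast myocardial T1 645 ms, blood 1900/450 ms,
#' hematocrit 0.393 — jointly giving a true ECV near 28%.
#'
#' @param grid_size Voxels per slice side (square grid).
#' @param n_slices Number of slices (>= 3).
#' @param voxel_spacing In-plane voxel size, mm.
#' @param slice_thickness Slice thickness, mm (no gap).
#' @param endo_radius,epi_radius End-diastolic cavity and epicardial radii,
#'   mm, one per slice; `epi_radius > endo_radius` everywhere.
#' @param endo_radius_es,epi_radius_es End-systolic counterparts; defaults
#'   shrink the cavity to an ejection fraction near 66% while conserving
#'   myocardial volume.
#' @param t1_myo_native,t1_myo_post,t1_blood_native,t1_blood_post T1, ms;
#'   post-contrast values must be below native ones.
#' @param hematocrit Fraction in (0, 1).
#' @param lesion_spec List of lesions, each
#'   `list(slice=, angle_start=, extent=, transmural=, multiplier=)`:
#'   angular position in degrees of sweep from the anterior RV insertion
#'   through the free wall, transmural fraction of wall depth from the
#'   endocardium, and the multiplicative hyperenhancement on the LGE image.
#' @param noise_sd Named vector `c(t1 = , lge = )`, additive Gaussian noise
#'   SD per modality (intensity units); `c(t1 = 0, lge = 0)` is noise-free.
#' @param heart_rate Heart rate, bpm.
#' @param height Height, cm.
#' @param weight Weight, kg.
#' @param subject_id,timepoint Identifiers carried into metadata.
#' @param lge_signal Baseline LGE-image intensity of non-enhanced myocardium.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   subjects.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_size = 112,
                           n_slices = 9,
                           voxel_spacing = 1,
                           slice_thickness = 8,
                           endo_radius = NULL,
                           epi_radius = NULL,
                           endo_radius_es = NULL,
                           epi_radius_es = NULL,
                           t1_myo_native = 1313,
                           t1_myo_post = 645,
                           t1_blood_native = 1900,
                           t1_blood_post = 450,
                           hematocrit = 0.393,
                           lesion_spec = list(),
                           noise_sd = c(t1 = 15, lge = 5),
                           heart_rate = 66,
                           height = 164,
                           weight = 63,
                           subject_id = "phantom",
                           timepoint = "pre",
                           lge_signal = 100,
                           seed = 1L) {
  if (n_slices < 3) stop("need at least 3 slices", call. = FALSE)
  if (is.null(endo_radius)) endo_radius <- seq(29, 16, length.out = n_slices)
  if (is.null(epi_radius)) epi_radius <- endo_radius + 11.6
  if (is.null(endo_radius_es)) endo_radius_es <- endo_radius * sqrt(0.341)
  if (is.null(epi_radius_es)) {
    epi_radius_es <- sqrt(endo_radius_es^2 + epi_radius^2 - endo_radius^2)
  }
  stopifnot(length(endo_radius) == n_slices, length(epi_radius) == n_slices,
            length(endo_radius_es) == n_slices,
            length(epi_radius_es) == n_slices)
  if (any(epi_radius <= endo_radius) || any(epi_radius_es <= endo_radius_es)) {
    stop("geometry error: epicardial radius must exceed endocardial radius on every slice",
         call. = FALSE)
  }
  if (any(epi_radius >= grid_size * voxel_spacing / 2 - voxel_spacing)) {
    stop("geometry error: epicardium does not fit on the grid", call. = FALSE)
  }
  stop_if_not_scalar_prob(hematocrit, "hematocrit")
  t1s <- c(t1_myo_native, t1_myo_post, t1_blood_native, t1_blood_post)
  if (any(t1s <= 0)) stop("all T1 values must be positive", call. = FALSE)
  if (t1_myo_post >= t1_myo_native || t1_blood_post >= t1_blood_native) {
    stop("post-contrast T1 must be below native T1 for both tissues", call. = FALSE)
  }
  if (!all(c("t1", "lge") %in% names(noise_sd))) {
    stop("noise_sd must be a named vector with elements 't1' and 'lge'", call. = FALSE)
  }
  for (les in lesion_spec) validate_lesion(les, n_slices)
  stopifnot(heart_rate > 0, height > 0, weight > 0)
  structure(
    list(grid_size = as.integer(grid_size), n_slices = as.integer(n_slices),
         voxel_spacing = voxel_spacing, slice_thickness = slice_thickness,
         endo_radius = endo_radius, epi_radius = epi_radius,
         endo_radius_es = endo_radius_es, epi_radius_es = epi_radius_es,
         t1_myo_native = t1_myo_native, t1_myo_post = t1_myo_post,
         t1_blood_native = t1_blood_native, t1_blood_post = t1_blood_post,
         hematocrit = hematocrit, lesion_spec = lesion_spec,
         noise_sd = noise_sd, heart_rate = heart_rate,
         height = height, weight = weight,
         subject_id = subject_id, timepoint = timepoint,
         lge_signal = lge_signal, seed = as.integer(seed)),
    class = "phantom_params")
}

validate_lesion <- function(les, n_slices) {
  need <- c("slice", "angle_start", "extent", "transmural", "multiplier")
  if (!all(need %in% names(les))) {
    stop("each lesion needs fields: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (les$slice < 1 || les$slice > n_slices || les$transmural <= 0 ||
      les$transmural > 1 || les$extent <= 0 || les$extent > 360) {
    stop("lesion outside myocardium or with invalid angular extent", call. = FALSE)
  }
  invisible(les)
}

# AHA level of each slice: thirds from base to apex.
slice_levels <- function(n_slices) {
  thirds <- ceiling(seq_len(n_slices) / (n_slices / 3))
  c("basal", "mid", "apical")[pmin(thirds, 3L)]
}

# The phantom places the anterior RV insertion at a fixed array angle and
# sweeps counterclockwise; the inferior insertion sits 240 deg along the sweep.
PHANTOM_THETA_ANTERIOR <- 135

#' Generate one synthetic subject
#'
#' Renders the image stack (native and post-contrast T1 maps, LGE magnitude
#' image), the label masks (end-diastolic and end-systolic label maps with
#' 0 background / 1 blood pool / 2 myocardium / 3 LGE-reference ROI, plus a
#' blood-pool ROI on the mid slice), the RV insertion points, subject
#' metadata, and the analytic ground truth implied by the parameters.
#'
#' @param params A [phantom_params()] object.
#' @return An object of class `cmr_subject`: list with elements `images`,
#'   `masks`, `insertions`, `levels`, `voxel_spacing`, `slice_thickness`,
#'   `meta`, `truth`, `params`.
#' @export
generate_subject <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  withr::with_seed(params$seed, generate_subject_impl(params))
}

generate_subject_impl <- function(p) {
  g <- p$grid_size
  n <- p$n_slices
  sp <- p$voxel_spacing
  center <- c((g - 1) / 2, (g - 1) / 2)
  polar <- slice_polar(c(g, g), center, sp)
  sweep <- sweep_angle(polar$theta, PHANTOM_THETA_ANTERIOR, 1)
  levels <- slice_levels(n)

  labels_ed <- array(0L, c(g, g, n))
  labels_es <- array(0L, c(g, g, n))
  lesion_mask <- array(FALSE, c(g, g, n))
  blood_roi <- array(FALSE, c(g, g, n))

  for (s in seq_len(n)) {
    er <- p$endo_radius[s]; pr <- p$epi_radius[s]
    sl <- matrix(0L, g, g)
    sl[polar$radius <= pr] <- 2L
    sl[polar$radius <= er] <- 1L
    wall <- pr - er
    for (les in p$lesion_spec) {
      if (les$slice != s) next
      r_out <- er + les$transmural * wall
      in_angle <- sweep_angle(sweep, les$angle_start, 1) < les$extent
      hit <- sl == 2L & in_angle & polar$radius <= r_out
      lesion_mask[, , s][hit] <- TRUE
    }
    # remote reference ROI: a 60-degree free-wall window clear of lesions,
    # central half of the wall
    roi_start <- reference_window(p$lesion_spec, s)
    in_roi <- sweep_angle(sweep, roi_start, 1) < 60 &
      polar$radius >= er + 0.25 * wall & polar$radius <= er + 0.75 * wall &
      sl == 2L & !lesion_mask[, , s]
    sl[in_roi] <- 3L
    labels_ed[, , s] <- sl

    sle <- matrix(0L, g, g)
    sle[polar$radius <= p$epi_radius_es[s]] <- 2L
    sle[polar$radius <= p$endo_radius_es[s]] <- 1L
    labels_es[, , s] <- sle
  }
  mid <- ceiling(n / 2)
  blood_roi[, , mid] <- polar$radius <= 0.6 * p$endo_radius[mid]

  t1_native <- array(0, c(g, g, n))
  t1_post <- array(0, c(g, g, n))
  lge <- array(0, c(g, g, n))
  myo <- labels_ed >= 2L
  blood <- labels_ed == 1L
  t1_native[myo] <- p$t1_myo_native
  t1_native[blood] <- p$t1_blood_native
  t1_post[myo] <- p$t1_myo_post
  t1_post[blood] <- p$t1_blood_post
  lge[myo] <- p$lge_signal
  lge[blood] <- 2.5 * p$lge_signal
  lge[lesion_mask] <- p$lge_signal * vapply_lesion_mult(p, lesion_mask)

  inside <- labels_ed > 0L
  if (p$noise_sd[["t1"]] > 0) {
    t1_native[inside] <- t1_native[inside] +
      stats::rnorm(sum(inside), 0, p$noise_sd[["t1"]])
    t1_post[inside] <- t1_post[inside] +
      stats::rnorm(sum(inside), 0, p$noise_sd[["t1"]])
  }
  if (p$noise_sd[["lge"]] > 0) {
    lge[inside] <- lge[inside] + stats::rnorm(sum(inside), 0, p$noise_sd[["lge"]])
  }

  insertions <- phantom_insertions(p, center)
  meta <- tibble::tibble(
    subject_id = p$subject_id, timepoint = p$timepoint,
    hematocrit = p$hematocrit, height = p$height, weight = p$weight,
    heart_rate = p$heart_rate)
  truth <- ground_truth(p)

  structure(
    list(images = list(t1_native = t1_native, t1_post = t1_post, lge = lge),
         masks = list(labels_ed = labels_ed, labels_es = labels_es,
                      blood_roi = blood_roi, lesions = lesion_mask),
         insertions = insertions, levels = levels,
         voxel_spacing = sp, slice_thickness = p$slice_thickness,
         meta = meta, truth = truth, params = p),
    class = "cmr_subject")
}

# each lesion may have its own multiplier; paint in spec order
vapply_lesion_mult <- function(p, lesion_mask) {
  mult <- array(1, dim(lesion_mask))
  g <- p$grid_size
  center <- c((g - 1) / 2, (g - 1) / 2)
  polar <- slice_polar(c(g, g), center, p$voxel_spacing)
  sweep <- sweep_angle(polar$theta, PHANTOM_THETA_ANTERIOR, 1)
  for (les in p$lesion_spec) {
    s <- les$slice
    er <- p$endo_radius[s]
    r_out <- er + les$transmural * (p$epi_radius[s] - er)
    hit <- sweep_angle(sweep, les$angle_start, 1) < les$extent &
      polar$radius <= r_out & polar$radius > er
    mult[, , s][hit] <- les$multiplier
  }
  mult[lesion_mask]
}

# a 60-degree sweep window free of lesions on this slice, preferring the
# lateral free wall (sweep 90)
reference_window <- function(lesion_spec, s) {
  cand <- c(90, 120, 60, 150, 30, 180)
  les <- Filter(function(l) l$slice == s, lesion_spec)
  intervals <- list()
  for (l in les) {
    a0 <- l$angle_start %% 360
    a1 <- a0 + l$extent
    if (a1 <= 360) {
      intervals[[length(intervals) + 1]] <- c(a0, a1)
    } else {  # wraps past 360
      intervals[[length(intervals) + 1]] <- c(a0, 360)
      intervals[[length(intervals) + 1]] <- c(0, a1 - 360)
    }
  }
  for (start in cand) {
    clear <- all(vapply(intervals, function(iv) {
      iv[2] <= start || iv[1] >= start + 60
    }, logical(1)))
    if (clear) return(start)
  }
  cand[1]
}

phantom_insertions <- function(p, center) {
  th_a <- PHANTOM_THETA_ANTERIOR * pi / 180
  th_i <- (PHANTOM_THETA_ANTERIOR + 240) * pi / 180
  purrr::map_dfr(seq_len(p$n_slices), function(s) {
    r <- p$epi_radius[s] / p$voxel_spacing
    tibble::tibble(
      slice = s,
      anterior_row = center[1] + r * cos(th_a),
      anterior_col = center[2] + r * sin(th_a),
      inferior_row = center[1] + r * cos(th_i),
      inferior_col = center[2] + r * sin(th_i))
  })
}

# Analytic ground truth from the generating parameters.
ground_truth <- function(p) {
  th <- p$slice_thickness
  ecv <- ecv_from_t1(p$t1_myo_native, p$t1_myo_post,
                     p$t1_blood_native, p$t1_blood_post, p$hematocrit)
  myo_vol <- sum(pi * (p$epi_radius^2 - p$endo_radius^2) * th) / 1000
  edv <- sum(pi * p$endo_radius^2 * th) / 1000
  esv <- sum(pi * p$endo_radius_es^2 * th) / 1000
  lge_vol <- 0
  for (les in p$lesion_spec) {
    er <- p$endo_radius[les$slice]
    wall <- p$epi_radius[les$slice] - er
    r_out <- er + les$transmural * wall
    lge_vol <- lge_vol + (les$extent / 360) * pi * (r_out^2 - er^2) * th / 1000
  }
  tibble::tibble(
    true_ecv = ecv,
    true_myo_volume_ed = myo_vol,
    true_mass = myo_vol * MYO_DENSITY,
    true_lge_volume = lge_vol,
    true_edv = edv,
    true_esv = esv,
    true_native_t1 = p$t1_myo_native)
}

#' @export
print.cmr_subject <- function(x, ...) {
  cat(sprintf("<cmr_subject> %s/%s: %d slices of %dx%d voxels (%.1f mm, %.1f mm thick)\n",
              x$meta$subject_id, x$meta$timepoint, dim(x$images$t1_native)[3],
              dim(x$images$t1_native)[1], dim(x$images$t1_native)[2],
              x$voxel_spacing, x$slice_thickness))
  cat(sprintf("  true ECV %.3f, true mass %.1f g, true LGE volume %.2f mL\n",
              x$truth$true_ecv, x$truth$true_mass, x$truth$true_lge_volume))
  invisible(x)
}
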