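#' Run configuration
#'
#' All analysis settings in one place. Defaults reproduce the conventional
#' measurement settings: 6-SD LGE threshold, 10% radial offset for T1/ECV,
#' myocardial density 1.05 g/mL, Mosteller BSA, Bonferroni family of 20 at
#' alpha 0.05.
#'
#' @param density Myocardial density, g/mL.
#' @param bsa_formula `"mosteller"` or `"dubois"`.
#' @param lge_sd LGE threshold in reference-ROI standard deviations.
#' @param offset_fraction Radial offset fraction for the T1/ECV core band.
#' @param exclusion_fraction Minimum enhanced fraction for a segment to be
#'   excluded from global T1/ECV (0: any enhanced voxel excludes it).
#' @param alpha Familywise significance level. @param family Family size.
#' @return An object of class `run_config`.
#' @export
run_config <- function(density = MYO_DENSITY, bsa_formula = "mosteller",
                       lge_sd = 6, offset_fraction = 0.10,
                       exclusion_fraction = 0, alpha = 0.05, family = 20) {
  stopifnot(density > 0, lge_sd > 0, offset_fraction >= 0,
            offset_fraction < 0.5, exclusion_fraction >= 0,
            exclusion_fraction <= 1)
  structure(list(density = density, bsa_formula = bsa_formula,
                 lge_sd = lge_sd, offset_fraction = offset_fraction,
                 exclusion_fraction = exclusion_fraction,
                 alpha = alpha, family = family),
            class = "run_config")
}

#' Quantify one subject end to end
#'
#' Runs the full single-subject pipeline: myocardial band and 10%-offset
#' core, AHA 16-segment model, segmental native/post-contrast T1, segmental
#' ECV with blood T1 from the mid-slice blood-pool ROI, 6-SD LGE
#' quantification with per-segment exclusion, global (area-weighted,
#' LGE-segment-excluded) native T1 and ECV, volumetrics, and the indexed
#' compartment volumes iECV and iCV.
#'
#' @param subject A `cmr_subject` bundle or a directory written by
#'   [write_subject()].
#' @param config A [run_config()].
#' @return One-row tibble of subject metrics (`subject_id`, `timepoint`,
#'   volumetrics, LGE, T1/ECV, `iecv`, `icv`).
#' @export
quantify_subject <- function(subject, config = run_config()) {
  if (is.character(subject)) subject <- read_subject(subject)
  stopifnot(inherits(subject, "cmr_subject"), inherits(config, "run_config"))
  sp <- subject$voxel_spacing
  th <- subject$slice_thickness
  n <- dim(subject$masks$labels_ed)[3]
  contours <- contours_from_labels(subject$masks$labels_ed, subject$insertions,
                                   subject$levels, sp, th)

  band3d <- array(FALSE, dim(subject$masks$labels_ed))
  core3d <- band3d
  segmap_core <- array(0L, dim(band3d))
  segmap_band <- segmap_core
  seg_rows <- vector("list", n)
  for (s in seq_len(n)) {
    band <- myocardial_band(contours[[s]])
    core <- radial_offset(band, contours[[s]], config$offset_fraction)
    band3d[, , s] <- band
    core3d[, , s] <- core
    model_core <- assign_segments(core, contours[[s]])
    model_band <- assign_segments(band, contours[[s]])
    segmap_core[, , s] <- model_core$segment_map
    segmap_band[, , s] <- model_band$segment_map

    t1n <- segment_stats(subject$images$t1_native[, , s], model_core)
    t1p <- segment_stats(subject$images$t1_post[, , s], model_core)
    seg_rows[[s]] <- dplyr::mutate(
      dplyr::rename(t1n, t1_native = mean),
      t1_post = t1p$mean, slice = s)
  }
  seg <- dplyr::bind_rows(seg_rows)
  # segments pooled across slices of the same level share a label already;
  # aggregate area-weighted per label
  seg_tbl <- dplyr::summarise(
    dplyr::group_by(seg, .data$segment),
    t1_native = stats::weighted.mean(.data$t1_native, .data$area_mm2, na.rm = TRUE),
    t1_post = stats::weighted.mean(.data$t1_post, .data$area_mm2, na.rm = TRUE),
    area_mm2 = sum(.data$area_mm2), .groups = "drop")

  blood_roi <- subject$masks$blood_roi
  if (!any(blood_roi)) stop("blood-pool ROI is empty", call. = FALSE)
  blood_native <- mean(subject$images$t1_native[blood_roi])
  blood_post <- mean(subject$images$t1_post[blood_roi])
  hct <- subject$meta$hematocrit

  seg_tbl$ecv <- ecv_from_t1(seg_tbl$t1_native, seg_tbl$t1_post,
                             blood_native, blood_post, hct)

  roi <- reference_roi(subject$images$lge, subject$masks$labels_ed == 3L,
                       band3d)
  lge_mask <- lge_threshold(subject$images$lge, band3d, roi, config$lge_sd)
  lge <- lge_quantify(lge_mask, band3d, sp, th, config$density,
                      segment_map = segmap_band,
                      min_fraction = config$exclusion_fraction)
  excl <- lge$segments_with_lge[[1]]

  g_ecv <- global_ecv(seg_tbl$ecv, seg_tbl$area_mm2, seg_tbl$segment, excl)
  g_t1 <- global_ecv(seg_tbl$t1_native, seg_tbl$area_mm2, seg_tbl$segment, excl)

  vol <- volumetrics(subject, config$density, config$bsa_formula)
  iecv <- indexed_ecv(vol$myo_volume_ed, lge$lge_volume, vol$bsa, g_ecv$value)
  icv <- indexed_cv(vol$myo_volume_ed, lge$lge_volume, vol$bsa, g_ecv$value)

  dplyr::bind_cols(
    tibble::tibble(subject_id = subject$meta$subject_id,
                   timepoint = subject$meta$timepoint),
    vol,
    tibble::tibble(
      lge_volume = lge$lge_volume, lge_mass = lge$lge_mass,
      lge_mass_indexed = lge$lge_mass / vol$bsa,
      lge_percent = lge$lge_percent,
      n_segments_with_lge = length(excl),
      global_native_t1 = g_t1$value, global_ecv = g_ecv$value,
      blood_native_t1 = blood_native, blood_post_t1 = blood_post,
      iecv = iecv, icv = icv))
}

# metrics entering the pre/post change table (the CMR block)
COHORT_METRICS <- c("edvi", "esvi", "svi", "ef", "co", "mass", "lvmi", "mwt",
                    "lge_mass", "lge_mass_indexed", "lge_percent",
                    "global_native_t1", "global_ecv", "iecv", "icv")

#' Run the full paired-cohort pipeline
#'
#' Materializes and quantifies every subject at both timepoints, pairs the
#' metrics by subject, and runs the statistics stage: normality-gated paired
#' tests with Bonferroni correction (the change table), Pearson correlations
#' between baseline fibrosis variables and changes, and the univariable
#' screen plus stepwise multivariable regression for the LVMI and iECV
#' reductions.
#'
#' @param cohort A `cmr_cohort` from [generate_paired_cohort()], or a
#'   pre-computed metrics tibble with `subject_id`/`timepoint` columns.
#' @param config A [run_config()].
#' @param progress Print per-subject progress.
#' @return A list of class `cmr_cohort_results`: `metrics` (per
#'   subject-timepoint), `paired` (long paired table), `change_table`
#'   (per-metric test results), `correlations` (`cmr_cormat`), `regressions`
#'   (list of `cmr_stepwise` + screen tibbles), `config`.
#' @export
run_cohort <- function(cohort, config = run_config(), progress = FALSE) {
  if (inherits(cohort, "cmr_cohort")) {
    n <- length(cohort$subjects)
    rows <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      for (tp in c("pre", "post")) {
        if (progress) message(sprintf("quantifying subject %d/%d (%s)", i, n, tp))
        subj <- cohort_subject(cohort, i, tp)
        rows[[2L * (i - 1L) + (tp == "post") + 1L]] <-
          quantify_subject(subj, config)
      }
    }
    metrics <- dplyr::bind_rows(rows)
  } else {
    metrics <- cohort
  }
  stopifnot(all(c("subject_id", "timepoint") %in% names(metrics)))

  paired <- build_paired_table(metrics,
                               intersect(COHORT_METRICS, names(metrics)))
  if (!nrow(paired)) stop("no complete pre/post pairs", call. = FALSE)
  change_table <- cohort_change_table(paired, config)

  wide <- paired_to_wide(paired)
  fib_vars <- intersect(c("global_ecv_pre", "iecv_pre", "icv_pre",
                          "global_native_t1_pre", "lge_percent_pre"),
                        names(wide))
  chg_vars <- intersect(c("reduction_lvmi", "reduction_iecv", "reduction_icv",
                          "delta_ef", "delta_edvi"), names(wide))
  correlations <- correlation_matrix(wide, c(fib_vars, chg_vars))

  regressions <- cohort_regressions(wide, config)

  structure(list(metrics = metrics, paired = paired,
                 change_table = change_table, correlations = correlations,
                 regressions = regressions, config = config),
            class = "cmr_cohort_results")
}

# one row per subject: <metric>_pre, <metric>_post, delta_<metric>,
# reduction_<metric>
paired_to_wide <- function(paired) {
  pre <- tidyr::pivot_wider(paired[, c("subject_id", "metric", "pre")],
                            names_from = "metric", values_from = "pre",
                            names_glue = "{metric}_pre")
  post <- tidyr::pivot_wider(paired[, c("subject_id", "metric", "post")],
                             names_from = "metric", values_from = "post",
                             names_glue = "{metric}_post")
  dl <- tidyr::pivot_wider(paired[, c("subject_id", "metric", "delta")],
                           names_from = "metric", values_from = "delta",
                           names_glue = "delta_{metric}")
  rd <- tidyr::pivot_wider(paired[, c("subject_id", "metric", "reduction")],
                           names_from = "metric", values_from = "reduction",
                           names_glue = "reduction_{metric}")
  Reduce(function(a, b) dplyr::left_join(a, b, by = "subject_id"),
         list(pre, post, dl, rd))
}

#' Per-metric change table with normality-gated paired tests
#'
#' @param paired Long paired table from [build_paired_table()].
#' @param config A [run_config()] (supplies alpha and family size).
#' @return Tibble with one row per metric: summary statistics of pre, post
#'   and change, the test used, p-value and Bonferroni-adjusted significance.
#' @export
cohort_change_table <- function(paired, config = run_config()) {
  metrics <- unique(paired$metric)
  purrr::map_dfr(metrics, function(mt) {
    d <- paired[paired$metric == mt, ]
    if (nrow(d) < 3) {
      tst <- tibble::tibble(test = "none (n < 3)", statistic = NA_real_,
                            p_value = NA_real_, significant = FALSE)
    } else {
      tst <- paired_compare(pre = d$pre, post = d$post, alpha = config$alpha,
                            m = config$family, metric = mt)
    }
    tibble::tibble(
      metric = mt, n = nrow(d),
      pre_mean = mean(d$pre), pre_sd = stats::sd(d$pre),
      pre_median = stats::median(d$pre),
      pre_q1 = unname(stats::quantile(d$pre, 0.25)),
      pre_q3 = unname(stats::quantile(d$pre, 0.75)),
      post_mean = mean(d$post), post_sd = stats::sd(d$post),
      post_median = stats::median(d$post),
      change_mean = mean(d$delta), change_sd = stats::sd(d$delta),
      change_median = stats::median(d$delta),
      test = tst$test, statistic = tst$statistic, p_value = tst$p_value,
      significant = tst$significant)
  })
}

cohort_regressions <- function(wide, config) {
  candidates <- intersect(
    c("lvmi_pre", "global_ecv_pre", "icv_pre", "iecv_pre",
      "global_native_t1_pre", "lge_percent_pre"),
    names(wide))
  out <- list()
  for (oc in intersect(c("reduction_lvmi", "reduction_iecv"), names(wide))) {
    if (stats::sd(wide[[oc]]) == 0) {
      out[[oc]] <- list(univariable = NULL, multivariable = NULL)
      next
    }
    screen <- suppressWarnings(univariable_screen(wide, oc, candidates,
                                                  alpha = 0.05))
    retained <- screen$term[screen$retained]
    model <- if (length(retained) && nrow(wide) > length(retained) + 2) {
      stepwise_multivariable(wide, oc, retained)
    } else NULL
    out[[oc]] <- list(univariable = screen, multivariable = model)
  }
  out
}

#' @export
print.cmr_cohort_results <- function(x, ...) {
  cat(sprintf("<cmr_cohort_results> %d subjects, %d metrics\n",
              length(unique(x$paired$subject_id)),
              length(unique(x$paired$metric))))
  sig <- x$change_table$metric[x$change_table$significant]
  cat("  significant changes (Bonferroni): ",
      if (length(sig)) paste(sig, collapse = ", ") else "(none)", "\n", sep = "")
  invisible(x)
}
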