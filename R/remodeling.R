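#' Indexed extracellular volume (iECV)
#'
#' The absolute extracellular myocardial volume normalized to body surface
#' area: the indexed non-enhanced end-diastolic myocardial volume times ECV,
#' `iECV = (myo_volume/BSA - lge_volume/BSA) * ECV` (mL/m2). The LGE volume
#' is subtracted after indexing, i.e. both terms are divided by BSA.
#'
#' @param myo_volume_ed End-diastolic myocardial volume, mL.
#' @param lge_volume Enhanced (LGE) volume, mL (`<= myo_volume_ed`).
#' @param bsa Body surface area, m2.
#' @param global_ecv Global ECV as a fraction.
#' @return iECV in mL/m2.
#' @export
indexed_ecv <- function(myo_volume_ed, lge_volume, bsa, global_ecv) {
  check_compartment_inputs(myo_volume_ed, lge_volume, bsa)
  (myo_volume_ed / bsa - lge_volume / bsa) * global_ecv
}

#' Indexed cellular volume (iCV)
#'
#' As [indexed_ecv()] with factor `(1 - ECV)`: the indexed non-enhanced
#' myocardial volume attributed to the cellular compartment.
#'
#' @inheritParams indexed_ecv
#' @return iCV in mL/m2.
#' @export
indexed_cv <- function(myo_volume_ed, lge_volume, bsa, global_ecv) {
  check_compartment_inputs(myo_volume_ed, lge_volume, bsa)
  (myo_volume_ed / bsa - lge_volume / bsa) * (1 - global_ecv)
}

check_compartment_inputs <- function(myo_volume_ed, lge_volume, bsa) {
  if (any(lge_volume > myo_volume_ed)) {
    stop("LGE volume exceeds myocardial volume", call. = FALSE)
  }
  stopifnot(all(myo_volume_ed >= 0), all(lge_volume >= 0), all(bsa > 0))
}

#' Within-person change of a metric
#'
#' Two sign conventions coexist in pre/post reporting: descriptive change
#' tables report `delta = post - pre` (negative means regression), while
#' regression outcomes use `change = pre - post` so that a reduction is
#' positive. Both are returned, together with the percent change relative to
#' baseline.
#'
#' @param pre,post Baseline and follow-up values.
#' @return Tibble with `delta` (post - pre), `reduction` (pre - post) and
#'   `percent_change` (`100 * (pre - post) / pre`, `NA` when `pre == 0`).
#' @export
paired_change <- function(pre, post) {
  tibble::tibble(
    delta = post - pre,
    reduction = pre - post,
    percent_change = ifelse(pre == 0, NA_real_, 100 * (pre - post) / pre))
}

#' Build the paired pre/post cohort table
#'
#' Pairs per-subject-timepoint metric rows by subject id and computes the
#' within-person change for each metric. Subjects missing either timepoint
#' are dropped (their count is reported as an attribute).
#'
#' @param metrics Tibble of per-subject-timepoint rows containing
#'   `subject_id`, `timepoint` (`"pre"`/`"post"`) and numeric metric columns.
#' @param metrics_cols Character vector of metric columns to pair; defaults
#'   to every numeric column.
#' @return Tibble with one row per subject and metric: `subject_id`,
#'   `metric`, `pre`, `post`, `delta`, `reduction`, `percent_change`.
#' @export
build_paired_table <- function(metrics, metrics_cols = NULL) {
  stopifnot(all(c("subject_id", "timepoint") %in% names(metrics)))
  if (is.null(metrics_cols)) {
    metrics_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                            c("subject_id"))
  }
  long <- tidyr::pivot_longer(
    metrics[, c("subject_id", "timepoint", metrics_cols)],
    dplyr::all_of(metrics_cols), names_to = "metric", values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "timepoint",
                             values_from = "value")
  if (!all(c("pre", "post") %in% names(wide))) {
    stop("need both 'pre' and 'post' timepoints", call. = FALSE)
  }
  complete <- !is.na(wide$pre) & !is.na(wide$post)
  n_dropped <- length(unique(wide$subject_id[!complete]))
  out <- dplyr::bind_cols(wide[complete, c("subject_id", "metric", "pre", "post")],
                          paired_change(wide$pre[complete], wide$post[complete]))
  attr(out, "n_dropped") <- n_dropped
  out
}
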