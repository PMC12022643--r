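#' Write a subject bundle to disk
#'
#' One directory per subject-timepoint: each modality as a NIfTI volume
#' (`t1_native.nii.gz`, `t1_post.nii.gz`, `lge.nii.gz`), the label maps
#' (`labels_ed.nii.gz`, `labels_es.nii.gz`; 0 background, 1 blood pool,
#' 2 myocardium, 3 LGE-reference ROI) and blood-pool ROI
#' (`blood_roi.nii.gz`) as integer NIfTI, and a `meta.json` sidecar with
#' metadata, RV insertion-point voxel coordinates, slice levels, voxel
#' geometry and the generating ground truth.
#'
#' @param subject A `cmr_subject` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "cmr_subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- c(subject$voxel_spacing, subject$voxel_spacing, subject$slice_thickness)
  wr <- function(arr, name, integer = FALSE) {
    if (integer) storage.mode(arr) <- "integer"
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(subject$images$t1_native, "t1_native")
  wr(subject$images$t1_post, "t1_post")
  wr(subject$images$lge, "lge")
  wr(subject$masks$labels_ed, "labels_ed", integer = TRUE)
  wr(subject$masks$labels_es, "labels_es", integer = TRUE)
  wr(subject$masks$blood_roi * 1L, "blood_roi", integer = TRUE)
  side <- list(meta = as.list(subject$meta),
               insertions = subject$insertions,
               levels = subject$levels,
               voxel_spacing = subject$voxel_spacing,
               slice_thickness = subject$slice_thickness,
               truth = as.list(subject$truth))
  jsonlite::write_json(side, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject bundle written by [write_subject()]
#'
#' @param dir Subject directory.
#' @return A `cmr_subject` bundle.
#' @export
read_subject <- function(dir) {
  need <- c("t1_native", "t1_post", "lge", "labels_ed", "labels_es",
            "blood_roi")
  files <- file.path(dir, paste0(need, ".nii.gz"))
  missing <- need[!file.exists(files)]
  if (length(missing)) {
    stop("missing modality file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rd <- function(name) {
    arr <- as.array(RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz"))))
    attributes(arr) <- list(dim = dim(arr))
    arr
  }
  side <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  imgs <- list(t1_native = rd("t1_native"), t1_post = rd("t1_post"),
               lge = rd("lge"))
  labels_ed <- rd("labels_ed"); storage.mode(labels_ed) <- "integer"
  labels_es <- rd("labels_es"); storage.mode(labels_es) <- "integer"
  dims <- lapply(c(imgs, list(labels_ed)), dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("mask/image misalignment: volume dimensions differ", call. = FALSE)
  }
  structure(
    list(images = imgs,
         masks = list(labels_ed = labels_ed, labels_es = labels_es,
                      blood_roi = rd("blood_roi") > 0),
         insertions = tibble::as_tibble(side$insertions),
         levels = side$levels,
         voxel_spacing = side$voxel_spacing,
         slice_thickness = side$slice_thickness,
         meta = tibble::as_tibble(side$meta),
         truth = tibble::as_tibble(side$truth),
         params = NULL),
    class = "cmr_subject")
}

#' Write cohort result tables to a directory
#'
#' Emits `metrics.csv` (one row per subject-timepoint), `paired.csv`,
#' `change_table.csv`, `correlations.csv` (long form) and, when present,
#' `regression_<outcome>.csv`, plus a `manifest.json` recording the
#' configuration.
#'
#' @param results A `cmr_cohort_results` from [run_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_results <- function(results, dir) {
  stopifnot(inherits(results, "cmr_cohort_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(results$paired, file.path(dir, "paired.csv"),
                   row.names = FALSE)
  utils::write.csv(results$change_table, file.path(dir, "change_table.csv"),
                   row.names = FALSE)
  utils::write.csv(generics::tidy(results$correlations),
                   file.path(dir, "correlations.csv"), row.names = FALSE)
  for (oc in names(results$regressions)) {
    reg <- results$regressions[[oc]]
    utils::write.csv(reg$univariable,
                     file.path(dir, paste0("regression_", oc, "_univariable.csv")),
                     row.names = FALSE)
    if (!is.null(reg$multivariable)) {
      utils::write.csv(reg$multivariable$coefficients,
                       file.path(dir, paste0("regression_", oc, "_multivariable.csv")),
                       row.names = FALSE)
    }
  }
  manifest <- c(unclass(results$config),
                list(package_version = as.character(utils::packageVersion("cmremodel")),
                     n_subjects = length(unique(results$paired$subject_id))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
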