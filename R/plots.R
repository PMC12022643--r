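#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

as_raster_tibble <- function(arr, slice, value_name = "value") {
  m <- arr[, , slice]
  tibble::tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m))
}

#' Plot one slice of a subject bundle
#'
#' @param object A `cmr_subject`.
#' @param slice Slice index (default: mid slice).
#' @param modality `"t1_native"`, `"t1_post"`, `"lge"` or `"labels"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cmr_subject <- function(object, slice = NULL,
                                 modality = c("t1_native", "t1_post", "lge",
                                              "labels"), ...) {
  modality <- match.arg(modality)
  n <- dim(object$masks$labels_ed)[3]
  if (is.null(slice)) slice <- ceiling(n / 2)
  if (modality == "labels") {
    d <- as_raster_tibble(object$masks$labels_ed, slice)
    d$value <- factor(d$value, levels = 0:3,
                      labels = c("background", "blood pool", "myocardium",
                                 "reference ROI"))
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                         fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_manual(values = c("grey15", "firebrick",
                                            "grey70", "gold"), name = NULL)
  } else {
    d <- as_raster_tibble(object$images[[modality]], slice)
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                         fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = modality)
  }
  p + ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, slice %d (%s)",
                                  object$meta$subject_id, slice,
                                  object$levels[slice])) +
    ggplot2::theme_minimal()
}

#' Paired pre/post spaghetti plot of one metric
#'
#' @param paired Long paired table from [build_paired_table()] (or the
#'   `paired` element of [run_cohort()] results).
#' @param metric Metric name to plot.
#' @return A ggplot object: one line per subject from pre to post.
#' @export
plot_paired_changes <- function(paired, metric) {
  d <- paired[paired$metric == metric, ]
  if (!nrow(d)) stop("metric not found in paired table", call. = FALSE)
  long <- tidyr::pivot_longer(d[, c("subject_id", "pre", "post")],
                              c("pre", "post"), names_to = "timepoint",
                              values_to = "value")
  long$timepoint <- factor(long$timepoint, levels = c("pre", "post"))
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value,
                                     group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap
#'
#' @param object A `cmr_cormat` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot heatmap of Pearson r.
#' @export
autoplot.cmr_cormat <- function(object, ...) {
  d <- generics::tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
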