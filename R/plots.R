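#' Plot an evaluation report
#'
#' Boxplots of the per-repeat test metrics (AUC, accuracy, sensitivity,
#' specificity) for one model variant.
#'
#' @param object A `dtp_eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dtp_eval_report <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("auc", "acc", "sen", "spe")),
                        names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(x = toupper(.data$metric), y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "test-set value",
                  title = attr(object, "variant")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot static vs DTP Spearman correlation tiers
#'
#' Lollipop chart of per-feature |rho| between static and DTP features with
#' the 0.5 / 0.7 tier boundaries; features below 0.7 are the candidates
#' carrying additional dynamic information.
#'
#' @param pairs Output of [spearman_pairs()].
#' @return A ggplot object.
#' @export
plot_correlation_tiers <- function(pairs) {
  pairs |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::mutate(feature = stats::reorder(.data$feature, abs(.data$rho))) |>
    ggplot2::ggplot(ggplot2::aes(x = abs(.data$rho), y = .data$feature,
                                 colour = .data$tier)) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = abs(.data$rho),
                                       yend = .data$feature)) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.7), linetype = "dashed") +
    ggplot2::labs(x = "|Spearman rho| (static vs DTP)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a mid-axial slice of a volume
#'
#' @param v An [image_volume()].
#' @param slice Slice index (default middle).
#' @return A ggplot object.
#' @export
plot_slice <- function(v, slice = NULL) {
  stopifnot(inherits(v, "image_volume"))
  if (is.null(slice)) slice <- ceiling(dim(v$data)[3] / 2)
  sl <- v$data[, , slice]
  df <- tibble::tibble(x = rep(seq_len(nrow(sl)), times = ncol(sl)),
                       y = rep(seq_len(ncol(sl)), each = nrow(sl)),
                       value = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = v$unit) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
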