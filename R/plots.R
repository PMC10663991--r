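#' BCV plot of a dispersion fit
#'
#' Biological coefficient of variation (square-root dispersion) against
#' average abundance: tagwise points, the trend line, and the common value.
#'
#' @param object a `dispersion_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dispersion_fit <- function(object, ...) {
  d <- object$gene
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ave_log_cpm)) +
    ggplot2::geom_point(ggplot2::aes(y = sqrt(.data$tagwise)),
                        size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = sqrt(.data$trended)),
                       colour = "blue") +
    ggplot2::geom_hline(yintercept = sqrt(object$common), colour = "red") +
    ggplot2::labs(x = "Average log2-CPM", y = "BCV",
                  title = "NB dispersion estimates") +
    ggplot2::theme_classic()
}

#' QL dispersion plot
#'
#' Quarter-root raw and squeezed quasi-likelihood dispersions against
#' average abundance, with the squeeze trend.
#'
#' @param object a [ql_fit].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ql_fit <- function(object, ...) {
  d <- tibble(ave = object$ave_log_cpm,
              raw = object$s2_raw, squeezed = object$s2_post,
              trend = object$s2_trend) |>
    tidyr::pivot_longer(-"ave", names_to = "kind", values_to = "s2") |>
    dplyr::filter(is.finite(.data$s2), .data$s2 > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ave, y = .data$s2^0.25,
                                  colour = .data$kind)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$kind != "trend"),
                        size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$kind == "trend")) +
    ggplot2::labs(x = "Average log2-CPM",
                  y = expression(QL~dispersion^{1/4}),
                  title = "QL dispersion squeeze") +
    ggplot2::theme_classic()
}

#' MDS plot of pseudo-bulk samples
#'
#' @param mds tibble from [mds_leading_logfc()].
#' @param labels optional point labels (e.g. rounded pseudotimes).
#' @param colour optional grouping for colours.
#' @return A ggplot object.
#' @export
plot_mds <- function(mds, labels = NULL, colour = NULL) {
  d <- dplyr::mutate(mds,
                     .label = labels %||% .data$sample_id,
                     .colour = colour %||% "sample")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                  colour = .data$.colour)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$.label), size = 3) +
    ggplot2::labs(x = "Leading logFC dim 1", y = "Leading logFC dim 2",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Fitted trend curves
#'
#' @param curves tibble from [fitted_curves()].
#' @return A ggplot object, one facet per gene.
#' @export
plot_trend_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$pseudotime,
                                       y = .data$log2cpm)) +
    ggplot2::geom_line(colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~symbol, scales = "free_y") +
    ggplot2::labs(x = "Pseudotime", y = "Log2-CPM") +
    ggplot2::theme_classic()
}

#' Heatmap of row-standardized expression
#'
#' @param z matrix from [heatmap_matrix()].
#' @return A ggplot tile plot; rows keep their block order.
#' @export
plot_heatmap <- function(z) {
  d <- as.data.frame(z) |>
    tibble::rownames_to_column("symbol") |>
    tidyr::pivot_longer(-"symbol", names_to = "sample_id",
                        values_to = "zscore") |>
    dplyr::mutate(symbol = factor(.data$symbol, levels = rev(rownames(z))),
                  sample_id = factor(.data$sample_id, levels = colnames(z)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$symbol,
                                  fill = .data$zscore)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", name = "Z score") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar plot of top enriched sets
#'
#' @param rows tibble from [directional_ora()] (or [top_sets()]).
#' @param direction which direction's p-values to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(rows, direction = c("Down", "Up")) {
  direction <- match.arg(direction)
  p <- rows[[paste0("P.", direction)]]
  d <- dplyr::mutate(rows, neg_log10_p = -log10(p),
                     term = factor(.data$term,
                                   levels = rev(unique(.data$term))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$neg_log10_p, y = .data$term)) +
    ggplot2::geom_col(fill = "cornflowerblue") +
    ggplot2::labs(x = "-log10 (P value)", y = NULL, title = direction) +
    ggplot2::theme_classic()
}

#' Average gene-set expression along pseudotime
#'
#' @param trend tibble from [geneset_average_trend()].
#' @param title plot title (e.g. the pathway name).
#' @return A ggplot object.
#' @export
plot_geneset_trend <- function(trend, title = NULL) {
  ggplot2::ggplot(trend, ggplot2::aes(x = .data$pseudotime)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$avg_log2cpm), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                       colour = "cornflowerblue", linewidth = 1) +
    ggplot2::labs(x = "Pseudotime", y = "Average log-CPM", title = title) +
    ggplot2::theme_classic()
}
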