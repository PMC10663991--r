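#' Classify each tested gene's trend direction
#'
#' The first re-parametrized coefficient measures the linear trend in
#' pseudotime, so its sign says whether a gene's expression generally
#' rises or falls along the trajectory. Genes with a positive `logFC.Z1`
#' are labelled `Up`, all others (including exactly zero) `Down`.
#'
#' @param result tibble from [ql_f_test()] containing a `logFC.Z1` column.
#' @return `result` with an added `trend` column.
#' @export
classify_trend <- function(result) {
  if (!"logFC.Z1" %in% names(result))
    abort("`result` must contain a logFC.Z1 column.")
  out <- dplyr::mutate(result,
                       trend = ifelse(.data$logFC.Z1 > 0, "Up", "Down"))
  attr(out, "tested_coefs") <- attr(result, "tested_coefs")
  out
}

#' Fitted expression curves along pseudotime
#'
#' Predicts each gene's expression at `n_points` evenly spaced pseudotimes
#' spanning the observed range, from a QL fit on the *raw-basis* design
#' `[1, X, stage dummies]` (coefficients on the orthonormalized design are
#' not interpretable for prediction). The linear predictor is the
#' intercept, plus the average stage effect — with the reference stage
#' contributing an implicit zero — plus the spline part evaluated on the
#' prediction grid; it is converted to log2-CPM as
#' `(eta + ln 1e6) / ln 2` (population-level CPM: the library-size offset
#' deliberately does not enter the curve).
#'
#' @param fit_raw a [ql_fit] on `design_raw` from [build_design()].
#' @param design the [build_design()] object (provides the spline basis and
#'   observed pseudotime range).
#' @param genes character vector of gene symbols to predict.
#' @param n_points grid resolution (default 100).
#' @return Tibble with columns `symbol`, `pseudotime`, `log2cpm`.
#' @export
fitted_curves <- function(fit_raw, design, genes, n_points = 100) {
  miss <- setdiff(genes, rownames(fit_raw$coefficients))
  if (length(miss))
    abort(sprintf("Gene(s) absent from fit: %s",
                  paste(head(miss, 5), collapse = ", ")))
  basis <- design$basis
  spline_cols <- paste0("X", seq_len(basis$df))
  group_cols <- setdiff(colnames(fit_raw$design),
                        c("(Intercept)", spline_cols))
  t_obs <- basis$t
  grid <- seq(min(t_obs), max(t_obs), length.out = n_points)
  X_new <- predict(basis, grid)
  purrr::map_dfr(genes, function(g) {
    beta <- fit_raw$coefficients[g, ]
    avg_intercept <- beta["(Intercept)"] +
      mean(c(0, unname(beta[group_cols])))
    eta <- avg_intercept + as.numeric(X_new %*% beta[spline_cols])
    tibble(symbol = g, pseudotime = grid,
           log2cpm = (eta + log(1e6)) / log(2))
  })
}

#' Row-standardized heatmap matrix of top trend genes
#'
#' Stacks the top up-trending genes over the top down-trending genes,
#' orders columns by ascending pseudotime, and standardizes each row to
#' mean 0 and standard deviation 1 (denominator n - 1), the usual display
#' scale for expression heatmaps. Rows with zero variance cannot be
#' standardized and are rejected.
#'
#' @param logcpm genes-by-samples log2-CPM matrix.
#' @param up_genes,down_genes character vectors of gene symbols (typically
#'   the top 20 of each direction).
#' @param pseudotime per-sample pseudotimes used to order columns (default:
#'   current column order).
#' @return The standardized matrix, up block first.
#' @export
heatmap_matrix <- function(logcpm, up_genes, down_genes, pseudotime = NULL) {
  genes <- c(up_genes, down_genes)
  miss <- setdiff(genes, rownames(logcpm))
  if (length(miss))
    abort(sprintf("Gene(s) absent from logcpm: %s",
                  paste(head(miss, 5), collapse = ", ")))
  z <- logcpm[genes, , drop = FALSE]
  if (!is.null(pseudotime)) z <- z[, order(pseudotime), drop = FALSE]
  sds <- apply(z, 1, sd)
  if (any(sds == 0))
    abort(sprintf("Constant row(s) cannot be standardized: %s",
                  paste(head(genes[sds == 0], 5), collapse = ", ")))
  t(scale(t(z)))
}

#' Average expression of a gene set along pseudotime
#'
#' Per-sample unweighted mean log2-CPM over the set members present in the
#' matrix, with a lowess smooth against pseudotime — the standard display
#' for asking whether a pathway as a whole rises or falls along the
#' trajectory.
#'
#' @param logcpm genes-by-samples log2-CPM matrix.
#' @param gene_set character vector of gene symbols.
#' @param pseudotime per-sample pseudotimes (length `ncol(logcpm)`).
#' @param span lowess smoother span (default 2/3).
#' @return Tibble with `sample_id`, `pseudotime`, `avg_log2cpm`,
#'   `smoothed` (lowess values at the observed pseudotimes).
#' @export
geneset_average_trend <- function(logcpm, gene_set, pseudotime, span = 2 / 3) {
  members <- intersect(gene_set, rownames(logcpm))
  if (!length(members)) abort("No gene-set members present in the matrix.")
  avg <- colMeans(logcpm[members, , drop = FALSE])
  sm <- lowess(pseudotime, avg, f = span)
  smoothed <- approx(sm$x, sm$y, xout = pseudotime, rule = 2, ties = mean)$y
  tibble(sample_id = colnames(logcpm) %||% as.character(seq_along(avg)),
         pseudotime = pseudotime, avg_log2cpm = unname(avg),
         smoothed = smoothed)
}
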