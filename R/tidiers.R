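#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-gene (or per-sample)
#' table of a fitted object as a tibble, `glance()` a one-row model
#' summary.
#'
#' @param x a fitted pseudotempo object.
#' @param ... unused.
#' @name tidy_pseudotempo
NULL

#' @rdname tidy_pseudotempo
#' @export
tidy.dispersion_fit <- function(x, ...) x$gene

#' @rdname tidy_pseudotempo
#' @export
glance.dispersion_fit <- function(x, ...) {
  tibble(common_dispersion = x$common, common_bcv = sqrt(x$common),
         n_genes = nrow(x$gene), n_bins = nrow(x$bins),
         prior_n = x$prior_n)
}

#' @rdname tidy_pseudotempo
#' @export
tidy.ql_fit <- function(x, ...) {
  coefs <- as_tibble(as.data.frame(x$coefficients))
  dplyr::bind_cols(tibble(symbol = x$genes$symbol), coefs) |>
    tidyr::pivot_longer(-"symbol", names_to = "term",
                        values_to = "estimate") |>
    dplyr::mutate(log2_estimate = .data$estimate / log(2))
}

#' @rdname tidy_pseudotempo
#' @export
glance.ql_fit <- function(x, ...) {
  fin <- x$prior_df[is.finite(x$prior_df)]
  tibble(n_genes = nrow(x$coefficients),
         n_coefficients = ncol(x$coefficients),
         residual_df = median(x$df_resid),
         prior_df = if (length(fin)) median(fin) else Inf,
         robust = x$robust)
}

#' @rdname tidy_pseudotempo
#' @export
tidy.pseudobulk_set <- function(x, ...) x$samples

#' @rdname tidy_pseudotempo
#' @export
glance.pseudobulk_set <- function(x, ...) {
  tibble(n_genes = nrow(x$counts), n_samples = ncol(x$counts),
         total_counts = sum(x$samples$lib_size),
         pseudotime_min = min(x$samples$pseudotime),
         pseudotime_max = max(x$samples$pseudotime))
}
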