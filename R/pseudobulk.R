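#' Pseudo-bulk profile container
#'
#' A `pseudobulk_set` holds a genes-by-pseudobulk integer count matrix plus
#' per-pseudobulk metadata: sample of origin (`group`), `cluster`, mean
#' member-cell `pseudotime`, `cell_number`, `lib_size` (column sum) and a
#' TMM `norm_factor` (1 until [calc_norm_factors()] is run).
#'
#' @param counts genes-by-pseudobulk integer matrix.
#' @param genes gene metadata tibble (`symbol` at least).
#' @param samples pseudobulk metadata tibble with columns `sample_id`,
#'   `group`, `cluster`, `pseudotime`, `cell_number` (and optionally
#'   `lib_size`, `norm_factor`).
#' @return A `pseudobulk_set` object.
#' @export
pseudobulk_set <- function(counts, genes, samples) {
  counts <- as.matrix(counts)
  genes <- as_tibble(genes)
  samples <- as_tibble(samples)
  if (nrow(genes) != nrow(counts) || nrow(samples) != ncol(counts))
    abort("Count matrix dimensions do not match gene/sample metadata.")
  samples$lib_size <- as.numeric(colSums(counts))
  if (!"norm_factor" %in% names(samples))
    samples$norm_factor <- rep(1, ncol(counts))
  rownames(counts) <- genes$symbol
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, genes = genes, samples = samples),
            class = "pseudobulk_set")
}

#' @export
#' @method print pseudobulk_set
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("pseudobulk_set: %d genes x %d pseudo-bulk samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$samples, n = 6)
  invisible(x)
}

#' @export
dim.pseudobulk_set <- function(x) dim(x$counts)

#' Subset a pseudobulk_set
#' @param x a `pseudobulk_set`.
#' @param i gene index.
#' @param j pseudobulk sample index.
#' @param ... unused.
#' @export
`[.pseudobulk_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$genes$symbol)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  samples <- x$samples[j, , drop = FALSE]
  counts <- x$counts[i, j, drop = FALSE]
  samples$lib_size <- as.numeric(colSums(counts))
  structure(list(counts = counts, genes = x$genes[i, , drop = FALSE],
                 samples = samples),
            class = "pseudobulk_set")
}

#' Aggregate annotated cells into pseudo-bulk profiles
#'
#' Sums read counts over all cells sharing a (sample, cluster) combination,
#' yielding one pseudo-bulk column per observed combination, named
#' `<sample>_C<cluster>`. Each pseudo-bulk sample records the number of
#' member cells and the arithmetic mean (optionally median) of their
#' pseudotimes; replicate-level variation between pseudo-bulk samples is
#' what makes bulk-style inference possible downstream. Cells with
#' non-finite pseudotime (unreachable on the trajectory) must be removed by
#' the caller first: they are refused, not silently dropped.
#'
#' @param counts a [cell_counts] object.
#' @param annot per-cell annotation tibble with columns `barcode`, `sample`,
#'   `cluster`, `pseudotime` (and optionally `doublet`); every cell in
#'   `counts` must be annotated.
#' @param summarise_pseudotime `"mean"` (default) or `"median"`.
#' @param order_by_pseudotime sort the resulting columns by ascending
#'   pseudotime (stable for ties; default `TRUE`).
#' @return A [pseudobulk_set].
#' @export
aggregate_cells <- function(counts, annot, summarise_pseudotime = c("mean", "median"),
                            order_by_pseudotime = TRUE) {
  summarise_pseudotime <- match.arg(summarise_pseudotime)
  annot <- as_tibble(annot)
  idx <- match(counts$cells$barcode, annot$barcode)
  if (anyNA(idx))
    abort(sprintf("%d cells have no annotation row.", sum(is.na(idx))))
  annot <- annot[idx, , drop = FALSE]
  bad <- !is.finite(annot$pseudotime)
  if (any(bad))
    abort(sprintf(
      "%d cells have non-finite pseudotime; remove them before aggregating.",
      sum(bad)))
  key <- paste0(annot$sample, "_C", annot$cluster)
  lev <- unique(key)
  fk <- factor(key, levels = lev)
  # genes x cells %*% cells x groups indicator does the group sums at once
  ind <- Matrix::sparseMatrix(i = seq_along(fk), j = as.integer(fk), x = 1,
                              dims = c(length(fk), length(lev)))
  agg <- as.matrix(counts$counts %*% ind)
  stat <- if (summarise_pseudotime == "mean") mean else median
  meta <- tibble(sample_id = lev,
                 group = as.character(tapply(annot$sample, fk,
                                             function(v) v[1])[lev]),
                 cluster = as.character(tapply(as.character(annot$cluster),
                                               fk, function(v) v[1])[lev]),
                 pseudotime = as.numeric(tapply(annot$pseudotime, fk, stat)[lev]),
                 cell_number = as.integer(table(fk)[lev]))
  pb <- pseudobulk_set(agg, counts$genes, meta)
  if (order_by_pseudotime) pb <- pb[, order(pb$samples$pseudotime)]
  pb
}

#' Drop pseudo-bulk samples built from few cells
#'
#' Pseudo-bulk samples assembled from a handful of cells carry unstable
#' expression profiles; samples are kept only when `cell_number` is
#' strictly greater than `min_cells` (so the default keeps samples with 31+
#' cells).
#'
#' @param pb a [pseudobulk_set].
#' @param min_cells strict lower bound on member cells.
#' @param verbose report how many samples were removed.
#' @return A filtered [pseudobulk_set].
#' @export
filter_small <- function(pb, min_cells = 30, verbose = TRUE) {
  keep <- pb$samples$cell_number > min_cells
  if (!any(keep)) abort("filter_small removed every pseudo-bulk sample.")
  if (verbose)
    message(sprintf("filter_small: removed %d of %d pseudo-bulk samples.",
                    sum(!keep), length(keep)))
  pb[, keep]
}

#' Remove genes with too few counts to analyse
#'
#' Keeps genes achieving a counts-per-million of at least
#' `min_count / median(lib_size) * 1e6` in at least `k` samples, where `k`
#' is the size of the smallest design group, and whose total count across
#' samples is at least `min_total`. Library sizes are recomputed after
#' filtering.
#'
#' @param pb a [pseudobulk_set].
#' @param min_count count a gene should reach in `k` samples (at the median
#'   library size).
#' @param min_total minimum total count across all samples.
#' @param group optional factor/character of design groups (defaults to the
#'   `group` column, the sample-stage blocking factor).
#' @return A filtered [pseudobulk_set].
#' @export
filter_genes <- function(pb, min_count = 10, min_total = 15, group = NULL) {
  lib <- pb$samples$lib_size
  group <- group %||% pb$samples$group
  k <- min(table(group))
  cpm_cutoff <- min_count / median(lib) * 1e6
  cpm <- t(t(pb$counts) / lib * 1e6)
  tol <- 1e-14
  keep <- rowSums(cpm >= cpm_cutoff) >= (k - tol) &
    rowSums(pb$counts) >= (min_total - tol)
  if (!any(keep)) warn("filter_genes kept zero genes.")
  pb[keep, ]
}

# Doubly trimmed weighted mean of M-values for one (obs, ref) library pair.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, sum_trim = 0.05) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (!length(M) || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  2^f
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors. The reference library
#' is the one whose 75th-percentile count fraction is closest to the mean of
#' those fractions; every other library is compared with it pairwise. Genes
#' with a zero count in either library are excluded; the per-pair factor is
#' a doubly trimmed (30% on M = log2 ratios, 5% on A = average abundance)
#' weighted mean of M, with inverse asymptotic binomial variances as
#' weights. Factors are rescaled so their geometric mean is 1, leaving the
#' overall scale of the data untouched.
#'
#' @param pb a [pseudobulk_set] (or a bare count matrix).
#' @param logratio_trim fraction trimmed from each tail of M.
#' @param sum_trim fraction trimmed from each tail of A.
#' @return Numeric vector of positive per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(pb, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- if (inherits(pb, "pseudobulk_set")) pb$counts else as.matrix(pb)
  if (ncol(counts) < 2) abort("TMM needs at least two samples.")
  lib <- colSums(counts)
  if (any(lib == 0)) abort("A sample has all-zero counts.")
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) quantile(counts[, j], 0.75) / lib[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    logratio_trim, sum_trim)
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Attach TMM normalization factors to a pseudobulk_set
#' @param pb a [pseudobulk_set].
#' @inheritParams tmm_factors
#' @return `pb` with `samples$norm_factor` filled in.
#' @export
calc_norm_factors <- function(pb, logratio_trim = 0.3, sum_trim = 0.05) {
  pb$samples$norm_factor <- unname(tmm_factors(pb, logratio_trim, sum_trim))
  pb
}

effective_lib_size <- function(pb) pb$samples$lib_size * pb$samples$norm_factor

#' Log2 counts per million
#'
#' Computes `log2((count + prior_j) / (L_j + 2 * prior_j) * 1e6)` where
#' `L_j` is the effective library size (library size times TMM factor) and
#' `prior_j` is `prior_count` scaled proportionally to `L_j / mean(L)`, so
#' that the prior represents the same fraction of every library.
#'
#' @param pb a [pseudobulk_set].
#' @param prior_count positive prior count (average across samples).
#' @return Dense genes-by-samples matrix of log2-CPM values.
#' @export
log_cpm <- function(pb, prior_count = 2) {
  if (prior_count <= 0) abort("`prior_count` must be positive.")
  L <- effective_lib_size(pb)
  prior <- prior_count * L / mean(L)
  lcpm <- log2(t((t(pb$counts) + prior) / (L + 2 * prior)) * 1e6)
  dimnames(lcpm) <- dimnames(pb$counts)
  lcpm
}

#' Average log2-CPM abundance per gene
#'
#' Pooled-count abundance on the log2-CPM scale, used to order genes for
#' dispersion-trend estimation and reported as `logCPM` in test tables.
#'
#' @param pb a [pseudobulk_set].
#' @param prior_count prior count (total across 2 pooled pseudo-samples).
#' @return Numeric vector, one value per gene.
#' @export
ave_log_cpm <- function(pb, prior_count = 2) {
  L <- sum(effective_lib_size(pb))
  as.numeric(log2((rowSums(pb$counts) + 2 * prior_count) /
                    (L + 4 * prior_count) * 1e6))
}

#' MDS on leading log-fold-change distances
#'
#' For every sample pair, the distance is the root-mean-square of the `top`
#' largest absolute log2-CPM differences between the two samples (the
#' "leading log fold change"), so each pair is compared on the genes that
#' most distinguish it. Classical (Torgerson) metric scaling of the
#' resulting distance matrix gives the plotted coordinates.
#'
#' @param logcpm genes-by-samples log2-CPM matrix (from [log_cpm()]).
#' @param top number of top genes per pair (clamped to the gene count,
#'   with a warning, when larger).
#' @param ndim number of dimensions to return.
#' @return A tibble with `sample_id` and `dim1..dimk` columns; the distance
#'   matrix is attached as attribute `"distances"`.
#' @export
mds_leading_logfc <- function(logcpm, top = 500, ndim = 2) {
  ns <- ncol(logcpm)
  if (top > nrow(logcpm)) {
    warn(sprintf("`top` (%d) exceeds gene count (%d); clamped.",
                 top, nrow(logcpm)))
    top <- nrow(logcpm)
  }
  dd <- matrix(0, ns, ns, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (i in seq_len(ns - 1)) for (j in seq((i + 1), ns)) {
    d2 <- sort((logcpm[, i] - logcpm[, j])^2, decreasing = TRUE)[seq_len(top)]
    dd[i, j] <- dd[j, i] <- sqrt(mean(d2))
  }
  xy <- cmdscale(stats::as.dist(dd), k = ndim)
  out <- as_tibble(as.data.frame(xy), .name_repair = ~ paste0("dim", seq_len(ndim)))
  out <- dplyr::bind_cols(tibble(sample_id = colnames(logcpm)), out)
  attr(out, "distances") <- dd
  out
}
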