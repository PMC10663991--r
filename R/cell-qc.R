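#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of expressed genes (count > 0), the
#' library size (total reads) and the percentage of reads mapping to
#' mitochondrial genes, identified by a symbol prefix (`"mt-"` for mouse,
#' `"MT-"` for human references).
#'
#' @param counts a [cell_counts] object.
#' @param mito_prefix symbol prefix marking mitochondrial genes.
#' @return A tibble with columns `barcode`, `sample`, `n_expressed_genes`,
#'   `lib_size`, `mito_pct` (0 for empty cells).
#' @export
compute_qc <- function(counts, mito_prefix = "mt-") {
  m <- counts$counts
  lib <- Matrix::colSums(m)
  nexp <- Matrix::colSums(m > 0)
  mito <- startsWith(counts$genes$symbol, mito_prefix)
  if (!any(mito)) {
    warn(sprintf("No gene symbols start with '%s'; mito_pct is all zero.",
                 mito_prefix))
    mt <- rep(0, ncol(m))
  } else {
    mt <- Matrix::colSums(m[mito, , drop = FALSE])
  }
  tibble(barcode = counts$cells$barcode,
         sample = counts$cells$sample,
         n_expressed_genes = as.integer(nexp),
         lib_size = as.integer(round(lib)),
         mito_pct = as.numeric(ifelse(lib > 0, 100 * mt / lib, 0)))
}

#' Basic gene/cell presence filter
#'
#' Within each sample, drops genes expressed in fewer than `min_cells` cells
#' and then cells expressing fewer than `min_features` genes (gene filter
#' first, per sample). Multi-sample objects are filtered per sample and the
#' per-sample results merged on common genes.
#'
#' @param counts a [cell_counts] object.
#' @param min_cells minimum number of cells a gene must be expressed in.
#' @param min_features minimum number of expressed genes per retained cell.
#' @return A filtered [cell_counts] object.
#' @export
basic_filter <- function(counts, min_cells = 3, min_features = 200) {
  one <- function(x) {
    keep_g <- Matrix::rowSums(x$counts > 0) >= min_cells
    x <- x[keep_g, ]
    keep_c <- Matrix::colSums(x$counts > 0) >= min_features
    if (!any(keep_c))
      abort("basic_filter removed every cell; lower `min_features`.")
    x[, keep_c]
  }
  samples <- unique(counts$cells$sample)
  if (length(samples) == 1L) return(one(counts))
  parts <- lapply(samples, function(s) one(counts[, counts$cells$sample == s]))
  merge_samples(parts)
}

#' Threshold-based cell QC filter
#'
#' Keeps cells with `min_genes < n_expressed_genes < max_genes[sample]`,
#' `mito_pct < max_mito`, and — when a doublet flag is supplied — only
#' `"singlet"` cells. All three thresholds are strict inequalities, so a
#' cell with exactly `min_genes` expressed genes or exactly `max_mito`
#' percent mitochondrial reads is removed. The upper gene-count bound is
#' per-sample, since what counts as "suspiciously many genes" depends on
#' each sample's depth.
#'
#' @param counts a [cell_counts] object.
#' @param metrics QC tibble from [compute_qc()] on (a superset of) the same
#'   cells; recomputed rows are matched by barcode.
#' @param min_genes lower bound on expressed genes (strict).
#' @param max_genes named vector/list mapping every sample to its upper
#'   bound on expressed genes (strict), or a single unnamed number applied
#'   to all samples.
#' @param max_mito upper bound on mitochondrial read percentage (strict).
#' @param doublet_flag optional character vector aligned with `metrics`
#'   rows (values such as `"singlet"`/`"doublet"`); non-singlets are
#'   removed.
#' @return A filtered [cell_counts] object.
#' @export
qc_filter <- function(counts, metrics, min_genes = 500, max_genes,
                      max_mito = 10, doublet_flag = NULL) {
  samples <- unique(counts$cells$sample)
  if (length(max_genes) == 1L && is.null(names(max_genes)))
    max_genes <- setNames(rep(as.numeric(max_genes), length(samples)), samples)
  missing_s <- setdiff(samples, names(max_genes))
  if (length(missing_s))
    abort(sprintf("No max_genes threshold for sample(s): %s",
                  paste(missing_s, collapse = ", ")))
  idx <- match(counts$cells$barcode, metrics$barcode)
  if (anyNA(idx)) abort("Some cells are missing from `metrics`.")
  nexp <- metrics$n_expressed_genes[idx]
  mito <- metrics$mito_pct[idx]
  upper <- unlist(max_genes)[counts$cells$sample]
  keep <- nexp > min_genes & nexp < upper & mito < max_mito
  if (!is.null(doublet_flag)) {
    flag <- doublet_flag[idx]
    keep <- keep & (is.na(flag) | flag == "singlet")
  }
  if (!any(keep)) abort("qc_filter removed every cell.")
  counts[, keep]
}

#' Cluster-by-sample cell proportions
#'
#' Converts a cluster-by-sample (or stage-by-cluster) cell count table into
#' row percentages, the standard composition diagnostic for comparing cell
#' type proportions across developmental stages.
#'
#' @param counts_table data frame or matrix of cell counts with groups in
#'   rows and clusters in columns (a `group` column, if present, is used
#'   for row names).
#' @param digits rounding applied to the percentages (default 2).
#' @return A tibble with `group` plus one percentage column per cluster.
#' @export
cluster_proportions <- function(counts_table, digits = 2) {
  tab <- as.data.frame(counts_table)
  grp <- if ("group" %in% names(tab)) {
    g <- tab$group; tab$group <- NULL; g
  } else rownames(tab)
  m <- as.matrix(tab)
  pct <- round(100 * m / rowSums(m), digits)
  dplyr::bind_cols(tibble(group = grp), as_tibble(as.data.frame(pct)))
}
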