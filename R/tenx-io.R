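#' Single-cell count container
#'
#' A `cell_counts` object holds a sparse genes-by-cells matrix of UMI counts
#' together with gene metadata (Ensembl id, symbol, optional Entrez id) and
#' cell metadata (barcode, sample of origin). All entries are non-negative
#' integers; within one object gene symbols are unique (first occurrence kept
#' at construction) and `(sample, barcode)` pairs are unique.
#'
#' @param counts sparse or dense genes-by-cells matrix of non-negative
#'   integer counts.
#' @param genes data frame with at least a `symbol` column; `ensembl_id` and
#'   `entrez_id` are carried when present.
#' @param cells data frame with `barcode` and `sample` columns.
#' @param dedup_symbols keep only the first row for each repeated symbol
#'   (default `TRUE`).
#'
#' @return A `cell_counts` object.
#' @export
cell_counts <- function(counts, genes, cells, dedup_symbols = TRUE) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  genes <- as_tibble(genes)
  cells <- as_tibble(cells)
  if (!"symbol" %in% names(genes)) abort("`genes` must have a `symbol` column.")
  if (!"ensembl_id" %in% names(genes)) genes$ensembl_id <- genes$symbol
  if (!all(c("barcode", "sample") %in% names(cells)))
    abort("`cells` must have `barcode` and `sample` columns.")
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts))
    abort("Count matrix dimensions do not match gene/cell metadata.")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    abort("Counts must be non-negative integers.")
  if (any(genes$symbol == "" | is.na(genes$symbol)))
    abort("Gene symbols must be non-empty.")
  if (dedup_symbols && anyDuplicated(genes$symbol)) {
    keep <- !duplicated(genes$symbol)
    counts <- counts[keep, , drop = FALSE]
    genes <- genes[keep, , drop = FALSE]
  }
  if (anyDuplicated(paste(cells$sample, cells$barcode, sep = "\r")))
    abort("Duplicated (sample, barcode) pairs in cell metadata.")
  rownames(counts) <- genes$symbol
  colnames(counts) <- cells$barcode
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "cell_counts")
}

#' @export
#' @method print cell_counts
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d genes x %d cells (%d sample%s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$sample)),
              if (length(unique(x$cells$sample)) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' Subset a cell_counts object
#'
#' @param x a `cell_counts` object.
#' @param i gene index (integer, logical or symbol character).
#' @param j cell index (integer, logical or barcode character).
#' @param ... unused.
#' @export
`[.cell_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$genes$symbol)
  if (is.character(j)) j <- match(j, x$cells$barcode)
  structure(list(counts = x$counts[i, j, drop = FALSE],
                 genes = x$genes[i, , drop = FALSE],
                 cells = x$cells[j, , drop = FALSE]),
            class = "cell_counts")
}

read_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a 10x-style sparse count triplet
#'
#' Reads a MatrixMarket coordinate matrix (optionally gzip'd; 1-based indices
#' on disk, as the format prescribes) together with its barcode and feature
#' TSV files into a [cell_counts] object. Feature files with two columns
#' (id, symbol) or three or more columns (id, symbol, type, ...) are both
#' accepted; extra columns are ignored, so mixtures of older and newer
#' reference builds read uniformly. Barcodes are prefixed with
#' `<sample_label>-` so that cells stay globally unique after merging
#' multiple samples, and repeated gene symbols are reduced to their first
#' occurrence.
#'
#' @param matrix_path path to the `.mtx`/`.mtx.gz` file.
#' @param barcodes_path path to the barcode TSV (one barcode per line).
#' @param features_path path to the feature TSV (>= 2 columns: id, symbol).
#' @param sample_label sample name recorded for every cell and used as the
#'   barcode prefix.
#'
#' @return A [cell_counts] object.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulate_cells(sim_config(n_genes = 50, cells_per_cluster = 5, seed = 1))
#' paths <- write_tenx_triplet(sim$counts, dir)
#' y <- read_mtx_triplet(paths$matrix, paths$barcodes, paths$features, "S1")
#' dim(y)
#' @export
read_mtx_triplet <- function(matrix_path, barcodes_path, features_path,
                             sample_label) {
  con <- read_maybe_gz(matrix_path)
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  m <- Matrix::readMM(con)
  if (length(m@x) && any(m@x != round(m@x)))
    abort("Matrix file contains non-integer entries.")
  barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  features <- readr::read_tsv(features_path, col_names = FALSE,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  if (ncol(features) < 2)
    abort("Feature file must have at least two columns (id, symbol).")
  if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m))
    abort(sprintf(paste0("Matrix header (%d x %d) does not match features ",
                         "(%d) / barcodes (%d)."),
                  nrow(m), ncol(m), nrow(features), nrow(barcodes)))
  genes <- tibble(ensembl_id = features[[1]], symbol = features[[2]])
  cells <- tibble(barcode = paste0(sample_label, "-", barcodes[[1]]),
                  sample = sample_label)
  cell_counts(m, genes, cells)
}

#' Merge per-sample count objects on their common genes
#'
#' Takes the ordered intersection of gene symbols across objects (first
#' object's order) and concatenates cells in input order. Each retained
#' gene's per-cell counts are untouched.
#'
#' @param objects list of [cell_counts] objects (each symbol-de-duplicated).
#' @return A single [cell_counts] object.
#' @export
merge_samples <- function(objects) {
  if (!length(objects)) abort("Need at least one object to merge.")
  objects <- lapply(objects, function(o) {
    if (!inherits(o, "cell_counts")) abort("All inputs must be cell_counts.")
    if (anyDuplicated(o$genes$symbol))
      o <- cell_counts(o$counts, o$genes, o$cells)
    o
  })
  if (length(objects) == 1L) return(objects[[1L]])
  common <- Reduce(intersect, lapply(objects, function(o) o$genes$symbol))
  if (!length(common)) {
    for (k in seq_along(objects)[-1]) {
      if (!length(intersect(objects[[1]]$genes$symbol,
                            objects[[k]]$genes$symbol)))
        abort(sprintf("Objects 1 and %d share no gene symbols.", k))
    }
    abort("Gene symbol intersection across objects is empty.")
  }
  parts <- lapply(objects, function(o) o[common, ])
  structure(list(counts = do.call(cbind, lapply(parts, function(o) o$counts)),
                 genes = parts[[1]]$genes,
                 cells = dplyr::bind_rows(lapply(parts, function(o) o$cells))),
            class = "cell_counts")
}

#' Write a tabular result as TSV
#'
#' Deterministic column order (as given), header line, UTF-8, no quoting of
#' numerics. Used for every tabular artifact the pipeline emits.
#'
#' @param rows data frame to write (non-empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    abort("`rows` must be a non-empty data frame.")
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path file path.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Write a cell_counts object as a 10x-style triplet
#'
#' Emits `matrix.mtx.gz`, `barcodes.tsv.gz` and `features.tsv.gz` under
#' `dir`. Barcodes are written without their sample prefix when
#' `strip_prefix` is set, so a write/read round trip through
#' [read_mtx_triplet()] reproduces the object.
#'
#' @param x a [cell_counts] object (single sample for faithful round trips).
#' @param dir output directory (created if needed).
#' @param strip_prefix drop a leading `<sample>-` from barcodes before
#'   writing (default `TRUE`).
#' @return Named list of the three file paths.
#' @export
write_tenx_triplet <- function(x, dir, strip_prefix = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(x$counts, mtx)
  mtx_gz <- paste0(mtx, ".gz")
  if (file.exists(mtx_gz)) file.remove(mtx_gz)
  con_in <- file(mtx, "rb"); con_out <- gzfile(mtx_gz, "wb")
  writeBin(readBin(con_in, "raw", file.info(mtx)$size), con_out)
  close(con_in); close(con_out); file.remove(mtx)
  bc <- x$cells$barcode
  if (strip_prefix) bc <- sub("^[^-]*-", "", bc)
  bc_path <- file.path(dir, "barcodes.tsv.gz")
  readr::write_tsv(tibble(x = bc), bc_path, col_names = FALSE, progress = FALSE)
  ft <- x$genes
  ft_path <- file.path(dir, "features.tsv.gz")
  readr::write_tsv(tibble(id = ft$ensembl_id, symbol = ft$symbol,
                          type = "Gene Expression"),
                   ft_path, col_names = FALSE, progress = FALSE)
  list(matrix = mtx_gz, barcodes = bc_path, features = ft_path)
}
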