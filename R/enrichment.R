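#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then one gene per field.
#' Duplicate members within a set are collapsed. An optional category tag
#' (e.g. `BP`/`CC`/`MF` for gene ontology domains, or `pathway`) can be
#' parsed from the description field when it equals one of
#' `known_categories`.
#'
#' @param path path to a `.gmt` file.
#' @param known_categories descriptions treated as category tags.
#' @return A `geneset_collection`: named list of character vectors with
#'   attributes `description` and `category`.
#' @export
read_gmt <- function(path, known_categories = c("BP", "CC", "MF", "pathway")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort(sprintf("%d malformed GMT line(s).", sum(bad)))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  structure(sets,
            description = setNames(desc, names(sets)),
            category = setNames(
              ifelse(desc %in% known_categories, desc, NA_character_),
              names(sets)),
            class = "geneset_collection")
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors (or a `geneset_collection`).
#' @param path output path.
#' @param description per-set description column (defaults to the stored
#'   descriptions, or the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description") %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Directional over-representation analysis
#'
#' For each gene set and each direction, tests whether the up- (or down-)
#' regulated list overlaps the set more than expected by chance, with a
#' one-sided hypergeometric upper-tail p-value: drawing `|direction list|`
#' genes from a universe of size `|universe|` containing
#' `|set intersected with universe|` set members, the p-value is the
#' probability of an overlap at least as large as observed. Sets are
#' intersected with the universe before testing, so genes outside the
#' analysis cannot inflate enrichment. Raw p-values are reported (each
#' direction is a single planned test per set); pass `adjust = TRUE` for
#' an extra pair of BH columns.
#'
#' @param up,down disjoint character vectors of significant genes, both
#'   subsets of `universe`.
#' @param universe all genes that could have been called (typically the
#'   filtered, identifier-valid genes).
#' @param sets named list of gene sets (or a `geneset_collection`).
#' @param adjust add `FDR.Up`/`FDR.Down` BH columns (default `FALSE`).
#' @return Tibble with `set`, `term`, `category`, `N` (universe members in
#'   the set), `Up`, `Down` (overlap counts), `P.Up`, `P.Down`.
#' @export
directional_ora <- function(up, down, universe, sets, adjust = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) abort("The gene universe is empty.")
  if (length(setdiff(up, universe)) || length(setdiff(down, universe)))
    abort("`up` and `down` must be subsets of `universe`.")
  if (length(intersect(up, down)))
    abort("`up` and `down` must be disjoint.")
  Nu <- length(universe)
  tail_p <- function(overlap, in_set, drawn) {
    if (drawn == 0L || in_set == 0L) return(1)
    phyper(overlap - 1L, in_set, Nu - in_set, drawn, lower.tail = FALSE)
  }
  desc <- attr(sets, "description")
  cat_tag <- attr(sets, "category")
  rows <- purrr::imap_dfr(as.list(sets), function(members, nm) {
    members <- intersect(members, universe)
    n_set <- length(members)
    n_up <- length(intersect(up, members))
    n_down <- length(intersect(down, members))
    tibble(set = nm,
           term = unname(desc[nm] %||% nm),
           category = unname(
             if (is.null(cat_tag)) NA_character_ else cat_tag[nm]),
           N = n_set, Up = n_up, Down = n_down,
           P.Up = tail_p(n_up, n_set, length(up)),
           P.Down = tail_p(n_down, n_set, length(down)))
  })
  if (adjust) {
    rows$FDR.Up <- bh_adjust(rows$P.Up)
    rows$FDR.Down <- bh_adjust(rows$P.Down)
  }
  rows
}

#' Top gene sets by directional enrichment
#'
#' @param rows tibble from [directional_ora()].
#' @param direction `"Up"` or `"Down"`: which direction's p-value to sort
#'   by (ascending).
#' @param n number of rows to return.
#' @param category optional category filter (e.g. `"BP"`).
#' @return The sorted, filtered head of `rows`.
#' @export
top_sets <- function(rows, direction = c("Down", "Up"), n = 10,
                     category = NULL) {
  direction <- match.arg(direction)
  if (!is.null(category))
    rows <- dplyr::filter(rows, .data$category %in% !!category)
  p <- rows[[paste0("P.", direction)]]
  rows[order(p, rows$set), ][seq_len(min(n, nrow(rows))), ]
}
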