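## Reference metadata from the mouse mammary gland development atlas
## (10x scRNA-seq of epithelial cells at five developmental stages;
## GEO accessions GSE103275 and GSE164017). Shipped as constants so the
## worked examples and checks run fully offline.

#' Pseudo-bulk sample metadata for the mammary gland development atlas
#'
#' Per-pseudo-bulk metadata of the 29 sample-by-cluster pseudo-bulk
#' profiles built from epithelial cells of five mouse mammary gland
#' developmental stages (E18.5 epithelium, P5, pre-puberty, puberty,
#' adult; GEO GSE103275/GSE164017), ordered by average pseudotime:
#' library size, mean member-cell pseudotime along the epithelial
#' trajectory, and number of member cells. Seven of the 29 profiles were
#' assembled from 30 or fewer cells and are removed by
#' [filter_small()] with its defaults.
#'
#' @return Tibble with columns `sample_id`, `group`, `cluster`,
#'   `lib_size`, `pseudotime`, `cell_number`.
#' @export
mammary_pseudobulk_info <- function() {
  tb <- tibble::tribble(
    ~sample_id,        ~lib_size, ~pseudotime, ~cell_number,
    "Pre-puberty_C1",   11886898,        4.65,        1590L,
    "Adult_C1",          9285265,        4.77,        2495L,
    "P5_C1",             2680089,        6.41,         347L,
    "Puberty_C1",        3112796,        6.48,         986L,
    "E18.5-epi_C1",      8084434,       10.16,         878L,
    "E18.5-epi_C5",         5179,       15.61,           3L,
    "P5_C5",               24491,       15.61,           3L,
    "Pre-puberty_C5",      57834,       15.61,           6L,
    "Puberty_C5",          12278,       15.61,           6L,
    "Adult_C4",           204212,       19.25,          32L,
    "E18.5-epi_C4",     11725731,       19.31,         921L,
    "P5_C4",             1917228,       19.68,         120L,
    "Puberty_C4",        1860770,       19.72,         265L,
    "Pre-puberty_C4",     289370,       22.10,          23L,
    "E18.5-epi_C3",     15806768,       28.03,        2341L,
    "Puberty_C2",        5841364,       28.62,        1535L,
    "P5_C3",             3862152,       28.94,         351L,
    "E18.5-epi_C2",       167242,       29.14,          29L,
    "Adult_C2",          8320630,       29.66,        2362L,
    "P5_C2",              347365,       29.67,          47L,
    "Pre-puberty_C2",    4625160,       30.51,         482L,
    "Puberty_C3",          63722,       31.73,          20L,
    "Pre-puberty_C3",    1432336,       32.64,          64L,
    "Adult_C3",           997670,       33.99,         171L,
    "Pre-puberty_C0",    6024872,       38.90,         381L,
    "E18.5-epi_C0",       990670,       39.64,         171L,
    "Adult_C0",         27621462,       40.44,        4281L,
    "P5_C0",             3113053,       40.68,         272L,
    "Puberty_C0",        8806924,       41.09,        1894L)
  tb$group <- sub("_C\\d+$", "", tb$sample_id)
  tb$cluster <- sub("^.*_C", "", tb$sample_id)
  tb[, c("sample_id", "group", "cluster", "lib_size", "pseudotime",
         "cell_number")]
}

#' Stage-by-cluster cell counts for the mammary gland development atlas
#'
#' Number of cells per integrated cluster (0-5) in each of the five
#' developmental stages. Clusters correspond to mature luminal (0), basal
#' (1), luminal progenitor (2), luminal intermediate (3), cycling (4) and
#' residual stromal (5) populations.
#'
#' @return Tibble with a `group` column and one count column per cluster.
#' @export
mammary_cluster_counts <- function() {
  tibble::tribble(
    ~group,        ~`0`,  ~`1`,  ~`2`,  ~`3`, ~`4`, ~`5`,
    "E18.5-epi",   171L,  878L,   29L, 2341L, 921L,  3L,
    "P5",          272L,  347L,   47L,  351L, 120L,  3L,
    "Pre-puberty", 381L, 1590L,  482L,   64L,  23L,  6L,
    "Puberty",    1894L,  986L, 1535L,   20L, 265L,  6L,
    "Adult",      4281L, 2495L, 2362L,  171L,  32L,  0L)
}

#' Retained pseudotime vector presets
#'
#' Named pseudotime vectors usable as the time axis of
#' [simulate_pseudobulk()]. The `"mammary"` preset is the 22 mean
#' pseudotimes of the pseudo-bulk samples retained by [filter_small()] in
#' the mammary gland development atlas.
#'
#' @param preset preset name (currently `"mammary"`).
#' @return Named numeric vector of pseudotimes with attribute `"group"`
#'   giving the originating stage of each sample.
#' @export
pseudotime_preset <- function(preset = "mammary") {
  if (!identical(preset, "mammary"))
    abort(sprintf("Unknown pseudotime preset '%s'.", preset))
  info <- mammary_pseudobulk_info()
  info <- info[info$cell_number > 30, ]
  out <- setNames(info$pseudotime, info$sample_id)
  attr(out, "group") <- factor(info$group,
                               levels = c("E18.5-epi", "P5", "Pre-puberty",
                                          "Puberty", "Adult"))
  out
}
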