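#' Configuration for the trajectory simulator
#'
#' Defines the synthetic study the generator emulates: five biological
#' samples (developmental stages) whose cells sit in overlapping cluster
#' windows along a single trajectory, genes with spline-shaped pseudotime
#' trends, per-sample multiplicative effects, negative-binomial counting
#' noise, mitochondrial content, doublets and a small dead-cell
#' population.
#'
#' @param n_samples number of biological samples (stages).
#' @param n_clusters clusters per sample, laid out along the trajectory.
#' @param cells_per_cluster cells in each (sample, cluster) combination.
#' @param n_genes number of genes.
#' @param trend_fraction fraction of genes given a pseudotime trend (split
#'   evenly between increasing and decreasing).
#' @param effect_size total natural-log fold change of a trend gene across
#'   the trajectory.
#' @param trend_shapes shape pool for trend genes: `"linear"`,
#'   `"sigmoid"`, `"smoothstep"` curves of pseudotime.
#' @param sample_effect_sd SD (natural-log scale) of per-gene, per-sample
#'   multiplicative effects — the replicate-level biological variation.
#' @param dispersion_shape,dispersion_mean gamma distribution of per-gene
#'   cell-level NB dispersions.
#' @param lib_meanlog,lib_sdlog log-normal cell library-size parameters.
#' @param t_max trajectory length (pseudotime units).
#' @param n_mito number of mitochondrial (`mt-` prefixed) genes.
#' @param mito_fraction expected mitochondrial read fraction of a healthy
#'   cell.
#' @param dead_rate fraction of cells simulated as dead/damaged.
#' @param dead_mito_fraction mitochondrial read fraction of dead cells
#'   (above the usual 10% QC cut by construction).
#' @param doublet_rate fraction of extra barcodes formed by summing two
#'   parent cells.
#' @param seed mandatory integer seed.
#' @return A `sim_config` list (validated).
#' @export
sim_config <- function(n_samples = 5, n_clusters = 4, cells_per_cluster = 60,
                       n_genes = 2000, trend_fraction = 0.1,
                       effect_size = 2.5,
                       trend_shapes = c("linear", "sigmoid", "smoothstep"),
                       sample_effect_sd = 0.1,
                       dispersion_shape = 2, dispersion_mean = 0.1,
                       lib_meanlog = log(10000), lib_sdlog = 0.4,
                       t_max = 40, n_mito = 10, mito_fraction = 0.05,
                       dead_rate = 0.02, dead_mito_fraction = 0.3,
                       doublet_rate = 0.05, seed = NULL) {
  if (is.null(seed)) abort("`seed` is mandatory for reproducibility.")
  cfg <- list(n_samples = n_samples, n_clusters = n_clusters,
              cells_per_cluster = cells_per_cluster, n_genes = n_genes,
              trend_fraction = trend_fraction, effect_size = effect_size,
              trend_shapes = trend_shapes,
              sample_effect_sd = sample_effect_sd,
              dispersion_shape = dispersion_shape,
              dispersion_mean = dispersion_mean,
              lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
              t_max = t_max, n_mito = n_mito,
              mito_fraction = mito_fraction, dead_rate = dead_rate,
              dead_mito_fraction = dead_mito_fraction,
              doublet_rate = doublet_rate, seed = as.integer(seed))
  rates <- c("trend_fraction", "mito_fraction", "dead_rate",
             "dead_mito_fraction", "doublet_rate")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1)
      abort(sprintf("`%s` must be in [0, 1].", r))
  }
  if (cfg$n_genes <= cfg$n_mito) abort("`n_genes` must exceed `n_mito`.")
  if (min(n_samples, n_clusters, cells_per_cluster) < 1)
    abort("Counts in the configuration must be positive.")
  structure(cfg, class = "sim_config")
}

trend_shape_fun <- function(shape) {
  switch(shape,
         linear = function(u) u,
         sigmoid = function(u) 1 / (1 + exp(-8 * (u - 0.5))),
         smoothstep = function(u) u^2 * (3 - 2 * u),
         abort(sprintf("Unknown trend shape '%s'.", shape)))
}

#' Simulate annotated single cells along one trajectory
#'
#' Draws cell pseudotimes from overlapping per-cluster windows on
#' `[0, t_max]`; gene means are
#' `mu_gc = L_c * p_gc` with `p_gc` proportional to
#' `base_g * exp(f_g(t_c) + s_{g, sample(c)})`, where `f_g` is the gene's
#' trend curve (zero for null genes) and `s` the per-sample effect; counts
#' are NB with per-gene dispersion. Dead cells get inflated mitochondrial
#' content; doublet barcodes are the sums of two sampled parents and are
#' flagged in the annotation (emulating an upstream doublet predictor).
#'
#' @param config a [sim_config].
#' @return List with `counts` (a [cell_counts]), `annotation` (tibble:
#'   `barcode`, `sample`, `cluster`, `pseudotime`, `doublet`) and `truth`
#'   (list of `gene` and `cell` tibbles).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  symbols <- c(paste0("mt-", seq_len(config$n_mito)),
               sprintf("Gene%04d", seq_len(G - config$n_mito)))
  is_mito <- startsWith(symbols, "mt-")

  base <- exp(rnorm(G, 0, 1.25))
  # pin the expected mitochondrial fraction of a healthy cell
  base[is_mito] <- sum(base[!is_mito]) *
    config$mito_fraction / (1 - config$mito_fraction) / config$n_mito

  n_trend <- round(config$trend_fraction * G)
  trendable <- which(!is_mito)
  trend_genes <- sample(trendable, min(n_trend, length(trendable)))
  direction <- rep(c(1, -1), length.out = length(trend_genes))
  shapes <- sample(config$trend_shapes, length(trend_genes), replace = TRUE)
  gene_truth <- tibble(symbol = symbols,
                       trend = "null", effect = 0, shape = NA_character_,
                       dispersion = rgamma(G, shape = config$dispersion_shape,
                                           scale = config$dispersion_mean /
                                             config$dispersion_shape))
  gene_truth$trend[trend_genes] <- ifelse(direction > 0, "up", "down")
  gene_truth$effect[trend_genes] <- direction * config$effect_size
  gene_truth$shape[trend_genes] <- shapes

  samples <- paste0("S", seq_len(config$n_samples))
  K <- config$n_clusters
  centers <- (seq_len(K) - 0.5) / K * config$t_max
  width <- 1.5 * config$t_max / K
  cells <- purrr::map_dfr(samples, function(s) {
    purrr::map_dfr(seq_len(K), function(k) {
      t <- runif(config$cells_per_cluster,
                 max(0, centers[k] - width / 2),
                 min(config$t_max, centers[k] + width / 2))
      tibble(sample = s, cluster = as.character(k - 1), pseudotime = t)
    })
  })
  n_cells <- nrow(cells)
  cells$barcode <- paste0(cells$sample, "-",
                          sprintf("CELL%05d", seq_len(n_cells)))
  cells$dead <- runif(n_cells) < config$dead_rate

  sample_eff <- matrix(rnorm(G * config$n_samples, 0,
                             config$sample_effect_sd),
                       G, config$n_samples,
                       dimnames = list(NULL, samples))
  u <- cells$pseudotime / config$t_max
  trend_mat <- matrix(0, G, n_cells)
  for (i in seq_along(trend_genes)) {
    g <- trend_genes[i]
    sfun <- trend_shape_fun(shapes[i])
    trend_mat[g, ] <- gene_truth$effect[g] * (sfun(u) - 0.5)
  }
  rate <- base * exp(trend_mat + sample_eff[, cells$sample])
  rate[is_mito, cells$dead] <- rate[is_mito, cells$dead] *
    (config$dead_mito_fraction / (1 - config$dead_mito_fraction)) /
    (config$mito_fraction / (1 - config$mito_fraction))
  prob <- sweep(rate, 2, colSums(rate), "/")
  lib <- rlnorm(n_cells, config$lib_meanlog, config$lib_sdlog)
  mu <- sweep(prob, 2, lib, "*")
  counts <- matrix(rnbinom(G * n_cells, mu = mu,
                           size = 1 / pmax(gene_truth$dispersion, 1e-8)),
                   G, n_cells)

  # doublets: sums of two sampled parents from the same sample
  n_doub <- round(config$doublet_rate * n_cells)
  if (n_doub > 0) {
    p1 <- sample(n_cells, n_doub, replace = TRUE)
    p2 <- vapply(p1, function(i) {
      same <- which(cells$sample == cells$sample[i])
      sample(same, 1)
    }, 1L)
    dcounts <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
    dcells <- tibble(sample = cells$sample[p1],
                     cluster = cells$cluster[p1],
                     pseudotime = (cells$pseudotime[p1] +
                                     cells$pseudotime[p2]) / 2,
                     barcode = paste0(cells$sample[p1], "-",
                                      sprintf("DOUB%05d", seq_len(n_doub))),
                     dead = FALSE,
                     parent1 = cells$barcode[p1],
                     parent2 = cells$barcode[p2])
    counts <- cbind(counts, dcounts)
    cells <- dplyr::bind_rows(cells, dcells)
  }
  cells$doublet <- rep(c("singlet", "doublet"),
                       c(n_cells, nrow(cells) - n_cells))

  cc <- cell_counts(counts,
                    tibble(ensembl_id = sprintf("ENSSIM%011d", seq_len(G)),
                           symbol = symbols),
                    cells[, c("barcode", "sample")])
  annotation <- cells[, c("barcode", "sample", "cluster", "pseudotime",
                          "doublet")]
  truth_cols <- intersect(c("barcode", "sample", "cluster", "pseudotime",
                            "doublet", "dead", "parent1", "parent2"),
                          names(cells))
  list(counts = cc, annotation = annotation,
       truth = list(gene = gene_truth, cell = cells[, truth_cols]))
}

#' Simulate pseudo-bulk counts directly
#'
#' Generates a [pseudobulk_set] at the replicate level, bypassing cells —
#' the fast route for statistical checks of the testing engine. Counts are
#' NB with log-mean `log(lib_s) + log p_gs`, where `p_gs` is proportional
#' to `base_g * exp(effect_g * (t_s / max(t) - 1/2) + u_{g, group(s)})`.
#' With `trend_fraction = 0` and `group_effect_sd = 0` this is an exact
#' null dataset.
#'
#' @param n_genes number of genes.
#' @param pseudotime numeric vector of pseudo-bulk pseudotimes, or a preset
#'   name for [pseudotime_preset()] (default `"mammary"`: the 22 retained
#'   reference pseudotimes).
#' @param group per-sample stage labels (defaults to the preset's stages,
#'   or a single group).
#' @param trend_fraction fraction of genes with a linear pseudotime trend.
#' @param effect_size total natural-log fold change of trend genes.
#' @param dispersion NB dispersion, scalar or per-gene.
#' @param group_effect_sd SD of per-gene, per-group log effects.
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters.
#' @param cell_number nominal member-cell count recorded per pseudo-bulk.
#' @param seed mandatory integer seed.
#' @return List with `pb` (a [pseudobulk_set]) and `truth` (gene tibble).
#' @export
simulate_pseudobulk <- function(n_genes = 2000, pseudotime = "mammary",
                                group = NULL, trend_fraction = 0,
                                effect_size = 2, dispersion = 0.2,
                                group_effect_sd = 0,
                                lib_meanlog = log(2e6), lib_sdlog = 0.7,
                                cell_number = 1000, seed = NULL) {
  if (is.null(seed)) abort("`seed` is mandatory for reproducibility.")
  set.seed(as.integer(seed))
  if (is.character(pseudotime)) {
    pt <- pseudotime_preset(pseudotime)
    group <- group %||% attr(pt, "group")
    ids <- names(pt)
    pseudotime <- as.numeric(pt)
  } else {
    ids <- paste0("PB", seq_along(pseudotime))
  }
  n <- length(pseudotime)
  group <- group %||% rep("all", n)
  G <- n_genes
  symbols <- sprintf("Gene%04d", seq_len(G))
  base <- exp(rnorm(G, 0, 1.25))
  n_trend <- round(trend_fraction * G)
  trend_genes <- if (n_trend) sample(G, n_trend) else integer(0)
  direction <- rep(c(1, -1), length.out = n_trend)
  effect <- rep(0, G)
  effect[trend_genes] <- direction * effect_size
  u <- pseudotime / max(pseudotime) - 0.5
  geff <- matrix(0, G, n)
  if (group_effect_sd > 0) {
    glev <- unique(as.character(group))
    gmat <- matrix(rnorm(G * length(glev), 0, group_effect_sd),
                   G, length(glev), dimnames = list(NULL, glev))
    geff <- gmat[, as.character(group), drop = FALSE]
  }
  rate <- base * exp(outer(effect, u) + geff)
  prob <- sweep(rate, 2, colSums(rate), "/")
  lib <- rlnorm(n, lib_meanlog, lib_sdlog)
  mu <- sweep(prob, 2, lib, "*")
  phi <- rep_len(dispersion, G)
  counts <- matrix(rnbinom(G * n, mu = mu, size = 1 / pmax(phi, 1e-8)),
                   G, n)
  truth <- tibble(symbol = symbols,
                  trend = ifelse(effect > 0, "up",
                                 ifelse(effect < 0, "down", "null")),
                  effect = effect, dispersion = phi)
  pb <- pseudobulk_set(counts,
                       tibble(ensembl_id = sprintf("ENSSIM%011d",
                                                   seq_len(G)),
                              symbol = symbols),
                       tibble(sample_id = ids,
                              group = group,
                              cluster = "0",
                              pseudotime = pseudotime,
                              cell_number = as.integer(cell_number)))
  list(pb = pb, truth = truth)
}
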