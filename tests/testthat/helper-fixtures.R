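# Fixtures and independent oracles shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Write a tiny MatrixMarket triplet by hand (no package code involved).
write_toy_triplet <- function(dir, entries, nrow, ncol,
                              symbols = sprintf("G%d", seq_len(nrow)),
                              barcodes = sprintf("BC%d", seq_len(ncol)),
                              gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  open_out <- function(p) if (gzip) gzfile(p, "wt") else file(p, "wt")
  ext <- if (gzip) ".gz" else ""
  mtx <- file.path(dir, paste0("matrix.mtx", ext))
  con <- open_out(mtx)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow, ncol, nrow(entries))), con)
  if (nrow(entries))
    writeLines(sprintf("%d %d %d", entries[, 1], entries[, 2],
                       entries[, 3]), con)
  close(con)
  bc <- file.path(dir, paste0("barcodes.tsv", ext))
  con <- open_out(bc); writeLines(barcodes, con); close(con)
  ft <- file.path(dir, paste0("features.tsv", ext))
  con <- open_out(ft)
  writeLines(paste(paste0("ENS", symbols), symbols, sep = "\t"), con)
  close(con)
  list(matrix = mtx, barcodes = bc, features = ft)
}

make_cell_counts <- function(mat, symbols = NULL, samples = NULL,
                             barcodes = NULL) {
  G <- nrow(mat); n <- ncol(mat)
  symbols <- symbols %||% sprintf("G%d", seq_len(G))
  barcodes <- barcodes %||% sprintf("BC%d", seq_len(n))
  samples <- samples %||% rep("S1", n)
  cell_counts(mat,
              tibble::tibble(ensembl_id = paste0("ENS", symbols),
                             symbol = symbols),
              tibble::tibble(barcode = barcodes, sample = samples))
}

# Naive TMM oracle with explicit loops, written straight from the
# definition: reference by 75th-percentile count fraction, pairwise doubly
# trimmed weighted mean of M, geometric-mean-1 rescaling.
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    f75[j] <- quantile(counts[, j], 0.75) / lib[j]
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    M <- c(); A <- c(); v <- c()
    for (g in seq_len(nrow(counts))) {
      o <- counts[g, j]; r <- counts[g, ref]
      if (o > 0 && r > 0) {
        M <- c(M, log2((o / lib[j]) / (r / lib[ref])))
        A <- c(A, (log2(o / lib[j]) + log2(r / lib[ref])) / 2)
        v <- c(v, (lib[j] - o) / lib[j] / o + (lib[ref] - r) / lib[ref] / r)
      }
    }
    if (!length(M) || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[j] <- if (any(keep)) {
      2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    } else 1
  }
  f / exp(mean(log(f)))
}

# Definitional Benjamini-Hochberg oracle: for each p, the smallest
# step-up bound over all larger-or-equal p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact hypergeometric upper tail by combinatorial enumeration.
hyper_tail_oracle <- function(overlap, in_set, universe, drawn) {
  if (drawn == 0 || in_set == 0) return(1)
  ks <- overlap:min(in_set, drawn)
  ks <- ks[drawn - ks <= universe - in_set]
  sum(choose(in_set, ks) * choose(universe - in_set, drawn - ks)) /
    choose(universe, drawn)
}

# Single-gene Cox-Reid APL oracle for an intercept-only design: profile
# the NB log-likelihood over the mean by 1-D optimization, subtract half
# the log of the weighted information.
apl_oracle_intercept <- function(y, phi, offset = 0) {
  nll <- function(beta) {
    mu <- exp(beta + offset)
    -sum(dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
  }
  opt <- optimize(nll, c(-20, 20), tol = 1e-10)
  mu <- rep(exp(opt$minimum + offset), length(y))
  -opt$objective - 0.5 * log(sum(mu / (1 + phi * mu)))
}

run_sim_pipeline <- function(seed, alpha = 0.05) {
  sim <- simulate_cells(sim_config(seed = seed))
  cc <- basic_filter(sim$counts)
  met <- compute_qc(cc)
  doub <- sim$annotation$doublet[match(met$barcode, sim$annotation$barcode)]
  cc <- qc_filter(cc, met, min_genes = 100, max_genes = 1e9,
                  max_mito = 10, doublet_flag = doub)
  pb <- aggregate_cells(cc, sim$annotation)
  pb <- filter_small(pb, 30, verbose = FALSE)
  pb <- calc_norm_factors(filter_genes(pb))
  des <- build_design(orthonormal_time_design(pb$samples$pseudotime),
                      pb$samples$group)
  disp <- estimate_dispersions(pb, des)
  fit <- ql_fit(pb, des, disp)
  res <- classify_trend(ql_f_test(fit, c("Z1", "Z2", "Z3")))
  truth <- sim$truth$gene[match(res$symbol, sim$truth$gene$symbol), ]
  sig <- res$FDR < alpha
  tp <- sig & truth$trend != "null"
  list(res = res, truth = truth, fit = fit, pb = pb, design = des,
       fdr = mean(truth$trend[sig] == "null"),
       power = mean(sig[truth$trend != "null"]),
       direction = mean(tolower(res$trend[tp]) == truth$trend[tp]))
}
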