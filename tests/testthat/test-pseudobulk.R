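test_that("aggregation sums counts and averages pseudotime per sample-cluster", {
  m <- matrix(c(2, 1, 0, 3, 5, 2), 2, 3)  # gene g = row 1: 2, 0, 5
  cc <- make_cell_counts(m, symbols = c("g", "h"))
  annot <- tibble::tibble(barcode = cc$cells$barcode, sample = "S",
                          cluster = "0", pseudotime = c(1, 2, 3))
  pb <- aggregate_cells(cc, annot)
  expect_equal(colnames(pb$counts), "S_C0")
  expect_equal(pb$counts["g", "S_C0"], 7)
  expect_equal(pb$samples$pseudotime, 2.0)
  expect_equal(pb$samples$cell_number, 3L)
  # two clusters: two columns, totals conserved
  annot2 <- annot; annot2$cluster <- c("0", "0", "1")
  pb2 <- aggregate_cells(cc, annot2, order_by_pseudotime = FALSE)
  expect_equal(ncol(pb2$counts), 2L)
  expect_equal(sum(pb2$counts), sum(m))
})

test_that("aggregation matches a brute-force groupby on simulated cells", {
  sim <- simulate_cells(sim_config(n_samples = 5, n_clusters = 6,
                                   cells_per_cluster = 10, n_genes = 120,
                                   doublet_rate = 0, seed = 3))
  pb <- aggregate_cells(sim$counts, sim$annotation,
                        order_by_pseudotime = FALSE)
  dense <- as.matrix(sim$counts$counts)
  key <- paste0(sim$annotation$sample, "_C", sim$annotation$cluster)
  for (k in unique(key)) {
    expect_equal(pb$counts[, k],
                 rowSums(dense[, key == k, drop = FALSE]))
  }
  expect_equal(sum(pb$counts), sum(dense))
  # median option
  pbm <- aggregate_cells(sim$counts, sim$annotation,
                         summarise_pseudotime = "median",
                         order_by_pseudotime = FALSE)
  k1 <- colnames(pbm$counts)[1]
  expect_equal(pbm$samples$pseudotime[1],
               median(sim$annotation$pseudotime[key == k1]))
})

test_that("cells with non-finite pseudotime are refused with a count", {
  cc <- make_cell_counts(matrix(1:4, 2, 2))
  annot <- tibble::tibble(barcode = cc$cells$barcode, sample = "S",
                          cluster = "0", pseudotime = c(1, Inf))
  expect_error(aggregate_cells(cc, annot), "1 cells")
})

test_that("ordering by pseudotime is ascending and stable for ties", {
  cc <- make_cell_counts(matrix(1, 1, 4))
  annot <- tibble::tibble(barcode = cc$cells$barcode, sample = "S",
                          cluster = c("b", "a", "c", "d"),
                          pseudotime = c(5, 2, 2, 1))
  pb <- aggregate_cells(cc, annot)
  expect_equal(pb$samples$pseudotime, c(1, 2, 2, 5))
  # ties keep first-appearance order: cluster "a" was seen before "c"
  expect_equal(pb$samples$cluster, c("d", "a", "c", "b"))
})

test_that("the small-sample filter keeps samples with strictly more cells", {
  info <- mammary_pseudobulk_info()
  pb <- pseudobulk_set(matrix(1, 3, nrow(info)),
                       tibble::tibble(symbol = c("a", "b", "c")),
                       info)
  expect_message(out <- filter_small(pb, 30), "removed 7 of 29")
  expect_equal(ncol(out$counts), 22L)
  # boundary: exactly 30 cells is removed
  pb30 <- pb
  pb30$samples$cell_number[1] <- 30L
  out30 <- filter_small(pb30, 30, verbose = FALSE)
  expect_false(pb30$samples$sample_id[1] %in% out30$samples$sample_id)
  # min_cells = 0 keeps everything with at least one cell
  expect_equal(ncol(filter_small(pb, 0, verbose = FALSE)$counts), 29L)
})

test_that("gene filtering applies the CPM-in-k-samples and total-count rules", {
  set.seed(1)
  n <- 6
  lib_target <- 1e6
  counts <- matrix(rpois(50 * n, 100), 50, n)
  counts[1, ] <- 0                      # all-zero: removed
  counts[2, ] <- c(10, 10, 0, 0, 0, 0)  # reaches min_count in k=2 samples
  counts[3, ] <- c(7, 7, 0, 0, 0, 0)    # total 14 < 15: removed
  scale_up <- lib_target - colSums(counts)
  counts[50, ] <- counts[50, ] + scale_up  # equalize library sizes
  pb <- pseudobulk_set(counts,
                       tibble::tibble(symbol = sprintf("g%02d", 1:50)),
                       tibble::tibble(sample_id = paste0("s", 1:n),
                                      group = rep(c("A", "B", "C"),
                                                  each = 2),
                                      cluster = "0",
                                      pseudotime = seq_len(n),
                                      cell_number = 100L))
  out <- filter_genes(pb, min_count = 10, min_total = 15)
  expect_false("g01" %in% out$genes$symbol)
  expect_true("g02" %in% out$genes$symbol)   # threshold arithmetic: kept
  expect_false("g03" %in% out$genes$symbol)  # fails min_total
  # library sizes are recomputed after filtering
  expect_equal(out$samples$lib_size, unname(colSums(out$counts)))
  # one-group design: k = number of samples
  pb1 <- pb
  pb1$samples$group <- "A"
  out1 <- filter_genes(pb1, min_count = 10, min_total = 0)
  expect_false("g02" %in% out1$genes$symbol)  # needs all 6 samples now
})

test_that("TMM factors equal the explicit-loop oracle and edgeR", {
  set.seed(42)
  counts <- matrix(rnbinom(1000 * 4, mu = 60, size = 3), 1000, 4)
  counts[1, 2] <- counts[1, 2] * 100  # composition spike in sample 2
  f <- tmm_factors(counts)
  expect_equal(unname(f), tmm_oracle(counts), tolerance = 1e-8)
  skip_if_not_installed("edgeR")
  ed <- edgeR::calcNormFactors(edgeR::DGEList(counts))$samples$norm.factors
  expect_equal(unname(f), ed, tolerance = 1e-10)
})

test_that("TMM is symmetric on identical columns and depth invariant", {
  counts <- matrix(rep(c(5, 10, 20, 40, 80), 3), 5, 3)
  expect_equal(unname(tmm_factors(counts)), rep(1, 3))
  set.seed(2)
  counts <- matrix(rnbinom(800 * 4, mu = 40, size = 5), 800, 4)
  counts[1, 2] <- 5000
  f1 <- tmm_factors(counts)
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 2  # uniform depth scaling of one library
  f2 <- tmm_factors(counts2)
  # invariance is asymptotic: the inverse-binomial weights do not scale
  # uniformly with depth, so small shifts remain (the reference
  # implementation shifts by the same amount on this data)
  expect_equal(unname(f1), unname(f2), tolerance = 0.01)
  expect_equal(unname(f2), tmm_oracle(counts2), tolerance = 1e-8)
  expect_lt(abs(sum(log(f1))), 1e-10)  # geometric mean one
  expect_lt(f1[2], 1)                  # spiked library is scaled down
  expect_error(tmm_factors(cbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("log-CPM follows its closed form and scale invariances", {
  counts <- matrix(c(0, 1000, 500, 0, 1000, 500), 3, 2)
  pb <- pseudobulk_set(counts, tibble::tibble(symbol = c("a", "b", "c")),
                       tibble::tibble(sample_id = c("s1", "s2"),
                                      group = "A", cluster = "0",
                                      pseudotime = 1:2, cell_number = 10L))
  pb$samples$lib_size <- c(1e6, 1e6)  # exact closed-form scenario
  lc <- log_cpm(pb, prior_count = 2)
  expect_equal(lc["a", 1], log2((0 + 2) / (1e6 + 4) * 1e6),
               tolerance = 1e-12)
  expect_lt(abs(lc["a", 1] - 1), 0.01)
  # doubling counts, library sizes and the prior together changes
  # nothing (the prior is pinned to the average library, so it must
  # scale too; without that, zero-count genes shift with global depth)
  pb2 <- pb
  pb2$counts <- pb$counts * 2
  pb2$samples$lib_size <- pb$samples$lib_size * 2
  expect_equal(log_cpm(pb2, prior_count = 4), log_cpm(pb, prior_count = 2),
               tolerance = 1e-12)
  nz <- rowSums(pb$counts) > 0
  expect_equal(log_cpm(pb2)[nz, ], log_cpm(pb)[nz, ], tolerance = 5e-3)
  # monotone in count within a sample
  expect_true(lc["b", 1] > lc["c", 1])
  expect_error(log_cpm(pb, prior_count = 0), "positive")
})

test_that("leading-logFC MDS matches a manual Torgerson embedding", {
  set.seed(8)
  lc <- matrix(rnorm(40 * 3), 40, 3,
               dimnames = list(NULL, c("s1", "s2", "s3")))
  res <- mds_leading_logfc(lc, top = 10, ndim = 2)
  dd <- attr(res, "distances")
  expect_equal(dd, t(dd))
  expect_equal(diag(dd), rep(0, 3), ignore_attr = TRUE)
  # manual oracle for one pair
  d2 <- sort((lc[, 1] - lc[, 2])^2, decreasing = TRUE)[1:10]
  expect_equal(dd["s1", "s2"], sqrt(mean(d2)))
  # Torgerson double centring + eigendecomposition, coordinates up to sign
  D2 <- dd^2
  J <- diag(3) - matrix(1 / 3, 3, 3)
  B <- -0.5 * J %*% D2 %*% J
  eig <- eigen(B, symmetric = TRUE)
  oracle <- eig$vectors[, 1:2] %*% diag(sqrt(pmax(eig$values[1:2], 0)))
  got <- as.matrix(res[, c("dim1", "dim2")])
  for (k in 1:2) {
    expect_true(max(abs(got[, k] - oracle[, k])) < 1e-8 ||
                  max(abs(got[, k] + oracle[, k])) < 1e-8)
  }
  # identical columns sit at distance zero
  lc2 <- cbind(lc, s4 = lc[, 1])
  dd2 <- attr(mds_leading_logfc(lc2, top = 10), "distances")
  expect_equal(dd2["s1", "s4"], 0)
  expect_warning(mds_leading_logfc(lc, top = 1000), "clamped")
})
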