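make_null_pb <- function(n_genes = 2000, phi = 0.2, seed = 11) {
  sim <- simulate_pseudobulk(n_genes = n_genes, pseudotime = "mammary",
                             dispersion = phi, seed = seed)
  calc_norm_factors(sim$pb)
}

mammary_design <- function(pb) {
  build_design(orthonormal_time_design(pb$samples$pseudotime),
               pb$samples$group)
}

test_that("the adjusted profile likelihood matches a 1-D profiling oracle", {
  y <- matrix(c(10, 14, 6, 11, 9, 13), 1, 6)
  off <- matrix(log(1e4), 1, 6)
  for (phi in c(0.01, 0.1, 0.3, 1)) {
    mine <- pseudotempo:::apl_per_gene(y, matrix(1, 6, 1), off, phi)
    oracle <- apl_oracle_intercept(as.numeric(y), phi, offset = log(1e4))
    expect_equal(mine, oracle, tolerance = 1e-4)
  }
})

test_that("common dispersion recovers simulation truth within 5 percent", {
  pb <- make_null_pb(n_genes = 2000, phi = 0.2, seed = 21)
  disp <- estimate_dispersions(pb, matrix(1, 22, 1))
  expect_lt(abs(disp$common - 0.2) / 0.2, 0.05)
})

test_that("Poisson counts give a near-zero common dispersion", {
  sim <- simulate_pseudobulk(n_genes = 1000, pseudotime = "mammary",
                             dispersion = 1e-8, seed = 22)
  disp <- estimate_dispersions(calc_norm_factors(sim$pb),
                               matrix(1, 22, 1))
  expect_lt(disp$common, 0.01)
})

test_that("trended and tagwise dispersions are positive and trend-shrunk", {
  pb <- make_null_pb(n_genes = 1000, phi = 0.2, seed = 23)
  des <- mammary_design(pb)
  disp <- estimate_dispersions(pb, des)
  expect_true(all(disp$gene$trended > 0))
  expect_true(all(disp$gene$tagwise > 0))
  # shrinkage: tagwise values hug the trend more than free per-gene
  # maxima would (their log-ratio spread stays moderate)
  lr <- log2(disp$gene$tagwise / disp$gene$trended)
  expect_lt(sd(lr), 3)
  expect_equal(disp$gene$trended,
               disp$trend_fun(disp$gene$ave_log_cpm))
})

test_that("raw QL dispersion is near one for large-count Poisson data", {
  sim <- simulate_pseudobulk(n_genes = 2000, pseudotime = "mammary",
                             dispersion = 1e-8, lib_meanlog = log(5e6),
                             lib_sdlog = 0.1, seed = 24)
  pb <- calc_norm_factors(sim$pb)
  fit <- ql_fit(pb, mammary_design(pb), dispersion = 1e-8)
  expect_lt(abs(mean(fit$s2_raw, na.rm = TRUE) - 1), 0.1)
})

test_that("the EB squeeze contracts QL dispersions toward the trend", {
  pb <- make_null_pb(n_genes = 1000, phi = 0.2, seed = 25)
  fit <- ql_fit(pb, mammary_design(pb),
                estimate_dispersions(pb, mammary_design(pb)))
  ok <- is.finite(fit$s2_raw)
  expect_lt(var(log(fit$s2_post[ok])), var(log(fit$s2_raw[ok])))
  # squeezed values lie between raw and trend
  lo <- pmin(fit$s2_raw[ok], fit$s2_trend[ok])
  hi <- pmax(fit$s2_raw[ok], fit$s2_trend[ok])
  expect_true(all(fit$s2_post[ok] >= lo - 1e-10 &
                    fit$s2_post[ok] <= hi + 1e-10))
  # infinite prior df collapses the posterior onto the trend
  inf_idx <- is.infinite(fit$prior_df)
  expect_equal(fit$s2_post[inf_idx], fit$s2_trend[inf_idx])
})

test_that("deviances are non-negative and nested fits order correctly", {
  pb <- make_null_pb(n_genes = 300, phi = 0.2, seed = 26)
  des <- mammary_design(pb)
  off <- log(pb$samples$lib_size * pb$samples$norm_factor)
  full <- nbglm_fit(pb$counts, des$design, off, 0.2)
  null <- nbglm_fit(pb$counts, des$design[, -(2:4)], off, 0.2)
  expect_true(all(full$deviance >= 0))
  expect_true(all(null$deviance >= full$deviance - 1e-6))
})

test_that("a gene whose null fit equals its full fit scores F = 0, p = 1", {
  counts <- matrix(rep(c(50, 80, 120), each = 8), 3, 8, byrow = TRUE)
  pb <- pseudobulk_set(counts,
                       tibble::tibble(symbol = c("a", "b", "c")),
                       tibble::tibble(sample_id = paste0("s", 1:8),
                                      group = "A", cluster = "0",
                                      pseudotime = 1:8,
                                      cell_number = 100L))
  des <- build_design(orthonormal_time_design(pb$samples$pseudotime),
                      pb$samples$group)
  fit <- ql_fit(pb, des, dispersion = 0.1, robust = FALSE)
  res <- ql_f_test(fit, c("Z1", "Z2", "Z3"))
  expect_true(all(res$F < 1e-6))
  expect_true(all(res$PValue > 0.999))
})

test_that("the quasi-F test is calibrated on null NB data", {
  pb <- make_null_pb(n_genes = 2000, phi = 0.2, seed = 11)
  des <- mammary_design(pb)
  fit <- ql_fit(pb, des, estimate_dispersions(pb, des))
  res <- ql_f_test(fit, c("Z1", "Z2", "Z3"))
  expect_identical(attr(res, "tested_coefs"), c("Z1", "Z2", "Z3"))
  # p-values reproduce from F with (3, df_resid + prior_df) df
  df2 <- fit$df_resid + fit$prior_df
  expect_equal(res$PValue,
               pmax(pf(res$F, 3, df2, lower.tail = FALSE),
                    .Machine$double.xmin),
               tolerance = 1e-12)
  # rejection rate within two binomial SDs of nominal
  alpha <- 0.05
  band <- 2 * sqrt(alpha * (1 - alpha) / nrow(res))
  expect_lt(abs(mean(res$PValue < alpha) - alpha), band)
  expect_error(ql_f_test(fit, 1), "ntercept")
  expect_error(ql_f_test(fit, "nonexistent"), "Unknown")
})

test_that("quasi-F p-values agree with Gaussian F-tests at large counts", {
  sim <- simulate_pseudobulk(n_genes = 500, pseudotime = "mammary",
                             dispersion = 1e-8, lib_meanlog = log(5e6),
                             lib_sdlog = 0.1, trend_fraction = 0.2,
                             effect_size = 0.3, seed = 27)
  pb <- calc_norm_factors(sim$pb)
  des <- mammary_design(pb)
  fit <- ql_fit(pb, des, dispersion = 1e-8, robust = FALSE)
  res <- ql_f_test(fit, c("Z1", "Z2", "Z3"))
  lc <- log_cpm(pb)
  X <- des$design
  p_lm <- vapply(seq_len(nrow(lc)), function(g) {
    full <- lm.fit(X, lc[g, ])
    null <- lm.fit(X[, -(2:4), drop = FALSE], lc[g, ])
    rss1 <- sum(full$residuals^2); rss0 <- sum(null$residuals^2)
    Fg <- ((rss0 - rss1) / 3) / (rss1 / (nrow(X) - ncol(X)))
    pf(Fg, 3, nrow(X) - ncol(X), lower.tail = FALSE)
  }, 0)
  expect_gt(cor(res$PValue, p_lm, method = "spearman"), 0.95)
})

test_that("median F never decreases as the planted effect grows", {
  med_f <- vapply(c(0.5, 1, 2), function(eff) {
    sim <- simulate_pseudobulk(n_genes = 400, pseudotime = "mammary",
                               trend_fraction = 0.25, effect_size = eff,
                               dispersion = 0.2, seed = 28)
    pb <- calc_norm_factors(sim$pb)
    des <- mammary_design(pb)
    fit <- ql_fit(pb, des, estimate_dispersions(pb, des))
    res <- ql_f_test(fit, c("Z1", "Z2", "Z3"))
    median(res$F[sim$truth$trend != "null"])
  }, 0)
  expect_true(all(diff(med_f) > 0))
})

test_that("BH adjustment matches hand computation and the oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(4)
  for (rep in 1:5) {
    p <- runif(50)
    expect_identical(bh_adjust(p), bh_oracle(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-15)
  }
  # FDR >= p and monotone in p-rank
  p <- runif(100)
  f <- bh_adjust(p)
  expect_true(all(f >= p))
  expect_true(all(diff(f[order(p)]) >= -1e-15))
})

test_that("decide_tests summarizes joint and directional calls", {
  empty <- tibble::tibble(symbol = character(0), logFC.Z1 = numeric(0),
                          F = numeric(0), PValue = numeric(0),
                          FDR = numeric(0))
  attr(empty, "tested_coefs") <- "Z1"
  expect_equal(sum(decide_tests(empty)$n), 0L)
  flat <- tibble::tibble(symbol = c("a", "b"), logFC.Z1 = c(1, -1),
                         F = c(0, 0), PValue = c(1, 1), FDR = c(1, 1))
  attr(flat, "tested_coefs") <- "Z1"
  d <- decide_tests(flat)
  expect_equal(d$n[d$status == "NotSig"], 2L)
  # planted-trend simulation: recovery with controlled FDR
  sim <- simulate_pseudobulk(n_genes = 1000, pseudotime = "mammary",
                             trend_fraction = 0.1, effect_size = 2,
                             dispersion = 0.2, seed = 29)
  pb <- calc_norm_factors(sim$pb)
  des <- mammary_design(pb)
  fit <- ql_fit(pb, des, estimate_dispersions(pb, des))
  res <- ql_f_test(fit, c("Z1", "Z2", "Z3"))
  lab <- attr(decide_tests(res, 0.05), "labels")
  sig <- lab == "Sig"
  expect_gt(mean(sig[sim$truth$trend != "null"]), 0.8)
  expect_lte(mean(sim$truth$trend[sig] == "null"), 0.1)
})

test_that("top_table sorts deterministically and survives permutation", {
  res <- tibble::tibble(symbol = c("c", "a", "b", "d"),
                        logFC.Z1 = 1:4,
                        F = c(5, 9, 9, 1),
                        PValue = c(0.02, 0.01, 0.01, 0.5),
                        FDR = c(0.04, 0.02, 0.02, 0.5))
  attr(res, "tested_coefs") <- "Z1"
  top <- top_table(res, 10)
  expect_equal(top$symbol, c("a", "b", "c", "d"))
  expect_true(all(diff(top$PValue) >= 0))
  set.seed(6)
  perm <- top_table(res[sample(4), ], 10)
  expect_equal(perm$symbol, top$symbol)
  expect_equal(nrow(top_table(res, 2)), 2L)
})
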