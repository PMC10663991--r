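test_that("trend labels follow the sign of the linear coefficient", {
  res <- tibble::tibble(symbol = c("Mlph", "Fhod3", "edge"),
                        logFC.Z1 = c(10.83, -13.88, 0),
                        F = 1, PValue = 0.5, FDR = 0.5)
  out <- classify_trend(res)
  expect_equal(out$trend, c("Up", "Down", "Down"))
  expect_error(classify_trend(res[, -2]), "logFC.Z1")
})

test_that("trend labels partition every tested gene", {
  sim <- simulate_pseudobulk(n_genes = 300, pseudotime = "mammary",
                             trend_fraction = 0.2, effect_size = 1,
                             dispersion = 0.2, seed = 31)
  pb <- calc_norm_factors(sim$pb)
  des <- build_design(orthonormal_time_design(pb$samples$pseudotime),
                      pb$samples$group)
  fit <- ql_fit(pb, des, dispersion = 0.2)
  out <- classify_trend(ql_f_test(fit, c("Z1", "Z2", "Z3")))
  expect_equal(sum(out$trend == "Up") + sum(out$trend == "Down"),
               nrow(out))
})

flat_pb <- function() {
  counts <- matrix(rep(c(100, 400), each = 10), 2, 10, byrow = TRUE)
  pseudobulk_set(counts, tibble::tibble(symbol = c("flatA", "flatB")),
                 tibble::tibble(sample_id = paste0("s", 1:10),
                                group = rep(c("g1", "g2"), each = 5),
                                cluster = "0",
                                pseudotime = c(1:5, 1.5 + 1:5),
                                cell_number = 50L))
}

test_that("constant genes produce flat curves at the intercept level", {
  pb <- flat_pb()
  des <- build_design(orthonormal_time_design(pb$samples$pseudotime),
                      pb$samples$group)
  fit_raw <- ql_fit(pb, des$design_raw, dispersion = 0.05, robust = FALSE)
  cv <- fitted_curves(fit_raw, des, "flatA")
  expect_equal(nrow(cv), 100L)
  expect_equal(range(cv$pseudotime), range(pb$samples$pseudotime))
  expect_lt(diff(range(cv$log2cpm)), 1e-4)
  # counts equal across equal libraries: eta0 = log(100 / lib)
  eta0 <- log(100 / pb$samples$lib_size[1])
  expect_equal(cv$log2cpm[1], (eta0 + log(1e6)) / log(2), tolerance = 1e-4)
  expect_error(fitted_curves(fit_raw, des, "missing"), "absent")
})

test_that("shifting all group effects shifts curves by the same constant", {
  pb <- flat_pb()
  des <- build_design(orthonormal_time_design(pb$samples$pseudotime),
                      pb$samples$group)
  fit_raw <- ql_fit(pb, des$design_raw, dispersion = 0.05, robust = FALSE)
  base <- fitted_curves(fit_raw, des, "flatB")
  shift <- 0.7
  fit_shift <- fit_raw
  grp_cols <- setdiff(colnames(fit_raw$design),
                      c("(Intercept)", "X1", "X2", "X3"))
  fit_shift$coefficients[, "(Intercept)"] <-
    fit_shift$coefficients[, "(Intercept)"] + shift
  shifted <- fitted_curves(fit_shift, des, "flatB")
  expect_equal(shifted$log2cpm, base$log2cpm + shift / log(2),
               tolerance = 1e-10)
})

test_that("planted increasing genes yield rising fitted curves", {
  n_rising <- vapply(1:3, function(s) {
    sim <- simulate_pseudobulk(n_genes = 300, pseudotime = "mammary",
                               trend_fraction = 0.2, effect_size = 2,
                               dispersion = 0.2, seed = 40 + s)
    pb <- calc_norm_factors(sim$pb)
    des <- build_design(orthonormal_time_design(pb$samples$pseudotime),
                        pb$samples$group)
    fit_raw <- ql_fit(pb, des$design_raw, dispersion = 0.2,
                      robust = FALSE)
    up <- sim$truth$symbol[sim$truth$trend == "up"]
    cv <- fitted_curves(fit_raw, des, up)
    ends <- dplyr::summarise(
      dplyr::group_by(cv, .data$symbol),
      delta = .data$log2cpm[dplyr::n()] - .data$log2cpm[1])
    mean(ends$delta > 0)
  }, 0)
  expect_gt(mean(n_rising), 0.95)
})

test_that("heatmap rows are standardized and blocks keep their order", {
  set.seed(12)
  lc <- matrix(rnorm(50 * 8), 50, 8,
               dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  up <- sprintf("g%02d", 1:20)
  down <- sprintf("g%02d", 21:40)
  z <- heatmap_matrix(lc, up, down, pseudotime = 8:1)
  expect_equal(nrow(z), 40L)
  expect_equal(rownames(z), c(up, down))
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
  expect_equal(colnames(z), paste0("s", 8:1))  # ascending pseudotime
  lc["g01", ] <- 3
  expect_error(heatmap_matrix(lc, up, down), "Constant")
})

test_that("gene-set averages reduce to member profiles in edge cases", {
  lc <- rbind(a = c(5, 4, 3, 2), b = c(5, 4, 3, 2), c = c(0, 0, 0, 0))
  colnames(lc) <- paste0("s", 1:4)
  pt <- 1:4
  single <- geneset_average_trend(lc, "a", pt)
  expect_equal(single$avg_log2cpm, unname(lc["a", ]))
  ident <- geneset_average_trend(lc, c("a", "b"), pt)
  expect_equal(ident$avg_log2cpm, unname(lc["a", ]))
  expect_error(geneset_average_trend(lc, "zz", pt), "No gene-set members")
})

test_that("a set of planted decreasing genes trends down with pseudotime", {
  sim <- simulate_pseudobulk(n_genes = 400, pseudotime = "mammary",
                             trend_fraction = 0.2, effect_size = 2,
                             dispersion = 0.2, seed = 33)
  pb <- calc_norm_factors(sim$pb)
  lc <- log_cpm(pb)
  down <- sim$truth$symbol[sim$truth$trend == "down"]
  tr <- geneset_average_trend(lc, down, pb$samples$pseudotime)
  expect_lt(cor(tr$pseudotime, tr$avg_log2cpm, method = "spearman"), 0)
})
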