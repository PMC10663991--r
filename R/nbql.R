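## Negative-binomial quasi-likelihood engine: Cox-Reid dispersion
## estimation, QL fitting with empirical-Bayes dispersion shrinkage, and
## quasi-F tests. The per-gene GLM fitting is compiled (src/nbglm.cpp).

as_design_matrix <- function(design) {
  if (inherits(design, "timecourse_design")) return(design$design)
  as.matrix(design)
}

expand_offset <- function(offset, G, n) {
  if (is.matrix(offset)) {
    stopifnot(nrow(offset) == G, ncol(offset) == n)
    offset
  } else {
    matrix(offset, nrow = G, ncol = n, byrow = TRUE)
  }
}

#' Fit negative-binomial GLMs for a count matrix
#'
#' Fits one log-link NB generalized linear model per gene, all sharing the
#' design, by iteratively reweighted least squares with step halving
#' (convergence tolerance `tol` on relative deviance change, at most
#' `maxit` iterations). Divergent genes are returned at their best visited
#' deviance and flagged.
#'
#' @param counts genes-by-samples count matrix.
#' @param design design matrix (samples by coefficients) or a
#'   `timecourse_design`.
#' @param offset per-sample log effective library sizes (vector) or a full
#'   genes-by-samples offset matrix.
#' @param dispersion NB dispersion, scalar or per-gene vector.
#' @param tol,maxit IRLS control.
#' @return List with `coefficients` (natural-log scale), `fitted`,
#'   `deviance`, `cr_adj` (0.5 log det of the weighted information, the
#'   Cox-Reid adjustment), `converged`.
#' @export
nbglm_fit <- function(counts, design, offset, dispersion,
                      tol = 1e-8, maxit = 50) {
  X <- as_design_matrix(design)
  counts <- as.matrix(counts)
  G <- nrow(counts); n <- ncol(counts)
  stopifnot(nrow(X) == n)
  off <- expand_offset(offset, G, n)
  phi <- rep_len(dispersion, G)
  fit <- .nbglm_fit_cpp(counts, X, off, phi, tol, maxit)
  for (v in c("deviance", "cr_adj", "iter", "converged"))
    fit[[v]] <- as.numeric(fit[[v]])
  colnames(fit$coefficients) <- colnames(X)
  rownames(fit$coefficients) <- rownames(counts)
  fit$design <- X
  fit$offset <- off
  fit$dispersion <- phi
  if (any(fit$converged == 0))
    warn(sprintf("%d gene fit(s) did not fully converge.",
                 sum(fit$converged == 0)))
  fit
}

# Cox-Reid adjusted profile log-likelihood per gene at dispersion phi.
apl_per_gene <- function(counts, X, off, phi) {
  G <- nrow(counts)
  fit <- .nbglm_fit_cpp(counts, X, off, rep_len(phi, G), 1e-6, 30)
  ll <- .nbglm_loglik_cpp(counts, fit$fitted, rep_len(phi, G))
  as.numeric(ll - fit$cr_adj)
}

#' Estimate NB dispersions by Cox-Reid adjusted profile likelihood
#'
#' The NB dispersion phi governs the mean-variance relation
#' `Var = mu + phi * mu^2`; its square root is the biological coefficient
#' of variation (BCV). Three estimates are produced: a *common* dispersion
#' maximizing the summed Cox-Reid adjusted profile likelihood (APL) over
#' all genes; a *trended* dispersion from per-abundance-bin APL maxima
#' smoothed over average log2-CPM by monotonicity-preserving cubic
#' interpolation; and *tagwise* (gene-specific) dispersions from a
#' weighted-likelihood empirical-Bayes rule that adds `prior_n` times the
#' moving-average APL of each gene's abundance neighbours to its own APL
#' before maximizing, shrinking noisy per-gene estimates toward the trend.
#'
#' @param pb a filtered, normalized [pseudobulk_set].
#' @param design design matrix or `timecourse_design` (full column rank).
#' @param prior_n weight on the neighbour-averaged likelihood in the
#'   tagwise estimate (larger means stronger shrinkage toward the trend).
#' @param interval search interval for the dispersion.
#' @param nbins_max maximum number of abundance bins for the trend.
#' @return A `dispersion_fit` with `common` (scalar), per-gene tibble
#'   `gene` (`symbol`, `ave_log_cpm`, `trended`, `tagwise`), bin table
#'   `bins`, and `trend_fun(ave_log_cpm)`.
#' @export
estimate_dispersions <- function(pb, design, prior_n = 10,
                                 interval = c(1e-6, 10), nbins_max = 20) {
  X <- as_design_matrix(design)
  counts <- pb$counts
  G <- nrow(counts); n <- ncol(counts)
  if (qr(X)$rank < ncol(X)) abort("Design matrix is rank deficient.")
  off <- expand_offset(log(effective_lib_size(pb)), G, n)
  ave <- ave_log_cpm(pb)
  lo <- log(interval[1]); hi <- log(interval[2])

  opt_subset <- function(rows) {
    f <- function(lphi) -sum(apl_per_gene(counts[rows, , drop = FALSE], X,
                                          off[rows, , drop = FALSE],
                                          exp(lphi)))
    exp(optimize(f, c(lo, hi), tol = 1e-6)$minimum)
  }

  common <- opt_subset(seq_len(G))

  nbins <- max(1L, min(nbins_max, floor(G / 50)))
  if (nbins >= 2) {
    bin <- cut(rank(ave, ties.method = "first"),
               breaks = nbins, labels = FALSE)
    bins <- tibble(
      ave_log_cpm = vapply(seq_len(nbins),
                           function(b) median(ave[bin == b]), 0),
      dispersion = vapply(seq_len(nbins),
                          function(b) opt_subset(which(bin == b)), 0))
    sf <- stats::splinefun(bins$ave_log_cpm, log(bins$dispersion),
                           method = "monoH.FC")
    rng <- range(bins$ave_log_cpm)
    trend_fun <- function(a) exp(sf(pmin(pmax(a, rng[1]), rng[2])))
  } else {
    bins <- tibble(ave_log_cpm = median(ave), dispersion = common)
    trend_fun <- function(a) rep(common, length(a))
  }
  trended <- trend_fun(ave)

  # weighted-likelihood tagwise estimates on a shared log-dispersion grid
  grid <- 2^seq(-6, 6, length.out = 21)
  apl <- matrix(0, G, length(grid))
  for (k in seq_along(grid)) {
    phi_k <- pmin(pmax(trended * grid[k], interval[1]), interval[2])
    fit <- .nbglm_fit_cpp(counts, X, off, phi_k, 1e-6, 30)
    apl[, k] <- .nbglm_loglik_cpp(counts, fit$fitted, phi_k) - fit$cr_adj
  }
  ord <- order(ave)
  w <- max(1L, floor(0.05 * G))
  apl_ma <- apl
  apl_ma[ord, ] <- apply(apl[ord, , drop = FALSE], 2, function(col) {
    stats::filter(col, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2) |>
      (\(v) { v[is.na(v)] <- col[is.na(v)]; v })()
  })
  score <- apl + prior_n * apl_ma
  best <- max.col(score, ties.method = "first")
  tagwise <- pmin(pmax(trended * grid[best], interval[1]), interval[2])

  structure(list(common = common,
                 gene = tibble(symbol = pb$genes$symbol,
                               ave_log_cpm = ave,
                               trended = trended,
                               tagwise = tagwise),
                 bins = bins, trend_fun = trend_fun, prior_n = prior_n),
            class = "dispersion_fit")
}

#' @export
#' @method print dispersion_fit
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("dispersion_fit: %d genes; common dispersion %.4g (BCV %.3f)\n",
              nrow(x$gene), x$common, sqrt(x$common)))
  invisible(x)
}

# limma-style Newton inversion of the trigamma function.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Quasi-likelihood NB model fit with dispersion squeezing
#'
#' Fits each gene's NB GLM with the dispersion fixed at the *trended* value
#' (gene-specific variability is deliberately not absorbed here), then
#' captures that remaining variability in the QL dispersion
#' `s2 = residual deviance / residual df`. Residual df is `n - p`, reduced
#' by the number of effectively-zero fitted values (counts pinned at zero
#' contribute no deviance information). The raw `s2` are squeezed toward an
#' abundance trend by empirical Bayes: a scaled-F prior is fitted by moment
#' matching on log dispersions (lowess trend of the debiased logs; prior df
#' `d0` from the inverse trigamma of the excess variance), and the
#' posterior value is the df-weighted average of raw and trend. With
#' `robust = TRUE` the moment matching winsorizes residual log-dispersions
#' at `winsor` quantiles and genes above the upper limit get a reduced
#' per-gene prior df, so hypervariable outliers are not shrunk into
#' significance.
#'
#' @param pb a filtered, normalized [pseudobulk_set].
#' @param design design matrix or `timecourse_design`.
#' @param dispersion a `dispersion_fit` (its trend is used) or a numeric
#'   vector/scalar of NB dispersions.
#' @param robust use the outlier-protected squeeze (default `TRUE`).
#' @param winsor winsorization quantiles for the robust squeeze.
#' @param prior_count prior count carried for downstream log-CPM displays.
#' @return A `ql_fit` object.
#' @export
ql_fit <- function(pb, design, dispersion, robust = TRUE,
                   winsor = c(0.05, 0.95), prior_count = 2) {
  X <- as_design_matrix(design)
  counts <- pb$counts
  G <- nrow(counts); n <- ncol(counts); p <- ncol(X)
  phi <- if (inherits(dispersion, "dispersion_fit")) {
    if (nrow(dispersion$gene) != G)
      abort("dispersion_fit does not match this pseudobulk_set.")
    dispersion$gene$trended
  } else rep_len(dispersion, G)
  offset <- log(effective_lib_size(pb))
  fit <- nbglm_fit(counts, X, offset, phi)
  ave <- ave_log_cpm(pb, prior_count)

  zero_fitted <- rowSums(fit$fitted < 1e-4)
  df_resid <- pmax(n - p - zero_fitted, 0)
  s2_raw <- ifelse(df_resid > 0, fit$deviance / df_resid, NA_real_)

  ok <- df_resid > 0
  z <- log(pmax(s2_raw[ok], 1e-8))
  dfo <- df_resid[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  lw <- lowess(ave[ok], e, f = 0.5)
  etrend_ok <- approx(lw$x, lw$y, xout = ave[ok], rule = 2, ties = mean)$y
  resid <- e - etrend_ok
  resid_w <- if (robust) {
    qs <- quantile(resid, winsor)
    pmin(pmax(resid, qs[1]), qs[2])
  } else resid
  rhs <- var(resid_w) - mean(trigamma(dfo / 2))
  d0 <- if (is.finite(rhs) && rhs > 0) 2 * trigamma_inverse(rhs) else Inf

  etrend <- approx(lw$x, lw$y, xout = ave, rule = 2, ties = mean)$y
  s2_trend <- if (is.finite(d0)) {
    exp(etrend + digamma(d0 / 2) - log(d0 / 2))
  } else exp(etrend)

  prior_df <- rep(d0, G)
  if (robust && is.finite(d0)) {
    exceed <- rep(0, G)
    exceed[ok] <- pmax(resid - quantile(resid, winsor[2]), 0)
    out <- exceed > 0
    prior_df[out] <- pmax(1, d0 * exp(-2 * exceed[out]))
  }

  s2_post <- ifelse(df_resid > 0,
                    ifelse(is.finite(prior_df),
                           (prior_df * s2_trend + df_resid * s2_raw) /
                             (prior_df + df_resid),
                           s2_trend),
                    s2_trend)

  structure(list(coefficients = fit$coefficients,
                 fitted = fit$fitted,
                 deviance = fit$deviance,
                 df_resid = df_resid,
                 s2_raw = s2_raw,
                 s2_trend = s2_trend,
                 s2_post = s2_post,
                 prior_df = prior_df,
                 ave_log_cpm = ave,
                 design = X,
                 offset = offset,
                 dispersion = phi,
                 genes = pb$genes,
                 counts = counts,
                 lib_size = effective_lib_size(pb),
                 prior_count = prior_count,
                 robust = robust),
            class = "ql_fit")
}

#' @export
#' @method print ql_fit
print.ql_fit <- function(x, ...) {
  d0 <- x$prior_df[is.finite(x$prior_df)]
  cat(sprintf(
    "ql_fit: %d genes, %d coefficients, residual df %s, prior df %s\n",
    nrow(x$coefficients), ncol(x$coefficients),
    paste(range(x$df_resid), collapse = "-"),
    if (length(d0)) sprintf("%.2f (median)", median(d0)) else "Inf"))
  invisible(x)
}

#' Quasi-likelihood F-test on a set of coefficients
#'
#' Tests, per gene, whether the named coefficients are jointly zero. The
#' statistic is the drop in deviance between the null fit (tested columns
#' removed, same trended dispersions) and the full fit, divided by the
#' number of tested coefficients and by the squeezed QL dispersion. Under
#' the null it is referred to an F distribution with
#' `(r, residual df + prior df)` degrees of freedom, so the empirical-Bayes
#' information borrowed across genes buys extra denominator df.
#'
#' @param fit a [ql_fit] object.
#' @param coef coefficient columns to test: integer indices or names
#'   (never the intercept).
#' @return A tibble with the gene annotation columns, `logFC.<coef>`
#'   columns (log2 scale), `logCPM`, `F`, `PValue`, `FDR`; tested
#'   coefficient names are attached as attribute `"tested_coefs"`.
#' @export
ql_f_test <- function(fit, coef) {
  cn <- colnames(fit$design)
  if (is.character(coef)) coef <- match(coef, cn)
  if (anyNA(coef) || any(coef < 1) || any(coef > length(cn)))
    abort("Unknown coefficient selection.")
  if (any(cn[coef] == "(Intercept)"))
    abort("The intercept cannot be tested.")
  r <- length(coef)
  null_fit <- nbglm_fit(fit$counts, fit$design[, -coef, drop = FALSE],
                        log(fit$lib_size), fit$dispersion)
  dev_drop <- pmax(null_fit$deviance - fit$deviance, 0)
  Fstat <- (dev_drop / r) / fit$s2_post
  Fstat <- pmax(Fstat, 0)
  df2 <- fit$df_resid + fit$prior_df
  pval <- ifelse(is.finite(df2),
                 pf(Fstat, r, df2, lower.tail = FALSE),
                 stats::pchisq(Fstat * r, r, lower.tail = FALSE))
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  out <- fit$genes
  lfc <- fit$coefficients[, coef, drop = FALSE] / log(2)
  colnames(lfc) <- paste0("logFC.", cn[coef])
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(lfc)))
  out$logCPM <- fit$ave_log_cpm
  out$F <- Fstat
  out$PValue <- pval
  out$FDR <- bh_adjust(pval)
  attr(out, "tested_coefs") <- cn[coef]
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; monotonicity is enforced by a
#' cumulative minimum over the sorted p-values.
#'
#' @param pvalues numeric vector of p-values.
#' @return FDR values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  m <- length(pvalues)
  if (!m) return(numeric(0))
  o <- order(pvalues)
  stepup <- pvalues[o] * m / seq_len(m)
  out <- numeric(m)
  out[o] <- pmin(1, rev(cummin(rev(stepup))))
  out
}

#' Summarize significance calls at an FDR threshold
#'
#' For a joint test (several coefficients) genes are labelled `Sig` or
#' `NotSig`; for a single-coefficient test significant genes split into
#' `Up`/`Down` by the sign of the tested coefficient (zero counted as
#' `Down`).
#'
#' @param result tibble from [ql_f_test()].
#' @param alpha FDR threshold.
#' @return Summary tibble (`status`, `n`); per-gene labels attached as
#'   attribute `"labels"`.
#' @export
decide_tests <- function(result, alpha = 0.05) {
  tested <- attr(result, "tested_coefs")
  if (nrow(result) == 0L) {
    lev <- if (length(tested) == 1L) c("Down", "NotSig", "Up")
           else c("NotSig", "Sig")
    out <- tibble(status = lev, n = 0L)
    attr(out, "labels") <- character(0)
    return(out)
  }
  sig <- result$FDR < alpha
  if (length(tested) == 1L) {
    lfc <- result[[paste0("logFC.", tested)]]
    lab <- ifelse(!sig, "NotSig", ifelse(lfc > 0, "Up", "Down"))
    lev <- c("Down", "NotSig", "Up")
  } else {
    lab <- ifelse(sig, "Sig", "NotSig")
    lev <- c("NotSig", "Sig")
  }
  out <- tibble(status = lev,
                n = as.integer(table(factor(lab, levels = lev))))
  attr(out, "labels") <- lab
  out
}

#' Top genes by evidence of association
#'
#' Sorts a test table by ascending p-value; ties broken by larger F first
#' and then by gene name, so the ordering is deterministic under row
#' permutations.
#'
#' @param result tibble from [ql_f_test()].
#' @param n number of rows to keep (all rows when larger than the table).
#' @return The sorted head of `result` (attributes preserved).
#' @export
top_table <- function(result, n = 10) {
  o <- order(result$PValue, -result$F, result$symbol)
  out <- result[o[seq_len(min(n, nrow(result)))], ]
  attr(out, "tested_coefs") <- attr(result, "tested_coefs")
  out
}
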