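#' Natural cubic spline basis over pseudotime
#'
#' Builds a `df`-column natural cubic spline basis (no intercept column)
#' with internal knots at equally spaced quantiles of `t` (the 1/3 and 2/3
#' quantiles for `df = 3`, linear-interpolation quantile definition) and
#' boundary knots at the range of `t`. "Natural" means the basis functions
#' are constrained to be linear beyond the boundary knots, which keeps
#' extrapolated fitted trends from exploding at the ends of the trajectory.
#'
#' @param t numeric pseudotime vector with at least `df + 1` distinct
#'   values.
#' @param df degrees of freedom (number of basis columns), default 3.
#' @return An `ns_basis` object with fields `df`, `internal_knots`,
#'   `boundary_knots` and the n-by-df basis matrix `X`.
#' @export
natural_spline_basis <- function(t, df = 3) {
  if (df < 1) abort("`df` must be at least 1.")
  if (length(unique(t)) < df + 1)
    abort(sprintf("Need at least %d distinct pseudotime values for df = %d.",
                  df + 1, df))
  X <- splines::ns(as.numeric(t), df = df)
  structure(list(df = df,
                 internal_knots = as.numeric(attr(X, "knots")),
                 boundary_knots = as.numeric(attr(X, "Boundary.knots")),
                 X = unclass(X)[, , drop = FALSE],
                 t = as.numeric(t)),
            class = "ns_basis")
}

#' Evaluate a stored natural spline basis at new pseudotimes
#'
#' Uses the knots fixed at training time; values beyond the boundary knots
#' extrapolate linearly (the natural constraint).
#'
#' @param object an `ns_basis`.
#' @param new_t numeric vector of pseudotimes (defaults to the training
#'   values, reproducing the stored basis).
#' @param ... unused.
#' @return Matrix with `length(new_t)` rows and `df` columns.
#' @export
predict.ns_basis <- function(object, new_t = NULL, ...) {
  new_t <- new_t %||% object$t
  X <- splines::ns(as.numeric(new_t), knots = object$internal_knots,
                   Boundary.knots = object$boundary_knots)
  unclass(X)[, , drop = FALSE]
}

#' Orthonormalized pseudotime covariates
#'
#' Re-parametrizes the spline design so its coefficients are interpretable:
#' forms `A = [1, t, X]` with `X` the natural spline basis, orthonormalizes
#' the columns in that order by QR decomposition with the positive-R-diagonal
#' sign convention (equivalent to Gram-Schmidt on 1, then t, then X), and
#' drops the first column (the intercept direction). Because `t` precedes
#' the spline columns, the first retained covariate is exactly
#' `Z1 = (t - mean(t)) / ||t - mean(t)||`: the linear trend in pseudotime.
#' Z2, Z3 capture orthogonal curvature.
#'
#' @param t numeric pseudotime vector.
#' @param df spline degrees of freedom (default 3).
#' @return n-by-df matrix `Z` with columns `Z1..Zdf`; the underlying
#'   `ns_basis` is attached as attribute `"basis"`.
#' @export
orthonormal_time_design <- function(t, df = 3) {
  basis <- natural_spline_basis(t, df = df)
  A <- cbind(1, t, basis$X)
  QR <- qr(A)
  # t is itself a natural spline, so [1, t, X] always has rank df + 1;
  # anything lower means the pseudotimes cannot support the basis
  r <- QR$rank
  if (r < df + 1)
    abort(sprintf("Design [1, t, spline] is rank deficient (rank %d < %d).",
                  r, df + 1))
  Q <- qr.Q(QR)[, seq_len(r), drop = FALSE]
  # fix the sign convention: make the R diagonal positive
  dR <- diag(qr.R(QR))[seq_len(r)]
  Q <- sweep(Q, 2, sign(dR), `*`)
  Z <- Q[, -1, drop = FALSE]
  colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  attr(Z, "basis") <- basis
  Z
}

#' Full time-course design matrix with sample blocking
#'
#' Binds the orthonormalized pseudotime covariates with treatment-contrast
#' indicator columns for the sample of origin (developmental stage). The
#' pseudo-bulk samples from one biological sample are not independent
#' replicates, so the stage enters as a blocking factor: every stage except
#' the reference (the first factor level, the earliest stage) gets an
#' indicator column, and the reference is absorbed into the intercept.
#'
#' @param Z matrix from [orthonormal_time_design()].
#' @param group_labels factor/character of sample stages, length `nrow(Z)`.
#' @param reference_group stage absorbed into the intercept (default: first
#'   factor level).
#' @return A `timecourse_design` object with fields `design`
#'   (`[(Intercept), Z1..Zdf, stages]`), `design_raw` (same column space
#'   with the raw spline basis, used for curve prediction), `Z`, `basis`,
#'   `group` and `reference_group`.
#' @export
build_design <- function(Z, group_labels, reference_group = NULL) {
  if (length(group_labels) != nrow(Z))
    abort("`group_labels` length must match rows of Z.")
  g <- as.factor(group_labels)
  if (any(table(g) == 0)) abort("Every group level must have members.")
  if (!is.null(reference_group)) {
    if (!reference_group %in% levels(g))
      abort(sprintf("Unknown reference group '%s'.", reference_group))
    g <- stats::relevel(g, ref = reference_group)
  }
  dummies <- NULL
  if (nlevels(g) > 1) {
    dummies <- stats::model.matrix(~g)[, -1, drop = FALSE]
    colnames(dummies) <- levels(g)[-1]
  }
  design <- cbind(`(Intercept)` = 1, Z, dummies)
  basis <- attr(Z, "basis")
  Xraw <- basis$X
  colnames(Xraw) <- paste0("X", seq_len(ncol(Xraw)))
  design_raw <- cbind(`(Intercept)` = 1, Xraw, dummies)
  if (qr(design)$rank < ncol(design))
    abort("Full design matrix is rank deficient.")
  structure(list(design = design, design_raw = design_raw, Z = Z,
                 basis = basis, group = g,
                 reference_group = levels(g)[1]),
            class = "timecourse_design")
}

#' @export
#' @method print timecourse_design
print.timecourse_design <- function(x, ...) {
  cat(sprintf("timecourse_design: %d samples, columns [%s]\n",
              nrow(x$design), paste(colnames(x$design), collapse = ", ")))
  invisible(x)
}

#' @rdname tidy_pseudotempo
#' @export
tidy.timecourse_design <- function(x, ...) {
  as_tibble(as.data.frame(x$design))
}
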