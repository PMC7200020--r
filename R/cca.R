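## Soft-threshold and L2-normalize a vector, choosing the threshold by
## binary search so that the L1 norm of the result is at most `c1`
## (penalized-matrix-decomposition style sparsity). `c1` in [1, sqrt(length)].
soft_l1_unit <- function(v, c1) {
  soft <- function(delta) {
    w <- sign(v) * pmax(abs(v) - delta, 0)
    n2 <- sqrt(sum(w^2))
    if (n2 == 0) w else w / n2
  }
  w <- soft(0)
  if (sum(abs(w)) <= c1 + 1e-12) return(w)
  lo <- 0; hi <- max(abs(v))
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    w <- soft(mid)
    if (sum(abs(w)) > c1) lo <- mid else hi <- mid
  }
  soft(hi)
}

#' Canonical correlation between two gene groups
#'
#' Finds the first pair of canonical vectors \eqn{a, b} maximizing the
#' correlation of \eqn{a^T X} with \eqn{b^T Y}, where the rows of \code{X}
#' and \code{Y} are genes and the columns are matched samples. Rows are
#' standardized first, so the result is invariant to per-gene affine
#' rescaling. The canonical correlation is reported as the non-negative
#' sample correlation of the two canonical variates.
#'
#' Two backends are available. \code{"diag-sparse"} (default) is a
#' penalized matrix decomposition: the within-group covariances are treated
#' as identity and power iterations are run on the sample cross-covariance
#' with L1 soft-thresholding of \eqn{a} and \eqn{b}, the per-side L1 bound
#' being \code{penalty * sqrt(dim)} (clamped to the feasible range). The
#' default \code{penalty = 1} imposes no shrinkage (the bound is always
#' met), which keeps the canonical weights faithful to the definition of
#' canonical correlation; lower it for large modules where sparse weights
#' are wanted. Conditioning statistics built from several canonical
#' correlations are sensitive to shrinkage, so the same penalty should be
#' used for all of them.
#' \code{"ridge"} is classical CCA with Tikhonov-regularized within-group
#' covariances \eqn{\Sigma_{XX} + \lambda I}, \eqn{\Sigma_{YY} + \lambda I};
#' \code{lambda = NULL} defaults to \code{0.1 * trace/dim} per side. With a
#' single gene on each side both backends reduce to the absolute Pearson
#' correlation.
#'
#' @param X m x s matrix (one gene group), \code{Y} n x s matrix (the other
#'   group), sharing the sample columns.
#' @param Y see \code{X}.
#' @param backend \code{"diag-sparse"} or \code{"ridge"}.
#' @param penalty sparsity level in (0, 1] for \code{"diag-sparse"}
#'   (default 1: no shrinkage).
#' @param lambda ridge regularization for \code{"ridge"}; \code{NULL} for
#'   the trace-scaled default.
#' @param maxIter,tol power-iteration controls for \code{"diag-sparse"}.
#' @return list with canonical weight vectors \code{a}, \code{b}, the
#'   canonical correlation \code{cc} in \code{[0, 1]}, and \code{backend}.
#' @export
canonicalCorrelation <- function(X, Y,
                                 backend = c("diag-sparse", "ridge"),
                                 penalty = 1, lambda = NULL,
                                 maxIter = 200L, tol = 1e-9) {
  backend <- match.arg(backend)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  if (ncol(X) != ncol(Y)) stop("X and Y must share their sample columns")
  s <- ncol(X)
  if (s < 3L) stop("at least 3 samples are required")
  Xs <- standardize_rows(X, "X")
  Ys <- standardize_rows(Y, "Y")
  m <- nrow(Xs); n <- nrow(Ys)
  Z <- Xs %*% t(Ys) / (s - 1)   # cross-correlation matrix, m x n
  if (backend == "diag-sparse") {
    c1 <- min(max(1, penalty * sqrt(m)), sqrt(m))
    c2 <- min(max(1, penalty * sqrt(n)), sqrt(n))
    sv <- svd(Z, nu = 1L, nv = 1L)
    a <- sv$u[, 1L]; b <- sv$v[, 1L]
    delta <- Inf
    for (it in seq_len(maxIter)) {
      a_new <- soft_l1_unit(drop(Z %*% b), c1)
      b_new <- soft_l1_unit(drop(crossprod(Z, a_new)), c2)
      delta <- max(abs(a_new - a), abs(b_new - b))
      a <- a_new; b <- b_new
      if (delta < tol) break
    }
    if (delta >= tol)
      stop(sprintf(
        "sparse CCA did not converge in %d iterations (last delta = %.3g)",
        maxIter, delta))
  } else {
    Sxx <- tcrossprod(Xs) / (s - 1)
    Syy <- tcrossprod(Ys) / (s - 1)
    if (is.null(lambda)) lambda <- 0.1 * c(sum(diag(Sxx)) / m,
                                           sum(diag(Syy)) / n)
    if (length(lambda) == 1L) lambda <- rep(lambda, 2L)
    Rx <- Sxx + diag(lambda[1L], m)
    Ry <- Syy + diag(lambda[2L], n)
    Wx <- inv_sqrt_sym(Rx)
    Wy <- inv_sqrt_sym(Ry)
    sv <- svd(Wx %*% Z %*% Wy, nu = 1L, nv = 1L)
    a <- drop(Wx %*% sv$u[, 1L])
    b <- drop(Wy %*% sv$v[, 1L])
  }
  if (all(a == 0) || all(b == 0))
    stop("degenerate canonical vectors (all-zero); ",
         "check the penalty/regularization settings")
  u <- drop(crossprod(Xs, a))
  v <- drop(crossprod(Ys, b))
  if (sd(u) == 0 || sd(v) == 0)
    stop("constant canonical variate")
  list(a = a, b = b, cc = abs(cor(u, v)), backend = backend)
}

## Symmetric inverse square root via eigendecomposition.
inv_sqrt_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Partial canonical correlation conditioning on a third group
#'
#' Combines three canonical correlations by the scalar partial-correlation
#' formula:
#' \deqn{PCC = (CC - CC_{mir,mr} \cdot CC_{mir,lncr}) /
#'   (\sqrt{1 - CC_{mir,mr}^2} \sqrt{1 - CC_{mir,lncr}^2})}
#' Because the three canonical correlations are each maximized over their
#' own weight vectors, the result can fall outside \code{[-1, 1]}; it is
#' returned as computed.
#'
#' @param cc canonical correlation between the lncRNA and mRNA groups.
#' @param ccMirMr canonical correlation between the conditioning (miRNA)
#'   group and the mRNA group, in \code{[0, 1)}.
#' @param ccMirLncr canonical correlation between the conditioning group
#'   and the lncRNA group, in \code{[0, 1)}.
#' @return the partial canonical correlation.
#' @export
partialCanonicalCorrelation <- function(cc, ccMirMr, ccMirLncr) {
  stopifnot(is.finite(cc), is.finite(ccMirMr), is.finite(ccMirLncr),
            ccMirMr >= 0, ccMirLncr >= 0)
  if (ccMirMr >= 1 || ccMirLncr >= 1)
    stop("conditioning canonical correlation of 1 gives a zero denominator")
  (cc - ccMirMr * ccMirLncr) /
    (sqrt(1 - ccMirMr^2) * sqrt(1 - ccMirLncr^2))
}

#' Sensitivity canonical correlation
#'
#' The drop in group-level canonical correlation attributable to the
#' conditioning miRNAs: \code{cc - pcc}, exactly.
#'
#' @param cc canonical correlation.
#' @param pcc partial canonical correlation.
#' @return \code{cc - pcc}.
#' @export
sensitivityCanonicalCorrelation <- function(cc, pcc) cc - pcc
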