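#' Normalized expression-level rank statistic per gene and sample
#'
#' First step of single-sample gene-set scoring. For each gene a
#' Gaussian-kernel estimate of its expression cumulative distribution
#' across samples is computed (bandwidth = per-gene sample standard
#' deviation / 4). The estimate is monotone in expression, so each gene's
#' cross-sample ordering of the statistic is invariant under any strictly
#' increasing per-gene transformation, and the whole statistic is exactly
#' invariant under per-gene affine rescaling. Within each sample, genes
#' are then ranked by that statistic in decreasing order (ties broken by
#' gene-id order) and the symmetric rank statistic
#' \eqn{r_{ij} = |p/2 - rank_{ij}|} is returned, where \code{p} is the
#' number of genes.
#'
#' @param expr genes x samples matrix (typically joined lncRNA + mRNA).
#' @return list with \code{r} (genes x samples matrix of rank statistics in
#'   \code{[0, p/2]}), \code{ordering} (genes x samples matrix of indices:
#'   column j gives the gene order \code{g(1..p)} for sample j, best-ranked
#'   first) and \code{kcdf} (the kernel CDF estimates the ranks are taken
#'   from).
#' @export
gsvaRankStatistic <- function(expr) {
  expr <- as_expression_matrix(expr)
  p <- nrow(expr); ns <- ncol(expr)
  if (ns < 2L) stop("at least 2 samples are required")
  kcdf <- matrix(0, p, ns, dimnames = dimnames(expr))
  for (i in seq_len(p)) {
    x <- expr[i, ]
    h <- sd(x) / 4
    if (h == 0) {
      kcdf[i, ] <- 0.5   # constant gene: ties, broken by gene order below
    } else {
      kcdf[i, ] <- colMeans(pnorm(outer(x, x, function(a, b) (b - a) / h)))
    }
  }
  r <- matrix(0, p, ns, dimnames = dimnames(expr))
  ordering <- matrix(0L, p, ns)
  for (j in seq_len(ns)) {
    ord <- order(-kcdf[, j], seq_len(p))  # rank 1 = largest statistic
    rank_ij <- integer(p); rank_ij[ord] <- seq_len(p)
    r[, j] <- abs(p / 2 - rank_ij)
    ordering[, j] <- ord
  }
  list(r = r, ordering = ordering, kcdf = kcdf)
}

#' Single-sample enrichment score of a gene set
#'
#' Kolmogorov-Smirnov-like random walk over a sample's ranked gene list.
#' With genes ordered \code{g(1..p)} by decreasing \code{|r|}, the walk at
#' position \code{l} is the in-set cumulative sum of \code{|r|^tau}
#' (normalized by the in-set total) minus the out-of-set cumulative count
#' divided by \code{p - |set|}. The enrichment score is the walk value at
#' its maximum absolute deviation from zero (signed). At \code{tau = 1}
#' both walk terms lie in \code{[0, 1]}, so the score lies in
#' \code{[-1, 1]}.
#'
#' @param rankStat result of [gsvaRankStatistic()], or a list with elements
#'   \code{r} and \code{ordering} of matching shape.
#' @param moduleGenes character vector: the gene set; must overlap the
#'   matrix genes and not cover all of them.
#' @param tau walk weight on the rank statistic (default 1).
#' @return numeric vector of one enrichment score per sample.
#' @export
gsvaEnrichmentScore <- function(rankStat, moduleGenes, tau = 1) {
  r <- rankStat$r; ordering <- rankStat$ordering
  p <- nrow(r); ns <- ncol(r)
  inset <- rownames(r) %in% moduleGenes
  if (!any(inset)) stop("gene set does not overlap the expression genes")
  if (all(inset)) stop("gene set covers every gene (zero denominator)")
  es <- numeric(ns)
  for (j in seq_len(ns)) {
    ord <- ordering[, j]
    w <- abs(r[ord, j])^tau
    member <- inset[ord]
    num <- cumsum(w * member) / sum(w * member)
    pen <- cumsum(!member) / (p - sum(inset))
    v <- num - pen
    es[j] <- v[which.max(abs(v))]
  }
  names(es) <- colnames(r)
  es
}

#' Enrichment-score matrix for a set of modules
#'
#' Convenience wrapper: one [gsvaRankStatistic()] pass, then one
#' [gsvaEnrichmentScore()] per module over its combined lncRNA + mRNA
#' member set.
#'
#' @param expr joined genes x samples matrix covering module members.
#' @param modules a [ModuleSet-class] (or [SpongeModuleSet-class]).
#' @param tau walk weight (default 1).
#' @return modules x samples matrix of enrichment scores.
#' @export
gsvaScores <- function(expr, modules, tau = 1) {
  stopifnot(is(modules, "ModuleSet"))
  rs <- gsvaRankStatistic(expr)
  es <- t(vapply(seq_len(length(modules)), function(i)
    gsvaEnrichmentScore(rs, c(modules@lncrna[[i]], modules@mrna[[i]]),
                        tau = tau),
    numeric(ncol(expr))))
  dimnames(es) <- list(modules@moduleIds, colnames(expr))
  es
}
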