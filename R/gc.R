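#' Pairwise sensitivity-correlation sponge network
#'
#' Graph-clustering baseline, step 1. Scores every (lncRNA, mRNA) pair:
#' the pair is kept as a network edge when (i) the two genes share at
#' least \code{minShared} miRNAs in the interaction table, (ii) the
#' sharing is significant by the upper-tail hypergeometric test at
#' \code{alpha}, (iii) their Pearson correlation is positive and
#' significant at \code{alpha} (one-sided t-test for a correlation
#' coefficient), and (iv) the sensitivity correlation — correlation minus
#' the partial correlation conditioning on the shared miRNAs' expression
#' (computed by residualizing both genes on the shared-miRNA block) —
#' exceeds \code{scMin}.
#'
#' @param lncrnaExpr,mrnaExpr,mirnaExpr genes x samples matrices with
#'   identical sample columns.
#' @param interactions data.frame with columns \code{mirna},
#'   \code{target}.
#' @param minShared minimum number of shared miRNAs (default 3).
#' @param scMin sensitivity-correlation threshold (default 0.1).
#' @param alpha significance level for sharing and correlation tests
#'   (default 0.05).
#' @return data.frame of retained edges with columns \code{lncrna},
#'   \code{mrna}, \code{shared_mirna_count}, \code{correlation},
#'   \code{partial_correlation}, \code{sensitivity_correlation},
#'   \code{p_share}, \code{p_correlation}. May have zero rows.
#' @export
scPairwiseNetwork <- function(lncrnaExpr, mrnaExpr, mirnaExpr,
                              interactions, minShared = 3L, scMin = 0.1,
                              alpha = 0.05) {
  lncrnaExpr <- as_expression_matrix(lncrnaExpr)
  mrnaExpr <- as_expression_matrix(mrnaExpr)
  mirnaExpr <- as_expression_matrix(mirnaExpr)
  if (!identical(colnames(lncrnaExpr), colnames(mrnaExpr)) ||
      !identical(colnames(lncrnaExpr), colnames(mirnaExpr)))
    stop("expression matrices must share identical sample columns; ",
         "run alignSamples() first")
  all_mirnas <- rownames(mirnaExpr)
  ia <- interactions[interactions$mirna %in% all_mirnas, , drop = FALSE]
  targets_of <- split(ia$mirna, ia$target)
  N1 <- length(all_mirnas)
  s <- ncol(lncrnaExpr)
  edges <- list()
  for (lnc in rownames(lncrnaExpr)) {
    mir_l <- unique(targets_of[[lnc]])
    if (length(mir_l) == 0L) next
    for (mr in rownames(mrnaExpr)) {
      mir_m <- unique(targets_of[[mr]])
      shared <- intersect(mir_l, mir_m)
      if (length(shared) < minShared) next
      p_share <- hypergeomEnrichment(N1, length(mir_l), length(mir_m),
                                     length(shared))
      if (p_share >= alpha) next
      x <- lncrnaExpr[lnc, ]; y <- mrnaExpr[mr, ]
      if (sd(x) == 0 || sd(y) == 0) next
      r <- cor(x, y)
      if (r <= 0) next
      p_cor <- cor_pvalue_onesided(r, s)
      if (p_cor >= alpha) next
      Z <- t(mirnaExpr[shared, , drop = FALSE])
      rx <- resid(lm(x ~ Z))
      ry <- resid(lm(y ~ Z))
      pr <- if (sd(rx) == 0 || sd(ry) == 0) 0 else cor(rx, ry)
      sc <- r - pr
      if (sc <= scMin) next
      edges[[length(edges) + 1L]] <- data.frame(
        lncrna = lnc, mrna = mr, shared_mirna_count = length(shared),
        correlation = r, partial_correlation = pr,
        sensitivity_correlation = sc, p_share = p_share,
        p_correlation = p_cor, stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(lncrna = character(), mrna = character(),
                      shared_mirna_count = integer(),
                      correlation = numeric(),
                      partial_correlation = numeric(),
                      sensitivity_correlation = numeric(),
                      p_share = numeric(), p_correlation = numeric()))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

## One-sided p-value for a positive Pearson correlation, via the exact
## t-statistic t = r sqrt((n-2)/(1-r^2)) on n-2 df.
cor_pvalue_onesided <- function(r, n) {
  if (n < 3L) return(1)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  pt(tstat, df = n - 2, lower.tail = FALSE)
}

#' Markov clustering of a sponge network
#'
#' Graph-clustering baseline, step 2. Builds an undirected graph from the
#' retained edges (self-loops added), forms the column-stochastic
#' transition matrix, and iterates expansion (matrix power
#' \code{expansion}) followed by inflation (entrywise power
#' \code{inflation} and column renormalization), pruning entries below
#' \code{pruneEps}, until the iterate changes by less than 1e-8 or
#' \code{maxIter} is reached (non-convergence returns the last iterate's
#' clusters with a warning). Clusters are read off the attractor rows of
#' the limit matrix; overlapping attractor supports are merged. Clusters
#' with fewer than 2 lncRNAs or fewer than 2 mRNAs are discarded.
#'
#' @param edges data.frame from [scPairwiseNetwork()] (columns
#'   \code{lncrna}, \code{mrna}); must be non-empty.
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param pruneEps entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param maxIter iteration cap (default 100).
#' @param minLncrna,minMrna per-cluster size filters (default 2 and 2).
#' @return a [ModuleSet-class] of the surviving clusters, labelled by
#'   decreasing size.
#' @export
mclCluster <- function(edges, inflation = 2, expansion = 2L,
                       pruneEps = 1e-5, maxIter = 100L,
                       minLncrna = 2L, minMrna = 2L) {
  if (!nrow(edges)) stop("'edges' is empty")
  lnc_ids <- unique(edges$lncrna)
  nodes <- c(lnc_ids, setdiff(unique(edges$mrna), lnc_ids))
  p <- length(nodes)
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$lncrna[i], edges$mrna[i]] <- 1
    A[edges$mrna[i], edges$lncrna[i]] <- 1
  }
  diag(A) <- 1
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < pruneEps] <- 0
    cs <- colSums(Minf)
    if (any(cs == 0)) {          # pruned a column empty; restore self-loop
      Minf[cbind(which(cs == 0), which(cs == 0))] <- 1
      cs <- colSums(Minf)
    }
    Mnew <- sweep(Minf, 2L, cs, "/")
    if (max(abs(Mnew - M)) < 1e-8) {
      M <- Mnew; converged <- TRUE; break
    }
    M <- Mnew
  }
  if (!converged)
    warning("Markov clustering did not converge in ", maxIter,
            " iterations; using the last iterate")
  attractors <- which(diag(M) > pruneEps)
  clusters <- lapply(attractors, function(a) nodes[M[a, ] > pruneEps])
  ## merge clusters sharing any node (overlapping attractor systems)
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(m) length(intersect(m, cl)) > 0,
                        NA))
    if (length(hit)) {
      merged[[hit[1L]]] <- union(Reduce(union, merged[hit]), cl)
      merged[hit[-1L]] <- NULL
    } else merged[[length(merged) + 1L]] <- cl
  }
  members <- lapply(merged, function(g)
    list(lncrna = sort(intersect(g, lnc_ids)),
         mrna = sort(setdiff(g, lnc_ids))))
  members <- Filter(function(m)
    length(m$lncrna) >= minLncrna && length(m$mrna) >= minMrna, members)
  if (!length(members)) return(ModuleSet(list(), list()))
  size <- vapply(members, function(m)
    length(m$lncrna) + length(m$mrna), 0L)
  firstid <- vapply(members, function(m) min(c(m$lncrna, m$mrna)), "")
  ord <- order(-size, firstid)
  members <- members[ord]
  ModuleSet(lapply(members, `[[`, "lncrna"),
            lapply(members, `[[`, "mrna"),
            paste0("GC", seq_along(members)))
}
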