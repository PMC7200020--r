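#' Choose a soft-thresholding power by scale-free fit
#'
#' For each candidate power \eqn{\beta} the unsigned weighted network
#' adjacency \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} is formed and the
#' connectivity \eqn{k_i = \sum_{j \ne i} a_{ij}} computed. Connectivities
#' are binned (equal-width bins) and the scale-free fit index is the squared
#' Pearson correlation of \eqn{\log_{10}}(bin frequency) versus
#' \eqn{\log_{10}}(mean connectivity per bin), with the sign flipped to
#' negative when the regression slope is positive (a rising degree
#' distribution is not scale-free). The smallest power reaching
#' \code{r2Target} is chosen; if none does, the power maximizing the fit
#' index is returned with \code{reached_target = FALSE} and a warning.
#'
#' @param expr genes x samples matrix (joined lncRNA + mRNA expression).
#' @param powers candidate integer powers (default 1:20).
#' @param r2Target minimum acceptable fit index (default 0.8).
#' @param nBins number of connectivity bins (default 10).
#' @return list with \code{power} (chosen), \code{reached_target}, and
#'   \code{scan}, a data.frame of \code{power}, \code{fit_r2} (signed) and
#'   \code{mean_connectivity}.
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, r2Target = 0.8,
                              nBins = 10L) {
  expr <- as_expression_matrix(expr)
  if (ncol(expr) < 4L) stop("at least 4 samples are required")
  if (!length(powers)) stop("'powers' must be non-empty")
  s <- apply(expr, 1L, sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " constant gene row(s) excluded")
    expr <- expr[s > 0, , drop = FALSE]
  }
  abscor <- abs(cor(t(expr)))
  diag(abscor) <- 0
  scan <- data.frame(power = powers, fit_r2 = NA_real_,
                     mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    a <- abscor^powers[i]
    k <- rowSums(a)
    scan$mean_connectivity[i] <- mean(k)
    scan$fit_r2[i] <- scaleFreeFitIndex(k, nBins = nBins)
  }
  fit <- ifelse(is.na(scan$fit_r2), -Inf, scan$fit_r2)
  if (r2Target <= 0)                  # no scale-free requirement
    return(list(power = powers[1L], reached_target = TRUE, scan = scan))
  ok <- which(fit >= r2Target)
  if (length(ok)) {
    chosen <- powers[ok[1L]]
    reached <- TRUE
  } else {
    chosen <- powers[which.max(fit)]
    reached <- FALSE
    warning(sprintf(
      "no candidate power reaches fit index %.2f; using power %d (R2 = %.3f)",
      r2Target, chosen, max(fit)))
  }
  list(power = chosen, reached_target = reached, scan = scan)
}

#' Signed scale-free topology fit index of a connectivity vector
#'
#' @param k non-negative connectivity values.
#' @param nBins number of equal-width bins.
#' @return signed R-squared of the log-log degree-distribution regression.
#' @export
scaleFreeFitIndex <- function(k, nBins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 2L) return(NA_real_)
  br <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  meank <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(NA_real_)
  x <- log10(meank[keep]); y <- log10(freq[keep] / sum(freq[keep]))
  if (sd(x) == 0 || sd(y) == 0) return(0)
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (coef(fit)[2L] > 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' Neighborhood-sharing similarity of an unsigned weighted network:
#' \deqn{TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{L_{ij} = \sum_u a_{iu} a_{uj}} and \eqn{k_i = \sum_j a_{ij}};
#' the diagonal is set to 1.
#'
#' @param adjacency symmetric matrix with entries in \code{[0, 1]} and zero
#'   diagonal.
#' @return symmetric matrix of the same dimension with unit diagonal and
#'   entries in \code{[0, 1]}.
#' @export
tomSimilarity <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("'adjacency' must be a square matrix")
  if (max(abs(adjacency - t(adjacency))) > 1e-10)
    stop("'adjacency' must be symmetric")
  if (any(diag(adjacency) != 0))
    stop("'adjacency' must have a zero diagonal")
  if (min(adjacency) < 0 || max(adjacency) > 1)
    stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(adjacency)
  L <- adjacency %*% adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (L + adjacency) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect lncRNA-mRNA co-expression modules
#'
#' Stage-one detector: joins the lncRNA and mRNA matrices, picks a
#' soft-thresholding power by scale-free fit (unless \code{power} is given),
#' builds the unsigned adjacency \eqn{|cor|^\beta}, converts it to a
#' topological overlap dissimilarity \eqn{1 - TOM}, clusters genes by
#' average-linkage hierarchical clustering, and cuts the tree at a fixed
#' height (\code{cutHeight} times the maximum merge height). Clusters
#' smaller than \code{minModuleSize} are treated as unassigned background
#' and dropped, as are clusters with fewer than 2 lncRNAs or fewer than 2
#' mRNAs. Modules are labelled \code{M1, M2, ...} by decreasing size (ties
#' broken by smallest member id) so the labelling does not depend on input
#' gene order.
#'
#' @param lncrna,mrna genes x samples matrices with identical, aligned
#'   sample columns; their gene id sets must be disjoint.
#' @param powers,r2Target,nBins passed to [pickSoftThreshold()].
#' @param minModuleSize smallest cluster kept (default 30).
#' @param cutHeight tree-cut height as a fraction of the maximum merge
#'   height (default 0.995).
#' @param power optional fixed soft power, skipping the scan.
#' @return a [ModuleSet-class]; the chosen power and scan are attached as
#'   attributes \code{"power"} and \code{"soft_threshold"}.
#' @export
detectCoexpressionModules <- function(lncrna, mrna, powers = 1:20,
                                      r2Target = 0.8, nBins = 10L,
                                      minModuleSize = 30L,
                                      cutHeight = 0.995, power = NULL) {
  lncrna <- as_expression_matrix(lncrna)
  mrna <- as_expression_matrix(mrna)
  if (!identical(colnames(lncrna), colnames(mrna)))
    stop("lncRNA and mRNA matrices must have identical sample columns; ",
         "run alignSamples() first")
  if (length(intersect(rownames(lncrna), rownames(mrna))))
    stop("lncRNA and mRNA gene id sets overlap")
  expr <- rbind(lncrna, mrna)
  s <- apply(expr, 1L, sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " constant gene row(s) excluded")
    expr <- expr[s > 0, , drop = FALSE]
  }
  if (is.null(power)) {
    st <- pickSoftThreshold(expr, powers = powers, r2Target = r2Target,
                            nBins = nBins)
    power <- st$power
  } else st <- NULL
  adj <- abs(cor(t(expr)))^power
  diag(adj) <- 0
  diss <- 1 - tomSimilarity(adj)
  tree <- hclust(as.dist(diss), method = "average")
  groups <- cutree(tree, h = cutHeight * max(tree$height))
  sets <- split(names(groups), groups)
  sets <- sets[lengths(sets) >= minModuleSize]
  lnc_ids <- rownames(lncrna)
  members <- lapply(sets, function(g)
    list(lncrna = sort(intersect(g, lnc_ids)),
         mrna = sort(setdiff(g, lnc_ids))))
  members <- Filter(function(m)
    length(m$lncrna) >= 2L && length(m$mrna) >= 2L, members)
  if (!length(members)) {
    warning("no co-expression module passed the size filters")
    out <- ModuleSet(list(), list())
  } else {
    size <- vapply(members, function(m)
      length(m$lncrna) + length(m$mrna), 0L)
    firstid <- vapply(members, function(m)
      min(c(m$lncrna, m$mrna)), "")
    ord <- order(-size, firstid)
    members <- members[ord]
    out <- ModuleSet(lapply(members, `[[`, "lncrna"),
                     lapply(members, `[[`, "mrna"),
                     paste0("M", seq_along(members)))
  }
  attr(out, "power") <- power
  attr(out, "soft_threshold") <- st
  out
}
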