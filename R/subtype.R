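#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (thin validated wrapper over
#' \code{stats::t.test}). When both groups are constant with equal means
#' the test is vacuous and p = 1 is returned.
#'
#' @param x,y numeric vectors with at least 2 observations each.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchTTest <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Call subtype-specific modules from enrichment scores
#'
#' A module is called up-regulated for a subtype when its mean enrichment
#' score in that subtype's samples is higher than in every other subtype
#' and every pairwise Welch test against the other subtypes has
#' p < \code{alpha}; down-regulated symmetrically. A module can carry an up
#' call for one subtype and a down call for another. Subtypes with fewer
#' than 2 samples are excluded with a warning. Optionally the pairwise
#' p-values of each candidate call can be Benjamini-Hochberg adjusted
#' before thresholding (off by default).
#'
#' @param es modules x samples enrichment-score matrix (see
#'   [gsvaScores()]).
#' @param labels named character vector or factor: subtype label per
#'   sample; names must match the columns of \code{es}.
#' @param alpha per-pair significance level (default 0.05).
#' @param adjust apply BH across the pairwise p-values of each
#'   module/subtype candidate (default \code{FALSE}).
#' @return data.frame with \code{module_id}, \code{subtype},
#'   \code{direction} (\code{"up"}/\code{"down"}), \code{max_pairwise_p}.
#' @export
subtypeSpecificModules <- function(es, labels, alpha = 0.05,
                                   adjust = FALSE) {
  if (is.null(names(labels))) {
    stopifnot(length(labels) == ncol(es))
    names(labels) <- colnames(es)
  }
  labels <- labels[colnames(es)]
  if (anyNA(labels)) stop("every sample in 'es' must carry a subtype label")
  labels <- as.character(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("subtype(s) with < 2 samples excluded: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    es <- es[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2L) stop("at least 2 subtypes are required")
  calls <- list()
  for (mod in rownames(es)) {
    v <- es[mod, ]
    means <- tapply(v, labels, mean)
    for (st in subtypes) {
      others <- setdiff(subtypes, st)
      pw <- vapply(others, function(o)
        welchTTest(v[labels == st], v[labels == o])$p, 0)
      if (adjust) pw <- bhAdjust(pw)
      dir <- if (all(means[st] > means[others])) "up"
             else if (all(means[st] < means[others])) "down"
             else NA_character_
      if (!is.na(dir) && all(pw < alpha))
        calls[[length(calls) + 1L]] <- data.frame(
          module_id = mod, subtype = st, direction = dir,
          max_pairwise_p = max(pw), stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(module_id = character(), subtype = character(),
                      direction = character(), max_pairwise_p = numeric()))
  do.call(rbind, calls)
}
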