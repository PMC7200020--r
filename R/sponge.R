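#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least \code{L} successes when \code{K} items
#' are drawn without replacement from a population of \code{N} items of
#' which \code{M} are successes:
#' \deqn{p = 1 - \sum_{i=0}^{L-1} \binom{M}{i}\binom{N-M}{K-i} / \binom{N}{K}}
#' evaluated through the log-space hypergeometric tail (not the literal
#' 1-minus-sum, which loses precision for extreme enrichments). Serves both
#' the miRNA-sharing test and disease-gene enrichment.
#'
#' @param N population size.
#' @param M number of success states in the population.
#' @param K number of draws.
#' @param L observed number of successes.
#' @return p-value in \code{[0, 1]}; \code{L = 0} gives exactly 1.
#' @export
hypergeomEnrichment <- function(N, M, K, L) {
  stopifnot(length(N) == 1L, length(M) == 1L, length(K) == 1L,
            length(L) == 1L)
  if (any(c(N, M, K, L) < 0) || any(c(N, M, K, L) != round(c(N, M, K, L))))
    stop("N, M, K, L must be non-negative integers")
  if (M > N || K > N)
    stop("M and K must not exceed the population size N")
  if (L > K || L > M)
    stop("L must not exceed min(M, K): check the argument order")
  if (L == 0) return(1)
  phyper(L - 1, m = M, n = N - M, k = K, lower.tail = FALSE)
}

#' miRNA sharing between a module's lncRNA and mRNA groups
#'
#' From the putative interaction table, collects the miRNAs interacting
#' with at least one module lncRNA (count \code{M1}) and with at least one
#' module mRNA (count \code{K1}); their intersection is the shared set
#' (count \code{L1}). \code{N1} is the number of all miRNAs in the dataset.
#' The sharing significance is the upper-tail hypergeometric p-value of the
#' overlap.
#'
#' @param lncrnaIds,mrnaIds character vectors of module members.
#' @param interactions data.frame with columns \code{mirna} and
#'   \code{target} (as returned by [readInteractionTable()]).
#' @param allMirnas character vector of every miRNA id in the dataset.
#' @return list with \code{N1}, \code{M1}, \code{K1}, \code{L1},
#'   \code{shared_ids} and \code{p_value}.
#' @export
sharedMirnas <- function(lncrnaIds, mrnaIds, interactions, allMirnas) {
  if (!length(allMirnas)) stop("'allMirnas' must be non-empty")
  stopifnot(all(c("mirna", "target") %in% colnames(interactions)))
  ia <- interactions[interactions$mirna %in% allMirnas, , drop = FALSE]
  mir_l <- unique(ia$mirna[ia$target %in% lncrnaIds])
  mir_m <- unique(ia$mirna[ia$target %in% mrnaIds])
  shared <- sort(intersect(mir_l, mir_m))
  N1 <- length(unique(allMirnas))
  res <- list(N1 = N1, M1 = length(mir_l), K1 = length(mir_m),
              L1 = length(shared), shared_ids = shared)
  res$p_value <- hypergeomEnrichment(N1, res$M1, res$K1, res$L1)
  res
}

#' Apply the sponge criteria to co-expression modules
#'
#' Screens each stage-one co-expression module through three sequential
#' criteria, discarding a module at the first criterion it fails:
#' \enumerate{
#'   \item significant miRNA sharing between the lncRNA and mRNA groups
#'     (hypergeometric p-value < \code{pShareMax}), with at least one
#'     shared miRNA;
#'   \item strong collective co-expression: canonical correlation between
#'     the lncRNA and mRNA expression groups > \code{ccMin};
#'   \item substantial miRNA influence: sensitivity canonical correlation
#'     (canonical correlation minus the partial canonical correlation
#'     conditioning on the shared-miRNA expression group) > \code{sccMin}.
#' }
#' All three canonical correlations entering the partial-correlation
#' formula are computed with the same backend and penalty.
#'
#' @param modules a [ModuleSet-class] from [detectCoexpressionModules()].
#' @param mirnaExpr,lncrnaExpr,mrnaExpr genes x samples matrices with
#'   identical sample columns.
#' @param interactions putative miRNA-target pairs (data.frame with
#'   \code{mirna}, \code{target}).
#' @param pShareMax,ccMin,sccMin acceptance thresholds
#'   (defaults 0.05, 0.8, 0.1).
#' @param backend,penalty passed to [canonicalCorrelation()].
#' @return a [SpongeModuleSet-class] of accepted modules. The attribute
#'   \code{"rejections"} is a data.frame recording, for each rejected
#'   module, the single criterion it failed.
#' @export
identifySpongeModules <- function(modules, mirnaExpr, lncrnaExpr, mrnaExpr,
                                  interactions, pShareMax = 0.05,
                                  ccMin = 0.8, sccMin = 0.1,
                                  backend = c("diag-sparse", "ridge"),
                                  penalty = 1) {
  stopifnot(is(modules, "ModuleSet"))
  backend <- match.arg(backend)
  mirnaExpr <- as_expression_matrix(mirnaExpr)
  lncrnaExpr <- as_expression_matrix(lncrnaExpr)
  mrnaExpr <- as_expression_matrix(mrnaExpr)
  if (!identical(colnames(mirnaExpr), colnames(lncrnaExpr)) ||
      !identical(colnames(mirnaExpr), colnames(mrnaExpr)))
    stop("expression matrices must share identical sample columns; ",
         "run alignSamples() first")
  all_mirnas <- rownames(mirnaExpr)
  acc <- list(); rej <- list()
  for (i in seq_len(length(modules))) {
    id <- modules@moduleIds[i]
    lnc <- modules@lncrna[[i]]; mr <- modules@mrna[[i]]
    missing <- c(setdiff(lnc, rownames(lncrnaExpr)),
                 setdiff(mr, rownames(mrnaExpr)))
    if (length(missing))
      stop(sprintf("module '%s' references genes absent from expression: %s",
                   id, paste(head(missing, 5L), collapse = ", ")))
    sh <- sharedMirnas(lnc, mr, interactions, all_mirnas)
    if (sh$p_value >= pShareMax || sh$L1 < 1L) {
      rej[[id]] <- "criterion1_mirna_sharing"
      next
    }
    cca <- canonicalCorrelation(lncrnaExpr[lnc, , drop = FALSE],
                                mrnaExpr[mr, , drop = FALSE],
                                backend = backend, penalty = penalty)
    if (cca$cc <= ccMin) {
      rej[[id]] <- "criterion2_canonical_correlation"
      next
    }
    Zm <- mirnaExpr[sh$shared_ids, , drop = FALSE]
    cc_mm <- canonicalCorrelation(Zm, mrnaExpr[mr, , drop = FALSE],
                                  backend = backend, penalty = penalty)$cc
    cc_ml <- canonicalCorrelation(Zm, lncrnaExpr[lnc, , drop = FALSE],
                                  backend = backend, penalty = penalty)$cc
    pcc <- partialCanonicalCorrelation(cca$cc, cc_mm, cc_ml)
    scc <- sensitivityCanonicalCorrelation(cca$cc, pcc)
    if (scc <= sccMin) {
      rej[[id]] <- "criterion3_sensitivity"
      next
    }
    acc[[id]] <- list(lncrna = lnc, mrna = mr, shared = sh$shared_ids,
                      stats = data.frame(p_share = sh$p_value, cc = cca$cc,
                                         cc_mir_mr = cc_mm,
                                         cc_mir_lncr = cc_ml,
                                         pcc = pcc, scc = scc))
  }
  stats <- if (length(acc)) do.call(rbind, lapply(acc, `[[`, "stats"))
           else data.frame(p_share = numeric(), cc = numeric(),
                           cc_mir_mr = numeric(), cc_mir_lncr = numeric(),
                           pcc = numeric(), scc = numeric())
  rownames(stats) <- NULL
  out <- new("SpongeModuleSet",
             moduleIds = as.character(names(acc)),
             lncrna = lapply(acc, `[[`, "lncrna"),
             mrna = lapply(acc, `[[`, "mrna"),
             sharedMirnas = lapply(acc, `[[`, "shared"),
             stats = stats)
  attr(out, "rejections") <- data.frame(
    module_id = names(rej),
    reason = unlist(rej, use.names = FALSE),
    stringsAsFactors = FALSE)
  out
}
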