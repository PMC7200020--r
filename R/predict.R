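#' Disease-gene enrichment of a module
#'
#' Upper-tail hypergeometric test of the overlap between a module's
#' members (lncRNAs and mRNAs) and a disease gene list, against a stated
#' background of all genes in the dataset. A module is flagged
#' disease-related when p < \code{alpha}.
#'
#' @param geneIds character vector: the module's combined members.
#' @param diseaseGenes character vector of disease-associated gene ids.
#' @param background character vector: every gene (lncRNA and mRNA) in the
#'   dataset; must contain all module members.
#' @param alpha flag threshold (default 0.05).
#' @return list with \code{p_value}, \code{related} and the test counts
#'   \code{N2} (background size), \code{M2} (disease genes in background),
#'   \code{K2} (module size), \code{L2} (disease genes in module).
#' @export
diseaseEnrichment <- function(geneIds, diseaseGenes, background,
                              alpha = 0.05) {
  geneIds <- unique(as.character(geneIds))
  background <- unique(as.character(background))
  outside <- setdiff(geneIds, background)
  if (length(outside))
    stop("module gene(s) outside the background: ",
         paste(head(outside, 5L), collapse = ", "))
  dis <- intersect(unique(as.character(diseaseGenes)), background)
  N2 <- length(background)
  M2 <- length(dis)
  K2 <- length(geneIds)
  L2 <- length(intersect(geneIds, dis))
  p <- hypergeomEnrichment(N2, M2, K2, L2)
  list(p_value = p, related = p < alpha, N2 = N2, M2 = M2, K2 = K2,
       L2 = L2)
}

#' Predict sponge lncRNA-mRNA pairs from modules
#'
#' Every lncRNA is predicted to sponge-pair with every mRNA of its own
#' module; pairs are pooled over modules and deduplicated.
#'
#' @param modules a [ModuleSet-class] or [SpongeModuleSet-class].
#' @return data.frame with columns \code{lncrna}, \code{mrna}.
#' @export
predictSpongePairs <- function(modules) {
  stopifnot(is(modules, "ModuleSet"))
  rows <- lapply(seq_len(length(modules)), function(i) {
    lnc <- modules@lncrna[[i]]; mr <- modules@mrna[[i]]
    if (!length(lnc) || !length(mr)) return(NULL)
    expand.grid(lncrna = lnc, mrna = mr, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(lncrna = character(), mrna = character()))
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict miRNA targets from modules
#'
#' Each shared miRNA of a module is predicted to target every lncRNA and
#' mRNA member of that module; pairs are pooled and deduplicated, with the
#' target class recorded.
#'
#' @param modules a [SpongeModuleSet-class] (shared miRNAs required).
#' @return data.frame with columns \code{mirna}, \code{target},
#'   \code{target_class} (\code{"lncRNA"}/\code{"mRNA"}).
#' @export
predictMirnaTargets <- function(modules) {
  stopifnot(is(modules, "SpongeModuleSet"))
  rows <- lapply(seq_len(length(modules)), function(i) {
    mir <- modules@sharedMirnas[[i]]
    if (!length(mir)) return(NULL)
    tgt <- c(modules@lncrna[[i]], modules@mrna[[i]])
    cls <- rep(c("lncRNA", "mRNA"),
               c(length(modules@lncrna[[i]]), length(modules@mrna[[i]])))
    data.frame(mirna = rep(mir, each = length(tgt)),
               target = rep(tgt, length(mir)),
               target_class = rep(cls, length(mir)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(mirna = character(), target = character(),
                      target_class = character()))
  out <- out[!duplicated(out[c("mirna", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two module-discovery results on shared downstream metrics
#'
#' For each of two module sets computed on the same inputs, reports the
#' percentage of disease-related modules (hypergeometric p < 0.05), the
#' percentage of survival biomarkers (log-rank p < 0.05 and HR > 2), and
#' the number of predicted sponge pairs found in a supplied ground-truth
#' pair list.
#'
#' @param methodModules named list of two (or more) [ModuleSet-class] /
#'   [SpongeModuleSet-class] objects, e.g.
#'   \code{list(sponge = ..., graph_clustering = ...)}.
#' @param diseaseGenes,background passed to [diseaseEnrichment()].
#' @param expr joined lncRNA + mRNA expression for survival scoring.
#' @param survival survival table, or \code{NULL} to skip that column.
#' @param truthPairs data.frame with columns \code{lncrna}, \code{mrna} of
#'   externally validated sponge pairs (may be empty).
#' @return data.frame with one row per method: \code{method},
#'   \code{n_modules}, \code{pct_disease}, \code{pct_biomarker},
#'   \code{n_pairs}, \code{n_validated_pairs}.
#' @export
compareMethods <- function(methodModules, diseaseGenes, background,
                           expr = NULL, survival = NULL,
                           truthPairs = NULL) {
  stopifnot(is.list(methodModules), length(methodModules) >= 2L,
            !is.null(names(methodModules)))
  rows <- lapply(names(methodModules), function(nm) {
    mods <- methodModules[[nm]]
    n <- length(mods)
    pct_dis <- if (n) {
      rel <- vapply(seq_len(n), function(i)
        diseaseEnrichment(c(mods@lncrna[[i]], mods@mrna[[i]]),
                          diseaseGenes, background)$related, NA)
      100 * mean(rel)
    } else NA_real_
    pct_bio <- if (n && !is.null(survival) && !is.null(expr)) {
      scr <- survivalScreen(mods, expr, survival)
      100 * mean(scr$biomarker)
    } else NA_real_
    pairs <- predictSpongePairs(mods)
    n_val <- if (!is.null(truthPairs) && nrow(pairs)) {
      key <- paste(pairs$lncrna, pairs$mrna)
      tkey <- paste(truthPairs$lncrna, truthPairs$mrna)
      sum(key %in% tkey)
    } else 0L
    data.frame(method = nm, n_modules = n, pct_disease = pct_dis,
               pct_biomarker = pct_bio, n_pairs = nrow(pairs),
               n_validated_pairs = n_val, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
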