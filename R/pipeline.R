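#' End-to-end sponge module discovery
#'
#' Convenience wrapper chaining the full two-stage pipeline:
#' [collapseReplicates()] on each matrix, [alignSamples()],
#' [detectCoexpressionModules()] on the lncRNA + mRNA matrices, then
#' [identifySpongeModules()] against the miRNA expression and interaction
#' table.
#'
#' @param mirna,lncrna,mrna genes x samples expression matrices.
#' @param interactions data.frame with columns \code{mirna},
#'   \code{target}.
#' @param coexpr list of arguments forwarded to
#'   [detectCoexpressionModules()].
#' @param sponge list of arguments forwarded to
#'   [identifySpongeModules()].
#' @return list with \code{coexpression} (the stage-one
#'   [ModuleSet-class]), \code{modules} (the accepted
#'   [SpongeModuleSet-class]), \code{rejections} (data.frame of rejected
#'   modules and reasons), and \code{aligned} (the aligned matrices).
#' @export
spongeModulePipeline <- function(mirna, lncrna, mrna, interactions,
                                 coexpr = list(), sponge = list()) {
  al <- alignSamples(collapseReplicates(mirna),
                     collapseReplicates(lncrna),
                     collapseReplicates(mrna))
  cx <- do.call(detectCoexpressionModules,
                c(list(lncrna = al$lncrna, mrna = al$mrna), coexpr))
  sp <- do.call(identifySpongeModules,
                c(list(modules = cx, mirnaExpr = al$mirna,
                       lncrnaExpr = al$lncrna, mrnaExpr = al$mrna,
                       interactions = interactions), sponge))
  list(coexpression = cx, modules = sp,
       rejections = attr(sp, "rejections"), aligned = al)
}
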