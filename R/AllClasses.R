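#' ModuleSet: a collection of lncRNA-mRNA modules
#'
#' Container for co-expression modules: each module is a labelled set of
#' lncRNA identifiers together with a set of mRNA identifiers. Modules are
#' disjoint gene sets (a gene belongs to at most one module).
#'
#' @slot moduleIds character vector of module labels.
#' @slot lncrna list of character vectors, one per module, the lncRNA members.
#' @slot mrna list of character vectors, one per module, the mRNA members.
#'
#' @seealso [detectCoexpressionModules()], [SpongeModuleSet-class]
#' @export
setClass("ModuleSet",
  representation(moduleIds = "character", lncrna = "list", mrna = "list"))

setValidity("ModuleSet", function(object) {
  n <- length(object@moduleIds)
  if (length(object@lncrna) != n || length(object@mrna) != n)
    return("moduleIds, lncrna and mrna must have equal length")
  if (anyDuplicated(object@moduleIds))
    return("module ids must be unique")
  for (i in seq_len(n)) {
    l <- object@lncrna[[i]]; m <- object@mrna[[i]]
    if (!is.character(l) || !is.character(m))
      return("module members must be character vectors")
    if (length(intersect(l, m)))
      return(sprintf("module '%s': lncRNA and mRNA member sets overlap",
                     object@moduleIds[i]))
  }
  TRUE
})

#' SpongeModuleSet: modules passing the miRNA sponge criteria
#'
#' Extends [ModuleSet-class] with the shared miRNAs of each module and the
#' sponge statistics: the miRNA-sharing p-value \code{p_share}, the canonical
#' correlation \code{cc} between the lncRNA and mRNA groups, the canonical
#' correlations of the shared-miRNA group with each side (\code{cc_mir_mr},
#' \code{cc_mir_lncr}), the partial canonical correlation \code{pcc}
#' conditioning on the shared miRNAs, and the sensitivity canonical
#' correlation \code{scc = cc - pcc}.
#'
#' @slot sharedMirnas list of character vectors, shared miRNAs per module.
#' @slot stats data.frame with one row per module and columns
#'   \code{p_share}, \code{cc}, \code{cc_mir_mr}, \code{cc_mir_lncr},
#'   \code{pcc}, \code{scc}.
#'
#' @seealso [identifySpongeModules()]
#' @export
setClass("SpongeModuleSet", contains = "ModuleSet",
  representation(sharedMirnas = "list", stats = "data.frame"))

setValidity("SpongeModuleSet", function(object) {
  n <- length(object@moduleIds)
  if (length(object@sharedMirnas) != n)
    return("sharedMirnas must have one entry per module")
  if (nrow(object@stats) != n)
    return("stats must have one row per module")
  needed <- c("p_share", "cc", "cc_mir_mr", "cc_mir_lncr", "pcc", "scc")
  if (!all(needed %in% colnames(object@stats)))
    return(paste("stats must contain columns:", paste(needed, collapse = ", ")))
  if (n && max(abs(object@stats$scc -
                   (object@stats$cc - object@stats$pcc))) > 1e-10)
    return("scc must equal cc - pcc")
  TRUE
})

ModuleSet <- function(lncrna, mrna, moduleIds = NULL) {
  if (is.null(moduleIds))
    moduleIds <- if (length(lncrna)) paste0("M", seq_along(lncrna))
                 else character()
  new("ModuleSet", moduleIds = as.character(moduleIds),
      lncrna = lapply(lncrna, as.character),
      mrna = lapply(mrna, as.character))
}

#' @describeIn ModuleSet-class number of modules.
#' @param x a \code{ModuleSet}.
#' @export
setMethod("length", "ModuleSet", function(x) length(x@moduleIds))

#' @export
setGeneric("moduleIds", function(x) standardGeneric("moduleIds"))
#' @describeIn ModuleSet-class module labels.
#' @export
setMethod("moduleIds", "ModuleSet", function(x) x@moduleIds)

#' @export
setGeneric("lncrnaMembers", function(x) standardGeneric("lncrnaMembers"))
#' @describeIn ModuleSet-class named list of lncRNA member sets.
#' @export
setMethod("lncrnaMembers", "ModuleSet",
  function(x) setNames(x@lncrna, x@moduleIds))

#' @export
setGeneric("mrnaMembers", function(x) standardGeneric("mrnaMembers"))
#' @describeIn ModuleSet-class named list of mRNA member sets.
#' @export
setMethod("mrnaMembers", "ModuleSet",
  function(x) setNames(x@mrna, x@moduleIds))

#' @export
setGeneric("sharedMirnaIds", function(x) standardGeneric("sharedMirnaIds"))
#' @describeIn SpongeModuleSet-class named list of shared-miRNA sets.
#' @param x a \code{SpongeModuleSet}.
#' @export
setMethod("sharedMirnaIds", "SpongeModuleSet",
  function(x) setNames(x@sharedMirnas, x@moduleIds))

#' @export
setGeneric("moduleStats", function(x) standardGeneric("moduleStats"))
#' @describeIn SpongeModuleSet-class data.frame of per-module sponge statistics.
#' @export
setMethod("moduleStats", "SpongeModuleSet", function(x) {
  out <- x@stats
  rownames(out) <- x@moduleIds
  out
})

#' @describeIn ModuleSet-class subset modules by index, logical or id.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ModuleSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@moduleIds)
  if (is.logical(i)) i <- which(i)
  initialize(x, moduleIds = x@moduleIds[i],
             lncrna = x@lncrna[i], mrna = x@mrna[i])
})

#' @export
setMethod("[", "SpongeModuleSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@moduleIds)
  if (is.logical(i)) i <- which(i)
  initialize(x, moduleIds = x@moduleIds[i],
             lncrna = x@lncrna[i], mrna = x@mrna[i],
             sharedMirnas = x@sharedMirnas[i],
             stats = x@stats[i, , drop = FALSE])
})

#' @importFrom methods show
setMethod("show", "ModuleSet", function(object) {
  cat(class(object), "with", length(object), "module(s)\n")
  n <- min(length(object), 5L)
  for (i in seq_len(n))
    cat(sprintf("  %s: %d lncRNAs, %d mRNAs\n", object@moduleIds[i],
                length(object@lncrna[[i]]), length(object@mrna[[i]])))
  if (length(object) > n) cat("  ...\n")
})

setMethod("show", "SpongeModuleSet", function(object) {
  cat(class(object), "with", length(object), "module(s)\n")
  n <- min(length(object), 5L)
  for (i in seq_len(n))
    cat(sprintf(
      "  %s: %d lncRNAs, %d mRNAs, %d shared miRNAs (cc=%.3f, scc=%.3f)\n",
      object@moduleIds[i], length(object@lncrna[[i]]),
      length(object@mrna[[i]]), length(object@sharedMirnas[[i]]),
      object@stats$cc[i], object@stats$scc[i]))
  if (length(object) > n) cat("  ...\n")
})
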