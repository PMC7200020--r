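#' Read a genes x samples expression matrix from TSV
#'
#' Parses a tab-separated file whose header row carries sample identifiers
#' and whose first column carries gene identifiers. Rows with an empty gene
#' identifier are removed (such rows typically arise from transcripts with
#' no assigned gene symbol); rows containing missing values are dropped with
#' a message. Gene identifiers are treated as opaque, case-sensitive strings.
#'
#' @param path path to a TSV file.
#' @param rnaClass one of \code{"miRNA"}, \code{"lncRNA"}, \code{"mRNA"};
#'   stored as the \code{"rnaClass"} attribute of the returned matrix.
#' @param genesInRows if \code{FALSE} the file is transposed on read
#'   (samples in rows).
#' @return numeric matrix (genes x samples) with dimnames and an
#'   \code{rnaClass} attribute.
#' @export
readExpressionMatrix <- function(path,
                                 rnaClass = c("mRNA", "lncRNA", "miRNA"),
                                 genesInRows = TRUE) {
  rnaClass <- match.arg(rnaClass)
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(fields)
  ## header may or may not carry a corner cell for the gene-id column
  body_width <- width[-1L]
  if (length(unique(body_width)) > 1L)
    stop(sprintf("ragged expression file '%s': line %d has %d fields, expected %d",
                 path, which(body_width != body_width[1L])[1L] + 1L,
                 body_width[which(body_width != body_width[1L])[1L]],
                 body_width[1L]))
  samples <- fields[[1L]]
  if (length(samples) == body_width[1L]) samples <- samples[-1L]
  else if (length(samples) != body_width[1L] - 1L)
    stop(sprintf("header of '%s' has %d fields but data rows have %d",
                 path, width[1L], body_width[1L]))
  gene <- vapply(fields[-1L], `[[`, "", 1L)
  vals <- lapply(fields[-1L], function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v) && any(f[-1L][is.na(v)] != "NA"))
      stop(sprintf("non-numeric expression value '%s' in '%s'",
                   f[-1L][is.na(v)][1L], path))
    v
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(gene, samples)
  if (!genesInRows) m <- t(m)
  keep <- !is.na(rownames(m)) & nzchar(rownames(m))
  if (any(!keep))
    message(sum(!keep), " row(s) without a gene identifier removed")
  m <- m[keep, , drop = FALSE]
  cc <- stats::complete.cases(m)
  if (any(!cc))
    message(sum(!cc), " row(s) with missing values dropped")
  m <- m[cc, , drop = FALSE]
  attr(m, "rnaClass") <- rnaClass
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionMatrix()]: header row of sample ids with a
#' leading \code{gene_id} corner cell, one row per gene.
#'
#' @param x genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(x, path) {
  x <- as_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse replicated gene rows by averaging
#'
#' Replaces every set of rows sharing one gene identifier by a single row of
#' arithmetic means, preserving the order of first appearance. Idempotent.
#'
#' @param x genes x samples numeric matrix with dimnames.
#' @return matrix with unique rownames.
#' @export
collapseReplicates <- function(x) {
  x <- as_expression_matrix(x)
  if (!anyDuplicated(rownames(x))) return(x)
  ids <- rownames(x)
  first <- !duplicated(ids)
  out <- rowsum(x, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  out <- out[unique(ids), , drop = FALSE]
  attr(out, "rnaClass") <- attr(x, "rnaClass")
  out
}

#' Restrict expression matrices to their common samples
#'
#' Intersects the sample (column) names of the three matrices and returns
#' all three restricted to the common samples, ordered as they appear in the
#' first matrix.
#'
#' @param mirna,lncrna,mrna genes x samples matrices with sample colnames.
#' @return named list with elements \code{mirna}, \code{lncrna}, \code{mrna}
#'   whose column name vectors are identical.
#' @export
alignSamples <- function(mirna, lncrna, mrna) {
  mirna <- as_expression_matrix(mirna)
  lncrna <- as_expression_matrix(lncrna)
  mrna <- as_expression_matrix(mrna)
  common <- intersect(intersect(colnames(mirna), colnames(lncrna)),
                      colnames(mrna))
  if (!length(common))
    stop("no samples are common to the three expression matrices")
  common <- colnames(mirna)[colnames(mirna) %in% common]
  list(mirna = mirna[, common, drop = FALSE],
       lncrna = lncrna[, common, drop = FALSE],
       mrna = mrna[, common, drop = FALSE])
}

#' Read a miRNA-target interaction table
#'
#' Two-column TSV (miRNA id, target id), with or without a header line;
#' duplicate pairs are removed. A third column, when present, is kept as the
#' target class.
#'
#' @param path TSV path.
#' @param header does the file carry a header row? Default \code{TRUE}.
#' @return data.frame with columns \code{mirna}, \code{target} and, when the
#'   file has three columns, \code{target_class}.
#' @export
readInteractionTable <- function(path, header = TRUE) {
  df <- read.delim(path, header = header, colClasses = "character")
  if (ncol(df) < 2L)
    stop("interaction table must have at least two columns (miRNA, target)")
  out <- data.frame(mirna = df[[1L]], target = df[[2L]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 3L) out$target_class <- df[[3L]]
  if (any(!nzchar(out$mirna)) || any(!nzchar(out$target)))
    stop("interaction table contains empty identifiers")
  out[!duplicated(out[c("mirna", "target")]), , drop = FALSE]
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines ignored; duplicates removed.
#'
#' @param path file path.
#' @return character vector of unique identifiers (warns when empty).
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x <- unique(trimws(x))
  x <- x[nzchar(x)]
  if (!length(x)) warning("gene list '", path, "' is empty")
  x
}

#' Serialize modules to a report directory
#'
#' Writes a machine-readable JSON document (module ids, member lists, shared
#' miRNAs and statistics where available) plus a flat TSV summary table.
#'
#' @param modules a [ModuleSet-class] or [SpongeModuleSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @seealso [readModuleReport()]
#' @export
writeModuleReport <- function(modules, dir) {
  stopifnot(is(modules, "ModuleSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sponge <- is(modules, "SpongeModuleSet")
  doc <- lapply(seq_len(length(modules)), function(i) {
    entry <- list(module_id = modules@moduleIds[i],
                  lncrna = modules@lncrna[[i]],
                  mrna = modules@mrna[[i]])
    if (sponge) {
      entry$shared_mirnas <- modules@sharedMirnas[[i]]
      entry$stats <- as.list(modules@stats[i, , drop = FALSE])
    }
    entry
  })
  json_path <- file.path(dir, "modules.json")
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  tab <- data.frame(
    module_id = modules@moduleIds,
    n_lncrna = lengths(modules@lncrna),
    n_mrna = lengths(modules@mrna),
    lncrna = vapply(modules@lncrna, paste, "", collapse = ","),
    mrna = vapply(modules@mrna, paste, "", collapse = ","))
  if (sponge) {
    tab$n_shared_mirna <- lengths(modules@sharedMirnas)
    tab$shared_mirnas <- vapply(modules@sharedMirnas, paste, "",
                                collapse = ",")
    tab <- cbind(tab, modules@stats)
  }
  tsv_path <- file.path(dir, "modules.tsv")
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Reload modules written by [writeModuleReport()]
#'
#' @param dir report directory.
#' @return a [ModuleSet-class] or [SpongeModuleSet-class], matching what was
#'   written.
#' @export
readModuleReport <- function(dir) {
  doc <- jsonlite::read_json(file.path(dir, "modules.json"))
  chr <- function(x) as.character(unlist(x))
  ids <- vapply(doc, function(e) e$module_id, "")
  lnc <- lapply(doc, function(e) chr(e$lncrna))
  mr <- lapply(doc, function(e) chr(e$mrna))
  if (length(doc) && !is.null(doc[[1L]]$stats)) {
    stats <- do.call(rbind, lapply(doc, function(e)
      as.data.frame(lapply(e$stats, as.numeric))))
    new("SpongeModuleSet", moduleIds = ids, lncrna = lnc, mrna = mr,
        sharedMirnas = lapply(doc, function(e) chr(e$shared_mirnas)),
        stats = stats)
  } else {
    ModuleSet(lnc, mr, ids)
  }
}
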