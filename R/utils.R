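#' @import methods
#' @importFrom stats cor sd rnorm runif rbinom rexp quantile median
#'   phyper p.adjust t.test pt hclust cutree as.dist dist lm resid coef
#'   complete.cases predict pchisq qnorm pnorm uniroot setNames
#' @importFrom utils read.delim write.table head
NULL

## Run an expression with a temporary RNG state seeded from `seed`,
## restoring the caller's RNG afterwards. All stochastic functions in the
## package route their randomness through this helper so that no call
## mutates global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Accept a plain matrix or a SummarizedExperiment (first assay) as a
## genes x samples expression matrix with dimnames.
as_expression_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("SummarizedExperiment input requires the SummarizedExperiment package")
    x <- SummarizedExperiment::assay(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix (genes x samples)", arg))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("'%s' must have gene rownames and sample colnames", arg))
  x
}

check_prob <- function(p, arg = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("'%s' must lie in [0, 1]", arg))
  invisible(p)
}

## Standardize matrix rows to mean 0, sd 1; errors on constant rows.
standardize_rows <- function(x, what = "expression") {
  s <- apply(x, 1L, sd)
  if (any(s == 0 | !is.finite(s)))
    stop(sprintf("constant %s row(s): %s", what,
                 paste(head(rownames(x)[s == 0 | !is.finite(s)], 5L),
                       collapse = ", ")))
  (x - rowMeans(x)) / s
}
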