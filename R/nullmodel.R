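## Loading weight alpha such that a one-factor group model with m (resp. n)
## standardized indicators x_i = alpha*f + sqrt(1-alpha^2)*e_i attains a
## population canonical correlation of target_cc between the two groups.
## The leading canonical variates are the group means, so
##   CC = alpha^2 / sqrt((alpha^2 + (1-alpha^2)/m) (alpha^2 + (1-alpha^2)/n)).
calibrate_loading <- function(target_cc, m, n) {
  stopifnot(target_cc >= 0, target_cc < 1)
  if (target_cc == 0) return(0)
  f <- function(alpha) {
    a2 <- alpha^2
    a2 / sqrt((a2 + (1 - a2) / m) * (a2 + (1 - a2) / n)) - target_cc
  }
  uniroot(f, c(1e-8, 1 - 1e-8), tol = 1e-10)$root
}

#' Draw sensitivity canonical correlations under the null
#'
#' The null hypothesis is that the shared miRNAs do not influence the
#' canonical correlation between the lncRNA and mRNA groups (sensitivity
#' canonical correlation of zero). Each draw simulates a dataset matched to
#' an observed module's dimensions: \code{m} lncRNA and \code{n} mRNA
#' variates share one latent factor with loadings calibrated so their
#' population canonical correlation is approximately \code{targetCc}, while
#' \code{k} miRNA variates are standard normal, independent of everything.
#' The sensitivity canonical correlation of each simulated dataset is then
#' computed with the same pipeline used on real modules
#' ([canonicalCorrelation()] three ways plus
#' [partialCanonicalCorrelation()]). With \code{k = 0} the conditioning
#' group is empty and every draw is exactly 0.
#'
#' @param m,n,k,s numbers of lncRNAs, mRNAs, shared miRNAs and samples.
#' @param targetCc population canonical correlation to match (in [0, 1)).
#' @param B number of draws (at least 100).
#' @param seed integer seed; the draw sequence is reproducible.
#' @param backend,penalty passed to [canonicalCorrelation()].
#' @return numeric vector of \code{B} null sensitivity canonical
#'   correlations.
#' @export
simulateNullScc <- function(m, n, k, s, targetCc, B = 1000L, seed = 1L,
                            backend = "diag-sparse", penalty = 1) {
  stopifnot(m >= 1, n >= 1, k >= 0, s >= 3, B >= 100)
  alpha <- calibrate_loading(targetCc, m, n)
  with_seed(seed, {
    vapply(seq_len(B), function(b) {
      f <- rnorm(s)
      X <- alpha * matrix(f, m, s, byrow = TRUE) +
        sqrt(1 - alpha^2) * matrix(rnorm(m * s), m, s)
      Y <- alpha * matrix(f, n, s, byrow = TRUE) +
        sqrt(1 - alpha^2) * matrix(rnorm(n * s), n, s)
      if (k == 0) return(0)
      Z <- matrix(rnorm(k * s), k, s)
      cc <- canonicalCorrelation(X, Y, backend = backend,
                                 penalty = penalty)$cc
      cc_zm <- canonicalCorrelation(Z, Y, backend = backend,
                                    penalty = penalty)$cc
      cc_zl <- canonicalCorrelation(Z, X, backend = backend,
                                    penalty = penalty)$cc
      sensitivityCanonicalCorrelation(
        cc, partialCanonicalCorrelation(cc, cc_zm, cc_zl))
    }, 0)
  })
}

#' Empirical p-value from null draws
#'
#' \code{p = (r + 1) / (B + 1)} with \code{r} the number of null draws at
#' least as large as the observed value; never zero, with floor
#' \code{1/(B+1)}.
#'
#' @param observed observed statistic.
#' @param nullDraws numeric vector of at least 100 null draws.
#' @return empirical p-value.
#' @export
empiricalPvalue <- function(observed, nullDraws) {
  stopifnot(length(nullDraws) >= 100L, is.finite(observed))
  (sum(nullDraws >= observed) + 1) / (length(nullDraws) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' \code{stats::p.adjust}, after validating the input range).
#'
#' @param p vector of p-values in \code{[0, 1]}.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  check_prob(p, "p")
  p.adjust(p, method = "BH")
}

#' Null-model significance of sponge modules
#'
#' For each accepted module, draws \code{B} null sensitivity canonical
#' correlations matched on the module's dimensions and observed canonical
#' correlation (see [simulateNullScc()]), computes the empirical p-value of
#' the observed sensitivity canonical correlation, and adjusts across
#' modules by Benjamini-Hochberg. Null draws are cached across modules with
#' identical dimensions and canonical correlation rounded to \code{ccBin},
#' so modules of the same shape share one null distribution.
#'
#' @param sponge a [SpongeModuleSet-class].
#' @param B null draws per module (default 1000; increase for smaller
#'   attainable p-values, floor \code{1/(B+1)}).
#' @param s number of samples the modules were scored on.
#' @param seed integer seed.
#' @param ccBin width of the canonical-correlation cache bin (default
#'   0.05).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param backend,penalty passed to [canonicalCorrelation()].
#' @return data.frame with \code{module_id}, \code{observed_scc},
#'   \code{null_exceed}, \code{p_raw}, \code{p_adjusted},
#'   \code{significant}.
#' @export
moduleSignificance <- function(sponge, s, B = 1000L, seed = 1L,
                               ccBin = 0.05, alpha = 0.05,
                               backend = "diag-sparse", penalty = 1) {
  stopifnot(is(sponge, "SpongeModuleSet"))
  nmod <- length(sponge)
  if (!nmod)
    return(data.frame(module_id = character(), observed_scc = numeric(),
                      null_exceed = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), significant = logical()))
  cache <- new.env(parent = emptyenv())
  p_raw <- numeric(nmod); r <- integer(nmod)
  for (i in seq_len(nmod)) {
    m <- length(sponge@lncrna[[i]])
    n <- length(sponge@mrna[[i]])
    k <- length(sponge@sharedMirnas[[i]])
    cc_bin <- min(round(sponge@stats$cc[i] / ccBin) * ccBin, 1 - ccBin / 2)
    key <- paste(m, n, k, s, format(cc_bin), sep = "_")
    if (!exists(key, envir = cache)) {
      assign(key, simulateNullScc(m, n, k, s, cc_bin, B = B,
                                  seed = as.integer(seed) +
                                    length(ls(cache)),
                                  backend = backend, penalty = penalty),
             envir = cache)
    }
    draws <- get(key, envir = cache)
    r[i] <- sum(draws >= sponge@stats$scc[i])
    p_raw[i] <- empiricalPvalue(sponge@stats$scc[i], draws)
  }
  p_adj <- bhAdjust(p_raw)
  data.frame(module_id = sponge@moduleIds, observed_scc = sponge@stats$scc,
             null_exceed = r, p_raw = p_raw, p_adjusted = p_adj,
             significant = p_adj < alpha, row.names = NULL)
}
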