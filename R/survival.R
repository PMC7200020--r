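#' Two-group log-rank test
#'
#' Direct observed-minus-expected implementation of the log-rank
#' chi-square: at each distinct event time the expected number of events in
#' group 1 under the null is \code{d * n1/n} with hypergeometric variance;
#' the statistic is \code{(O - E)^2 / V} on 1 degree of freedom.
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @param group two-level grouping vector.
#' @return list with \code{chi_square}, \code{p}, and the per-group
#'   observed/expected event counts.
#' @export
logRankTest <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(time > 0), all(event %in% c(0, 1)))
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("'group' must have exactly two levels")
  g1 <- g == levels(g)[1L]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE),
       observed = c(O, sum(event == 1) - O),
       expected = c(E, sum(event == 1) - E))
}

#' Evaluate one module as a survival biomarker
#'
#' Per-sample risk scores are the linear predictor of a proportional-
#' hazards fit on the module's gene expression: an unpenalized Cox fit
#' (\code{survival::coxph}) when the genes are few relative to the samples,
#' otherwise a ridge-penalized Cox fit (\code{glmnet}, fixed penalty) to
#' keep wide or collinear modules stable. Samples are split at the median
#' risk score (ties to the low-risk group) and the groups compared with the
#' log-rank test; the hazard ratio of high versus low risk comes from a
#' one-covariate Cox fit with a 95\% confidence interval. A module is
#' flagged a biomarker when the log-rank p < \code{alpha} and HR >
#' \code{hrMin}.
#'
#' @param geneIds character vector: the module's lncRNA + mRNA members.
#' @param expr joined genes x samples matrix containing those genes.
#' @param survival data.frame with columns \code{sample_id}, \code{time}
#'   (> 0), \code{event} (0/1); sample_ids must exist in \code{expr}.
#' @param alpha log-rank significance level (default 0.05).
#' @param hrMin hazard-ratio threshold (default 2).
#' @param ridgeLambda fixed ridge penalty used when the module has at least
#'   half as many genes as samples (default 0.1).
#' @return list with \code{chi_square}, \code{p}, \code{hr}, \code{hr_low95},
#'   \code{hr_up95}, \code{biomarker}, \code{risk_group} (named vector).
#' @export
survivalBiomarker <- function(geneIds, expr, survival, alpha = 0.05,
                              hrMin = 2, ridgeLambda = 0.1) {
  expr <- as_expression_matrix(expr)
  stopifnot(all(c("sample_id", "time", "event") %in% colnames(survival)))
  if (!all(survival$sample_id %in% colnames(expr)))
    stop("survival table references samples absent from expression")
  missing <- setdiff(geneIds, rownames(expr))
  if (length(missing))
    stop("module genes absent from expression: ",
         paste(head(missing, 5L), collapse = ", "))
  if (sum(survival$event == 1) < 10L)
    stop("at least 10 events are required")
  x <- t(expr[geneIds, survival$sample_id, drop = FALSE])
  keep <- apply(x, 2L, sd) > 0
  x <- x[, keep, drop = FALSE]
  if (!ncol(x)) stop("all module genes are constant across samples")
  y <- survival::Surv(survival$time, survival$event)
  if (ncol(x) >= nrow(x) / 2 || ncol(x) > 50L) {
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 0,
                          lambda = c(1, ridgeLambda),
                          standardize = TRUE)
    score <- drop(predict(fit, newx = x, s = ridgeLambda))
  } else {
    fit <- survival::coxph(y ~ x)
    beta <- coef(fit)
    beta[is.na(beta)] <- 0
    score <- drop(x %*% beta)
  }
  high <- score > median(score)          # ties go to the low-risk group
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  lr <- logRankTest(survival$time, survival$event, grp)
  cx <- survival::coxph(y ~ grp)
  sm <- summary(cx)
  hr <- unname(sm$conf.int[1, "exp(coef)"])
  lo <- unname(sm$conf.int[1, "lower .95"])
  up <- unname(sm$conf.int[1, "upper .95"])
  list(chi_square = lr$chi_square, p = lr$p, hr = hr,
       hr_low95 = lo, hr_up95 = up,
       biomarker = lr$p < alpha && hr > hrMin,
       risk_group = setNames(as.character(grp), survival$sample_id))
}

#' Survival screening over a module set
#'
#' Runs [survivalBiomarker()] for every module and tabulates the results.
#'
#' @param modules a [ModuleSet-class] or [SpongeModuleSet-class].
#' @param expr joined lncRNA + mRNA expression matrix.
#' @param survival survival table (see [survivalBiomarker()]).
#' @param ... passed to [survivalBiomarker()].
#' @return data.frame with one row per module: \code{module_id},
#'   \code{chi_square}, \code{p}, \code{hr}, \code{hr_low95},
#'   \code{hr_up95}, \code{biomarker}.
#' @export
survivalScreen <- function(modules, expr, survival, ...) {
  stopifnot(is(modules, "ModuleSet"))
  rows <- lapply(seq_len(length(modules)), function(i) {
    res <- survivalBiomarker(c(modules@lncrna[[i]], modules@mrna[[i]]),
                             expr, survival, ...)
    data.frame(module_id = modules@moduleIds[i],
               chi_square = res$chi_square, p = res$p, hr = res$hr,
               hr_low95 = res$hr_low95, hr_up95 = res$hr_up95,
               biomarker = res$biomarker, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(module_id = character(), chi_square = numeric(),
                      p = numeric(), hr = numeric(), hr_low95 = numeric(),
                      hr_up95 = numeric(), biomarker = logical()))
  do.call(rbind, rows)
}
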