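#' Simulate a sponge-module dataset with planted ground truth
#'
#' Generates matched miRNA / lncRNA / mRNA expression with planted
#' modules of two kinds, an interaction table, and optional survival and
#' subtype annotations.
#'
#' \strong{Mediated modules} follow the sponge competition structure: the
#' module's \code{nSharedMirna} miRNAs are independent standard normals;
#' writing \eqn{\bar z} for their standardized per-sample mean,
#' \eqn{\rho} for \code{mediation} and \eqn{c} for
#' \code{residualCoupling}, every member lncRNA and mRNA is
#' \deqn{x = -\rho \bar z + \sqrt{1 - \rho^2}\, c f + \sigma \epsilon}
#' with \eqn{f} a module latent factor and \eqn{\sigma} = \code{noiseSd}.
#' Members are positively co-expressed (miRNAs repress both sides, with
#' the negative loading inducing positive lncRNA-mRNA correlation), and as
#' \eqn{\rho \to 1} that co-expression is entirely explained by the shared
#' miRNAs. The residual-coupling knob \eqn{c} sets how much of the
#' non-miRNA residual is shared co-regulation rather than private noise;
#' the default 0.3 keeps the common signal of a mediated module
#' overwhelmingly miRNA-driven, which is what "miRNA-mediated" means
#' here. \strong{Decoy modules} are driven purely by a latent factor
#' independent of every miRNA (\eqn{x = f + \sigma\epsilon}); they also
#' receive \code{nSharedMirna} nominal miRNAs in the interaction table,
#' so they exhibit nominal miRNA sharing but no expression mediation.
#'
#' The interaction table always contains every (module miRNA, member)
#' pair of every planted module, plus uniform false-positive pairs drawn
#' at rate \code{interactionFpRate} over all remaining (miRNA, gene)
#' combinations. Background genes of each class are independent noise.
#' Survival times are exponential with log-hazard proportional to the
#' first planted module's common signal; subtype labels cut the second
#' module's latent factor (or fresh noise) at equal quantiles.
#'
#' @param nSamples number of samples (default 300).
#' @param planted list describing the mediated modules, each element a
#'   list with \code{nLncrna}, \code{nMrna}, \code{nSharedMirna},
#'   \code{mediation} in \code{[0, 1]}, \code{noiseSd}, and optionally
#'   \code{residualCoupling} (default 0.3). Default: two modules of 10
#'   lncRNAs, 20 mRNAs, 5 shared miRNAs, mediation 0.9, noise 0.3.
#' @param nDecoy number of decoy modules (default 2), each shaped like
#'   \code{decoyShape}.
#' @param decoyShape list with \code{nLncrna}, \code{nMrna},
#'   \code{nSharedMirna}, \code{noiseSd} (defaults 10, 20, 5, 0.3).
#' @param nBackground named vector/list: background gene counts per class
#'   (defaults: 20 miRNAs, 30 lncRNAs, 60 mRNAs).
#' @param interactionFpRate false-positive interaction rate (default
#'   0.01).
#' @param survivalBeta log-hazard coefficient on the first module's
#'   signal (default 1); \code{NULL} disables the survival table.
#' @param nSubtypes number of subtype labels (default 3); \code{NULL}
#'   disables labels.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list with \code{mirna}, \code{lncrna}, \code{mrna} (genes x
#'   samples matrices), \code{interactions} (data.frame \code{mirna},
#'   \code{target}, \code{target_class}), \code{truth} (list per planted
#'   module: \code{id}, \code{type} \code{"mediated"}/\code{"decoy"},
#'   member and miRNA ids), \code{survival} (data.frame or \code{NULL}),
#'   \code{labels} (named character vector or \code{NULL}).
#' @export
simulateSpongeDataset <- function(
    nSamples = 300L,
    planted = rep(list(list(nLncrna = 10L, nMrna = 20L, nSharedMirna = 5L,
                            mediation = 0.9, noiseSd = 0.3)), 2L),
    nDecoy = 2L,
    decoyShape = list(nLncrna = 10L, nMrna = 20L, nSharedMirna = 5L,
                      noiseSd = 0.3),
    nBackground = c(mirna = 20L, lncrna = 30L, mrna = 60L),
    interactionFpRate = 0.01,
    survivalBeta = 1,
    nSubtypes = 3L,
    seed = 1L) {
  stopifnot(nSamples >= 4L, nDecoy >= 0L)
  for (pm in planted)
    stopifnot(pm$mediation >= 0, pm$mediation <= 1, pm$noiseSd >= 0)
  with_seed(seed, {
    s <- as.integer(nSamples)
    samples <- sprintf("S%03d", seq_len(s))
    mir_rows <- list(); lnc_rows <- list(); mr_rows <- list()
    truth <- list(); ia <- list()
    factors <- list()   # per-module latent signal, for survival/subtypes

    gen_members <- function(n, signal, noiseSd, prefix, ids_from) {
      m <- matrix(rnorm(n * s, sd = noiseSd), n, s) +
        matrix(signal, n, s, byrow = TRUE)
      rownames(m) <- sprintf("%s%02d", prefix, ids_from + seq_len(n))
      m
    }

    n_lnc_so_far <- 0L; n_mr_so_far <- 0L; n_mir_so_far <- 0L
    add_module <- function(shape, type, idx) {
      k <- shape$nSharedMirna
      Z <- matrix(rnorm(k * s), k, s,
                  dimnames = list(
                    sprintf("mir%02d", n_mir_so_far + seq_len(k)), samples))
      f <- rnorm(s)
      if (type == "mediated") {
        rho <- shape$mediation
        knob <- if (is.null(shape$residualCoupling)) 0.3
                else shape$residualCoupling
        zbar <- if (k > 0) colMeans(Z) * sqrt(k) else numeric(s)
        signal <- -rho * zbar + sqrt(1 - rho^2) * knob * f
      } else {
        signal <- f
      }
      lnc <- gen_members(shape$nLncrna, signal, shape$noiseSd, "lnc",
                         n_lnc_so_far)
      mr <- gen_members(shape$nMrna, signal, shape$noiseSd, "mr",
                        n_mr_so_far)
      colnames(lnc) <- samples; colnames(mr) <- samples
      members <- c(rownames(lnc), rownames(mr))
      ia_mod <- expand.grid(mirna = rownames(Z), target = members,
                            stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
      ia_mod$target_class <- rep(
        c("lncRNA", "mRNA"),
        times = c(nrow(lnc), nrow(mr)))[match(ia_mod$target, members)]
      list(Z = Z, lnc = lnc, mr = mr, ia = ia_mod, signal = signal,
           truth = list(id = sprintf("%s%d", type, idx), type = type,
                        lncrna = rownames(lnc), mrna = rownames(mr),
                        mirnas = rownames(Z)))
    }

    all_mods <- list()
    for (i in seq_along(planted)) {
      mod <- add_module(planted[[i]], "mediated", i)
      all_mods[[length(all_mods) + 1L]] <- mod
      n_lnc_so_far <- n_lnc_so_far + nrow(mod$lnc)
      n_mr_so_far <- n_mr_so_far + nrow(mod$mr)
      n_mir_so_far <- n_mir_so_far + nrow(mod$Z)
    }
    for (i in seq_len(nDecoy)) {
      mod <- add_module(decoyShape, "decoy", i)
      all_mods[[length(all_mods) + 1L]] <- mod
      n_lnc_so_far <- n_lnc_so_far + nrow(mod$lnc)
      n_mr_so_far <- n_mr_so_far + nrow(mod$mr)
      n_mir_so_far <- n_mir_so_far + nrow(mod$Z)
    }

    mirna <- do.call(rbind, lapply(all_mods, `[[`, "Z"))
    lncrna <- do.call(rbind, lapply(all_mods, `[[`, "lnc"))
    mrna <- do.call(rbind, lapply(all_mods, `[[`, "mr"))
    truth <- lapply(all_mods, `[[`, "truth")
    ia <- do.call(rbind, lapply(all_mods, `[[`, "ia"))

    nb <- as.list(nBackground)
    if (nb$mirna > 0) {
      bg <- matrix(rnorm(nb$mirna * s), nb$mirna, s,
                   dimnames = list(sprintf("mir_bg%02d", seq_len(nb$mirna)),
                                   samples))
      mirna <- rbind(mirna, bg)
    }
    if (nb$lncrna > 0) {
      bg <- matrix(rnorm(nb$lncrna * s), nb$lncrna, s,
                   dimnames = list(sprintf("lnc_bg%02d",
                                           seq_len(nb$lncrna)), samples))
      lncrna <- rbind(lncrna, bg)
    }
    if (nb$mrna > 0) {
      bg <- matrix(rnorm(nb$mrna * s), nb$mrna, s,
                   dimnames = list(sprintf("mr_bg%02d", seq_len(nb$mrna)),
                                   samples))
      mrna <- rbind(mrna, bg)
    }

    ## uniform false-positive interactions over all remaining pairs
    if (interactionFpRate > 0) {
      genes <- c(rownames(lncrna), rownames(mrna))
      cls <- rep(c("lncRNA", "mRNA"),
                 c(nrow(lncrna), nrow(mrna)))
      n_fp <- rbinom(1L, length(rownames(mirna)) * length(genes),
                     interactionFpRate)
      if (n_fp > 0) {
        fp <- data.frame(
          mirna = sample(rownames(mirna), n_fp, replace = TRUE),
          target = sample(genes, n_fp, replace = TRUE),
          stringsAsFactors = FALSE)
        fp$target_class <- cls[match(fp$target, genes)]
        ia <- rbind(ia, fp)
      }
    }
    ia <- ia[!duplicated(ia[c("mirna", "target")]), , drop = FALSE]
    rownames(ia) <- NULL

    surv <- NULL
    if (!is.null(survivalBeta)) {
      driver <- all_mods[[1L]]$signal
      times <- rexp(s, rate = 0.1 * exp(survivalBeta * driver))
      cens <- rexp(s, rate = 0.05)
      surv <- data.frame(sample_id = samples,
                         time = pmin(times, cens),
                         event = as.integer(times <= cens))
      surv$time <- pmax(surv$time, 1e-6)
    }

    labels <- NULL
    if (!is.null(nSubtypes) && nSubtypes >= 2L) {
      u <- if (length(all_mods) >= 2L) all_mods[[2L]]$signal else rnorm(s)
      qs <- quantile(u, probs = seq(0, 1, length.out = nSubtypes + 1L))
      qs[1L] <- -Inf; qs[length(qs)] <- Inf
      labels <- setNames(
        paste0("subtype", as.integer(cut(u, qs, labels = FALSE))),
        samples)
    }

    attr(mirna, "rnaClass") <- "miRNA"
    attr(lncrna, "rnaClass") <- "lncRNA"
    attr(mrna, "rnaClass") <- "mRNA"
    list(mirna = mirna, lncrna = lncrna, mrna = mrna, interactions = ia,
         truth = truth, survival = surv, labels = labels)
  })
}

#' Score recovery of planted modules
#'
#' For every planted module, finds the best-matching discovered module by
#' Jaccard index over the combined member sets (lncRNAs and mRNAs), and
#' summarizes recovery of mediated plants and leakage of decoys.
#'
#' @param found a [ModuleSet-class] or [SpongeModuleSet-class] of
#'   discovered (accepted) modules.
#' @param truth the \code{truth} element of [simulateSpongeDataset()].
#' @param matchThreshold Jaccard above which a plant counts as matched
#'   (default 0.25).
#' @return list with \code{per_module} (data.frame: \code{planted_id},
#'   \code{type}, \code{best_match}, \code{jaccard}),
#'   \code{mean_jaccard_mediated}, and \code{decoy_match_rate} (fraction
#'   of decoys matched by any accepted module).
#' @export
moduleRecoveryScore <- function(found, truth, matchThreshold = 0.25) {
  stopifnot(is(found, "ModuleSet"))
  found_sets <- lapply(seq_len(length(found)), function(i)
    c(found@lncrna[[i]], found@mrna[[i]]))
  per <- lapply(truth, function(tr) {
    tset <- c(tr$lncrna, tr$mrna)
    if (!length(found_sets)) {
      j <- 0; best <- NA_character_
    } else {
      js <- vapply(found_sets, function(fs)
        length(intersect(fs, tset)) / length(union(fs, tset)), 0)
      j <- max(js)
      best <- found@moduleIds[which.max(js)]
    }
    data.frame(planted_id = tr$id, type = tr$type, best_match = best,
               jaccard = j, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  med <- per$type == "mediated"
  list(per_module = per,
       mean_jaccard_mediated = if (any(med)) mean(per$jaccard[med])
                               else NA_real_,
       decoy_match_rate = if (any(!med))
         mean(per$jaccard[!med] > matchThreshold) else NA_real_)
}
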