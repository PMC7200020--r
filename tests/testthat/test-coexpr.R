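test_that("scale-free fit index is ~1 on an exact power-law degree vector", {
  # distinct connectivity values placed one per bin, frequencies C * k^-2:
  # the binned log-log regression is then exactly linear up to rounding
  v <- seq(10, 100, by = 10)
  freq <- round(1e5 * v^-2)
  k <- rep(v, times = freq)
  r2 <- scaleFreeFitIndex(k, nBins = 10)
  expect_gt(r2, 0.999)
})

test_that("fit index is signed negative when the degree trend rises", {
  v <- seq(10, 100, by = 10)
  freq <- round(v^1.5)      # frequency increasing with connectivity
  k <- rep(v, times = freq)
  expect_lt(scaleFreeFitIndex(k, nBins = 10), 0)
})

test_that("soft-threshold selection honours the target and falls back to argmax", {
  d <- default_sim()
  expr <- rbind(d$lncrna, d$mrna)[1:40, 1:60]
  # vacuous target: smallest candidate power wins
  st0 <- pickSoftThreshold(expr, powers = c(2L, 4L, 6L), r2Target = 0)
  expect_identical(st0$power, 2L)
  expect_true(st0$reached_target)
  # white noise typically reaches no high target: argmax power + warning
  noise <- rand_expr(sprintf("g%02d", 1:30), 40, seed = 5)
  expect_warning(st1 <- pickSoftThreshold(noise, powers = 1:6,
                                          r2Target = 0.999),
                 "no candidate power")
  expect_false(st1$reached_target)
  fit <- ifelse(is.na(st1$scan$fit_r2), -Inf, st1$scan$fit_r2)
  expect_identical(st1$power, st1$scan$power[which.max(fit)])
  expect_error(pickSoftThreshold(expr[, 1:3]), "4 samples")
})

test_that("topological overlap matches closed forms and the brute-force oracle", {
  # 2-gene network: TOM_12 = t
  for (t in c(0.2, 0.5, 0.9)) {
    a <- matrix(c(0, t, t, 0), 2)
    expect_equal(tomSimilarity(a)[1, 2], t, tolerance = 1e-12)
  }
  # complete graph: all overlaps 1
  a1 <- matrix(1, 5, 5); diag(a1) <- 0
  expect_equal(max(abs(tomSimilarity(a1) - 1)), 0, tolerance = 1e-12)
  # random networks up to 10 genes vs triple-loop oracle
  for (p in c(4, 6, 10)) {
    set.seed(p)
    a <- matrix(runif(p * p), p)
    a <- (a + t(a)) / 2; diag(a) <- 0
    expect_equal(tomSimilarity(a), tom_brute(a), tolerance = 1e-12)
  }
  expect_error(tomSimilarity(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("planted co-expression blocks are detected as modules", {
  d <- default_sim()
  mods <- suppressWarnings(
    detectCoexpressionModules(d$lncrna, d$mrna, minModuleSize = 20))
  expect_equal(length(mods), 4L)   # 2 mediated + 2 decoy blocks
  truth_sets <- lapply(d$truth, function(tr) c(tr$lncrna, tr$mrna))
  found_sets <- Map(c, lncrnaMembers(mods), mrnaMembers(mods))
  for (ts in truth_sets) {
    match <- vapply(found_sets, function(fs) setequal(fs, ts), NA)
    expect_true(any(match))
  }
  # modules are disjoint gene sets
  allg <- unlist(found_sets)
  expect_false(anyDuplicated(allg) > 0)
})

test_that("modules violating the 2-lncRNA / 2-mRNA rule are dropped", {
  # one block of 1 lncRNA + 25 mRNAs: co-expressed but not a valid module
  set.seed(9)
  s <- 80
  f <- rnorm(s)
  lnc <- matrix(f, 1, s, byrow = TRUE) + matrix(rnorm(s, sd = 0.3), 1, s)
  rownames(lnc) <- "lncA"
  mr <- matrix(f, 25, s, byrow = TRUE) + matrix(rnorm(25 * s, sd = 0.3), 25, s)
  rownames(mr) <- sprintf("mr%02d", 1:25)
  colnames(lnc) <- colnames(mr) <- sprintf("S%02d", 1:s)
  mods <- suppressWarnings(
    detectCoexpressionModules(lnc, mr, minModuleSize = 10, power = 6))
  expect_equal(length(mods), 0L)
})

test_that("pure noise yields no modules", {
  lnc <- rand_expr(sprintf("l%02d", 1:15), 50, seed = 21)
  mr <- rand_expr(sprintf("m%02d", 1:25), 50, seed = 22)
  mods <- suppressWarnings(
    detectCoexpressionModules(lnc, mr, minModuleSize = 30, power = 6))
  expect_equal(length(mods), 0L)
})

test_that("module membership is invariant to gene-row permutation", {
  d <- default_sim()
  m1 <- suppressWarnings(
    detectCoexpressionModules(d$lncrna, d$mrna, minModuleSize = 20,
                              power = 6))
  set.seed(31)
  perm_l <- sample(nrow(d$lncrna)); perm_m <- sample(nrow(d$mrna))
  m2 <- suppressWarnings(
    detectCoexpressionModules(d$lncrna[perm_l, ], d$mrna[perm_m, ],
                              minModuleSize = 20, power = 6))
  sets1 <- lapply(seq_along(moduleIds(m1)), function(i)
    sort(c(lncrnaMembers(m1)[[i]], mrnaMembers(m1)[[i]])))
  sets2 <- lapply(seq_along(moduleIds(m2)), function(i)
    sort(c(lncrnaMembers(m2)[[i]], mrnaMembers(m2)[[i]])))
  expect_identical(sets1, sets2)   # deterministic size/id-based labelling
})
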