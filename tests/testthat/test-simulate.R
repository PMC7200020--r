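test_that("simulation is bit-identical under a fixed seed", {
  d1 <- simulateSpongeDataset(seed = 101)
  d2 <- simulateSpongeDataset(seed = 101)
  expect_identical(d1, d2)
  d3 <- simulateSpongeDataset(seed = 102)
  expect_false(identical(d1$lncrna, d3$lncrna))
})

test_that("interaction table contains every planted (miRNA, member) pair", {
  d <- simulateSpongeDataset(seed = 103)
  key <- paste(d$interactions$mirna, d$interactions$target)
  for (tr in d$truth) {
    want <- expand.grid(m = tr$mirnas, t = c(tr$lncrna, tr$mrna),
                        stringsAsFactors = FALSE)
    expect_true(all(paste(want$m, want$t) %in% key))
  }
  # ids in truth exist in the matrices
  for (tr in d$truth) {
    expect_true(all(tr$lncrna %in% rownames(d$lncrna)))
    expect_true(all(tr$mrna %in% rownames(d$mrna)))
    expect_true(all(tr$mirnas %in% rownames(d$mirna)))
  }
})

test_that("full mediation gives miRNA-explained pairwise correlation", {
  d <- simulateSpongeDataset(
    planted = list(list(nLncrna = 6, nMrna = 6, nSharedMirna = 5,
                        mediation = 1, noiseSd = 0.1)),
    nDecoy = 0, nBackground = c(mirna = 0, lncrna = 0, mrna = 0),
    seed = 105)
  tr <- d$truth[[1]]
  Z <- t(d$mirna[tr$mirnas, ])
  cors <- pcors <- c()
  for (l in tr$lncrna[1:3]) for (g in tr$mrna[1:3]) {
    x <- d$lncrna[l, ]; y <- d$mrna[g, ]
    cors <- c(cors, cor(x, y))
    pcors <- c(pcors, cor(resid(lm(x ~ Z)), resid(lm(y ~ Z))))
  }
  expect_true(all(cors > 0.8))
  expect_true(all(abs(pcors) < 0.2))
})

test_that("decoy modules carry near-zero sensitivity canonical correlation", {
  d <- simulateSpongeDataset(seed = 106)
  tr <- Filter(function(t) t$type == "decoy", d$truth)[[1]]
  cc <- canonicalCorrelation(d$lncrna[tr$lncrna, ], d$mrna[tr$mrna, ])$cc
  cmm <- canonicalCorrelation(d$mirna[tr$mirnas, ], d$mrna[tr$mrna, ])$cc
  cml <- canonicalCorrelation(d$mirna[tr$mirnas, ], d$lncrna[tr$lncrna, ])$cc
  scc <- cc - partialCanonicalCorrelation(cc, cmm, cml)
  expect_lt(abs(scc), 0.05)
  expect_gt(cc, 0.8)     # decoys are genuinely co-expressed
})

test_that("recovery scoring computes best-match Jaccard", {
  d <- simulateSpongeDataset(seed = 107)
  truth_mods <- ModuleSet(lapply(d$truth, `[[`, "lncrna"),
                          lapply(d$truth, `[[`, "mrna"),
                          vapply(d$truth, `[[`, "", "id"))
  perfect <- moduleRecoveryScore(truth_mods, d$truth)
  expect_true(all(perfect$per_module$jaccard == 1))
  expect_equal(perfect$mean_jaccard_mediated, 1)
  expect_equal(perfect$decoy_match_rate, 1)
  # disjoint: all zeros
  disjoint <- ModuleSet(list(c("x1", "x2")), list(c("y1", "y2")))
  none <- moduleRecoveryScore(disjoint, d$truth)
  expect_true(all(none$per_module$jaccard == 0))
  # half the mRNAs missing: hand-computed Jaccard
  tr <- d$truth[[1]]
  half <- ModuleSet(list(tr$lncrna), list(tr$mrna[1:10]))
  sc <- moduleRecoveryScore(half, d$truth)
  expect_equal(sc$per_module$jaccard[1], 20 / 30, tolerance = 1e-12)
})

test_that("survival and subtype annotations are consistent with the samples", {
  d <- simulateSpongeDataset(seed = 108)
  expect_true(all(d$survival$sample_id %in% colnames(d$mirna)))
  expect_true(all(d$survival$time > 0))
  expect_true(all(d$survival$event %in% c(0, 1)))
  expect_identical(sort(names(d$labels)), sort(colnames(d$mirna)))
  expect_equal(length(unique(d$labels)), 3L)
})

test_that("mediated plants separate from decoys on SCC across replicates", {
  scc_of <- function(tr, d) {
    cc <- canonicalCorrelation(d$lncrna[tr$lncrna, ], d$mrna[tr$mrna, ])$cc
    cmm <- canonicalCorrelation(d$mirna[tr$mirnas, ], d$mrna[tr$mrna, ])$cc
    cml <- canonicalCorrelation(d$mirna[tr$mirnas, ],
                                d$lncrna[tr$lncrna, ])$cc
    cc - partialCanonicalCorrelation(cc, cmm, cml)
  }
  n_rep <- 100
  wins <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- simulateSpongeDataset(
      planted = list(list(nLncrna = 6, nMrna = 8, nSharedMirna = 4,
                          mediation = 0.9, noiseSd = 0.3)),
      nDecoy = 1,
      decoyShape = list(nLncrna = 6, nMrna = 8, nSharedMirna = 4,
                        noiseSd = 0.3),
      nBackground = c(mirna = 5, lncrna = 0, mrna = 0),
      nSamples = 150, seed = 1000 + r)
    med <- Filter(function(t) t$type == "mediated", d$truth)[[1]]
    dec <- Filter(function(t) t$type == "decoy", d$truth)[[1]]
    wins[r] <- scc_of(med, d) > scc_of(dec, d)
  }
  expect_gte(mean(wins), 0.95)
})
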