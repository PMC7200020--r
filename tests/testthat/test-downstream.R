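test_that("disease enrichment delegates to the hypergeometric tail", {
  bg <- sprintf("g%03d", 1:200)
  disease <- bg[1:40]
  module <- bg[c(1:10, 101:110)]            # 10 disease genes of 20
  res <- diseaseEnrichment(module, disease, bg)
  expect_equal(res$p_value, hyper_tail_enum(200, 40, 20, 10),
               tolerance = 1e-12)
  expect_true(res$related)
  expect_equal(c(res$N2, res$M2, res$K2, res$L2), c(200, 40, 20, 10))
  # no disease genes in module
  res0 <- diseaseEnrichment(bg[101:105], disease, bg)
  expect_identical(res0$p_value, 1)
  expect_false(res0$related)
  expect_error(diseaseEnrichment(c("zz"), disease, bg), "background")
})

test_that("Welch test matches hand-computed toy and null calibration", {
  w <- welchTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.22474487, tolerance = 1e-6)
  expect_equal(w$df, 4, tolerance = 1e-9)
  same <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # p-values roughly uniform under equal means
  set.seed(29)
  ps <- replicate(400, welchTTest(rnorm(10), rnorm(12))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("subtype calls require a consistent mean ordering and all pairs significant", {
  set.seed(33)
  n_per <- 30
  labels <- setNames(rep(c("A", "B", "C"), each = n_per),
                     sprintf("S%03d", 1:(3 * n_per)))
  es <- rbind(
    up_in_A = c(rnorm(n_per, 2), rnorm(n_per), rnorm(n_per)),
    flat = rnorm(3 * n_per),
    down_in_C = c(rnorm(n_per), rnorm(n_per), rnorm(n_per, -2)))
  colnames(es) <- names(labels)
  calls <- subtypeSpecificModules(es, labels)
  expect_true(any(calls$module_id == "up_in_A" & calls$subtype == "A" &
                    calls$direction == "up"))
  expect_true(any(calls$module_id == "down_in_C" & calls$subtype == "C" &
                    calls$direction == "down"))
  expect_false("flat" %in% calls$module_id)
  # highest mean but one clearly non-significant pair: no call
  set.seed(35)
  base <- rnorm(n_per)
  es2 <- rbind(m = c(base + 0.01, base, rnorm(n_per, -2)))
  colnames(es2) <- names(labels)
  calls2 <- subtypeSpecificModules(es2, labels)
  expect_false(any(calls2$subtype == "A" & calls2$direction == "up"))
})

test_that("subtype calls are stable under within-subtype sample permutation", {
  set.seed(34)
  labels <- setNames(rep(c("A", "B"), each = 20), sprintf("S%02d", 1:40))
  es <- rbind(m1 = c(rnorm(20, 1.5), rnorm(20)))
  colnames(es) <- names(labels)
  c1 <- subtypeSpecificModules(es, labels)
  perm <- c(sample(1:20), sample(21:40))
  c2 <- subtypeSpecificModules(es[, perm, drop = FALSE], labels[perm])
  expect_identical(c1[c("module_id", "subtype", "direction")],
                   c2[c("module_id", "subtype", "direction")])
})

test_that("small subtypes are excluded with a warning", {
  labels <- setNames(c(rep("A", 10), rep("B", 10), "C"),
                     sprintf("S%02d", 1:21))
  es <- matrix(rnorm(21), 1, dimnames = list("m1", names(labels)))
  expect_warning(subtypeSpecificModules(es, labels), "excluded")
})

test_that("sponge-pair and miRNA-target prediction count cross products", {
  sp <- new("SpongeModuleSet", moduleIds = c("M1", "M2"),
            lncrna = list(c("l1", "l2"), c("l1", "l3")),
            mrna = list(c("g1", "g2", "g3"), c("g1", "g4")),
            sharedMirnas = list(c("m1", "m2"), "m1"),
            stats = data.frame(p_share = c(0.01, 0.01), cc = c(0.9, 0.9),
                               cc_mir_mr = 0, cc_mir_lncr = 0,
                               pcc = c(0.9, 0.9), scc = c(0, 0)))
  pairs <- predictSpongePairs(sp[1])
  expect_equal(nrow(pairs), 6L)            # 2 lncRNAs x 3 mRNAs
  tg <- predictMirnaTargets(sp[1])
  expect_equal(nrow(tg), 10L)              # 2 miRNAs x 5 members
  expect_equal(sum(tg$target_class == "lncRNA"), 4L)
  expect_equal(sum(tg$target_class == "mRNA"), 6L)
  # overlapping modules deduplicate: (l1, g1) counted once
  both <- predictSpongePairs(sp)
  expect_equal(nrow(both), 6L + 4L - 1L)
  # empty set
  empty <- new("SpongeModuleSet", moduleIds = character(), lncrna = list(),
               mrna = list(), sharedMirnas = list(),
               stats = data.frame(p_share = numeric(), cc = numeric(),
                                  cc_mir_mr = numeric(),
                                  cc_mir_lncr = numeric(),
                                  pcc = numeric(), scc = numeric()))
  expect_equal(nrow(predictSpongePairs(empty)), 0L)
  expect_equal(nrow(predictMirnaTargets(empty)), 0L)
})

test_that("method comparison table is produced and internally consistent", {
  d <- default_sim()
  coex <- suppressWarnings(
    detectCoexpressionModules(d$lncrna, d$mrna, minModuleSize = 20,
                              power = 6))
  sp <- identifySpongeModules(coex, d$mirna, d$lncrna, d$mrna,
                              d$interactions)
  bg <- c(rownames(d$lncrna), rownames(d$mrna))
  disease <- unlist(lapply(d$truth[1], function(t) c(t$lncrna, t$mrna)))
  truth_pairs <- predictSpongePairs(sp)
  tab <- compareMethods(list(sponge = sp, coexpr = coex), disease, bg,
                        truthPairs = truth_pairs)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n_validated_pairs[tab$method == "sponge"],
               nrow(truth_pairs))
  expect_true(all(tab$pct_disease >= 0 & tab$pct_disease <= 100,
                  na.rm = TRUE))
  # identical module lists give identical rows
  tab2 <- compareMethods(list(a = sp, b = sp), disease, bg,
                         truthPairs = truth_pairs)
  expect_equal(tab2$pct_disease[1], tab2$pct_disease[2])
  expect_equal(tab2$n_validated_pairs[1], tab2$n_validated_pairs[2])
  # empty truth list: zero validated
  tab3 <- compareMethods(list(a = sp, b = coex), disease, bg,
                         truthPairs = data.frame(lncrna = character(),
                                                 mrna = character()))
  expect_true(all(tab3$n_validated_pairs == 0))
})
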