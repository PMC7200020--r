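test_that("pairwise network enforces the shared-miRNA floor and mediation", {
  d <- default_sim()
  tr_med <- d$truth[[1]]                       # mediated plant
  tr_dec <- d$truth[[3]]                       # decoy plant
  sub_l <- d$lncrna[c(tr_med$lncrna[1:2], tr_dec$lncrna[1:2]), ]
  sub_m <- d$mrna[c(tr_med$mrna[1:2], tr_dec$mrna[1:2]), ]
  net <- scPairwiseNetwork(sub_l, sub_m, d$mirna, d$interactions)
  key <- paste(net$lncrna, net$mrna)
  # mediated pairs retained with near-zero partial correlation
  med_rows <- net[net$lncrna %in% tr_med$lncrna &
                    net$mrna %in% tr_med$mrna, ]
  expect_gt(nrow(med_rows), 0)
  expect_true(all(med_rows$sensitivity_correlation > 0.1))
  expect_true(all(abs(med_rows$partial_correlation) <
                    med_rows$correlation))
  # decoy pairs are never retained (sensitivity ~ 0)
  expect_false(any(net$lncrna %in% tr_dec$lncrna &
                     net$mrna %in% tr_dec$mrna))
  # identity holds exactly on every edge
  expect_equal(net$sensitivity_correlation,
               net$correlation - net$partial_correlation, tolerance = 1e-12)
  expect_true(all(net$shared_mirna_count >= 3))
})

test_that("pairs sharing fewer than the minimum miRNAs are excluded", {
  set.seed(47)
  s <- 60
  f <- rnorm(s)
  lnc <- matrix(f + rnorm(s, sd = 0.2), 1, dimnames = list("L1", NULL))
  mr <- matrix(f + rnorm(s, sd = 0.2), 1, dimnames = list("G1", NULL))
  mir <- rand_expr(c("m1", "m2", "m3"), s, seed = 48)
  colnames(lnc) <- colnames(mr) <- colnames(mir)
  ia <- data.frame(mirna = c("m1", "m2", "m1", "m2"),
                   target = c("L1", "L1", "G1", "G1"))  # only 2 shared
  net <- scPairwiseNetwork(lnc, mr, mir, ia)
  expect_equal(nrow(net), 0L)
})

test_that("retained edges shrink monotonically in the thresholds", {
  d <- default_sim()
  tr <- d$truth[[1]]
  sub_l <- d$lncrna[tr$lncrna[1:4], ]
  sub_m <- d$mrna[tr$mrna[1:4], ]
  base <- scPairwiseNetwork(sub_l, sub_m, d$mirna, d$interactions,
                            minShared = 3, scMin = 0.1)
  tighter_sc <- scPairwiseNetwork(sub_l, sub_m, d$mirna, d$interactions,
                                  minShared = 3, scMin = 0.3)
  tighter_sh <- scPairwiseNetwork(sub_l, sub_m, d$mirna, d$interactions,
                                  minShared = 5, scMin = 0.1)
  key <- function(x) paste(x$lncrna, x$mrna)
  expect_true(all(key(tighter_sc) %in% key(base)))
  expect_true(all(key(tighter_sh) %in% key(base)))
})

test_that("Markov clustering separates disconnected cliques", {
  tri1 <- expand.grid(lncrna = c("l1", "l2"), mrna = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  tri2 <- expand.grid(lncrna = c("l3", "l4"), mrna = c("g3", "g4"),
                      stringsAsFactors = FALSE)
  mods <- mclCluster(rbind(tri1, tri2))
  expect_equal(length(mods), 2L)
  sets <- Map(c, lncrnaMembers(mods), mrnaMembers(mods))
  expect_true(any(vapply(sets, setequal, NA, y = c("l1", "l2", "g1", "g2"))))
  expect_true(any(vapply(sets, setequal, NA, y = c("l3", "l4", "g3", "g4"))))
})

test_that("MCL on a 4-node path matches an independent step-by-step iteration", {
  edges <- data.frame(lncrna = c("l1", "l2", "l2"),
                      mrna = c("g1", "g1", "g2"))
  # independent oracle: explicit MCL iteration with plain loops
  nodes <- c("l1", "l2", "g1", "g2")
  A <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  A["l1", "g1"] <- A["g1", "l1"] <- 1
  A["l2", "g1"] <- A["g1", "l2"] <- 1
  A["l2", "g2"] <- A["g2", "l2"] <- 1
  diag(A) <- 1
  M <- A
  for (j in 1:4) M[, j] <- M[, j] / sum(M[, j])
  for (iter in 1:200) {
    Me <- M %*% M
    Mi <- Me * Me
    for (j in 1:4) Mi[, j] <- Mi[, j] / sum(Mi[, j])
    if (max(abs(Mi - M)) < 1e-10) { M <- Mi; break }
    M <- Mi
  }
  oracle_clusters <- lapply(which(diag(M) > 1e-5), function(a)
    sort(nodes[M[a, ] > 1e-5]))
  oracle_clusters <- unique(oracle_clusters)
  got <- mclCluster(edges, minLncrna = 0, minMrna = 0)
  got_sets <- lapply(seq_len(length(got)), function(i)
    sort(c(lncrnaMembers(got)[[i]], mrnaMembers(got)[[i]])))
  for (cl in oracle_clusters)
    expect_true(any(vapply(got_sets, identical, NA, y = cl)))
  # partition property: every node appears exactly once
  expect_setequal(unlist(got_sets), nodes)
  expect_false(anyDuplicated(unlist(got_sets)) > 0)
})

test_that("MCL clusters violating the module size rule are dropped", {
  edges <- data.frame(lncrna = c("l1", "l1", "l1"),
                      mrna = c("g1", "g2", "g3"))   # 1 lncRNA, 3 mRNAs
  mods <- mclCluster(edges)
  expect_equal(length(mods), 0L)
})
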