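mkZ <- function(m, group = rep("CP", nrow(m)),
                ids = sprintf("S%02d", seq_len(nrow(m)))) {
  zt <- zScoreTable(m, group, ids)
  attr(zt, "aggregates") <- colnames(m)
  zt
}

test_that("profile distances follow the pairwise-complete rescaling", {
  m <- rbind(c(0, 0), c(3, 4), c(0, 0))
  colnames(m) <- c("a", "b")
  D <- pairwiseDistance(mkZ(m), columns = c("a", "b"))
  expect_equal(D[1, 2], 5)           # 3-4-5 triangle
  expect_equal(D[1, 3], 0)           # identical rows
  expect_equal(diag(unclass(D)), rep(0, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(D)))
  # one shared column of two, difference 3 -> 3 * sqrt(2)
  m2 <- rbind(c(0, NA), c(3, 1))
  colnames(m2) <- c("a", "b")
  D2 <- pairwiseDistance(mkZ(m2), columns = c("a", "b"))
  expect_equal(D2[1, 2], 3 * sqrt(2))
  # a pair sharing nothing is an error
  m3 <- rbind(c(1, NA), c(NA, 1))
  colnames(m3) <- c("a", "b")
  expect_error(pairwiseDistance(mkZ(m3)), "share no")
  # an all-missing participant is dropped with a warning
  m4 <- rbind(c(1, 2), c(2, 1), c(NA, NA))
  colnames(m4) <- c("a", "b")
  expect_warning(D4 <- pairwiseDistance(mkZ(m4)), "all columns missing")
  expect_equal(nrow(D4), 2)
})

test_that("complete linkage reproduces hand-computed merges", {
  # two identical profiles merge at height zero
  m <- rbind(c(1, 1), c(1, 1), c(4, 5))
  colnames(m) <- c("a", "b")
  dn <- completeLinkage(pairwiseDistance(mkZ(m)))
  expect_equal(dn$height[1], 0)
  # points on a line at 0, 1, 10: merge {0,1} at 1, then with 10 at 10
  ml <- cbind(x = c(0, 1, 10), y = 0)
  dl <- completeLinkage(pairwiseDistance(mkZ(ml), columns = c("x", "y")))
  expect_equal(dl$height, c(1, 10))
  expect_equal(sort(dl$merge[1, ]), c(-2, -1))
  # final merge height equals the maximum pairwise distance
  set.seed(40)
  mr <- matrix(rnorm(8 * 4), 8)
  colnames(mr) <- paste0("c", 1:4)
  Dr <- pairwiseDistance(mkZ(mr), columns = colnames(mr))
  dr <- completeLinkage(Dr)
  expect_equal(max(dr$height), max(unclass(Dr)))
  expect_true(all(diff(dr$height) >= -1e-12))
})

test_that("clustering outputs are equivariant to participant order", {
  set.seed(41)
  m <- matrix(rnorm(10 * 3), 10)
  colnames(m) <- paste0("c", 1:3)
  ids <- sprintf("S%02d", 1:10)
  zt <- mkZ(m, ids = ids)
  perm <- sample(10)
  ztP <- mkZ(m[perm, ], ids = ids[perm])
  k1 <- cutDendrogram(completeLinkage(pairwiseDistance(zt,
                                                       columns = colnames(m))), 3)
  k2 <- cutDendrogram(completeLinkage(pairwiseDistance(ztP,
                                                       columns = colnames(m))), 3)
  # same partition, independent of row order (labels may differ)
  tab <- table(k1[ids], k2[ids])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("planted subtype archetypes are recovered by the clustering", {
  skip_if_not_installed("mclust")
  hits <- 0
  for (r in 1:10) {
    sim <- simulateArchetypeProfiles(nCP = 13, seed = 500 + r)
    cp <- attr(sim$ztab, "group") == "CP"
    zcp <- zScoreTable(unclass(sim$ztab)[cp, ], rep("CP", sum(cp)),
                       rownames(sim$ztab)[cp])
    attr(zcp, "aggregates") <- colnames(zcp)
    kk <- cutDendrogram(completeLinkage(pairwiseDistance(zcp)), 3)
    ari <- mclust::adjustedRandIndex(kk[names(sim$archetype)],
                                     sim$archetype)
    hits <- hits + (ari > 0.8)
  }
  expect_gte(hits, 8)
})

test_that("the profile report is ordered by the dendrogram leaves", {
  sim <- simulateArchetypeProfiles(nCP = 6, nControls = 8, seed = 44)
  zt <- sim$ztab
  dn <- completeLinkage(pairwiseDistance(zt))
  defs <- deficitCalls(zt)
  rep_ <- profileReport(zt, defs, dn)
  expect_setequal(rep_$participant_id, rownames(zt))
  expect_equal(rep_$participant_id, dn$labels[dn$order])
  expect_true(all(c("overall_z", "overall_deficit", "overall_missing")
                  %in% names(rep_)))
  # z cells round-trip from the table
  expect_equal(rep_$perceptual_z,
               round(unclass(zt)[rep_$participant_id, "perceptual"], 3),
               ignore_attr = TRUE)
})
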