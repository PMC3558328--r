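test_that("tree simulation is seeded, conditioned, and ultrametric", {
  t1 <- simTree(50, "yule", rate = 1, seed = 7)
  expect_equal(length(t1$tip.label), 50L)
  expect_equal(t1$Nnode, 49L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-6))
  # determinism: identical Newick under the same seed
  t1b <- simTree(50, "yule", rate = 1, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t1b))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(simTree(50, "yule", 1, seed = 8))))
  # provenance records the spec
  expect_equal(attr(t1, "simSpec")$seed, 7)
  # birth-death returns n extant tips after pruning
  t2 <- simTree(25, "birthdeath", rate = 2, a = 0.4, seed = 3)
  expect_equal(length(t2$tip.label), 25L)
  expect_true(ape::is.ultrametric(t2, tol = 1e-6))
  # yule2rate: the youngest branching sits exactly at the shift age
  t3 <- simTree(30, "yule2rate", rate = 20, r2 = 4, shiftAge = 0.02, seed = 5)
  expect_equal(length(t3$tip.label), 30L)
  expect_equal(min(branchingTimes(t3)), 0.02, tolerance = 1e-9)
})

test_that("mean Yule root age matches the analytic expectation", {
  r <- 2; N <- 12
  roots <- vapply(1:300, function(s)
    max(branchingTimes(simTree(N, "yule", rate = r, seed = 9000 + s))), 0)
  expected <- sum(1 / (2:N)) / r   # E[sum of Exp(i r) waits], i = 2..N
  expect_lt(abs(mean(roots) - expected) / expected, 0.15)
})

test_that("species+coalescent trees carry their true partition", {
  sim <- simSpeciesCoalescentTree(8, 4, 1, 20, seed = 11)
  expect_equal(length(sim$tree$tip.label), 32L)
  expect_equal(nBlocks(sim$partition), 8L)
  expect_equal(sum(lengths(partitionBlocks(sim$partition))), 32L)
  expect_true(ape::is.ultrametric(sim$tree, tol = 1e-6))
  # within-species depths stay well below the youngest species age
  bt <- sort(ape::branching.times(sim$tree), decreasing = TRUE)
  minSp <- bt[7]                     # 7 species splits
  expect_lt(max(bt[-(1:7)]), minSp / 5)
  # one tip per species degenerates to the species tree
  s1 <- simSpeciesCoalescentTree(6, 1, 1, 20, seed = 2)
  expect_equal(length(s1$tree$tip.label), 6L)
  expect_equal(nBlocks(s1$partition), 6L)
})

test_that("K80 sequence evolution is seeded and model-consistent", {
  tr <- simTree(6, "yule", rate = 1, seed = 3)
  a1 <- simSequencesK80(tr, length = 120, kappa = 4, scale = 0.1, seed = 9)
  expect_s4_class(a1, "BarcodeAlignment")
  expect_equal(alignmentLength(a1), 120L)
  expect_identical(alignedSeqs(a1),
                   alignedSeqs(simSequencesK80(tr, 120, 4, 0.1, seed = 9)))
  # scale = 0 -> all sequences identical
  a0 <- simSequencesK80(tr, length = 50, kappa = 4, scale = 0, seed = 1)
  expect_equal(length(unique(alignedSeqs(a0))), 1L)
  # estimator consistency: mean K2P distance ~= true separation
  two <- ape::read.tree(text = "(x:0.05,y:0.05);")
  dd <- vapply(1:100, function(s) {
    aln <- simSequencesK80(two, length = 2000, kappa = 4, scale = 1,
                           seed = 500 + s)
    k2pDistance(alignedSeqs(aln)[[1]], alignedSeqs(aln)[[2]])$d
  }, 0)
  expect_lt(abs(mean(dd) - 0.1) / 0.1, 0.10)
})

test_that("planted-gap datasets honour their guarantees by construction", {
  pg <- makePlantedGapDataset(6, 4, 0.01, 0.06, 500, seed = 13)
  d <- distanceMatrix(pg$distances)
  ids <- rownames(d)
  same <- outer(sub("_t.*", "", ids), sub("_t.*", "", ids), "==")
  ut <- upper.tri(d)
  expect_lte(max(d[ut & same]), 0.01)
  expect_gte(min(d[ut & !same]), 0.06)
  # any threshold inside the gap recovers the truth
  for (ct in c(0.015, 0.032, 0.05)) {
    expect_true(samePartition(thresholdPartition(pg$distances, ct),
                              pg$partition))
  }
  expect_error(makePlantedGapDataset(4, 4, intraMax = 0.06, interMin = 0.01),
               "exceed")
})

test_that("morphospecies label edits are feasible-checked and logged", {
  part <- lineagePartition(setNames(rep(as.character(1:6), each = 3),
                                    paste0("s", 1:18)))
  lab <- assignMorphospeciesLabels(part, nLumps = 2, nSplits = 1, seed = 4)
  expect_length(lab, 18L)
  log <- attr(lab, "editLog")
  expect_equal(vapply(log, `[[`, "", "edit"), c("lump", "lump", "split"))
  # names count: 6 - 2 (merged away) + 1 (split adds one)
  expect_equal(length(unique(lab)), 5L)
  expect_error(assignMorphospeciesLabels(part, nLumps = 4, nSplits = 0),
               "not enough")
  # identity edits leave one name per block
  lab0 <- assignMorphospeciesLabels(part, 0, 0, seed = 1)
  expect_equal(length(unique(lab0)), 6L)
})

test_that("suitability grids overlap less as their centres separate", {
  g0 <- makeSuitabilityGrids(c(30, 30), c(4, 4), separation = 0, seed = 1)
  ov0 <- nicheOverlapStats(g0$g1, g0$g2)
  expect_equal(ov0$D, 1, tolerance = 1e-6)
  seps <- c(0, 4, 8, 16, 24)
  Ds <- vapply(seps, function(s) {
    g <- makeSuitabilityGrids(c(30, 30), c(4, 4), separation = s, seed = 1)
    nicheOverlapStats(g$g1, g$g2)$D
  }, 0)
  expect_true(all(diff(Ds) < 0))
  expect_lte(Ds[length(Ds)], 0.05)
  # deterministic under a fixed seed
  g1 <- makeSuitabilityGrids(c(20, 20), c(3, 3), 5, seed = 2)
  g2 <- makeSuitabilityGrids(c(20, 20), c(3, 3), 5, seed = 2)
  expect_identical(g1$g1, g2$g1)
})
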