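test_that("the join merges through chains of co-membership", {
  p1 <- lineagePartition(c(s1 = "a", s2 = "a", s3 = "b"))
  p2 <- lineagePartition(c(s1 = "x", s2 = "y", s3 = "y"))
  j <- joinPartitions(list(p1, p2))
  expect_equal(nBlocks(j), 1L)
  # idempotence on identical inputs
  expect_true(samePartition(joinPartitions(list(p1, p1)), p1))
  # join with all-singletons partition is the identity
  singles <- lineagePartition(c(s1 = "1", s2 = "2", s3 = "3"))
  expect_true(samePartition(joinPartitions(list(p1, singles)), p1))
  expect_error(joinPartitions(list()), "empty")
  expect_error(joinPartitions(list(p1, lineagePartition(c(s9 = "a")))),
               "different specimen sets")
})

test_that("join is commutative, associative, idempotent vs graph oracle", {
  skip_if_not_installed("igraph")
  ids <- sprintf("s%02d", 1:12)
  for (seed in 1:6) {
    ps <- list(randomPartition(ids, 4, seed), randomPartition(ids, 5, seed + 50),
               randomPartition(ids, 3, seed + 100))
    j <- joinPartitions(ps)
    # oracle: connected components of the union co-membership graph
    edges <- do.call(rbind, lapply(ps, function(p) {
      a <- blockAssignment(p)
      do.call(rbind, lapply(split(names(a), a), function(b)
        if (length(b) > 1) cbind(b[-length(b)], b[-1]) else NULL))
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                              name = setdiff(ids, igraph::V(g)$name))
    comp <- igraph::components(g)$membership[ids]
    expect_true(sameGrouping(unname(blockAssignment(j)[ids]), unname(comp)))
    # order invariance
    expect_true(samePartition(j, joinPartitions(rev(ps))))
    # idempotent: joining the join changes nothing
    expect_true(samePartition(j, joinPartitions(c(ps, list(j)))))
    # block count bounded by the finest input
    expect_lte(nBlocks(j), min(vapply(ps, nBlocks, 0L)))
  }
})

test_that("cross-validation statuses match their definitions", {
  # consensus identical to morphospecies -> all match
  cons <- lineagePartition(c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  lab <- c(s1 = "m1", s2 = "m1", s3 = "m2", s4 = "m2")
  cv <- crossvalidateMorphospecies(cons, lab)
  expect_equal(unname(cv$counts["matches"]), 2L)
  expect_equal(sum(cv$counts), 2L)
  # one morphospecies over two pure ELs -> split, one unrecognized EL
  cons2 <- lineagePartition(c(s1 = "A", s2 = "B", s3 = "B", s4 = "C"))
  lab2 <- c(s1 = "m1", s2 = "m1", s3 = "m1", s4 = "m2")
  cv2 <- crossvalidateMorphospecies(cons2, lab2)
  expect_equal(unname(cv2$status["m1"]), "split")
  expect_equal(cv2$unrecognizedEls, 1L)
  expect_equal(unname(cv2$splitInto["m1"]), 2L)
  # two names in one EL -> both lumped, EL reported
  cons3 <- lineagePartition(c(s1 = "A", s2 = "A"))
  lab3 <- c(s1 = "m1", s2 = "m2")
  cv3 <- crossvalidateMorphospecies(cons3, lab3)
  expect_equal(unname(cv3$counts["lumped"]), 2L)
  expect_equal(cv3$lumpedEls, "A")
  # mixed: several ELs, one shared
  cons4 <- lineagePartition(c(s1 = "A", s2 = "B", s3 = "B"))
  lab4 <- c(s1 = "m1", s2 = "m1", s3 = "m2")
  expect_equal(unname(crossvalidateMorphospecies(cons4, lab4)$status["m1"]),
               "mixed")
  expect_error(crossvalidateMorphospecies(cons, lab[1:3]), "unlabeled")
})

test_that("generator edits are recovered exactly by cross-validation", {
  pg <- makePlantedGapDataset(8, 4, 0.01, 0.06, 400, seed = 6)
  truth <- pg$partition
  # m lumping edits -> m names spanning 2 pure ELs each: status "split"
  for (m in 1:3) {
    lab <- assignMorphospeciesLabels(truth, nLumps = m, nSplits = 0,
                                     seed = 20 + m)
    cv <- crossvalidateMorphospecies(truth, lab)
    expect_equal(unname(cv$counts["split"]), m)
    expect_equal(unname(cv$counts["lumped"]), 0L)
    expect_equal(cv$unrecognizedEls, m)
  }
  # s splitting edits -> s ELs holding >= 2 names; 2s lumped names
  for (s in 1:3) {
    lab <- assignMorphospeciesLabels(truth, nLumps = 0, nSplits = s,
                                     seed = 30 + s)
    cv <- crossvalidateMorphospecies(truth, lab)
    expect_equal(length(cv$lumpedEls), s)
    expect_equal(unname(cv$counts["lumped"]), 2L * s)
  }
  # no edits -> all match
  lab0 <- assignMorphospeciesLabels(truth, 0, 0, seed = 1)
  expect_equal(unname(crossvalidateMorphospecies(truth, lab0)$counts["matches"]),
               nBlocks(truth))
})

test_that("the contingency table conserves specimen counts", {
  pg <- makePlantedGapDataset(6, 4, 0.01, 0.06, 400, seed = 9)
  lab <- assignMorphospeciesLabels(pg$partition, 1, 1, seed = 2)
  cv <- crossvalidateMorphospecies(pg$partition, lab)
  expect_equal(sum(cv$contingency), 24L)
  expect_equal(sort(unname(rowSums(cv$contingency))),
               sort(unname(lengths(partitionBlocks(pg$partition)))))
})
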