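test_that("branching times and LTT points are read off correctly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(branchingTimes(tr), c(2, 1))
  # balanced 4-tip tree, depth 3, cherries at 1
  tr4 <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  expect_equal(branchingTimes(tr4), c(3, 1, 1))
  tr20 <- simTree(20, "yule", rate = 1, seed = 2)
  expect_length(branchingTimes(tr20), 19L)
  ltt <- lttPoints(c(2, 1))
  expect_equal(ltt$time[1:2], c(-1, -0.5))
  expect_equal(ltt$lineages[1:2], c(2, 3))
  expect_equal(ltt$lineages[nrow(ltt)], 3)
  expect_true(all(diff(ltt$lineages) >= 0))
})

test_that("the generalized-Yule likelihood matches a hand expansion", {
  # cherry-tree ages [2, 1], N = 3: lnL = ln(2 lam) - lam (2*1 + 3*1)
  lam <- 0.8
  expect_equal(generalizedYuleLoglik(c(2, 1), function(n, t) lam),
               log(2 * lam) - lam * (2 * 1 + 3 * 1), tolerance = 1e-12)
  # scaling law: ages * c and rate / c change lnL by (N-2) * log(1/c)
  bt <- branchingTimes(simTree(15, "yule", rate = 2, seed = 4))
  cc <- 3
  expect_equal(generalizedYuleLoglik(bt * cc, function(n, t) lam / cc),
               generalizedYuleLoglik(bt, function(n, t) lam) +
                 (15 - 2) * log(1 / cc), tolerance = 1e-8)
  expect_error(generalizedYuleLoglik(c(2, 1), function(n, t) 0),
               "domain error")
})

test_that("pureBirth MLE matches a brute-force grid search", {
  for (seed in 1:5) {
    bt <- branchingTimes(simTree(20, "yule", rate = 5, seed = 600 + seed))
    fit <- fitDivModel(bt, "pureBirth")
    grid <- seq(0.5, 30, length.out = 4000)
    lnl <- vapply(grid, function(r)
      generalizedYuleLoglik(bt, function(n, t) r), 0)
    rGrid <- grid[which.max(lnl)]
    expect_equal(fit@params[["r1"]], rGrid, tolerance = 1e-3)
    expect_gte(fit@logLik + 1e-9, max(lnl))
  }
})

test_that("model nesting and the bd/pureBirth boundary identity hold", {
  bt <- branchingTimes(simTree(30, "yule", rate = 10, seed = 12))
  pb <- fitDivModel(bt, "pureBirth")
  y2 <- fitDivModel(bt, "yule2rate")
  bd <- fitDivModel(bt, "bd")
  expect_gte(y2@logLik, pb@logLik - 1e-9)
  expect_gte(bd@logLik, pb@logLik - 1e-9)
  # the bd likelihood at a = 0 IS the pureBirth likelihood
  iv <- LineageDelim:::.btIntervals(bt)
  r <- pb@params[["r1"]]
  expect_equal(LineageDelim:::.bdLnl(iv, r, 0), pb@logLik, tolerance = 1e-9)
  # AIC arithmetic for every fit
  for (f in list(pb, y2, bd)) {
    expect_equal(f@aic, 2 * f@nParams - 2 * f@logLik, tolerance = 1e-9)
  }
})

test_that("yule2rate recovers a strong shift and prefers the oldest tie", {
  tr <- simTree(45, "yule2rate", rate = 30, r2 = 6, shiftAge = 0.01,
                seed = 21)
  bt <- branchingTimes(tr)
  y2 <- fitDivModel(bt, "yule2rate")
  expect_lt(abs(y2@params[["st"]] - 0.01), 0.005)
  expect_gt(y2@params[["r1"]], y2@params[["r2"]])
})

test_that("yule2rate r1 recovery across replicates is within 20%", {
  r1hat <- vapply(1:40, function(s) {
    tr <- simTree(45, "yule2rate", rate = 30, r2 = 6, shiftAge = 0.01,
                  seed = 700 + s)
    fitDivModel(branchingTimes(tr), "yule2rate")@params[["r1"]]
  }, 0)
  expect_lt(abs(median(r1hat) - 30) / 30, 0.20)
})

test_that("the model table ranks by AIC with consistent deltas", {
  bt <- branchingTimes(simTree(30, "yule", rate = 10, seed = 13))
  tab <- modelSelectionTable(bt)
  expect_equal(nrow(tab), 5L)
  expect_true(!is.unsorted(tab$AIC))
  expect_equal(tab$dAIC, tab$AIC - min(tab$AIC))
  expect_equal(tab$AIC, 2 * tab$P - 2 * tab$LH, tolerance = 1e-9)
  expect_setequal(tab$model, c("pureBirth", "bd", "DDL", "DDX", "yule2rate"))
})

test_that("the delta-AIC null test honours its smoothing boundary", {
  set.seed(8)
  bt <- LineageDelim:::.simPureBirthBt(20, 10)
  one <- deltaAicNullTest(bt, nSims = 1, seed = 5)
  expect_true(one$p %in% c(0.5, 1))
  nt <- deltaAicNullTest(bt, nSims = 30, seed = 5)
  expect_length(nt$null, 30L)
  expect_gte(nt$p, 1 / 31)
  # determinism under the same seed
  nt2 <- deltaAicNullTest(bt, nSims = 30, seed = 5)
  expect_identical(nt$null, nt2$null)
})

test_that("truncation slices the recent history cleanly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:0.05,D:0.05):1.95);")
  # slicing at 5% of depth 2 (0.1) removes the young cherry: 3 tips remain
  tt <- truncateRecentHistory(tr, 0.05)
  expect_equal(length(tt$tip.label), 3L)
  expect_equal(attr(tt, "depth"), 1.9, tolerance = 1e-9)
  # a slice below every node keeps the tip count
  tt2 <- truncateRecentHistory(tr, 0.01)
  expect_equal(length(tt2$tip.label), 4L)
  expect_equal(attr(tt2, "depth"), 2 * 0.99, tolerance = 1e-9)
  expect_error(truncateRecentHistory(tr, 1.2), "fraction")
  # branching times shift by exactly the slice depth
  tr3 <- simTree(25, "yule", rate = 2, seed = 44)
  s <- 0.05 * attr(tr3, "depth")
  bt3 <- branchingTimes(tr3)
  tt3 <- truncateRecentHistory(tr3, 0.05)
  expect_equal(branchingTimes(tt3), bt3[bt3 > s] - s, tolerance = 1e-9)
})

test_that("a recent slowdown flips to rate-constancy after truncation", {
  # one seeded replicate of the truncation experiment
  tr <- simTree(45, "yule2rate", rate = 30, r2 = 6, shiftAge = 0.004,
                seed = 1003)
  tab1 <- modelSelectionTable(branchingTimes(tr))
  expect_equal(tab1$mtype[1], "RV")
  tab2 <- modelSelectionTable(branchingTimes(truncateRecentHistory(tr, 0.05)))
  expect_lte(tab2$dAIC[tab2$model == "pureBirth"], 2)
})
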