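test_that("the event table decomposes intervals and classes correctly", {
  tr <- handTree6()
  # null layout: one class, standard branching intervals
  et0 <- gmycEventTable(tr)
  expect_equal(nrow(et0), 5L)
  expect_equal(sum(et0$duration), 4, tolerance = 1e-9)
  expect_equal(et0$nDiv, 2:6)
  expect_true(all(et0$eventClass[1:4] == "diversification"))
  expect_true(is.na(et0$eventClass[5]))
  # threshold between the two levels: three cherry clusters
  et <- gmycEventTable(tr, thresholds = 1)
  ccols <- grep("^cluster", names(et))
  expect_equal(length(ccols), 3L)
  # above the threshold no coalescent lineages; below, nDiv is empty
  expect_equal(et$nDiv[et$duration > 0.9], c(2, 3))
  below <- which(rowSums(et[, ccols, drop = FALSE]) > 0)
  expect_true(all(et$nDiv[below] == 0))
  # counts increase by exactly one lineage at each branching event
  # (and stay flat across the threshold boundary)
  tot <- et$nDiv + rowSums(et[, ccols, drop = FALSE])
  expect_equal(diff(tot),
               ifelse(is.na(et$eventClass[-nrow(et)]), 0, 1))
  # durations sum to the depth
  expect_equal(sum(et$duration), 4, tolerance = 1e-9)
  expect_error(gmycEventTable(tr, thresholds = 99), "inside")
})

test_that("threshold just above the tips leaves every tip its own entity", {
  tr <- handTree6()
  et <- gmycEventTable(tr, thresholds = 0.05)   # below all cherries
  expect_equal(length(grep("^cluster", names(et))), 0L)
  expect_equal(et$nDiv[nrow(et)], 6)
})

test_that("gmycLoglik reduces to the Yule form in null mode", {
  tr <- handTree6()
  et <- gmycEventTable(tr)
  lam <- 0.7
  bt <- branchingTimes(tr)
  expect_equal(gmycLoglik(et, lambdaD = lam, pD = 1),
               generalizedYuleLoglik(bt, function(n, t) lam),
               tolerance = 1e-9)
})

test_that("gmycLoglik matches a term-by-term manual evaluation", {
  # 4-tip tree, threshold at 1: one cherry cluster (a1, a2), b and c single
  tr <- ape::read.tree(text = "(((a1:0.2,a2:0.2):2.8,b:3):1,c:4);")
  et <- gmycEventTable(tr, thresholds = 1)
  lamD <- 0.5; pD <- 1; lamC <- 3; pC <- 2
  # intervals (ages): [3,4] nDiv=2; [1,3] nDiv=3; [0.2,1] nDiv=2 + 1-lineage
  # cluster stem (no coalescent exposure); [0,0.2] nDiv=2, cluster=2
  manual <-
    -lamD * 2^pD * 1 + log(lamD * 2^pD) +         # wait + event at age 3
    -lamD * 3^pD * 2 +                            # ages 3 -> 1 (no event)
    -lamD * 2^pD * 0.8 +                          # 1 -> 0.2; stem inert
    log(lamC * 2^pC) +                            # cherry coalescence at 0.2
    -(lamD * 2^pD + lamC * 2^pC) * 0.2            # final interval
  expect_equal(gmycLoglik(et, lamD, pD, lamC, pC), manual, tolerance = 1e-9)
})

test_that("rescaling time and rates shifts lnL by the exact unit change", {
  tr <- simTree(12, "yule", rate = 2, seed = 31)
  et1 <- gmycEventTable(tr)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  et2 <- gmycEventTable(tr2)
  lam <- 1.3
  # with p = 1, halving lambda on a doubled tree subtracts ln(2) per event
  nEv <- sum(!is.na(et1$eventClass))
  expect_equal(gmycLoglik(et2, lam / 2, 1),
               gmycLoglik(et1, lam, 1) - nEv * log(2), tolerance = 1e-8)
})

test_that("fits are nested, partitions valid, and limits behave", {
  sim <- simSpeciesCoalescentTree(6, 4, 1, 20, seed = 77)
  f0 <- fitGmyc(sim$tree, "null")
  f1 <- fitGmyc(sim$tree, "single")
  f2 <- fitGmyc(sim$tree, "multiple")
  expect_lte(f0@logLik, f1@logLik + 1e-9)
  expect_lte(f1@logLik, f2@logLik + 1e-9)
  expect_equal(gmycNParams(f0), 2L)
  expect_gte(gmycNParams(f1), 5L)
  # entity partition is a valid partition over all tips
  p <- gmycPartition(f1)
  expect_setequal(names(blockAssignment(p)), sim$tree$tip.label)
  expect_gte(f1@nEntities, f1@nClusters)
  # null model groups everything into one entity
  expect_equal(fitGmyc(sim$tree, "null")@nEntities, 1L)
})

test_that("clear species structure is recovered with a significant LR test", {
  sim <- simSpeciesCoalescentTree(10, 5, 1, 20, seed = 811)
  f1 <- fitGmyc(sim$tree, "single")
  f0 <- fitGmyc(sim$tree, "null")
  expect_true(samePartition(gmycPartition(f1), sim$partition))
  expect_equal(f1@nEntities, 10L)
  expect_equal(f1@nClusters, 10L)
  lr <- lrTest(f1@logLik, f0@logLik, df = 3)
  expect_lt(lr$p, 0.05)
})

test_that("the effective diversification rate is recovered across replicates", {
  # trees simulated under the GMYC generative model with speciation rate 1;
  # the identifiable quantity is lambda_d * n^p_d at a reference count
  errs <- vapply(1:15, function(s) {
    sim <- simSpeciesCoalescentTree(20, 5, 1, 20, seed = 400 + s)
    pd <- fitGmyc(sim$tree, "single")@params$diversification
    abs(pd[["lambda"]] * 10^pd[["p"]] - 10) / 10
  }, 0)
  expect_lte(median(errs), 0.25)
})

test_that("the likelihood-ratio test follows the chi-square upper tail", {
  expect_equal(lrTest(5, 5, 3)$statistic, 0)
  expect_equal(lrTest(5, 5, 3)$p, 1)
  r <- lrTest(10, 6, 2)
  expect_equal(r$statistic, 8)
  expect_equal(r$p, pchisq(8, 2, lower.tail = FALSE))
  expect_error(lrTest(5, 6, 3), "below")
  expect_error(lrTest(5, 4, 0), "df")
})
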