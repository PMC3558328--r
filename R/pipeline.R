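# High-level entry points tying the stages together: the integrative
# delimitation run, the diversification test, and the niche-overlap report.
# Defaults encode the canonical settings: 3.2% K2P cutoff, ABGD with 50
# screening steps, SP at 95% connection probability, 500 null simulations,
# 5% truncation.

.DELIM_METHODS <- c("threshold", "abgd", "gmyc", "sp")

#' Run the integrative delimitation pipeline
#'
#' Applies the requested delimitation methods to one alignment (plus an
#' ultrametric tree for GMYC), joins them into the conservative consensus,
#' and — when morphospecies labels are supplied — cross-validates the
#' consensus against them.
#'
#' @param aln a [BarcodeAlignment-class]
#' @param tree rooted ultrametric `ape::phylo`; required iff `"gmyc"` is
#'   among `methods`.
#' @param methods subset of `c("threshold", "abgd", "gmyc", "sp")`.
#' @param labels optional named character vector of morphospecies labels.
#' @param threshold distance cutoff for the threshold method (default
#'   `0.032`).
#' @param abgd an [abgdConfig()]; the modal-prior partition is used.
#' @param spConfidence SP connection probability (default `0.95`).
#' @param gmycMode `"single"` or `"multiple"`.
#' @param outPath optional path: when given, the partition comparison TSV is
#'   written there via [writePartitionTable()].
#' @return list with `partitions` (named list of [LineagePartition-class]),
#'   `consensus`, `blockCounts`, `crossval` (or `NULL`) and `gmycFit` (when
#'   run).
#' @export
runDelimitation <- function(aln, tree = NULL,
                            methods = c("threshold", "abgd", "sp"),
                            labels = NULL, threshold = 0.032,
                            abgd = abgdConfig(), spConfidence = 0.95,
                            gmycMode = c("single", "multiple"),
                            outPath = NULL) {
  stopifnot(is(aln, "BarcodeAlignment"))
  gmycMode <- match.arg(gmycMode)
  bad <- setdiff(methods, .DELIM_METHODS)
  if (length(bad))
    stop("input error: unknown method(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(.DELIM_METHODS, collapse = ", "))
  if (length(methods) == 0L) stop("input error: no methods requested")
  if ("gmyc" %in% methods && is.null(tree))
    stop("input error: GMYC requested but no ultrametric tree supplied")
  partitions <- list()
  gmycFit <- NULL
  needDm <- any(c("threshold", "abgd") %in% methods)
  dm <- if (needDm) buildDistanceMatrix(aln, "K2P") else NULL
  for (m in methods) {
    partitions[[m]] <- switch(m,
      threshold = thresholdPartition(dm, threshold),
      abgd = {
        scan <- abgdPriorScan(dm, abgd)
        scan$partitions[[which(scan$blockCounts == scan$modalBlocks)[1L]]]
      },
      sp = spPartition(aln, confidence = spConfidence),
      gmyc = {
        gmycFit <- fitGmyc(tree, mode = gmycMode)
        part <- gmycPartition(gmycFit)
        ids <- specimenIds(aln)
        if (!setequal(names(blockAssignment(part)), ids))
          stop("input error: tree tips do not match alignment ids")
        part
      })
  }
  consensus <- joinPartitions(unname(partitions))
  crossval <- if (!is.null(labels))
    crossvalidateMorphospecies(consensus, labels) else NULL
  if (!is.null(outPath)) writePartitionTable(partitions, outPath)
  list(partitions = partitions, consensus = consensus,
       blockCounts = c(vapply(partitions, nBlocks, 0L),
                       consensus = nBlocks(consensus)),
       crossval = crossval, gmycFit = gmycFit)
}

#' Run the diversification-tempo analysis
#'
#' Fits the five diversification models to the tree's branching times, runs
#' the simulated delta-AIC rate-constancy test, and optionally repeats both
#' on the tree truncated by [truncateRecentHistory()].
#'
#' @param tree rooted ultrametric `ape::phylo`.
#' @param nSims null simulations for the delta-AIC test (default 500).
#' @param seed integer seed.
#' @param truncateFraction `NULL` (default) or a fraction in (0, 1) at which
#'   the truncated re-run is performed.
#' @return list with `table` (the model-selection data frame), `nullTest`
#'   (from [deltaAicNullTest()]), `ltt` (from [lttPoints()]) and `truncated`
#'   (same three fields on the truncated tree, or `NULL`).
#' @export
runDivTest <- function(tree, nSims = 500, seed = 1, truncateFraction = NULL) {
  bt <- branchingTimes(tree)
  out <- list(table = modelSelectionTable(bt),
              nullTest = deltaAicNullTest(bt, nSims = nSims, seed = seed),
              ltt = lttPoints(bt))
  if (!is.null(truncateFraction)) {
    ttree <- truncateRecentHistory(tree, truncateFraction)
    tbt <- branchingTimes(ttree)
    out$truncated <- list(table = modelSelectionTable(tbt),
                          nullTest = deltaAicNullTest(tbt, nSims = nSims,
                                                      seed = seed + 1L),
                          ltt = lttPoints(tbt))
  } else {
    out$truncated <- NULL
  }
  out
}

#' Niche-overlap report for two suitability grids
#'
#' @param g1,g2 numeric matrices (same shape) or file paths readable by
#'   [readSuitabilityGrid()].
#' @param ... passed to [nicheOverlapStats()].
#' @return list with `D`, `I`, `RR`, `breadth1`, `breadth2`.
#' @export
runNicheOverlap <- function(g1, g2, ...) {
  if (is.character(g1)) g1 <- readSuitabilityGrid(g1)
  if (is.character(g2)) g2 <- readSuitabilityGrid(g2)
  ov <- nicheOverlapStats(g1, g2, ...)
  c(ov, list(breadth1 = nicheBreadth(g1), breadth2 = nicheBreadth(g2)))
}
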