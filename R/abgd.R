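# Automatic barcode gap discovery: recursive partitioning at a detected gap
# between intra- and inter-group distance distributions, scanned over a
# geometric series of prior intraspecific divergences.

#' ABGD scan configuration
#'
#' @param pMin,pMax minimum and maximum prior intraspecific divergence,
#'   `0 < pMin <= pMax < 1`.
#' @param X minimum relative gap width (> 0).
#' @param steps number of priors in the geometric series (>= 1).
#' @param model distance model used when a matrix must be built.
#' @return list of class `abgdConfig`. Defaults mirror common barcoding
#'   practice: priors 0.001..0.1, X = 0.1, 50 screening steps, K2P distances.
#' @export
abgdConfig <- function(pMin = 0.001, pMax = 0.1, X = 0.1, steps = 50,
                       model = "K2P") {
  if (!(pMin > 0 && pMin <= pMax && pMax < 1))
    stop("input error: need 0 < pMin <= pMax < 1")
  if (X <= 0) stop("input error: X must be > 0")
  if (steps < 1) stop("input error: steps must be >= 1")
  structure(list(pMin = pMin, pMax = pMax, X = X, steps = as.integer(steps),
                 model = model), class = "abgdConfig")
}

#' Detect a barcode gap in a sorted distance vector
#'
#' Scans the ascending distances for the first significant gap beyond the
#' prior intraspecific divergence: the smallest index `i` such that
#' `d[i+1] > priorP` and `d[i+1] - d[i] > X * d[i]`. The proposed cutoff is
#' the gap midpoint `(d[i] + d[i+1]) / 2`.
#'
#' @param sortedDistances numeric vector sorted ascending (length >= 1).
#' @param priorP prior maximum intraspecific divergence.
#' @param X minimum relative gap width.
#' @return `NULL` when no gap is found, else list with `index` (lower edge),
#'   `lower`, `upper` and `cutoff`.
#' @examples
#' detectBarcodeGap(c(0.005, 0.008, 0.010, 0.060, 0.065), 0.02, 0.5)$cutoff
#' @export
detectBarcodeGap <- function(sortedDistances, priorP, X) {
  d <- sortedDistances
  if (length(d) < 1L) stop("input error: need at least one distance")
  if (is.unsorted(d)) stop("input error: distances must be sorted ascending")
  if (length(d) < 2L) return(NULL)
  i <- seq_len(length(d) - 1L)
  hit <- which(d[i + 1L] > priorP & (d[i + 1L] - d[i]) > X * d[i])
  if (length(hit) == 0L) return(NULL)
  k <- hit[1L]
  list(index = k, lower = d[k], upper = d[k + 1L],
       cutoff = (d[k] + d[k + 1L]) / 2)
}

#' ABGD partition at one prior
#'
#' Recursive barcode-gap partitioning: detect a gap in the current group's
#' pairwise distances; if found, split the group by single linkage at the gap
#' midpoint and recurse into each subgroup (reusing the distance sub-matrix);
#' stop when no gap is detected. Saturated (`Inf`) distances sort above every
#' finite distance and any gap.
#'
#' @param dm a [GeneticDistances-class]
#' @param priorP prior maximum intraspecific divergence.
#' @param X minimum relative gap width (default `0.1`).
#' @return a [LineagePartition-class]
#' @export
abgdPartition <- function(dm, priorP, X = 0.1) {
  stopifnot(is(dm, "GeneticDistances"))
  d <- dm@d
  dimnames(d) <- list(dm@ids, dm@ids)
  assign <- setNames(rep(NA_character_, length(dm@ids)), dm@ids)
  nextLab <- 1L
  recurse <- function(ids) {
    if (length(ids) <= 1L) {
      assign[ids] <<- as.character(nextLab); nextLab <<- nextLab + 1L
      return(invisible())
    }
    sub <- d[ids, ids, drop = FALSE]
    vals <- sort(sub[upper.tri(sub)])
    fin <- vals[is.finite(vals)]
    gap <- if (length(fin)) detectBarcodeGap(fin, priorP, X) else NULL
    # a saturated pair above an otherwise gap-free finite range is itself
    # a gap beyond any prior
    if (is.null(gap) && length(fin) && length(fin) < length(vals)) {
      gap <- list(cutoff = max(fin) + 1)
    }
    if (is.null(gap)) {
      assign[ids] <<- as.character(nextLab); nextLab <<- nextLab + 1L
      return(invisible())
    }
    part <- .linkagePartition(sub, ids, gap$cutoff)
    blocks <- partitionBlocks(part)
    if (length(blocks) == 1L) {  # chaining bridged the gap: no usable split
      assign[ids] <<- as.character(nextLab); nextLab <<- nextLab + 1L
      return(invisible())
    }
    for (b in blocks) recurse(b)
  }
  recurse(dm@ids)
  canonicalPartition(lineagePartition(assign))
}

#' Scan ABGD over a geometric series of priors
#'
#' Runs [abgdPartition()] at `steps` priors spaced geometrically from `pMin`
#' to `pMax` and summarises the stability of the block count across priors.
#'
#' @param dm a [GeneticDistances-class]
#' @param config an [abgdConfig()] list.
#' @return list with `priors`, `partitions` (one [LineagePartition-class] per
#'   prior), `blockCounts`, `modalBlocks` (the modal block count),
#'   `stability` (fraction of priors at the modal count) and `allAgree`.
#' @export
abgdPriorScan <- function(dm, config = abgdConfig()) {
  stopifnot(is(dm, "GeneticDistances"), inherits(config, "abgdConfig"))
  if (config$pMin == config$pMax && config$steps > 1L) {
    warning("degenerate prior series (pMin == pMax): single prior used")
    priors <- config$pMin
  } else if (config$steps == 1L) {
    priors <- config$pMin
  } else {
    priors <- exp(seq(log(config$pMin), log(config$pMax),
                      length.out = config$steps))
  }
  partitions <- lapply(priors, function(p) abgdPartition(dm, p, config$X))
  counts <- vapply(partitions, nBlocks, 0L)
  tab <- table(counts)
  modal <- as.integer(names(tab)[which.max(tab)])
  list(priors = priors, partitions = partitions, blockCounts = counts,
       modalBlocks = modal, stability = max(tab) / length(counts),
       allAgree = length(unique(counts)) == 1L)
}
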