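# Accessors and show methods for the S4 containers.

#' @describeIn BarcodeAlignment-class specimen identifiers
#' @param x a `BarcodeAlignment`
#' @export
specimenIds <- function(x) {
  stopifnot(is(x, "BarcodeAlignment"))
  x@ids
}

#' @describeIn BarcodeAlignment-class aligned sequences, named by specimen id
#' @export
alignedSeqs <- function(x) {
  stopifnot(is(x, "BarcodeAlignment"))
  setNames(x@seqs, x@ids)
}

#' @describeIn BarcodeAlignment-class number of aligned sites
#' @export
alignmentLength <- function(x) {
  stopifnot(is(x, "BarcodeAlignment"))
  nchar(x@seqs[1L])
}

#' Build a BarcodeAlignment from id and sequence vectors
#'
#' Sequences are normalised to uppercase and RNA `U` is mapped to `T`.
#'
#' @param ids character vector of unique specimen identifiers.
#' @param seqs character vector of equal-length sequences.
#' @return a [BarcodeAlignment-class]
#' @export
barcodeAlignment <- function(ids, seqs) {
  seqs <- chartr("u", "U", toupper(as.character(seqs)))
  seqs <- chartr("U", "T", seqs)
  new("BarcodeAlignment", ids = as.character(ids), seqs = seqs)
}

# internal: alignment as a character matrix (rows = specimens)
charMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln@seqs, "", fixed = TRUE))
  rownames(m) <- aln@ids
  m
}

setMethod("show", "BarcodeAlignment", function(object) {
  cat(sprintf("BarcodeAlignment: %d specimens x %d sites\n",
              length(object@ids), alignmentLength(object)))
  cat("  ids: ", paste(head(object@ids, 5L), collapse = ", "),
      if (length(object@ids) > 5L) ", ..." else "", "\n", sep = "")
})

#' @describeIn GeneticDistances-class the symmetric distance matrix
#' @param x a `GeneticDistances`
#' @export
distanceMatrix <- function(x) {
  stopifnot(is(x, "GeneticDistances"))
  m <- x@d
  dimnames(m) <- list(x@ids, x@ids)
  m
}

#' @describeIn GeneticDistances-class the substitution model tag
#' @export
distanceModel <- function(x) {
  stopifnot(is(x, "GeneticDistances"))
  x@model
}

#' @describeIn GeneticDistances-class per-pair effective site counts
#' @export
effectiveSites <- function(x) {
  stopifnot(is(x, "GeneticDistances"))
  m <- x@sites
  dimnames(m) <- list(x@ids, x@ids)
  m
}

setMethod("show", "GeneticDistances", function(object) {
  up <- object@d[upper.tri(object@d)]
  cat(sprintf("GeneticDistances (%s): %d specimens\n",
              object@model, length(object@ids)))
  if (length(up))
    cat(sprintf("  range %.4g .. %.4g; %d saturated pair(s)\n",
                min(up), max(up[is.finite(up)]), sum(!is.finite(up))))
})

#' Construct a LineagePartition
#'
#' @param assignment named character (or factor/integer coercible) vector
#'   mapping specimen id to block label.
#' @return a [LineagePartition-class]
#' @export
lineagePartition <- function(assignment) {
  a <- setNames(as.character(assignment), names(assignment))
  new("LineagePartition", assignment = a)
}

#' Blocks of a partition
#'
#' @param x a [LineagePartition-class]
#' @return list of character vectors of specimen ids, one per block, in order
#'   of first appearance.
#' @export
partitionBlocks <- function(x) {
  stopifnot(is(x, "LineagePartition"))
  a <- x@assignment
  split(names(a), factor(a, levels = unique(a)))
}

#' @describeIn partitionBlocks number of blocks
#' @export
nBlocks <- function(x) {
  stopifnot(is(x, "LineagePartition"))
  length(unique(x@assignment))
}

#' @describeIn partitionBlocks the id -> block label vector
#' @export
blockAssignment <- function(x) {
  stopifnot(is(x, "LineagePartition"))
  x@assignment
}

#' Relabel partition blocks by their smallest member id
#'
#' Gives a deterministic canonical labelling: each block is named after its
#' first member in the partition's specimen order.
#'
#' @param x a [LineagePartition-class]
#' @export
canonicalPartition <- function(x) {
  stopifnot(is(x, "LineagePartition"))
  a <- x@assignment
  first <- tapply(names(a), a, function(v) v[1L])
  lineagePartition(setNames(unname(first[a]), names(a)))
}

#' Do two partitions group specimens identically?
#'
#' Block labels are ignored; only co-membership matters.
#'
#' @param x,y [LineagePartition-class] objects over the same specimen set.
#' @export
samePartition <- function(x, y) {
  ax <- blockAssignment(canonicalPartition(x))
  ay <- blockAssignment(canonicalPartition(y))
  if (!setequal(names(ax), names(ay))) return(FALSE)
  identical(ax[sort(names(ax))], ay[sort(names(ay))])
}

setMethod("show", "LineagePartition", function(object) {
  b <- partitionBlocks(object)
  cat(sprintf("LineagePartition: %d specimens in %d block(s)\n",
              length(object@assignment), length(b)))
  sizes <- lengths(b)
  cat("  block sizes: ", paste(head(sizes, 12L), collapse = " "),
      if (length(sizes) > 12L) " ..." else "", "\n", sep = "")
})

setMethod("show", "GmycFit", function(object) {
  cat(sprintf("GmycFit (%s): lnL = %.4f, %d entities (%d clusters)\n",
              object@mode, object@logLik, object@nEntities, object@nClusters))
  if (length(object@thresholds))
    cat("  threshold age(s): ",
        paste(signif(object@thresholds, 5), collapse = ", "), "\n", sep = "")
  if (!object@converged) cat("  WARNING: optimiser did not converge\n")
})

setMethod("show", "DivModelFit", function(object) {
  cat(sprintf("DivModelFit %s [%s]: lnL = %.4f, P = %d, AIC = %.4f\n",
              object@model, object@modelClass, object@logLik,
              object@nParams, object@aic))
  p <- object@params
  cat("  ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "),
      "\n", sep = "")
})
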