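# Fixed-threshold DNA-barcoding delimitation: specimens closer than a cutoff
# fall into one evolutionary lineage.

# internal: connected components of the graph with edges d <= cutoff,
# via single-linkage agglomeration (chaining == transitive closure).
.linkagePartition <- function(d, ids, cutoff, linkage = "single") {
  n <- length(ids)
  if (n == 1L) return(lineagePartition(setNames(ids, ids)))
  dd <- d
  dimnames(dd) <- list(ids, ids)
  # saturated pairs sit above any threshold; keep hclust finite
  big <- 2 * (max(dd[is.finite(dd)], 1) + cutoff + 1)
  dd[!is.finite(dd)] <- big
  h <- hclust(as.dist(dd), method = if (linkage == "single") "single"
                                    else "complete")
  grp <- cutree(h, h = cutoff)
  lineagePartition(setNames(as.character(grp[ids]), ids))
}

#' Threshold delimitation of evolutionary lineages
#'
#' Partitions specimens into the connected components of the graph with an
#' edge between two specimens iff their genetic distance is at most
#' `threshold` (single linkage, i.e. transitive closure: the classic
#' barcoding "cluster at threshold" rule). The default cutoff is the 3.2%
#' K2P threshold established for carychiid barcodes.
#'
#' @param dm a [GeneticDistances-class]
#' @param threshold positive distance cutoff (default `0.032`).
#' @param linkage `"single"` (default, chaining) or `"complete"`.
#' @return a [LineagePartition-class] with canonical block labels.
#' @examples
#' aln <- barcodeAlignment(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAT"))
#' thresholdPartition(buildDistanceMatrix(aln), 0.2)
#' @export
thresholdPartition <- function(dm, threshold = 0.032,
                               linkage = c("single", "complete")) {
  stopifnot(is(dm, "GeneticDistances"))
  linkage <- match.arg(linkage)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("input error: threshold must be a single positive number")
  canonicalPartition(.linkagePartition(dm@d, dm@ids, threshold, linkage))
}
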