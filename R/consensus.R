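# Conservative consensus over delimitation methods (partition-lattice join)
# and cross-validation of the consensus against morphospecies hypotheses.

#' Join partitions: the most comprehensive grouping predicted by any method
#'
#' Two specimens share a consensus block iff they are connected by a chain of
#' co-membership edges drawn from any input partition — the join in the
#' partition lattice, computed by union-find. This is the conservative
#' consensus rule: merge whenever any method merges, deliberately risking
#' taxonomic lumping rather than oversplitting. The operation is commutative,
#' associative and idempotent.
#'
#' @param partitions non-empty list of [LineagePartition-class] objects over
#'   the same specimen set.
#' @return a [LineagePartition-class] with canonical block labels.
#' @examples
#' p1 <- lineagePartition(c(a = "x", b = "x", c = "y"))
#' p2 <- lineagePartition(c(a = "u", b = "v", c = "v"))
#' nBlocks(joinPartitions(list(p1, p2)))  # 1
#' @export
joinPartitions <- function(partitions) {
  if (!is.list(partitions) || length(partitions) == 0L)
    stop("input error: empty partition list")
  ids <- names(blockAssignment(partitions[[1L]]))
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (p in partitions) {
    stopifnot(is(p, "LineagePartition"))
    a <- blockAssignment(p)
    if (!setequal(names(a), ids))
      stop("input error: partitions cover different specimen sets")
    for (blk in split(match(names(a), ids), a)) {
      r <- find(blk[1L])
      for (i in blk[-1L]) parent[find(i)] <- r
    }
  }
  roots <- vapply(seq_along(ids), find, 0L)
  canonicalPartition(lineagePartition(setNames(as.character(roots), ids)))
}

#' Cross-validate a consensus delimitation against morphospecies labels
#'
#' Classifies each morphospecies hypothesis against the evolutionary lineages
#' (ELs) of the consensus partition:
#' \describe{
#'   \item{match}{occupies exactly one EL, and that EL contains no other
#'     morphospecies;}
#'   \item{split}{occupies two or more ELs, none of which is shared with
#'     another morphospecies (molecular data subdivide the morphospecies);}
#'   \item{lumped}{occupies a single EL that also contains another
#'     morphospecies (molecular data cannot separate them);}
#'   \item{mixed}{both: several ELs, at least one shared.}
#' }
#' ELs "unrecognized by morphology" counts, within every split or mixed
#' morphospecies, all occupied ELs beyond the first.
#'
#' @param consensus a [LineagePartition-class]
#' @param labels named character vector, specimen id -> morphospecies name,
#'   covering every specimen of `consensus`.
#' @return list with `status` (named character per morphospecies), `counts`
#'   (matches / split / lumped / mixed), `splitInto` (per split morphospecies,
#'   how many ELs), `unrecognizedEls`, `lumpedEls` (ELs holding > 1
#'   morphospecies) and `contingency` (EL x morphospecies specimen counts).
#' @export
crossvalidateMorphospecies <- function(consensus, labels) {
  stopifnot(is(consensus, "LineagePartition"))
  a <- blockAssignment(consensus)
  miss <- setdiff(names(a), names(labels))
  if (length(miss))
    stop("input error: unlabeled specimen(s): ", paste(miss, collapse = ", "))
  labels <- labels[names(a)]
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("input error: empty morphospecies name")
  cont <- table(EL = a, morphospecies = labels)
  elsOf <- lapply(split(a, labels), unique)          # morphospecies -> ELs
  spOf <- lapply(split(labels, a), unique)           # EL -> morphospecies
  status <- vapply(names(elsOf), function(m) {
    els <- elsOf[[m]]
    shared <- any(vapply(els, function(e) length(spOf[[e]]) > 1L, NA))
    if (length(els) == 1L) {
      if (shared) "lumped" else "match"
    } else {
      if (shared) "mixed" else "split"
    }
  }, "")
  splitInto <- vapply(names(status)[status %in% c("split", "mixed")],
                      function(m) length(elsOf[[m]]), 0L)
  counts <- c(matches = sum(status == "match"),
              split = sum(status == "split"),
              lumped = sum(status == "lumped"),
              mixed = sum(status == "mixed"))
  list(status = status, counts = counts, splitInto = splitInto,
       unrecognizedEls = sum(pmax(splitInto - 1L, 0L)),
       lumpedEls = names(spOf)[vapply(spOf, length, 0L) > 1L],
       contingency = cont)
}
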