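# Reading and writing the standard formats the pipeline touches:
# FASTA alignments, Newick ultrametric trees, TSV partition/label tables.

#' Read an aligned FASTA file
#'
#' Parses a FASTA file of aligned nucleotide sequences into a
#' [BarcodeAlignment-class]. Lowercase is normalised to uppercase and RNA `U`
#' to `T`; gaps (`-`), missing data (`N`) and IUPAC ambiguity codes are kept
#' verbatim.
#'
#' @param path path to a FASTA file.
#' @return a [BarcodeAlignment-class]
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' aln <- readFastaAlignment(f)
#' alignmentLength(aln)
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE),
    error = function(e) stop("input error: empty or malformed FASTA file"))
  if (length(recs) == 0L) stop("input error: empty FASTA file")
  ids <- names(recs)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("input error: duplicate ids: ", paste(dup, collapse = ", "))
  }
  seqs <- vapply(recs, function(s) as.character(s)[1L], "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  barcodeAlignment(ids, seqs)
}

#' Write a BarcodeAlignment as FASTA
#'
#' @param aln a [BarcodeAlignment-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaAlignment <- function(aln, path) {
  stopifnot(is(aln, "BarcodeAlignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", aln@ids, "\n", aln@seqs), con, sep = "\n")
  invisible(path)
}

#' Tip ages and depth of a rooted tree with branch lengths
#'
#' @param tree an `ape::phylo`.
#' @return list with `tipDepths` (root-to-tip path lengths, named) and
#'   `nodeDepths` (for all nodes).
#' @keywords internal
nodeTimes <- function(tree) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  list(tipDepths = setNames(depths[seq_len(n)], tree$tip.label),
       nodeDepths = depths)
}

#' Check a tree for ultrametricity
#'
#' A rooted tree is accepted as ultrametric when the spread of root-to-tip
#' path lengths does not exceed `tolerance` times the depth.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param tolerance relative tolerance on tip-age spread (default `1e-6`).
#' @param strict if `TRUE` (default) a violation is an error; if `FALSE` it is
#'   a warning and the tree is returned anyway.
#' @return the tree, with attribute `"depth"` set to the mean root-to-tip
#'   distance.
#' @export
validateUltrametric <- function(tree, tolerance = 1e-6, strict = TRUE) {
  if (is.null(tree$edge.length))
    stop("input error: tree has no branch lengths")
  if (length(tree$tip.label) < 2L)
    stop("input error: tree must have at least 2 tips")
  td <- nodeTimes(tree)$tipDepths
  depth <- mean(td)
  dev <- max(abs(td - depth))
  if (dev > tolerance * depth) {
    msg <- sprintf(
      "tree is not ultrametric: max tip-depth deviation %.3g (tolerance %.3g)",
      dev, tolerance * depth)
    if (strict) stop("validation error: ", msg) else warning(msg)
  }
  attr(tree, "depth") <- depth
  tree
}

#' Read a rooted ultrametric tree from a Newick file
#'
#' @param path path to a Newick file (first tree is used).
#' @param tolerance relative ultrametricity tolerance (default `1e-6`).
#' @param strict error (default) or merely warn on non-ultrametric input.
#' @return an `ape::phylo` with attribute `"depth"`.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", f)
#' tr <- readNewickUltrametric(f)
#' attr(tr, "depth")
#' @export
readNewickUltrametric <- function(path, tolerance = 1e-6, strict = TRUE) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree)) stop("input error: no tree in file")
  validateUltrametric(tree, tolerance = tolerance, strict = strict)
}

#' Write a multi-method partition comparison table
#'
#' One row per specimen, one column per method, plus a `consensus` column
#' holding the lattice join of all methods ([joinPartitions()]). Rows follow
#' the specimen order of the first partition; block labels are canonical
#' (smallest member id, see [canonicalPartition()]).
#'
#' @param partitions non-empty named list of [LineagePartition-class] objects
#'   over the same specimen set.
#' @param path output TSV path.
#' @return the written data frame, invisibly.
#' @export
writePartitionTable <- function(partitions, path) {
  if (!is.list(partitions) || length(partitions) == 0L)
    stop("input error: empty partition list")
  if (is.null(names(partitions)) || any(!nzchar(names(partitions))))
    names(partitions) <- paste0("method", seq_along(partitions))
  ids <- names(blockAssignment(partitions[[1L]]))
  for (p in partitions)
    if (!setequal(names(blockAssignment(p)), ids))
      stop("input error: partitions cover different specimen sets")
  cols <- lapply(partitions, function(p)
    unname(blockAssignment(canonicalPartition(p))[ids]))
  cons <- joinPartitions(unname(partitions))
  tab <- data.frame(specimen = ids, cols,
                    consensus = unname(blockAssignment(
                      canonicalPartition(cons))[ids]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("specimen", names(partitions), "consensus")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read back a partition table written by [writePartitionTable()]
#'
#' @param path TSV path.
#' @return named list of [LineagePartition-class] objects (one per column,
#'   including `consensus`).
#' @export
readPartitionTable <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"specimen" %in% names(tab)) stop("input error: no 'specimen' column")
  cols <- setdiff(names(tab), "specimen")
  lapply(setNames(cols, cols), function(cn)
    lineagePartition(setNames(tab[[cn]], tab$specimen)))
}

#' Read specimen -> morphospecies labels from a two-column TSV
#'
#' The file must have a header with columns `specimen` and `morphospecies`.
#'
#' @param path TSV path.
#' @return named character vector, specimen id -> morphospecies name.
#' @export
readMorphospeciesLabels <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("specimen", "morphospecies")
  if (!all(need %in% names(tab)))
    stop("input error: columns 'specimen' and 'morphospecies' required")
  if (anyDuplicated(tab$specimen))
    stop("input error: duplicate specimen ids")
  if (any(!nzchar(tab$morphospecies)))
    stop("input error: empty morphospecies name")
  setNames(tab$morphospecies, tab$specimen)
}
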