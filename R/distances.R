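# Pairwise genetic distances: Kimura two-parameter with pairwise deletion,
# plain Hamming distances for haplotype networks, and haplotype collapsing.

# Purines A/G are transition partners, as are pyrimidines C/T. Any character
# outside ACGT (gap, N, other IUPAC ambiguity) is treated as missing and the
# site is excluded for that pair (pairwise deletion).
.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P distance with pairwise deletion. Sites where either
#' sequence carries a gap, `N` or any non-ACGT character are excluded; over
#' the remaining `nSites`, `P` is the proportion of transitions (A<->G,
#' C<->T) and `Q` the proportion of transversions, and
#' \deqn{d = -\tfrac12 \ln\big[(1-2P-Q)\sqrt{1-2Q}\big].}
#' When the log argument is non-positive the pair is saturated and `d` is
#' returned as `Inf` with `saturated = TRUE`.
#'
#' @param seqA,seqB equal-length character strings (or character vectors of
#'   single characters).
#' @return list with `d`, `P`, `Q`, `nSites`, `saturated`.
#' @examples
#' k2pDistance(strrep("A", 100), paste0(strrep("A", 90), strrep("G", 10)))$d
#' @export
k2pDistance <- function(seqA, seqB) {
  a <- if (length(seqA) == 1L) strsplit(toupper(seqA), "")[[1L]] else toupper(seqA)
  b <- if (length(seqB) == 1L) strsplit(toupper(seqB), "")[[1L]] else toupper(seqB)
  if (length(a) != length(b))
    stop("input error: sequences have unequal lengths")
  .k2pPair(a, b)
}

# internal vector-based worker
.k2pPair <- function(a, b) {
  ok <- a %in% c(.PURINES, .PYRIMIDINES) & b %in% c(.PURINES, .PYRIMIDINES)
  n <- sum(ok)
  if (n == 0L)
    stop("undefined-distance error: no comparable sites for this pair")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & ((a %in% .PURINES & b %in% .PURINES) |
                (a %in% .PYRIMIDINES & b %in% .PYRIMIDINES))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(list(d = Inf, P = P, Q = Q, nSites = n, saturated = TRUE))
  list(d = -0.5 * log(arg1 * sqrt(arg2)), P = P, Q = Q, nSites = n,
       saturated = FALSE)
}

#' Build a pairwise distance matrix from an alignment
#'
#' All specimen pairs are computed with pairwise deletion; the result is
#' symmetric by construction. For `model = "K2P"` saturated pairs are stored
#' as `Inf` (they sort above any threshold in clustering); for
#' `model = "HAMMING"` the distance is the count of differing sites among the
#' pairwise-complete ACGT sites.
#'
#' @param aln a [BarcodeAlignment-class] with at least two sequences.
#' @param model `"K2P"` (default) or `"HAMMING"`.
#' @return a [GeneticDistances-class]
#' @export
buildDistanceMatrix <- function(aln, model = c("K2P", "HAMMING")) {
  stopifnot(is(aln, "BarcodeAlignment"))
  model <- match.arg(model)
  n <- length(aln@ids)
  if (n < 2L) stop("input error: need at least 2 sequences")
  m <- charMatrix(aln)
  valid <- m %in% c(.PURINES, .PYRIMIDINES)
  dim(valid) <- dim(m)
  d <- matrix(0, n, n)
  sites <- matrix(0L, n, n)
  diag(sites) <- as.integer(rowSums(valid))
  undef <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    ns <- sum(ok)
    if (ns == 0L) {
      undef <- c(undef, paste(aln@ids[i], aln@ids[j], sep = "/"))
      next
    }
    if (model == "HAMMING") {
      dij <- sum(m[i, ok] != m[j, ok])
    } else {
      dij <- .k2pPair(m[i, ok], m[j, ok])$d
    }
    d[i, j] <- d[j, i] <- dij
    sites[i, j] <- sites[j, i] <- ns
  }
  if (length(undef))
    stop("undefined-distance error: no comparable sites for pair(s): ",
         paste(undef, collapse = ", "))
  new("GeneticDistances", ids = aln@ids, d = d, sites = sites, model = model)
}

#' Collapse identical sequences into haplotypes
#'
#' Sequences are merged only when their full aligned strings are exactly
#' equal; sequences differing only by missing data are kept apart (a
#' conservative rule that avoids chaining haplotypes through `N` runs).
#'
#' @param aln a [BarcodeAlignment-class]
#' @return list with `haplotypes` (a [BarcodeAlignment-class] of the distinct
#'   sequences, ids `H1`, `H2`, ... in order of first appearance) and
#'   `members` (named list, haplotype id -> character vector of specimen ids).
#' @export
collapseHaplotypes <- function(aln) {
  stopifnot(is(aln, "BarcodeAlignment"))
  key <- factor(aln@seqs, levels = unique(aln@seqs))
  hapIds <- paste0("H", seq_len(nlevels(key)))
  members <- setNames(split(aln@ids, key), hapIds)
  hap <- barcodeAlignment(hapIds, levels(key))
  list(haplotypes = hap, members = members)
}

#' Export a distance matrix in square PHYLIP format
#'
#' @param dm a [GeneticDistances-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhylipDistances <- function(dm, path) {
  stopifnot(is(dm, "GeneticDistances"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm@ids)), con)
  for (i in seq_along(dm@ids))
    writeLines(paste(c(formatC(dm@ids[i], width = -10),
                       sprintf("%.6f", dm@d[i, ])), collapse = " "), con)
  invisible(path)
}
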