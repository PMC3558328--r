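# Statistical-parsimony delimitation: haplotypes are connected while the
# mutational distance stays within the limit at which a parsimonious
# (non-homoplastic) connection retains at least the requested probability;
# connected components of the resulting network are the entities.

#' Probability of parsimony for j mutational steps
#'
#' Under an equal-rate model with mutations falling independently and
#' uniformly on `seqLength` sites, a connection of `j` observed differences is
#' parsimonious when the `j` underlying mutations hit `j` distinct sites (no
#' superimposed or parallel change). That probability is
#' \deqn{P(j) = \prod_{i=1}^{j-1}\Big(1 - \frac{i}{L}\Big),}
#' with `P(1) = 1`: a single-step connection is always parsimonious.
#'
#' @param j number of mutational steps (vectorised).
#' @param seqLength number of sites L (>= 1).
#' @return numeric vector of probabilities.
#' @export
parsimonyProbability <- function(j, seqLength) {
  if (seqLength < 1) stop("input error: seqLength must be >= 1")
  vapply(j, function(jj) {
    if (jj < 1) return(1)
    if (jj > seqLength) return(0)
    prod(1 - seq_len(jj - 1L) / seqLength)
  }, 0)
}

#' Connection limit at a given statistical confidence
#'
#' The largest number of mutational steps `jMax` for which the probability of
#' parsimony [parsimonyProbability()] still meets `confidence`. The audit
#' table `probTable` lists `P(1..jMax+1)`.
#'
#' @param seqLength number of aligned sites.
#' @param confidence connection probability in (0, 1); default `0.95`.
#' @return list with `jMax` and `probTable` (data frame `j`, `Pj`).
#' @examples
#' parsimonyConnectionLimit(607)$jMax
#' @export
parsimonyConnectionLimit <- function(seqLength, confidence = 0.95) {
  if (seqLength < 1) stop("input error: seqLength must be >= 1")
  if (!(confidence > 0 && confidence < 1))
    stop("input error: confidence must be in (0, 1)")
  jMax <- 1L
  while (jMax < seqLength &&
         parsimonyProbability(jMax + 1L, seqLength) >= confidence)
    jMax <- jMax + 1L
  js <- seq_len(min(jMax + 1L, seqLength))
  list(jMax = jMax,
       probTable = data.frame(j = js, Pj = parsimonyProbability(js, seqLength)))
}

#' Statistical-parsimony delimitation
#'
#' Collapses the alignment to haplotypes, computes Hamming distances between
#' haplotypes (gaps and ambiguity codes treated as missing), connects
#' haplotype pairs in increasing-distance order while the distance does not
#' exceed the connection limit, and returns the connected components expanded
#' back to specimens. Only component membership is computed; intermediate
#' (unsampled) haplotypes are not reconstructed, because delimitation needs
#' connectivity only.
#'
#' @param aln a [BarcodeAlignment-class]
#' @param confidence connection probability (default `0.95`).
#' @param jMax override the connection limit directly (mainly for limit-case
#'   analyses); `Inf` connects everything, `0` returns the haplotype-identity
#'   partition.
#' @return a [LineagePartition-class]; attributes `jMax` and `probTable`
#'   carry the connection-limit audit trail.
#' @export
spPartition <- function(aln, confidence = 0.95, jMax = NULL) {
  stopifnot(is(aln, "BarcodeAlignment"))
  hap <- collapseHaplotypes(aln)
  lim <- NULL
  if (is.null(jMax)) {
    lim <- parsimonyConnectionLimit(alignmentLength(aln), confidence)
    jMax <- lim$jMax
  }
  hapAln <- hap$haplotypes
  nh <- length(hapAln@ids)
  if (nh == 1L) {
    grp <- setNames("1", hapAln@ids)
  } else {
    hd <- buildDistanceMatrix(hapAln, model = "HAMMING")
    if (is.infinite(jMax)) {
      grp <- setNames(rep("1", nh), hapAln@ids)
    } else {
      # components of the <= jMax edge graph == single linkage at jMax + 0.5
      grp <- blockAssignment(.linkagePartition(hd@d, hd@ids, jMax + 0.5))
    }
  }
  assign <- setNames(rep(NA_character_, length(aln@ids)), aln@ids)
  for (h in names(hap$members)) assign[hap$members[[h]]] <- grp[[h]]
  out <- canonicalPartition(lineagePartition(assign))
  attr(out, "jMax") <- jMax
  if (!is.null(lim)) attr(out, "probTable") <- lim$probTable
  out
}
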