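#' @import methods
#' @importFrom stats optim optimize pchisq setNames hclust cutree as.dist
#'   rexp runif median quantile
#' @importFrom utils read.delim write.table head tail
NULL

#' Aligned DNA barcode sequences
#'
#' Container for an aligned set of uppercase IUPAC nucleotide sequences with
#' unique specimen identifiers. The gap character is `-` and fully missing
#' sites are `N`; other ambiguity codes are kept verbatim but treated as
#' missing when distances are computed.
#'
#' @slot ids character vector of unique specimen identifiers.
#' @slot seqs character vector of equal-length uppercase sequences, parallel
#'   to `ids`.
#'
#' @seealso [readFastaAlignment()], [buildDistanceMatrix()]
#' @export
setClass("BarcodeAlignment",
  representation(ids = "character", seqs = "character"))

setValidity("BarcodeAlignment", function(object) {
  if (length(object@ids) == 0L)
    return("alignment must contain at least one sequence")
  if (length(object@ids) != length(object@seqs))
    return("ids and seqs differ in length")
  if (anyDuplicated(object@ids))
    return("duplicate specimen ids")
  if (any(!nzchar(object@ids)) || anyNA(object@ids))
    return("empty or missing specimen id")
  len <- unique(nchar(object@seqs))
  if (length(len) != 1L)
    return("sequences are not all the same length")
  if (len == 0L)
    return("alignment length must be > 0")
  TRUE
})

#' Pairwise genetic distances
#'
#' Symmetric matrix of pairwise distances between specimens, together with the
#' substitution model used (`"K2P"` or `"HAMMING"`) and the per-pair count of
#' comparable (non-missing) sites after pairwise deletion. Saturated K2P pairs
#' (where the distance is undefined because the log argument is non-positive)
#' are stored as `Inf` and behave as "above any threshold" in clustering.
#'
#' @slot ids character vector of specimen identifiers (row/column order).
#' @slot d numeric distance matrix; diagonal 0, symmetric, non-negative.
#' @slot sites integer-valued matrix of per-pair effective site counts.
#' @slot model `"K2P"` or `"HAMMING"`.
#' @export
setClass("GeneticDistances",
  representation(ids = "character", d = "matrix", sites = "matrix",
                 model = "character"))

setValidity("GeneticDistances", function(object) {
  n <- length(object@ids)
  if (!identical(dim(object@d), c(n, n)))
    return("distance matrix dimensions do not match ids")
  if (!identical(dim(object@sites), c(n, n)))
    return("site-count matrix dimensions do not match ids")
  if (!object@model %in% c("K2P", "HAMMING"))
    return("model must be K2P or HAMMING")
  if (any(abs(diag(object@d)) > 0))
    return("diagonal must be zero")
  if (!isTRUE(all.equal(object@d, t(object@d), tolerance = 0)))
    return("distance matrix must be exactly symmetric")
  fin <- object@d[is.finite(object@d)]
  if (any(fin < 0))
    return("distances must be non-negative")
  TRUE
})

#' An assignment of specimens to evolutionary lineages
#'
#' The common currency of all delimitation methods: a partition of the
#' specimen set into disjoint, exhaustive blocks ("evolutionary lineages").
#' Stored as a named character vector mapping specimen id to block label.
#'
#' @slot assignment named character vector, specimen id -> block label.
#' @seealso [partitionBlocks()], [joinPartitions()]
#' @export
setClass("LineagePartition",
  representation(assignment = "character"))

setValidity("LineagePartition", function(object) {
  a <- object@assignment
  if (length(a) == 0L) return("partition covers no specimens")
  if (is.null(names(a)) || any(!nzchar(names(a))) || anyDuplicated(names(a)))
    return("assignment must carry unique non-empty specimen ids as names")
  if (anyNA(a) || any(!nzchar(a)))
    return("every specimen must carry a non-empty block label")
  TRUE
})

#' A fitted generalized mixed Yule-coalescent model
#'
#' @slot mode one of `"null"`, `"single"`, `"multiple"`.
#' @slot thresholds numeric vector of threshold times (ages before present);
#'   empty for the null model.
#' @slot logLik maximised log-likelihood.
#' @slot params list of per-class parameter pairs; element `"diversification"`
#'   holds `c(lambda=, p=)` for the between-species (Yule) class, elements
#'   `"coalescent1"`, `"coalescent2"`, ... one per threshold.
#' @slot partition [LineagePartition-class] of tips into ML entities.
#' @slot nEntities number of ML entities (clusters plus unclustered tips).
#' @slot nClusters number of ML clusters (entities with >= 2 tips).
#' @slot converged logical; `FALSE` flags an optimiser failure.
#' @export
setClass("GmycFit",
  representation(mode = "character", thresholds = "numeric",
                 logLik = "numeric", params = "list",
                 partition = "LineagePartition",
                 nEntities = "integer", nClusters = "integer",
                 converged = "logical"))

setValidity("GmycFit", function(object) {
  if (!object@mode %in% c("null", "single", "multiple"))
    return("mode must be null, single or multiple")
  if (!is.finite(object@logLik)) return("log-likelihood must be finite")
  if (object@nEntities < object@nClusters)
    return("entities must be >= clusters")
  TRUE
})

#' A fitted diversification-rate model
#'
#' Holds one row of a model-selection table: model name, its class
#' (rate-constant `"RC"` or rate-variable `"RV"`), the fitted parameters,
#' the log-likelihood, the free-parameter count and the AIC.
#'
#' Parameters follow the usual naming: `r1`, `r2` net diversification rates,
#' `a` extinction fraction d/b, `xp` density exponent, `k` carrying capacity,
#' `st` shift time (age before present).
#'
#' @slot model one of `"pureBirth"`, `"bd"`, `"DDL"`, `"DDX"`, `"yule2rate"`.
#' @slot modelClass `"RC"` or `"RV"`.
#' @slot params named numeric vector of fitted parameters.
#' @slot logLik maximised log-likelihood.
#' @slot nParams free-parameter count P.
#' @slot aic 2*P - 2*logLik.
#' @slot converged logical.
#' @export
setClass("DivModelFit",
  representation(model = "character", modelClass = "character",
                 params = "numeric", logLik = "numeric",
                 nParams = "integer", aic = "numeric",
                 converged = "logical"))

setValidity("DivModelFit", function(object) {
  if (!object@model %in% c("pureBirth", "bd", "DDL", "DDX", "yule2rate"))
    return("unknown model name")
  if (!object@modelClass %in% c("RC", "RV"))
    return("modelClass must be RC or RV")
  if (!is.finite(object@logLik)) return("log-likelihood must be finite")
  if (abs(object@aic - (2 * object@nParams - 2 * object@logLik)) > 1e-6)
    return("AIC inconsistent with logLik and parameter count")
  TRUE
})
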