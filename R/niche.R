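# Niche overlap and breadth statistics on habitat-suitability grids.
# Model fitting is out of scope: these operate on given suitability surfaces.

#' Read a suitability grid from plain text
#'
#' Accepts either a bare whitespace-separated numeric matrix or an
#' ESRI-ASCII-style file (header lines `key value` followed by the matrix;
#' `NODATA_value` cells become `NA`). `NA` cells are masked (invalid).
#'
#' @param path file path.
#' @return numeric matrix with `NA` for masked cells.
#' @export
readSuitabilityGrid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  isHeader <- grepl("^\\s*[A-Za-z]", lines)
  nodata <- NA_real_
  if (any(isHeader)) {
    for (h in lines[isHeader]) {
      kv <- strsplit(trimws(h), "\\s+")[[1L]]
      if (length(kv) >= 2L && tolower(kv[1L]) == "nodata_value")
        nodata <- as.numeric(kv[2L])
    }
    lines <- lines[!isHeader]
  }
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  if (length(unique(lengths(rows))) != 1L)
    stop("input error: ragged grid rows")
  g <- do.call(rbind, rows)
  if (!is.na(nodata)) g[g == nodata] <- NA
  g
}

#' Normalize a suitability grid to a probability surface
#'
#' Scores over the valid (non-`NA`, finite) cells are rescaled to sum to 1;
#' masked cells stay `NA`. Idempotent.
#'
#' @param grid numeric matrix of non-negative scores, `NA` = masked.
#' @return matrix of the same shape summing to 1 over valid cells.
#' @export
normalizeSuitability <- function(grid) {
  v <- !is.na(grid)
  if (!any(v)) stop("input error: no valid cells")
  if (any(grid[v] < 0) || any(!is.finite(grid[v])))
    stop("input error: scores must be finite and non-negative")
  tot <- sum(grid[v])
  if (tot <= 0) stop("input error: all-zero grid cannot be normalized")
  grid[v] <- grid[v] / tot
  grid
}

#' Niche overlap statistics between two suitability grids
#'
#' Both grids are normalized over their shared valid cells, then three
#' overlap statistics are computed, each ranging from 0 (disjoint niches)
#' to 1 (identical niches):
#' \describe{
#'   \item{D}{Schoener's statistic, `1 - 0.5 * sum |p1 - p2|`;}
#'   \item{I}{the Hellinger-based statistic,
#'     `1 - 0.5 * sum (sqrt(p1) - sqrt(p2))^2`;}
#'   \item{RR}{relative rank: the proportion of valid cell pairs whose
#'     suitability ordering agrees between the two grids (ties count 1/2),
#'     computed exactly for up to `exactLimit` cells and by seeded pair
#'     sampling above.}
#' }
#'
#' @param g1,g2 numeric matrices of the same shape; cells masked (`NA`) in
#'   either grid are excluded from both.
#' @param exactLimit cell count up to which RR is exact (default 2000).
#' @param nSamplePairs number of sampled pairs above the limit.
#' @param seed seed for pair sampling.
#' @return list with `D`, `I`, `RR`.
#' @export
nicheOverlapStats <- function(g1, g2, exactLimit = 2000,
                              nSamplePairs = 200000, seed = 1) {
  if (!identical(dim(g1), dim(g2)))
    stop("input error: grids differ in shape")
  v <- !is.na(g1) & !is.na(g2)
  p1 <- normalizeSuitability(ifelse(v, g1, NA))[v]
  p2 <- normalizeSuitability(ifelse(v, g2, NA))[v]
  D <- 1 - 0.5 * sum(abs(p1 - p2))
  I <- 1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2)
  n <- length(p1)
  concord <- function(i, j) {
    s1 <- sign(p1[i] - p1[j]); s2 <- sign(p2[i] - p2[j])
    ifelse(s1 == s2, ifelse(s1 == 0, 1, 1), ifelse(s1 == 0 | s2 == 0, 0.5, 0))
  }
  if (n <= 1L) {
    RR <- 1
  } else if (n <= exactLimit) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    RR <- mean(concord(ij[, 1L], ij[, 2L]))
  } else {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    i <- sample.int(n, nSamplePairs, replace = TRUE)
    j <- sample.int(n, nSamplePairs, replace = TRUE)
    ok <- i != j
    RR <- mean(concord(i[ok], j[ok]))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  list(D = D, I = I, RR = RR)
}

#' Standardized Levins niche breadth
#'
#' Measures the flatness of a suitability distribution over grid cells:
#' `B = (1 / sum p_i^2 - 1) / (n - 1)`, which is 1 for a uniform surface
#' and 0 when all mass sits on a single cell.
#'
#' @param grid numeric matrix (normalized internally); needs >= 2 valid
#'   cells.
#' @return breadth in `[0, 1]`.
#' @export
nicheBreadth <- function(grid) {
  p <- normalizeSuitability(grid)
  p <- p[!is.na(p)]
  n <- length(p)
  if (n < 2L) stop("input error: need at least 2 valid cells")
  (1 / sum(p^2) - 1) / (n - 1)
}
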