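# Diversification-rate analysis on branching times: five constant- and
# variable-rate models fitted by maximum likelihood, AIC model selection,
# a simulated delta-AIC null test for rate constancy, lineage-through-time
# data, and truncation of the most recent slice of evolutionary history.
#
# Likelihood convention: the generalized-Yule density of the inter-event
# intervals with no conditioning constant on survival or tip count; constants
# cancel in within-convention AIC comparisons.

#' Branching times of an ultrametric tree
#'
#' @param tree rooted ultrametric `ape::phylo` (checked).
#' @param tolerance ultrametricity tolerance.
#' @return numeric vector of internal-node ages (time before present),
#'   sorted descending; length `N - 1`, first element the tree depth.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' branchingTimes(tr)  # 2 1
#' @export
branchingTimes <- function(tree, tolerance = 1e-6) {
  tree <- validateUltrametric(tree, tolerance = tolerance, strict = TRUE)
  bt <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  bt
}

# internal: interval decomposition shared by all model likelihoods.
# bt descending ages t_1 (root) > ... > t_{N-1}; interval i runs from age
# t_i down to t_{i+1} (0 for the last) carrying n_i = i + 1 lineages; the
# event ending interval i (i <= N-2) is the branching at age t_{i+1}.
.btIntervals <- function(bt) {
  if (is.unsorted(rev(bt))) bt <- sort(bt, decreasing = TRUE)
  if (length(bt) < 1L || any(bt <= 0))
    stop("input error: branching times must be positive ages")
  nInt <- length(bt)
  hi <- bt
  lo <- c(bt[-1L], 0)
  list(hi = hi, lo = lo, x = hi - lo, n = seq_len(nInt) + 1,
       nEvents = nInt - 1L, N = nInt + 1L)
}

#' Generalized-Yule log-likelihood for an arbitrary rate function
#'
#' Over the inter-event intervals from the root (2 lineages) to the present
#' (`N` lineages; the final interval carries no event term):
#' `lnL = sum_events log(n_i * lambda_i) - sum_intervals n_i * lambda_i * x_i`
#' with `lambda_i = rateFn(n_i, t_i)` evaluated at the interval's lineage
#' count and its upper (older) age.
#'
#' @param bt branching times, descending ages.
#' @param rateFn function of `(n, t)` returning the per-lineage speciation
#'   rate; must be positive over the tree's span.
#' @return the log-likelihood.
#' @export
generalizedYuleLoglik <- function(bt, rateFn) {
  iv <- .btIntervals(bt)
  lam <- vapply(seq_along(iv$n), function(i) rateFn(iv$n[i], iv$hi[i]), 0)
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("domain error: non-positive rate in interval ",
         which(!is.finite(lam) | lam <= 0)[1L])
  ev <- seq_len(iv$nEvents)
  sum(log(iv$n[ev] * lam[ev])) - sum(iv$n * lam * iv$x)
}

.RATE_MIN <- 1e-8

# closed-form rate MLE for events k over exposure W, floored so r > 0 holds
.rateMle <- function(k, W) {
  r <- k / W
  if (!is.finite(r)) return(.RATE_MIN)
  max(r, .RATE_MIN)
}

# profile log-likelihood contribution of one constant-rate regime
.regimeLnl <- function(k, S, W) {
  # k events with sum log n = S, total exposure W = sum n_i x_i
  r <- .rateMle(k, W)
  k * log(r) + S - r * W
}

.fitPureBirth <- function(iv) {
  W <- sum(iv$n * iv$x)
  k <- iv$nEvents
  S <- sum(log(iv$n[seq_len(k)]))
  r <- .rateMle(k, W)
  list(params = c(r1 = r), logLik = .regimeLnl(k, S, W), nParams = 1L,
       converged = TRUE)
}

.fitYule2rate <- function(iv) {
  k <- iv$nEvents
  S <- iv$n
  # candidates: observed branching times strictly inside the tree's span
  cand <- iv$hi[-1L]                      # exclude the root age
  best <- NULL
  for (st in cand) {
    # interval i spans (lo_i, hi_i); regime 1 governs ages >= st
    inR1 <- iv$lo >= st
    inR2 <- iv$hi <= st
    # a straddling interval (lo < st < hi) is split between regimes
    straddle <- !(inR1 | inR2)
    W1 <- sum(iv$n[inR1] * iv$x[inR1]) + sum(iv$n[straddle] * (iv$hi[straddle] - st))
    W2 <- sum(iv$n[inR2] * iv$x[inR2]) + sum(iv$n[straddle] * (st - iv$lo[straddle]))
    evAges <- iv$lo[seq_len(k)]           # event i is at age lo_i
    e1 <- evAges >= st
    k1 <- sum(e1); k2 <- k - k1
    S1 <- sum(log(iv$n[seq_len(k)][e1]))
    S2 <- sum(log(iv$n[seq_len(k)][!e1]))
    lnl <- .regimeLnl(k1, S1, W1) + .regimeLnl(k2, S2, W2)
    if (is.null(best) || lnl > best$logLik + 1e-12)
      best <- list(params = c(r1 = .rateMle(k1, W1), r2 = .rateMle(k2, W2),
                              st = st),
                   logLik = lnl, nParams = 3L, converged = TRUE)
  }
  best
}

.fitDDL <- function(iv) {
  k <- iv$nEvents
  N <- iv$N
  S <- iv$n
  obj <- function(u) {
    kk <- N + exp(u)                      # carrying capacity, kept > N
    g <- 1 - iv$n / kk
    W <- sum(iv$n * g * iv$x)
    ev <- seq_len(k)
    .regimeLnl(k, sum(log(iv$n[ev] * g[ev])), W)
  }
  o <- optimize(obj, c(-12, 25), maximum = TRUE, tol = 1e-8)
  kk <- N + exp(o$maximum)
  g <- 1 - iv$n / kk
  W <- sum(iv$n * g * iv$x)
  list(params = c(r1 = .rateMle(k, W), k = kk), logLik = o$objective,
       nParams = 2L, converged = TRUE)
}

.fitDDX <- function(iv) {
  k <- iv$nEvents
  obj <- function(xp) {
    g <- iv$n^(-xp)
    W <- sum(iv$n * g * iv$x)
    ev <- seq_len(k)
    .regimeLnl(k, sum(log(iv$n[ev] * g[ev])), W)
  }
  o <- optimize(obj, c(-5, 5), maximum = TRUE, tol = 1e-8)
  xp <- o$maximum
  g <- iv$n^(-xp)
  W <- sum(iv$n * g * iv$x)
  list(params = c(r1 = .rateMle(k, W), xp = xp), logLik = o$objective,
       nParams = 2L, converged = TRUE)
}

# constant-rate birth-death via the reconstructed-process intensity
# lambda_eff(t) = r / (1 - a e^{-r t}); reduces exactly to pureBirth at a = 0
.bdLnl <- function(iv, r, a) {
  ev <- seq_len(iv$nEvents)
  lamEv <- r / (1 - a * exp(-r * iv$lo[ev]))
  # per-lineage integral of lambda_eff over (lo, hi), written stably as
  # r (hi - lo) + log1p(-a e^{-r hi}) - log1p(-a e^{-r lo})
  intl <- r * iv$x + log1p(-a * exp(-r * iv$hi)) - log1p(-a * exp(-r * iv$lo))
  sum(log(iv$n[ev] * lamEv)) - sum(iv$n * intl)
}

.fitBd <- function(iv) {
  pb <- .fitPureBirth(iv)
  r0 <- pb$params[["r1"]]
  obj <- function(par) {
    r <- exp(par[1L]); a <- 1 / (1 + exp(-par[2L]))  # a in (0,1)
    v <- .bdLnl(iv, r, a)
    if (!is.finite(v)) 1e10 else -v
  }
  o <- tryCatch(
    optim(c(log(r0), -2), obj, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  cands <- list(list(r = r0, a = 0, lnl = pb$logLik, conv = TRUE))
  if (!is.null(o)) {
    r <- exp(o$par[1L]); a <- 1 / (1 + exp(-o$par[2L]))
    cands <- c(cands, list(list(r = r, a = a, lnl = -o$value,
                                conv = o$convergence == 0)))
  }
  bestI <- which.max(vapply(cands, `[[`, 0, "lnl"))
  b <- cands[[bestI]]
  list(params = c(r1 = b$r, a = b$a), logLik = b$lnl, nParams = 2L,
       converged = b$conv)
}

.DIV_MODELS <- c("pureBirth", "bd", "DDL", "DDX", "yule2rate")
.DIV_CLASS <- c(pureBirth = "RC", bd = "RC", DDL = "RV", DDX = "RV",
                yule2rate = "RV")

#' Fit one diversification model to branching times
#'
#' Models: `pureBirth` (constant rate, closed-form MLE), `bd` (constant-rate
#' birth-death in `(r1 = b - d, a = d/b)`), `DDL` (logistic density
#' dependence, `lambda = r1 (1 - n/k)`, `k > N`), `DDX` (power-law density
#' dependence, `lambda = r1 n^{-xp}`) and `yule2rate` (rate `r1` at ages
#' `>= st`, `r2` after; the shift time is searched over observed branching
#' times, oldest preferred on ties).
#'
#' @param bt branching times (descending ages), `N >= 4` tips.
#' @param model one of `"pureBirth"`, `"bd"`, `"DDL"`, `"DDX"`,
#'   `"yule2rate"`.
#' @return a [DivModelFit-class]
#' @export
fitDivModel <- function(bt, model = .DIV_MODELS) {
  model <- match.arg(model)
  iv <- .btIntervals(bt)
  if (iv$N < 4L) stop("input error: need at least 4 tips")
  f <- switch(model,
              pureBirth = .fitPureBirth(iv),
              bd = .fitBd(iv),
              DDL = .fitDDL(iv),
              DDX = .fitDDX(iv),
              yule2rate = .fitYule2rate(iv))
  new("DivModelFit", model = model,
      modelClass = unname(.DIV_CLASS[model]), params = f$params,
      logLik = f$logLik, nParams = f$nParams,
      aic = 2 * f$nParams - 2 * f$logLik, converged = f$converged)
}

#' Fit and rank all five diversification models
#'
#' @param bt branching times (descending ages).
#' @return data frame sorted by ascending AIC (ties broken by fewer
#'   parameters) with columns `model`, `mtype`, `P`, `LH`, the parameter
#'   estimates (`r1`, `r2`, `a`, `xp`, `k`, `st`), `AIC` and `dAIC`;
#'   attribute `"fits"` keeps the [DivModelFit-class] objects.
#' @export
modelSelectionTable <- function(bt) {
  fits <- lapply(.DIV_MODELS, function(m) fitDivModel(bt, m))
  names(fits) <- .DIV_MODELS
  getp <- function(f, nm) if (nm %in% names(f@params)) f@params[[nm]] else NA_real_
  tab <- data.frame(
    model = .DIV_MODELS,
    mtype = unname(.DIV_CLASS[.DIV_MODELS]),
    P = vapply(fits, function(f) f@nParams, 0L),
    LH = vapply(fits, function(f) f@logLik, 0),
    r1 = vapply(fits, getp, 0, "r1"),
    r2 = vapply(fits, getp, 0, "r2"),
    a = vapply(fits, getp, 0, "a"),
    xp = vapply(fits, getp, 0, "xp"),
    k = vapply(fits, getp, 0, "k"),
    st = vapply(fits, getp, 0, "st"),
    AIC = vapply(fits, function(f) f@aic, 0),
    row.names = NULL)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab <- tab[order(tab$AIC, tab$P), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

# observed test statistic: AIC(best rate-constant) - AIC(best rate-variable)
.deltaAicRc <- function(bt) {
  tab <- modelSelectionTable(bt)
  min(tab$AIC[tab$mtype == "RC"]) - min(tab$AIC[tab$mtype == "RV"])
}

# fast pure-birth branching times conditioned on N tips: forward waits
# Exp(i * r) for i = 2..N (the last wait runs to the present)
.simPureBirthBt <- function(N, rate) {
  w <- rexp(N - 1L, rate = (2:N) * rate)
  tot <- sum(w)
  ages <- tot - cumsum(c(0, w[-length(w)]))
  ages
}

#' Rate-constancy test against a simulated delta-AIC null
#'
#' The statistic is `AIC(best rate-constant) - AIC(best rate-variable)` on
#' the observed branching times. Its null distribution is obtained by
#' recomputing it on `nSims` pure-birth trees with the same number of tips,
#' simulated at the pure-birth MLE rate; the p-value uses add-one smoothing,
#' `p = (1 + #[null >= observed]) / (nSims + 1)`.
#'
#' @param bt observed branching times.
#' @param nSims number of null simulations (>= 1; default 500).
#' @param seed integer seed for the null simulations.
#' @return list with `statistic`, `null` (the simulated statistics), `p`,
#'   and `rate` (the pure-birth MLE used for simulation).
#' @export
deltaAicNullTest <- function(bt, nSims = 500, seed = 1) {
  if (nSims < 1) stop("input error: nSims must be >= 1")
  iv <- .btIntervals(bt)
  obs <- .deltaAicRc(bt)
  rate <- .fitPureBirth(iv)$params[["r1"]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  null <- vapply(seq_len(nSims), function(i)
    .deltaAicRc(.simPureBirthBt(iv$N, rate)), 0)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(statistic = obs, null = null,
       p = (1 + sum(null >= obs)) / (nSims + 1), rate = rate)
}

#' Lineage-through-time points
#'
#' Step-function coordinates of cumulative lineage count against relative
#' time (present = 0, root = -1): the root contributes `(-1, 2)`, each
#' later branching adds one lineage, and the final row `(0, N)` closes the
#' curve at the present.
#'
#' @param bt branching times (descending ages).
#' @return data frame with columns `time` and `lineages`.
#' @examples
#' lttPoints(c(2, 1))  # (-1, 2), (-0.5, 3), (0, 3)
#' @export
lttPoints <- function(bt) {
  bt <- sort(bt, decreasing = TRUE)
  depth <- bt[1L]
  data.frame(time = c(-bt / depth, 0),
             lineages = c(seq_along(bt) + 1, length(bt) + 1))
}

#' Truncate the most recent slice of evolutionary history
#'
#' Slices the tree at age `fraction * depth` before the present: every
#' lineage crossing the slice becomes a tip (labelled by one of its
#' descendants), everything younger is discarded. The result is ultrametric
#' with depth `(1 - fraction) * depth`. Used to ask whether an apparent
#' recent rate shift survives removal of the youngest part of the tree,
#' where protracted speciation inflates or deflates lineage counts.
#'
#' @param tree rooted ultrametric `ape::phylo`.
#' @param fraction slice depth as a fraction of tree depth, in (0, 1);
#'   default `0.05`.
#' @param tolerance ultrametricity tolerance.
#' @return an `ape::phylo` with attribute `"depth"`.
#' @export
truncateRecentHistory <- function(tree, fraction = 0.05, tolerance = 1e-6) {
  if (!(fraction > 0 && fraction < 1))
    stop("input error: fraction must be in (0, 1)")
  tree <- validateUltrametric(tree, tolerance = tolerance, strict = TRUE)
  depth <- attr(tree, "depth")
  s <- fraction * depth
  N <- length(tree$tip.label)
  nd <- ape::node.depth.edgelength(tree)
  ages <- depth - nd
  ages[seq_len(N)] <- 0
  root <- N + 1L
  if (ages[root] <= s) stop("input error: slice is above the root")
  keep <- which(ages > s)                 # internal nodes surviving the slice
  keep <- keep[keep > N]
  # crossing edges: parent kept, child (tip or internal) below the slice
  newTipOf <- function(v) {               # representative label under node v
    while (v > N) v <- tree$edge[tree$edge[, 1L] == v, 2L][1L]
    tree$tip.label[v]
  }
  idMap <- integer(max(tree$edge))
  labels <- character(0)
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  nTipNew <- 0L
  crossing <- which(ages[tree$edge[, 1L]] > s & ages[tree$edge[, 2L]] <= s)
  nTipTotal <- length(crossing)
  if (nTipTotal < 2L) stop("input error: fewer than 2 lineages cross the slice")
  # assign new ids: tips 1..nTipTotal in the order edges are emitted,
  # internal nodes nTipTotal+1 .. ; root first
  internalOrder <- c(root, setdiff(keep, root))
  for (i in seq_along(internalOrder)) idMap[internalOrder[i]] <- nTipTotal + i
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    if (ages[p] <= s) next
    if (ages[c] > s) {
      edges <- rbind(edges, c(idMap[p], idMap[c]))
      lens <- c(lens, ages[p] - ages[c])
    } else {
      nTipNew <- nTipNew + 1L
      edges <- rbind(edges, c(idMap[p], nTipNew))
      lens <- c(lens, ages[p] - s)
      labels <- c(labels, newTipOf(c))
    }
  }
  storage.mode(edges) <- "integer"
  out <- list(edge = edges, edge.length = lens, tip.label = labels,
              Nnode = length(internalOrder))
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  validateUltrametric(out, tolerance = 1e-6, strict = TRUE)
}
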