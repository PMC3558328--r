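# Generalized mixed Yule-coalescent (GMYC) delimitation on ultrametric trees.
#
# Branching older than a threshold follows a generalized-Yule
# "diversification" process with per-interval rate lambda_d * n_d^p_d;
# branching younger than the threshold, inside each subtree crossing it,
# follows a within-species branching class with rate lambda_c * n_j^p_c
# (the generalized-Yule dialect: n^p of the lineage count). A branch crossing
# a threshold belongs to the diversification class above it and to its
# subtree's coalescent class below it, so classes always sum to the total
# lineage count. The threshold(s) and exponents are estimated by maximum
# likelihood; per-class rate scalings have closed-form MLEs given the
# exponents, so the search is a cheap profile likelihood.

# ---- tree preprocessing -----------------------------------------------------

.gmycPrep <- function(tree, tolerance = 1e-6) {
  tree <- validateUltrametric(tree, tolerance = tolerance, strict = TRUE)
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree, random = FALSE)
  N <- length(tree$tip.label)
  if (N < 3L) stop("input error: GMYC needs a tree with >= 3 tips")
  depth <- attr(tree, "depth")
  nd <- ape::node.depth.edgelength(tree)
  ages <- depth - nd
  ages[seq_len(N)] <- 0                     # ultrametric: tips at the present
  nNode <- tree$Nnode
  root <- N + 1L
  # descendant sets (tips, internal-or-self) per node, via postorder edges
  tipsUnder <- vector("list", N + nNode)
  intUnder <- vector("list", N + nNode)
  for (i in seq_len(N)) { tipsUnder[[i]] <- i; intUnder[[i]] <- integer(0) }
  for (v in (N + 1L):(N + nNode)) { tipsUnder[[v]] <- integer(0); intUnder[[v]] <- v }
  eo <- ape::postorder(tree)
  for (e in eo) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    tipsUnder[[p]] <- c(tipsUnder[[p]], tipsUnder[[c]])
    intUnder[[p]] <- c(intUnder[[p]], intUnder[[c]])
  }
  intAges <- ages[(N + 1L):(N + nNode)]
  ord <- order(-intAges)
  gridNodes <- (N:(N + nNode))[-1L][ord]    # internal ids, oldest first
  # make sure the root leads (it is the unique deepest node; guard ties)
  if (gridNodes[1L] != root) {
    k <- which(gridNodes == root)
    gridNodes <- c(root, gridNodes[-k])
  }
  b <- c(ages[gridNodes], 0)                # interval boundaries, descending
  list(tree = tree, N = N, depth = depth, ages = ages, root = root,
       edge = tree$edge, tipsUnder = tipsUnder, intUnder = intUnder,
       gridNodes = gridNodes, b = b, dur = b[-length(b)] - b[-1L],
       tipLabels = tree$tip.label)
}

# clusters for one global threshold time: edges whose child is strictly
# younger than T while the parent is not; only subtrees with >= 2 tips form
# coalescent classes (singleton entities stay in the diversification class)
.crossingClusters <- function(prep, T, group = 1L) {
  out <- list()
  for (e in seq_len(nrow(prep$edge))) {
    p <- prep$edge[e, 1L]; c <- prep$edge[e, 2L]
    if (prep$ages[c] < T && prep$ages[p] >= T &&
        length(prep$tipsUnder[[c]]) >= 2L)
      out[[length(out) + 1L]] <- list(cc = c, T = T, group = group)
  }
  out
}

# ---- event table ------------------------------------------------------------

# Interval-by-interval lineage accounting for a given cluster state.
# `extraBounds` injects additional interval boundaries (used when a
# reported threshold is not itself a branching time).
#
# Class conventions: the diversification (Yule) class runs forward — an
# event ending interval i occurs at that interval's lineage count. A
# coalescent class runs backward — it accrues waiting rate only while it
# holds >= 2 lineages, and the event ending interval i is the coalescence
# closing the (younger) count-(n_i + 1) period, so its rate uses n_i + 1.
# evN always records the count of the event's own class during interval i.
.classStats <- function(prep, clusters, extraBounds = numeric(0)) {
  b <- prep$b
  gridNodes <- prep$gridNodes
  if (length(extraBounds)) {
    extra <- setdiff(extraBounds, b)
    if (length(extra)) {
      nodeAt <- c(gridNodes[-1L], NA)          # node at each lower boundary
      lower <- c(b[-1L])
      ord <- order(-c(lower, extra))
      lower <- c(lower, extra)[ord]
      nodeAt <- c(nodeAt, rep(NA, length(extra)))[ord]
      b <- c(b[1L], lower)
      gridNodes <- c(gridNodes[1L], nodeAt)    # NA marks non-event boundaries
    }
  }
  nI <- length(b) - 1L
  hi <- b[seq_len(nI)]
  intAges <- prep$ages[prep$gridNodes]
  nTot <- 1 + vapply(hi, function(h) sum(intAges >= h), 0)
  K <- length(clusters)
  counts <- matrix(0, nI, max(K, 1L))
  nodeCluster <- rep(0L, length(prep$ages))
  if (K) {
    for (k in seq_len(K)) {
      cl <- clusters[[k]]
      memAges <- prep$ages[prep$intUnder[[cl$cc]]]
      below <- hi <= cl$T
      if (any(below)) {
        counts[below, k] <- if (length(memAges))
          1 + colSums(outer(memAges, hi[below], ">=")) else 1
      }
      nodeCluster[prep$intUnder[[cl$cc]]] <- k
    }
  }
  nDiv <- nTot - if (K) rowSums(counts) else 0
  # event terminating interval i is the node at boundary i+1 (if any)
  evNode <- if (length(gridNodes) > 1L) c(gridNodes[-1L], NA) else NA
  evNode <- evNode[seq_len(nI)]
  evCluster <- rep(NA_integer_, nI)
  evN <- rep(NA_real_, nI)
  for (i in seq_len(nI)) {
    if (is.na(evNode[i])) next
    k <- nodeCluster[evNode[i]]
    evCluster[i] <- k
    evN[i] <- if (k > 0L) counts[i, k] else nDiv[i]
  }
  list(duration = b[-length(b)] - b[-1L], nDiv = nDiv, counts = counts,
       evCluster = evCluster, evN = evN,
       groups = if (K) vapply(clusters, `[[`, 0L, "group") else integer(0),
       thresholds = if (K) vapply(clusters, `[[`, 0, "T") else numeric(0))
}

#' Interval event table for a GMYC model
#'
#' Decomposes an ultrametric tree into inter-event intervals and, for a given
#' set of threshold times, reports per interval the duration, the number of
#' diversification-class lineages, the per-cluster coalescent-class lineage
#' counts, and which class the terminating branching event belongs to.
#'
#' @param tree a rooted ultrametric `ape::phylo`.
#' @param thresholds numeric vector of threshold ages in `(0, depth)`; empty
#'   for the null (single-class) layout. Each threshold applies tree-wide.
#' @param tolerance ultrametricity tolerance passed to
#'   [validateUltrametric()].
#' @return data frame with columns `duration`, `nDiv`, one `cluster<k>`
#'   column per coalescent class, `eventClass` (`"diversification"`,
#'   `"coalescent"`, or `NA` for the final interval) and `eventN` (the class
#'   lineage count at the event).
#' @export
gmycEventTable <- function(tree, thresholds = numeric(0), tolerance = 1e-6) {
  prep <- .gmycPrep(tree, tolerance)
  for (T in thresholds)
    if (T <= 0 || T >= prep$depth)
      stop("input error: threshold must lie strictly inside (0, depth)")
  clusters <- list()
  taken <- rep(FALSE, length(prep$ages))   # nodes already inside a cluster
  g <- 0L
  for (T in sort(thresholds, decreasing = TRUE)) {
    g <- g + 1L
    for (cl in .crossingClusters(prep, T, group = g)) {
      if (taken[cl$cc]) next
      clusters[[length(clusters) + 1L]] <- cl
      taken[c(cl$cc, prep$intUnder[[cl$cc]], prep$tipsUnder[[cl$cc]])] <- TRUE
    }
  }
  st <- .classStats(prep, clusters, extraBounds = thresholds)
  K <- length(clusters)
  out <- data.frame(duration = st$duration, nDiv = st$nDiv)
  if (K) {
    cc <- st$counts[, seq_len(K), drop = FALSE]
    colnames(cc) <- paste0("cluster", seq_len(K))
    out <- cbind(out, cc)
  }
  out$eventClass <- ifelse(is.na(st$evN), NA,
                           ifelse(!is.na(st$evCluster) & st$evCluster > 0L,
                                  "coalescent", "diversification"))
  out$eventN <- st$evN
  out
}

#' GMYC log-likelihood at fixed parameters
#'
#' Evaluates the mixed likelihood on an event table from
#' [gmycEventTable()]. Per interval `i` the total event rate is
#' `R_i = lambdaD * nDiv_i^pD + lambdaC * sum_j n_{j,i}^pC`, where the
#' diversification (Yule) class contributes whenever it holds at least one
#' lineage and a coalescent class only while it holds at least two (a fully
#' coalesced within-species stem can produce no further event). Then
#' `lnL = sum_events log(rate of the component producing the event)
#'  - sum_intervals R_i * x_i`; a diversification event's rate uses its
#' interval's count, while a coalescent event — the coalescence closing the
#' younger, count-`(n+1)` period — uses `eventN + 1`.
#'
#' @param table event table from [gmycEventTable()].
#' @param lambdaD,pD diversification-class rate scaling (> 0) and exponent.
#' @param lambdaC,pC coalescent-class rate scaling (> 0) and exponent
#'   (ignored when the table has no coalescent class).
#' @return the log-likelihood.
#' @export
gmycLoglik <- function(table, lambdaD, pD, lambdaC = 1, pC = 1) {
  if (lambdaD <= 0 || lambdaC <= 0)
    stop("input error: rate scalings must be > 0")
  ccols <- grep("^cluster", names(table))
  lnL <- 0
  for (i in seq_len(nrow(table))) {
    nd <- table$nDiv[i]
    R <- if (nd > 0) lambdaD * nd^pD else 0
    for (jc in ccols) {
      nj <- table[i, jc]
      if (nj >= 2) R <- R + lambdaC * nj^pC
    }
    lnL <- lnL - R * table$duration[i]
    if (!is.na(table$eventClass[i])) {
      n <- table$eventN[i]
      lnL <- lnL + if (table$eventClass[i] == "diversification")
        log(lambdaD * n^pD) else log(lambdaC * (n + 1)^pC)
    }
    if (!is.finite(lnL))
      stop("numerical error in GMYC likelihood at interval ", i)
  }
  lnL
}

# ---- profile fitting --------------------------------------------------------

.RATE_FLOOR <- 1e-8
# Exponent ranges per class, centred on the canonical values (Yule: 1,
# Kingman-style within-species branching: 2) and kept disjoint: letting the
# between-species class accelerate super-linearly toward the coalescent
# regime lets one class absorb the whole mixed process and destroys the
# identifiability of the threshold.
.P_BOUNDS_DIV <- c(0, 1.5)
.P_BOUNDS_COAL <- c(1.5, 2.5)

# profile fit of one class group: closed-form lambda given exponent p,
# then a guarded 1-D search over p within `bounds`
.profileClassFit <- function(kEv, sumLogN, w, v, bounds, pDefault = 1) {
  # w: interval durations repeated per active (class, interval) cell
  # v: the matching lineage counts
  Wfun <- function(p) sum(w * v^p)
  obj <- function(p) {
    W <- Wfun(p)
    if (!is.finite(W) || W <= 0)
      return(if (kEv == 0) 0 else -Inf)
    if (kEv == 0) return(-.RATE_FLOOR * W)
    kEv * log(kEv / W) + p * sumLogN - kEv
  }
  if (kEv == 0 || length(v) == 0 || all(v == v[1L])) {
    # exponent unidentifiable (no events, or constant counts)
    p <- pDefault
  } else {
    grid <- seq(bounds[1L], bounds[2L], length.out = 9L)
    vals <- vapply(grid, obj, 0)
    p0 <- grid[which.max(vals)]
    step <- grid[2L] - grid[1L]
    o <- optimize(obj, c(max(bounds[1L], p0 - step),
                         min(bounds[2L], p0 + step)),
                  maximum = TRUE, tol = 1e-7)
    p <- if (o$objective >= max(vals)) o$maximum else p0
  }
  W <- Wfun(p)
  lambda <- if (kEv > 0 && W > 0) kEv / W else .RATE_FLOOR
  list(lambda = max(lambda, .RATE_FLOOR), p = p, value = obj(p))
}

# maximised log-likelihood for a cluster state; returns per-group params too
.stateLoglik <- function(prep, clusters) {
  st <- .classStats(prep, clusters)
  nI <- length(st$duration)
  evI <- which(!is.na(st$evN))
  # diversification class
  dIdx <- evI[st$evCluster[evI] == 0L]
  act <- st$nDiv > 0
  fd <- .profileClassFit(length(dIdx), sum(log(st$nDiv[dIdx])),
                         st$duration[act], st$nDiv[act],
                         bounds = .P_BOUNDS_DIV, pDefault = 1)
  total <- fd$value
  params <- list(diversification = c(lambda = fd$lambda, p = fd$p))
  groups <- unique(st$groups)
  gThr <- numeric(0)
  for (g in sort(groups)) {
    cols <- which(st$groups == g)
    gIdx <- evI[st$evCluster[evI] %in% cols]
    cm <- st$counts[, cols, drop = FALSE]
    # backward-coalescent convention: waiting only while a class holds >= 2
    # lineages; an event's rate uses the count on its younger side (n + 1)
    nz <- which(cm >= 2, arr.ind = TRUE)
    fg <- .profileClassFit(
      length(gIdx),
      sum(log(st$evN[gIdx] + 1)),
      st$duration[nz[, 1L]], cm[nz],
      bounds = .P_BOUNDS_COAL, pDefault = 2)
    total <- total + fg$value
    params[[paste0("coalescent", g)]] <- c(lambda = fg$lambda, p = fg$p)
    gThr[as.character(g)] <- st$thresholds[cols[1L]]
  }
  list(logLik = total, params = params, thresholds = unname(gThr),
       stats = st)
}

.entityPartition <- function(prep, clusters) {
  lab <- setNames(rep(NA_character_, prep$N), prep$tipLabels)
  for (k in seq_along(clusters)) {
    tips <- prep$tipsUnder[[clusters[[k]]$cc]]
    lab[tips] <- paste0("cl", k)
  }
  single <- is.na(lab)
  lab[single] <- paste0("tip_", names(lab)[single])
  canonicalPartition(lineagePartition(lab))
}

#' Fit a GMYC model by maximum likelihood
#'
#' * `mode = "null"`: one class for the whole tree; optimises `(lambda, p)`.
#' * `mode = "single"`: one threshold time, searched over all non-root
#'   branching times; subtrees crossing the threshold form coalescent
#'   classes sharing `(lambdaC, pC)`.
#' * `mode = "multiple"`: greedy refinement starting from the single fit —
#'   repeatedly splits one existing cluster at one of its internal branching
#'   times (the split's subtrees form a new coalescent group with its own
#'   rate and exponent) and keeps the move while the log-likelihood improves
#'   by at least `1e-4`.
#'
#' Rate scalings are profiled out in closed form given the exponents. The
#' exponents are bounded to disjoint ranges around their canonical values —
#' diversification `[0, 1.5]` (Yule: 1), coalescent `[1.5, 2.5]`
#' (Kingman-style pair rate: 2) — because overlapping ranges let a single
#' accelerating class absorb the whole mixed process and destroy the
#' identifiability of the threshold. Parameter counts: 2 (null) plus 3 per
#' threshold (the time and its class's rate and exponent).
#'
#' @param tree rooted ultrametric `ape::phylo`.
#' @param mode `"single"` (default), `"multiple"` or `"null"`.
#' @param tolerance ultrametricity tolerance.
#' @return a [GmycFit-class]; `nEntities`/`nClusters` count ML entities and
#'   multi-tip clusters, and the entity partition is in `gmycPartition()`.
#' @export
fitGmyc <- function(tree, mode = c("single", "multiple", "null"),
                    tolerance = 1e-6) {
  mode <- match.arg(mode)
  prep <- .gmycPrep(tree, tolerance)
  nullFit <- .stateLoglik(prep, list())
  makeFit <- function(mode, clusters, sl) {
    if (mode == "null" || length(clusters) == 0L) {
      # a single generalized-Yule class: one entity (a single population)
      part <- canonicalPartition(lineagePartition(
        setNames(rep("1", prep$N), prep$tipLabels)))
    } else {
      part <- .entityPartition(prep, clusters)
    }
    new("GmycFit", mode = mode, thresholds = sl$thresholds,
        logLik = sl$logLik, params = sl$params, partition = part,
        nEntities = as.integer(nBlocks(part)),
        nClusters = length(clusters),
        converged = is.finite(sl$logLik))
  }
  if (mode == "null") return(makeFit("null", list(), nullFit))

  cand <- sort(unique(prep$ages[prep$gridNodes[-1L]]), decreasing = TRUE)
  cand <- cand[cand > 0 & cand < prep$depth * (1 - 1e-12)]
  # the null layout is the degenerate candidate: keeps lnL(single) >= lnL(null)
  best <- nullFit
  bestClusters <- list()
  for (T in cand) {
    clusters <- .crossingClusters(prep, T)
    if (length(clusters) == 0L) next
    sl <- .stateLoglik(prep, clusters)
    if (sl$logLik > best$logLik + 1e-12) {
      best <- sl; bestClusters <- clusters
    }
  }
  if (mode == "single") return(makeFit("single", bestClusters, best))

  # greedy multiple-threshold refinement
  clusters <- bestClusters
  cur <- best
  nextGroup <- 2L
  repeat {
    bestMove <- NULL
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      times <- unique(prep$ages[prep$intUnder[[cl$cc]]])
      times <- times[times > 0 & times < cl$T]
      for (t in times) {
        sub <- .crossingClustersWithin(prep, cl$cc, t, nextGroup)
        if (length(sub) == 0L) next
        trial <- c(clusters[-k], sub)
        sl <- .stateLoglik(prep, trial)
        if (is.null(bestMove) || sl$logLik > bestMove$sl$logLik)
          bestMove <- list(sl = sl, clusters = trial)
      }
    }
    if (is.null(bestMove) || bestMove$sl$logLik < cur$logLik + 1e-4) break
    clusters <- bestMove$clusters
    cur <- bestMove$sl
    nextGroup <- nextGroup + 1L
  }
  makeFit("multiple", clusters, cur)
}

# crossing clusters of time t restricted to the subtree of node top
.crossingClustersWithin <- function(prep, top, t, group) {
  nodes <- c(prep$intUnder[[top]])
  out <- list()
  for (v in nodes) {
    # edges from v to its children
    kids <- prep$edge[prep$edge[, 1L] == v, 2L]
    for (c in kids) {
      if (prep$ages[c] < t && prep$ages[v] >= t &&
          length(prep$tipsUnder[[c]]) >= 2L)
        out[[length(out) + 1L]] <- list(cc = c, T = t, group = group)
    }
  }
  out
}

#' Entity partition of a GMYC fit
#'
#' @param fit a [GmycFit-class]
#' @return the [LineagePartition-class] of tips into ML entities.
#' @export
gmycPartition <- function(fit) {
  stopifnot(is(fit, "GmycFit"))
  fit@partition
}

#' Free-parameter count of a GMYC fit
#'
#' Two parameters for the diversification class plus three per threshold.
#'
#' @param fit a [GmycFit-class]
#' @export
gmycNParams <- function(fit) {
  stopifnot(is(fit, "GmycFit"))
  2L + 3L * length(fit@thresholds)
}

#' Likelihood-ratio test between nested fits
#'
#' @param lnLGeneral,lnLRestricted maximised log-likelihoods of the general
#'   and restricted models; the general one must not be smaller beyond a
#'   `1e-6` numerical tolerance.
#' @param df degrees of freedom (>= 1).
#' @return list with `statistic` (`2 * (lnLGeneral - lnLRestricted)`, clamped
#'   at 0) and `p` (upper-tail chi-square probability).
#' @examples
#' lrTest(1315.46, 1275.858, df = 3)$statistic  # 79.204
#' @export
lrTest <- function(lnLGeneral, lnLRestricted, df) {
  if (df < 1) stop("input error: df must be >= 1")
  if (lnLGeneral < lnLRestricted - 1e-6)
    stop("input error: general model log-likelihood below restricted model")
  stat <- max(2 * (lnLGeneral - lnLRestricted), 0)
  list(statistic = stat, p = pchisq(stat, df = df, lower.tail = FALSE))
}
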