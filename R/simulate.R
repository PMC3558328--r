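# Seeded synthetic-data generators. Each generator seeds the global RNG
# explicitly and embeds its full parameter list (including the seed) in a
# "simSpec" attribute, so any output can be regenerated bit-identically.

.simSpec <- function(...) {
  spec <- list(...)
  spec
}

# ---- forward birth(-death) simulation --------------------------------------

# lineage records -> phylo. rec: data.frame(parent, tStart, tEnd, type)
# type: "split" (internal), "alive" (extant tip), "dead" (extinct tip).
# Records 1 and 2 are the root's children; the root split is at time 0.
.recordsToPhylo <- function(rec, present) {
  end <- ifelse(is.na(rec$tEnd), present, rec$tEnd)
  tipRec <- which(rec$type != "split")
  intRec <- which(rec$type == "split")
  nTip <- length(tipRec)
  id <- integer(nrow(rec))
  id[tipRec] <- seq_len(nTip)
  # root is node nTip + 1; splits follow in record order
  id[intRec] <- nTip + 1L + seq_along(intRec)
  rootId <- nTip + 1L
  parentNode <- ifelse(rec$parent == 0L, rootId, id[pmax(rec$parent, 1L)])
  edges <- cbind(parentNode, id)
  lens <- end - rec$tStart
  tr <- list(edge = matrix(as.integer(edges), ncol = 2),
             edge.length = lens,
             tip.label = paste0(ifelse(rec$type[tipRec] == "alive", "t", "x"),
                                seq_along(tipRec)),
             Nnode = length(intRec) + 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

.gillespie <- function(n, birth, death = 0, finalWait = c("exp", "none"),
                       fixedTail = 0, tailRate = NULL) {
  # forward simulation from 2 lineages until n are alive simultaneously;
  # returns NULL if the clade dies out
  finalWait <- match.arg(finalWait)
  rec <- data.frame(parent = c(0L, 0L), tStart = c(0, 0), tEnd = NA_real_,
                    type = "alive", stringsAsFactors = FALSE)
  alive <- c(1L, 2L)
  t <- 0
  while (length(alive) < n) {
    k <- length(alive)
    if (k == 0L) return(NULL)
    t <- t + rexp(1L, rate = k * (birth + death))
    i <- alive[sample.int(k, 1L)]
    if (runif(1L) < birth / (birth + death)) {
      rec$tEnd[i] <- t; rec$type[i] <- "split"
      rec <- rbind(rec, data.frame(parent = c(i, i), tStart = c(t, t),
                                   tEnd = NA_real_, type = "alive"))
      alive <- c(setdiff(alive, i), nrow(rec) - 1L, nrow(rec))
    } else {
      rec$tEnd[i] <- t; rec$type[i] <- "dead"
      alive <- setdiff(alive, i)
    }
  }
  present <- if (finalWait == "exp") {
    t + rexp(1L, rate = n * (if (is.null(tailRate)) birth + death else tailRate))
  } else {
    t + fixedTail
  }
  list(rec = rec, present = present, reachedAt = t)
}

#' Simulate an ultrametric tree under a lineage-birth process
#'
#' Forward Gillespie simulation conditioned on `n` extant tips:
#' * `"yule"` — constant speciation rate `rate`, no extinction; after the
#'   n-th lineage appears the tree is closed by an `Exp(n * rate)` wait.
#' * `"birthdeath"` — birth `rate`, death `rate * a`; runs until `n` lineages
#'   are alive, retrying (up to `maxTries`) when the clade dies out; extinct
#'   lineages are pruned, so the returned reconstructed tree is ultrametric.
#' * `"yule2rate"` — rate `rate` until `n` lineages exist, then a terminal
#'   window of length `shiftAge` at rate `r2`, conditioned (by bounded
#'   rejection) on no further birth, so the shift sits exactly `shiftAge`
#'   before the present and the tree has exactly `n` tips. This reproduces a
#'   recent rate slowdown such as protracted speciation induces.
#'
#' @param n number of extant tips (>= 3).
#' @param process `"yule"`, `"birthdeath"` or `"yule2rate"`.
#' @param rate speciation rate (r1).
#' @param r2 post-shift rate (yule2rate only).
#' @param shiftAge age of the rate shift before the present (yule2rate).
#' @param a extinction fraction d/b (birthdeath only).
#' @param seed integer seed.
#' @param maxTries retry bound for conditioned processes.
#' @return an `ape::phylo`, ultrametric, with attribute `"simSpec"`.
#' @export
simTree <- function(n, process = c("yule", "birthdeath", "yule2rate"),
                    rate = 1, r2 = rate, shiftAge = 0, a = 0, seed = 1,
                    maxTries = 1000) {
  process <- match.arg(process)
  if (n < 3L) stop("input error: need n >= 3")
  if (rate <= 0 || r2 <= 0) stop("input error: rates must be > 0")
  set.seed(seed)
  tr <- NULL
  for (try in seq_len(maxTries)) {
    if (process == "yule") {
      g <- .gillespie(n, birth = rate)
      tr <- .recordsToPhylo(g$rec, g$present)
      break
    } else if (process == "birthdeath") {
      if (!(a >= 0 && a < 1)) stop("input error: need 0 <= a < 1")
      g <- .gillespie(n, birth = rate, death = rate * a)
      if (is.null(g)) next
      tr <- .recordsToPhylo(g$rec, g$present)
      dead <- grep("^x", tr$tip.label, value = TRUE)
      if (length(dead)) tr <- ape::drop.tip(tr, dead)
      break
    } else {
      if (shiftAge <= 0) stop("input error: yule2rate needs shiftAge > 0")
      g <- .gillespie(n, birth = rate, finalWait = "none",
                      fixedTail = shiftAge)
      # accept only if no birth falls in the terminal window at rate r2
      if (rexp(1L, rate = n * r2) > shiftAge) {
        tr <- .recordsToPhylo(g$rec, g$present)
        break
      }
    }
  }
  if (is.null(tr))
    stop("simulation error: conditioning failed within ", maxTries, " tries")
  attr(tr, "simSpec") <- .simSpec(process = process, n = n, rate = rate,
                                  r2 = r2, shiftAge = shiftAge, a = a,
                                  seed = seed)
  validateUltrametric(tr, strict = TRUE)
}

# ---- species tree + within-species coalescent ------------------------------

# random Kingman-style coalescent subtree of k tips with pair-rate 1/theta;
# returns list(newick = subtree without trailing ';', depth)
.coalescentNewick <- function(labels, theta) {
  k <- length(labels)
  cl <- as.list(labels)
  ages <- rep(0, k)
  t <- 0
  while (length(cl) > 1L) {
    j <- length(cl)
    t <- t + rexp(1L, rate = choose(j, 2) / theta)
    pick <- sample.int(j, 2L)
    nw <- sprintf("(%s:%.10f,%s:%.10f)", cl[[pick[1L]]], t - ages[pick[1L]],
                  cl[[pick[2L]]], t - ages[pick[2L]])
    cl <- c(cl[-pick], nw)
    ages <- c(ages[-pick], t)
  }
  list(newick = cl[[1L]], depth = t)
}

#' Simulate a species tree with coalescent tip clusters
#'
#' A Yule species tree over `nSpecies` tips, each species tip replaced by a
#' Kingman-style coalescent genealogy of `tipsPerSpecies` samples whose depth
#' is kept roughly `separation` times shallower than the youngest speciation
#' event — the generative model of GMYC delimitation. Within-species
#' genealogies are redrawn (bounded) if they would reach above the species'
#' pendant branch.
#'
#' @param nSpecies number of species (>= 2).
#' @param tipsPerSpecies samples per species (>= 1).
#' @param speciationRate Yule rate of the species tree.
#' @param separation ratio of youngest species age to expected coalescent
#'   depth (default 20).
#' @param seed integer seed.
#' @return list with `tree` (ultrametric `ape::phylo`, tips
#'   `sp<i>_t<j>`) and `partition` (the true species [LineagePartition-class]).
#' @export
simSpeciesCoalescentTree <- function(nSpecies, tipsPerSpecies,
                                     speciationRate = 1, separation = 20,
                                     seed = 1) {
  if (nSpecies < 2L) stop("input error: need >= 2 species")
  if (tipsPerSpecies < 1L) stop("input error: need >= 1 tip per species")
  set.seed(seed)
  g <- .gillespie(nSpecies, birth = speciationRate)
  sp <- .recordsToPhylo(g$rec, g$present)
  sp$tip.label <- paste0("sp", seq_len(nSpecies))
  bt <- sort(unname(ape::branching.times(sp)))
  minAge <- bt[1L]
  theta <- minAge / (2 * separation)
  tree <- sp
  if (tipsPerSpecies > 1L) {
    for (i in seq_len(nSpecies)) {
      lab <- paste0("sp", i)
      tipIdx <- which(tree$tip.label == lab)
      pend <- tree$edge.length[tree$edge[, 2L] == tipIdx]
      sub <- NULL
      # keep the realized coalescent depth both under the pendant branch and
      # well inside the requested speciation/coalescent separation
      maxDepth <- min(0.9 * pend, 2 * minAge / separation)
      for (try in seq_len(100L)) {
        cand <- .coalescentNewick(paste0(lab, "_t", seq_len(tipsPerSpecies)),
                                  theta)
        if (cand$depth < maxDepth) { sub <- cand; break }
      }
      if (is.null(sub))
        stop("simulation error: coalescent depth kept exceeding the pendant branch")
      subTree <- ape::read.tree(text = paste0(sub$newick, ";"))
      tree$edge.length[tree$edge[, 2L] == tipIdx] <- pend - sub$depth
      tree <- ape::bind.tree(tree, subTree, where = which(tree$tip.label == lab))
    }
  } else {
    tree$tip.label <- paste0(tree$tip.label, "_t1")
  }
  tree <- validateUltrametric(tree, strict = TRUE)
  ids <- tree$tip.label
  part <- canonicalPartition(lineagePartition(
    setNames(sub("_t[0-9]+$", "", ids), ids)))
  attr(tree, "simSpec") <- .simSpec(process = "species+coalescent",
                                    nSpecies = nSpecies,
                                    tipsPerSpecies = tipsPerSpecies,
                                    speciationRate = speciationRate,
                                    separation = separation, seed = seed)
  list(tree = tree, partition = part)
}

# ---- K80 sequence evolution -------------------------------------------------

# K80 per-site change probabilities after expected t substitutions/site.
# Bases coded 1:4 = A, G, C, T; transition partner = code xor within pair.
.k80Probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)                 # each of the two transversions
}

.TS_PARTNER <- c(2L, 1L, 4L, 3L)
.TV_PARTNERS <- list(c(3L, 4L), c(3L, 4L), c(1L, 2L), c(1L, 2L))

#' Simulate sequences on a tree under the K80 model
#'
#' The root sequence is uniform over ACGT; each branch applies the K80
#' transition kernel with expected `branch length * scale` substitutions per
#' site and transition/transversion ratio `kappa`.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param length number of sites.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param scale substitutions per site per unit branch length.
#' @param seed integer seed.
#' @return a [BarcodeAlignment-class] of the tip sequences.
#' @export
simSequencesK80 <- function(tree, length = 607, kappa = 4, scale = 1,
                            seed = 1) {
  if (length < 1L) stop("input error: length must be >= 1")
  if (kappa <= 0) stop("input error: kappa must be > 0")
  set.seed(seed)
  N <- base::length(tree$tip.label)
  nNode <- tree$Nnode
  seqs <- vector("list", N + nNode)
  root <- N + 1L
  seqs[[root]] <- sample.int(4L, length, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1L]; ch <- ord[e, 2L]
    pr <- .k80Probs(lens[e] * scale, kappa)
    parent <- seqs[[p]]
    u <- runif(length)
    out <- parent
    isTs <- u >= pr[["same"]] & u < pr[["same"]] + pr[["ts"]]
    out[isTs] <- .TS_PARTNER[parent[isTs]]
    isTv1 <- u >= pr[["same"]] + pr[["ts"]] &
      u < pr[["same"]] + pr[["ts"]] + pr[["tv"]]
    isTv2 <- u >= pr[["same"]] + pr[["ts"]] + pr[["tv"]]
    for (b in 1:4) {
      out[isTv1 & parent == b] <- .TV_PARTNERS[[b]][1L]
      out[isTv2 & parent == b] <- .TV_PARTNERS[[b]][2L]
    }
    seqs[[ch]] <- out
  }
  bases <- c("A", "G", "C", "T")
  tipSeqs <- vapply(seq_len(N), function(i)
    paste(bases[seqs[[i]]], collapse = ""), "")
  aln <- barcodeAlignment(tree$tip.label, tipSeqs)
  attr(aln, "simSpec") <- .simSpec(length = length, kappa = kappa,
                                   scale = scale, seed = seed)
  aln
}

# ---- planted barcode gap ----------------------------------------------------

# deterministic species scaffold: a backbone caterpillar whose species stems
# are long (ages spread over [1.4, 1.7] * interMin) and whose within-species
# genealogies are shallow caterpillars (ages 0.02 * intraMax * j), so the
# expected intra/inter K2P distances sit far inside/outside the target band.
.plantedGapTree <- function(nSpecies, tipsPerSpecies, intraMax, interMin) {
  within <- function(sp) {
    labs <- paste0("sp", sp, "_t", seq_len(tipsPerSpecies))
    if (tipsPerSpecies == 1L) return(list(newick = labs, depth = 0))
    nw <- labs[1L]
    age <- 0
    for (j in 2L:tipsPerSpecies) {
      newAge <- 0.02 * intraMax * (j - 1L)
      nw <- sprintf("(%s:%.10f,%s:%.10f)", nw, newAge - age, labs[j], newAge)
      age <- newAge
    }
    list(newick = nw, depth = age)
  }
  subs <- lapply(seq_len(nSpecies), within)
  bbAges <- seq(1.4 * interMin, 1.7 * interMin, length.out = nSpecies - 1L)
  nw <- subs[[1L]]$newick
  age <- subs[[1L]]$depth
  for (i in 2L:nSpecies) {
    nw <- sprintf("(%s:%.10f,%s:%.10f)", nw, bbAges[i - 1L] - age,
                  subs[[i]]$newick, bbAges[i - 1L] - subs[[i]]$depth)
    age <- bbAges[i - 1L]
  }
  ape::read.tree(text = paste0(nw, ";"))
}

#' Generate an alignment with a planted barcode gap
#'
#' Simulates K80 sequences on a species scaffold whose within-species
#' divergences are far below `intraMax` and whose between-species divergences
#' are far above `interMin`, then verifies the realized K2P distances and
#' regenerates (bounded) on any violation. The returned ground-truth
#' partition is recovered exactly by any threshold inside the gap.
#'
#' @param nSpecies,tipsPerSpecies design (>= 2 species).
#' @param intraMax maximum allowed intraspecific K2P distance (default 0.01).
#' @param interMin minimum allowed interspecific K2P distance (default 0.06).
#' @param length alignment length (default 607).
#' @param kappa transition/transversion ratio for the K80 simulation.
#' @param seed integer seed.
#' @param maxTries rejection bound (default 25).
#' @return list with `alignment` ([BarcodeAlignment-class]), `partition`
#'   (true [LineagePartition-class]), `tree` (the generating ultrametric
#'   `ape::phylo`) and `distances` (the realized [GeneticDistances-class]).
#' @export
makePlantedGapDataset <- function(nSpecies = 8, tipsPerSpecies = 5,
                                  intraMax = 0.01, interMin = 0.06,
                                  length = 607, kappa = 4, seed = 1,
                                  maxTries = 25) {
  if (interMin <= intraMax)
    stop("input error: interMin must exceed intraMax")
  if (nSpecies < 2L) stop("input error: need >= 2 species")
  tree <- .plantedGapTree(nSpecies, tipsPerSpecies, intraMax, interMin)
  ids <- tree$tip.label
  truth <- canonicalPartition(lineagePartition(
    setNames(sub("_t[0-9]+$", "", ids), ids)))
  sameSp <- outer(sub("_t[0-9]+$", "", ids), sub("_t[0-9]+$", "", ids), "==")
  for (try in seq_len(maxTries)) {
    aln <- simSequencesK80(tree, length = length, kappa = kappa, scale = 1,
                           seed = seed + (try - 1L) * 1009L)
    dm <- buildDistanceMatrix(aln, "K2P")
    d <- dm@d
    ut <- upper.tri(d)
    okIntra <- all(d[ut & sameSp] <= intraMax)
    okInter <- all(d[ut & !sameSp] >= interMin) && all(is.finite(d[ut]))
    if (okIntra && okInter) {
      out <- list(alignment = aln, partition = truth, tree = tree,
                  distances = dm)
      attr(out, "simSpec") <- .simSpec(nSpecies = nSpecies,
                                       tipsPerSpecies = tipsPerSpecies,
                                       intraMax = intraMax,
                                       interMin = interMin, length = length,
                                       kappa = kappa, seed = seed,
                                       acceptedTry = try)
      return(out)
    }
  }
  stop("simulation error: planted-gap construction infeasible for these ",
       "parameters (rejection bound exceeded)")
}

# ---- morphospecies label edits ----------------------------------------------

#' Derive morphospecies labels from true lineages, with controlled errors
#'
#' Starts from the true partition (one name per lineage), then applies
#' `nLumps` merges — adjacent block pairs relabelled to one shared name,
#' emulating taxonomic lumping — and `nSplits` splits — a proper subset of a
#' multi-specimen block relabelled to a new name, emulating oversplitting.
#' Edited blocks are chosen with the seeded RNG and never overlap.
#'
#' @param truePartition a [LineagePartition-class]
#' @param nLumps,nSplits edit counts (default 0).
#' @param seed integer seed.
#' @return named character vector specimen id -> morphospecies name, with an
#'   attribute `"editLog"` describing each applied edit.
#' @export
assignMorphospeciesLabels <- function(truePartition, nLumps = 0, nSplits = 0,
                                      seed = 1) {
  stopifnot(is(truePartition, "LineagePartition"))
  set.seed(seed)
  blocks <- partitionBlocks(truePartition)
  nb <- length(blocks)
  if (2 * nLumps + nSplits > nb)
    stop("input error: not enough blocks for the requested edits")
  labels <- setNames(rep(NA_character_, length(blockAssignment(truePartition))),
                     names(blockAssignment(truePartition)))
  log <- list()
  nameI <- 0L
  edited <- logical(nb)
  # lumps: disjoint adjacent block pairs, picked with the seeded RNG
  starts <- sample.int(nb - 1L)
  lumped <- 0L
  for (s in starts) {
    if (lumped == nLumps) break
    if (edited[s] || edited[s + 1L]) next
    edited[c(s, s + 1L)] <- TRUE
    lumped <- lumped + 1L
    nameI <- nameI + 1L
    nm <- paste0("M", nameI)
    labels[unlist(blocks[c(s, s + 1L)])] <- nm
    log[[length(log) + 1L]] <- list(edit = "lump", blocks = c(s, s + 1L),
                                    name = nm)
  }
  if (lumped < nLumps)
    stop("input error: could not place ", nLumps, " disjoint adjacent lumps")
  splittable <- which(!edited & lengths(blocks) >= 2L)
  if (length(splittable) < nSplits)
    stop("input error: not enough multi-specimen blocks to split")
  if (nSplits > 0L) for (b in sample(splittable)[seq_len(nSplits)]) {
    edited[b] <- TRUE
    members <- blocks[[b]]
    cut <- sample.int(length(members) - 1L, 1L)
    nameI <- nameI + 1L; nmA <- paste0("M", nameI)
    nameI <- nameI + 1L; nmB <- paste0("M", nameI)
    labels[members[seq_len(cut)]] <- nmA
    labels[members[-seq_len(cut)]] <- nmB
    log[[length(log) + 1L]] <- list(edit = "split", block = b,
                                    names = c(nmA, nmB))
  }
  for (b in seq_len(nb)) {
    if (any(is.na(labels[blocks[[b]]]))) {
      nameI <- nameI + 1L
      labels[blocks[[b]]] <- paste0("M", nameI)
    }
  }
  attr(labels, "editLog") <- log
  attr(labels, "simSpec") <- .simSpec(nLumps = nLumps, nSplits = nSplits,
                                      seed = seed)
  labels
}

# ---- suitability grids -------------------------------------------------------

#' Generate a pair of Gaussian-bump suitability grids
#'
#' Two smooth non-negative suitability surfaces whose centres are separated
#' along the x-axis by `separation` cells; their analytic overlap decreases
#' monotonically as the separation grows.
#'
#' @param shape integer vector `c(nrow, ncol)` (default `c(40, 40)`).
#' @param widths Gaussian standard deviations of the two bumps, in cells.
#' @param separation centre-to-centre distance in cells.
#' @param seed integer seed (recorded; the surfaces are deterministic).
#' @return list with `g1`, `g2` (numeric matrices).
#' @export
makeSuitabilityGrids <- function(shape = c(40, 40), widths = c(5, 5),
                                 separation = 0, seed = 1) {
  set.seed(seed)
  nr <- shape[1L]; nc <- shape[2L]
  cy <- (nr + 1) / 2
  cx1 <- (nc + 1) / 2 - separation / 2
  cx2 <- (nc + 1) / 2 + separation / 2
  bump <- function(cx, w) {
    outer(seq_len(nr), seq_len(nc), function(y, x)
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * w^2)))
  }
  out <- list(g1 = bump(cx1, widths[1L]), g2 = bump(cx2, widths[2L]))
  attr(out, "simSpec") <- .simSpec(shape = shape, widths = widths,
                                   separation = separation, seed = seed)
  out
}
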