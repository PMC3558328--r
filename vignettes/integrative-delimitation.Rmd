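---
title: "Integrative species delimitation and diversification analysis with LineageDelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation and diversification analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LineageDelim)
```

## The problem

Shell-based taxonomy in minute gastropods (and many other groups with
plastic or conserved morphology) routinely lumps separately evolving
lineages under one morphospecies name, or splits one lineage into several.
`LineageDelim` implements an integrative molecular protocol for this
situation: several independent single-locus delimitation methods are applied
to the same DNA-barcode alignment, their partitions are merged by a
deliberately conservative consensus, the consensus is cross-validated
against the morphospecies hypotheses, and the tempo of diversification of
the resulting lineages is analysed on an ultrametric tree. Every stage has a
seeded synthetic-data generator with known ground truth, so the whole
pipeline is testable end to end without any external data.

The common currency of all methods is the `LineagePartition`: an assignment
of specimens to disjoint "evolutionary lineages" (ELs).

## Delimitation methods

**Fixed threshold.** `thresholdPartition()` clusters specimens whose
Kimura two-parameter (K2P) distance chains below a cutoff (default 3.2%,
the established carychiid barcode threshold). With pairwise deletion,
`P` and `Q` are the transition and transversion fractions over the
comparable sites and

$$d = -\tfrac12 \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

Sites carrying a gap, `N` or any other ambiguity code in either sequence
are excluded for that pair only, and the per-pair effective site count is
retained so downstream users can flag pairs with few comparable sites.
Saturated pairs (non-positive log argument) are stored as `Inf` and behave
as "above any threshold". Single linkage (transitive closure) is the
default reading of "cluster at threshold"; complete linkage is available
as an option because the original protocol does not name its linkage.

**Automatic barcode gap discovery (ABGD).** `abgdPartition()` sorts the
group's pairwise distances and looks for the first significant gap beyond
a prior maximum intraspecific divergence: the smallest index $i$ with
$d_{i+1} > p$ and $d_{i+1} - d_i > X\,d_i$, where $X$ is the minimum
relative gap width. The group is split by single linkage at the gap
midpoint and the procedure recurses into each subgroup. (We index the gap
by the first distance *above* the prior; a prior below the observed
intraspecific distances makes the method split haplotype clusters, exactly
as the reference tool does.) `abgdPriorScan()` runs a geometric series of
priors — 50 screening steps by default — and summarises block-count
stability across priors. Our local gap rule is a fully specified dialect
of the reference tool's windowed slope heuristic; on data with a real gap
the two agree.

**Statistical parsimony (SP).** `spPartition()` collapses identical
sequences into haplotypes, connects haplotype pairs whose mutational
distance does not exceed the connection limit, and returns the connected
components. The limit `parsimonyConnectionLimit()` is the largest number
of steps $j$ whose probability of parsimony still reaches the confidence
level (default 95%). We evaluate that probability under an equal-rate,
uniform-sites model: $j$ mutations are parsimonious when they hit $j$
distinct sites of $L$, so

$$P(j) = \prod_{i=1}^{j-1}\left(1 - \frac{i}{L}\right),$$

with $P(1) = 1$. For a 607-bp barcode at 95% this gives a limit of 8
steps. The original estimator additionally conditions on coalescent
expectations, so absolute limits from the reference software can differ by
a step or two; the full $P(1..j_{max}+1)$ table is attached to the result
for audit. Gaps are treated as missing (not a fifth state), and network
internals beyond component membership are not reconstructed because only
connectivity matters for delimitation.

**GMYC.** `fitGmyc()` fits the generalized mixed Yule-coalescent model on
an ultrametric tree: branching older than a threshold time belongs to a
between-species diversification class, branching younger than it, within
each subtree crossing it, to within-species coalescent classes. Per
inter-event interval $i$ the total event rate is

$$R_i = \lambda_d\, n_{d,i}^{\,p_d} + \lambda_c \sum_j n_{j,i}^{\,p_c},$$

and the log-likelihood is the usual point-process sum of per-event log
rates minus rate-times-duration exposures. Two conventions matter and are
deliberate:

* *No double counting.* A branch crossing the threshold counts in the
  diversification class above it and in its subtree's coalescent class
  below it, so class counts always sum to the total lineage count.
* *Coalescent classes are backward processes.* A class holding a single
  lineage (a fully coalesced within-species stem) accrues no waiting rate,
  and an event's rate uses the lineage count on its younger side
  ($n+1$). Without this, long species stems pay an event-free waiting
  penalty that *grows* with the speciation/coalescent separation, and the
  likelihood maximum migrates to degenerate near-tip thresholds.

Given the exponents, each class's rate scaling has a closed-form maximum
($\hat\lambda = k/W(p)$, events over exposure), so fitting reduces to
independent 1-D searches over the exponents — deterministic, with no
multi-start heuristics. The exponents are bounded to disjoint ranges
around their canonical values: $p_d \in [0, 1.5]$ (Yule: 1) and
$p_c \in [1.5, 2.5]$ (Kingman-style pair coalescence: 2). This is an
identifiability constraint, not a tuning knob: with overlapping ranges a
single accelerating class can absorb the entire mixed process (we observed
recovery collapsing from ~96% to ~30% on generated data when either class
may take exponent 3).

The single-threshold search scans all non-root branching times; the
multiple-threshold mode refines greedily, splitting one existing cluster
at one of its internal branching times — each accepted move adds a
threshold with its own $(\lambda, p)$, i.e. 3 parameters, which reproduces
the df = 6 convention when comparing a three-threshold fit against a
single-threshold one. When no threshold improves on the single-class
(null) layout, the single fit degenerates to it, which keeps the
likelihood nesting `null <= single <= multiple` exact. `lrTest()` compares
fits on the chi-square upper tail.

**Consensus and cross-validation.** `joinPartitions()` implements the
conservative rule "the most comprehensive grouping of specimens predicted
by any method" as the join in the partition lattice: two specimens share a
consensus block iff a chain of co-membership edges (from any input)
connects them. This is the only order-independent reading, and it
deliberately risks lumping rather than splitting.
`crossvalidateMorphospecies()` then classifies each morphospecies as
*match* (one EL, unshared), *split* (several pure ELs), *lumped* (shares
its single EL with another name) or *mixed*, and counts ELs unrecognized
by morphology.

## Diversification analyses

`modelSelectionTable()` fits five models to the branching times by maximum
likelihood and ranks them by AIC ($2P - 2\ln L$): `pureBirth`
(closed form $\hat r_1 = (N-2)/\sum n_i x_i$), `bd` (constant-rate
birth-death), `DDL` ($\lambda = r_1(1 - n/k)$, $k > N$), `DDX`
($\lambda = r_1 n^{-x_p}$) and `yule2rate` (rate $r_1$ at ages $\ge s_t$,
$r_2$ after, with the shift searched over observed branching times, ties
to the oldest). The likelihood convention carries no conditioning constant
on survival or tip count; those constants cancel in within-convention AIC
comparisons, which is how the table is used. The `bd` likelihood uses the
reconstructed-process intensity $\lambda_{\text{eff}}(t) = r/(1 - a e^{-rt})$
(with $r = b - d$, $a = d/b$), which reduces *exactly* to `pureBirth` at
$a = 0$ — so on trees without extinction signal the two print equal
log-likelihoods and bd trails by its extra parameter, the familiar
pattern in published tables. Regimes that end up with zero events take
the boundary rate, floored at $10^{-8}$ so rates stay positive while the
profile log-likelihood equals its limit to within $10^{-8}$.

`deltaAicNullTest()` tests rate constancy with the statistic
AIC(best rate-constant) − AIC(best rate-variable), compared against the
same statistic on pure-birth trees simulated at the pure-birth MLE rate
with the same tip count (add-one-smoothed p-value). A point worth knowing
when reading its output: on pure-birth data the *ranking* alone picks a
rate-variable model roughly 40–50% of the time (three flexible RV models
compete against effectively one RC model), which is exactly why the null
distribution is simulated instead of trusting the ranking.

`truncateRecentHistory()` slices the tree at a fraction of its depth
(default the youngest 5%), turning every crossing lineage into a tip; a
recent rate shift that lives inside the slice disappears, so a
rate-constant model is expected back within a small ΔAIC of the best
model after truncation — the protracted-speciation diagnostic.
`lttPoints()` exports the lineage-through-time step function on relative
time (root = −1, present = 0).

## Niche statistics

On habitat-suitability grids normalized to probability surfaces,
`nicheOverlapStats()` returns Schoener's
$D = 1 - \tfrac12\sum|p_1 - p_2|$, the Hellinger-based
$I = 1 - \tfrac12\sum(\sqrt{p_1} - \sqrt{p_2})^2$ (so $I \ge D$ always),
and a relative-rank statistic RR — the proportion of valid cell pairs
whose suitability ordering agrees between the grids, ties counting one
half, computed exactly up to 2000 cells and by seeded pair sampling above
(the reference tool's exact RR estimator is unpublished; this Kendall-style
concordance is our documented dialect). `nicheBreadth()` is the
standardized Levins measure $B = (1/\sum p_i^2 - 1)/(n - 1) \in [0, 1]$.
Because the surfaces are normalized, all statistics are invariant to
positive rescaling of the input (raw vs cumulative scores) but not to
monotone transforms, which is the main caveat when comparing fitted
habitat models from different software. Model fitting itself is out of
scope: the statistics operate on given grids.

## The synthetic-data generators

All generators (`simTree`, `simSpeciesCoalescentTree`, `simSequencesK80`,
`makePlantedGapDataset`, `assignMorphospeciesLabels`,
`makeSuitabilityGrids`) seed the global RNG explicitly and embed their
full parameter list, including the seed, in a `simSpec` attribute, so any
output regenerates bit-identically.

* `simTree()` runs a forward Gillespie simulation conditioned on the tip
  count. The two-rate variant places the shift exactly `shiftAge` before
  the present by running the first phase to $N$ tips and conditioning the
  terminal window (rate $r_2$) on no further birth — a bounded rejection
  that reproduces a recent slowdown with the shift age and tip count both
  exact, and leaves the first-phase rate estimate unbiased.
* `simSpeciesCoalescentTree()` grafts Kingman-style coalescent genealogies
  onto a Yule species tree. The `separation` parameter is enforced on the
  *realized* coalescent depths (redraw while a depth exceeds
  $2\,t_{\min}/\text{separation}$, with $t_{\min}$ the youngest speciation
  age), because exponential coalescent tails otherwise produce occasional
  species whose internal depth rivals the species ages, which is not the
  regime the separation factor is meant to describe.
* `simSequencesK80()` evolves sequences site-independently under the K80
  kernel (closed-form transition probabilities), matching the distance
  model used by the analysis; `makePlantedGapDataset()` builds a
  star-like species scaffold with long stems and shallow within-species
  caterpillars, then verifies the realized K2P distances against the
  requested intra/inter band and regenerates on violation (bounded), so
  its ground truth is recovered *exactly* by any threshold inside the gap.

What the generators do **not** emulate: rate variation across sites and
lineages, recombination, indel evolution and alignment error, sampling
bias across species, and real spatial autocorrelation in suitability
surfaces. Tests passing on these fixtures therefore demonstrate
correctness of the algorithms under their own model assumptions, not
robustness to the full messiness of empirical barcodes.

## Numerical choices and degenerate inputs

* Ultrametricity is checked with a relative tip-age tolerance of $10^{-6}$
  (typical dating-software output passes); the check can be relaxed to a
  warning but never skipped silently.
* Sequences are compared after uppercase/`U→T` normalisation; haplotype
  collapse requires exact string equality, so sequences differing only in
  missing data are *not* merged (conservative; avoids chaining through
  `N` runs).
* Threshold clustering handles `Inf` (saturated) distances by mapping them
  above every finite cutoff; ABGD treats a saturated pair above an
  otherwise gap-free finite range as a gap beyond any prior.
* Tie-breaks: equal-likelihood GMYC thresholds and `yule2rate` shift times
  resolve to the oldest candidate; AIC ties rank the model with fewer
  parameters first.
* Typical problem sizes in the test-suite and acceptance runs: 40–100-tip
  trees, 25–50 replicate simulations per performance check, 60–500 null
  simulations per rate-constancy test. These are the sizes at which the
  checked proportions are stable to a few percent.

## Worked example

```{r example, eval = FALSE}
pg <- makePlantedGapDataset(nSpecies = 8, tipsPerSpecies = 5,
                            intraMax = 0.01, interMin = 0.06,
                            length = 607, seed = 1)
out <- runDelimitation(pg$alignment, tree = pg$tree,
                       methods = c("threshold", "abgd", "gmyc", "sp"),
                       labels = assignMorphospeciesLabels(pg$partition,
                                                          nLumps = 2,
                                                          nSplits = 0,
                                                          seed = 1))
out$blockCounts
out$crossval$counts

div <- runDivTest(simTree(45, "yule2rate", rate = 30, r2 = 6,
                          shiftAge = 0.004, seed = 2),
                  nSims = 500, seed = 3, truncateFraction = 0.05)
div$table
div$nullTest$p
```

## Known limitations

* The delimitation methods are single-locus by design; mitochondrial
  introgression or incomplete lineage sorting can mislead all five at
  once, which is precisely why the consensus is conservative and the
  cross-validation reports disagreement rather than resolving it.
* The ABGD gap rule and the SP parsimony probability are documented
  dialects of their reference tools; block counts on real data can differ
  slightly from those tools even when the planted-gap behaviour is
  identical.
* GMYC entity counts are sensitive to the ultrametric tree's quality; the
  method is applied to the tree it is given and does not model dating
  uncertainty.
* The diversification likelihoods are unconditioned on survival, so their
  absolute values are comparable only within this package's convention.
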