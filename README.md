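# LineageDelim

Integrative molecular species delimitation and diversification analysis
for DNA-barcode data, written for groups — such as carychiid microsnails —
whose shell-based morphospecies hypotheses routinely hide or split
separately evolving lineages.

The package implements five single-locus delimitation methods on one
common currency (a partition of specimens into evolutionary lineages,
ELs), merges them conservatively, cross-validates the result against
morphology, and analyses the tempo of lineage diversification:

* **3.2% K2P threshold** — single-linkage clustering of Kimura
  two-parameter distances, `d = -½ ln[(1-2P-Q)√(1-2Q)]`, with pairwise
  deletion of gaps/ambiguities and per-pair effective site counts.
* **ABGD** — recursive barcode-gap discovery: split where
  `d[i+1] - d[i] > X·d[i]` beyond a prior intraspecific divergence,
  scanned over a geometric series of priors (50 screening steps).
* **GMYC** (single- and multiple-threshold) — maximum-likelihood mixed
  Yule-coalescent model on an ultrametric tree, with likelihood-ratio
  tests against the single-class null.
* **Statistical parsimony** — haplotype networks connected up to the 95%
  parsimony connection limit; connected components are the entities.
* **Conservative consensus** — the partition-lattice join ("the most
  comprehensive grouping predicted by any method") plus morphospecies
  cross-validation (match / split / lumped / mixed).

Downstream, `modelSelectionTable()` fits pureBirth, birth-death, DDL, DDX
and yule2rate models to branching times and ranks them by
`AIC = 2P - 2 lnL`; `deltaAicNullTest()` calibrates the rate-constancy
statistic against simulated pure-birth trees; `truncateRecentHistory()`
re-runs the comparison without the youngest slice of the tree (the
protracted-speciation diagnostic); `lttPoints()` exports
lineage-through-time curves; and `nicheOverlapStats()` /
`nicheBreadth()` compute Schoener's D, Hellinger I, relative rank and
Levins breadth on habitat-suitability grids.

Seeded generators (`simTree`, `simSpeciesCoalescentTree`,
`simSequencesK80`, `makePlantedGapDataset`, `assignMorphospeciesLabels`,
`makeSuitabilityGrids`) produce data with known ground truth for every
stage.

## Worked example

Delimit a synthetic barcode dataset with a planted gap (8 species × 5
specimens, 607 bp) with all four methods, join them, and cross-validate
against morphospecies labels carrying two deliberate lumping errors:

```r
library(LineageDelim)

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
#> threshold      abgd      gmyc        sp consensus
#>         8         8         8         8         8
out$crossval$counts
#> matches   split  lumped   mixed
#>       4       2       0       0
```

All four methods recover the 8 planted lineages exactly, as does the
consensus; the two lumped morphospecies names are reported as "split"
(each spans two pure ELs — molecular data subdivide the name).

Diversification analysis of a 45-tip tree with a recent rate slowdown
(r1 = 30 → r2 = 6 at age 0.004):

```r
div <- runDivTest(simTree(45, "yule2rate", rate = 30, r2 = 6,
                          shiftAge = 0.004, seed = 2),
                  nSims = 500, seed = 3, truncateFraction = 0.05)
div$table[, c("model", "mtype", "P", "LH", "AIC", "dAIC")]
#>       model mtype P       LH       AIC   dAIC
#> 1 yule2rate    RV 3 229.0786 -452.1573 0.0000
#> 2 pureBirth    RC 1 223.9346 -445.8691 6.2881
#> 3       DDX    RV 2 224.0392 -444.0783 8.0790
#> 4        bd    RC 2 224.0238 -444.0476 8.1097
#> 5       DDL    RV 2 223.9346 -443.8691 8.2881
div$nullTest$p
#> [1] 0.04191617
div$truncated$table$model[1]
#> [1] "bd"
```

The two-rate model wins before truncation (ΔAIC 6.3 over pureBirth, null
test p = 0.042, estimated shift at age 0.004); after cutting the youngest
5% of the history a rate-constant model leads the table — the shift lived
entirely in the removed slice.

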