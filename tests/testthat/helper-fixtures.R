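# Shared helpers: hand-built trees, independent oracles, random fixtures.

# independent union-find oracle: connected components of the graph with an
# edge wherever d[i, j] <= cutoff
ufComponents <- function(d, cutoff) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.finite(d[i, j]) && d[i, j] <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# are two integer/character groupings the same partition (up to labels)?
sameGrouping <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# random symmetric distance matrix with ids
randomDistMatrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, 0.2)
  m <- m + t(m)
  ids <- sprintf("s%02d", seq_len(n))
  new("GeneticDistances", ids = ids, d = m,
      sites = matrix(100L, n, n), model = "K2P")
}

# random partition over given ids
randomPartition <- function(ids, k, seed) {
  set.seed(seed)
  lineagePartition(setNames(as.character(sample.int(k, length(ids),
                                                    replace = TRUE)), ids))
}

# a 6-tip hand tree with two clear levels: three cherries at ages
# 0.1 / 0.15 / 0.12 joined deep at ages 2 and 3
handTree6 <- function() {
  ape::read.tree(text = paste0(
    "(((a1:0.1,a2:0.1):2.9,(b1:0.15,b2:0.15):2.85):1,",
    "(c1:0.12,c2:0.12):3.88);"))
}
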