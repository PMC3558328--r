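test_that("K2P distance matches hand evaluation of the closed form", {
  # identical sequences
  r0 <- k2pDistance(strrep("A", 100), strrep("A", 100))
  expect_equal(r0$d, 0)
  expect_equal(r0$P, 0)
  expect_equal(r0$Q, 0)
  # 10 transitions in 100 sites: d = -0.5 ln(0.8)
  r1 <- k2pDistance(strrep("A", 100),
                    paste0(strrep("A", 90), strrep("G", 10)))
  expect_equal(r1$P, 0.10)
  expect_equal(r1$Q, 0)
  expect_equal(r1$d, -0.5 * log(1 - 2 * 0.10), tolerance = 1e-9)
  # P = Q = 0.25: d = -0.5 ln(0.25 * sqrt(0.5))
  a <- paste0(strrep("A", 50), strrep("C", 50))
  b <- paste0(strrep("G", 25), strrep("A", 25),   # 25 transitions
              strrep("A", 25), strrep("C", 25))   # 25 transversions
  r2 <- k2pDistance(a, b)
  expect_equal(r2$P, 0.25)
  expect_equal(r2$Q, 0.25)
  expect_equal(r2$d, -0.5 * log(0.25 * sqrt(0.5)), tolerance = 1e-9)
  # same value via the equivalent two-term form of the K2P estimator
  expect_equal(r2$d, 0.5 * log(1 / 0.25) + 0.25 * log(1 / 0.5),
               tolerance = 1e-9)
})

test_that("pairwise deletion excludes gaps, N and ambiguity codes", {
  r <- k2pDistance("ACGT-NRAC", "ACGAANGAC")
  # comparable sites: positions 1,2,3,4,9 minus none -> gap at 5, N at 6, R at 7
  expect_equal(r$nSites, 6L)
  expect_error(k2pDistance("NNNN", "ACGT"), "no comparable sites")
})

test_that("saturation flags d as Inf rather than erroring", {
  r <- k2pDistance(strrep("A", 10), strrep("G", 10))  # P = 1
  expect_true(r$saturated)
  expect_true(is.infinite(r$d))
})

test_that("K2P is symmetric and dominates the raw p-distance", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    x <- paste(sample(bases, 50, TRUE), collapse = "")
    y <- paste(sample(bases, 50, TRUE), collapse = "")
    rxy <- k2pDistance(x, y)
    ryx <- k2pDistance(y, x)
    expect_identical(rxy[c("d", "P", "Q")], ryx[c("d", "P", "Q")])
    if (is.finite(rxy$d)) {
      p <- rxy$P + rxy$Q
      expect_gte(rxy$d, p)
      if (p > 0) expect_gt(rxy$d, p)
    }
  }
})

test_that("matrix construction agrees with ape::dist.dna on random data", {
  skip_if_not_installed("ape")
  tr <- simTree(12, "yule", rate = 1, seed = 9)
  aln <- simSequencesK80(tr, length = 400, kappa = 4, scale = 0.05, seed = 2)
  dm <- buildDistanceMatrix(aln, "K2P")
  bin <- ape::as.DNAbin(strsplit(tolower(alignedSeqs(aln)), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(distanceMatrix(dm)[rownames(ref), colnames(ref)],
               ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("matrix equals pair-by-pair calls and zero for identical input", {
  aln <- barcodeAlignment(c("a", "b", "c"),
                          c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"))
  expect_true(all(distanceMatrix(buildDistanceMatrix(aln)) == 0))
  aln2 <- barcodeAlignment(c("a", "b"), c("AAAA", "AAAT"))
  expect_equal(distanceMatrix(buildDistanceMatrix(aln2, "HAMMING"))["a", "b"], 1)
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  seqs <- replicate(4, paste(sample(bases, 60, TRUE), collapse = ""))
  aln3 <- barcodeAlignment(letters[1:4], seqs)
  dm <- buildDistanceMatrix(aln3)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(distanceMatrix(dm)[i, j],
                 k2pDistance(seqs[i], seqs[j])$d)
  }
})

test_that("PHYLIP export writes a readable square matrix", {
  aln <- barcodeAlignment(c("a", "b", "c"),
                          c("ACGTACGTAC", "ACGTACGTAT", "ACGAACGTAT"))
  dm <- buildDistanceMatrix(aln)
  f <- withr::local_tempfile(fileext = ".phy")
  writePhylipDistances(dm, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  row2 <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  expect_equal(row2[1], "b")
  expect_equal(as.numeric(row2[-1]), unname(distanceMatrix(dm)["b", ]),
               tolerance = 1e-5)
})

test_that("haplotype collapsing is exact-match and conserves specimens", {
  aln <- barcodeAlignment(paste0("s", 1:5),
                          c("AAAA", "AAAA", "AAAT", "AAAA", "AAAT"))
  h <- collapseHaplotypes(aln)
  expect_equal(length(h$members), 2L)
  expect_equal(sort(h$members$H1), c("s1", "s2", "s4"))
  expect_equal(sum(lengths(h$members)), 5L)
  # N-differing sequences are not merged
  alnN <- barcodeAlignment(c("a", "b"), c("AAAA", "AAAN"))
  expect_equal(length(collapseHaplotypes(alnN)$members), 2L)
  # all distinct -> identity map
  alnD <- barcodeAlignment(c("a", "b"), c("AAAA", "TTTT"))
  expect_equal(lengths(collapseHaplotypes(alnD)$members),
               c(H1 = 1L, H2 = 1L))
})
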