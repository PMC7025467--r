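test_that("anchoring filter keeps chromosomes 1-19 only, order preserved", {
  G <- mkGeno(matrix(0L, 6, 2), chrom = c("1", "unanchored", "5", "19",
                                          "unanchored", "2"),
              pos = c(10L, 5L, 7L, 3L, 9L, 1L))
  out <- filterAnchoredSnps(G)
  expect_equal(snpInfo(out)$chrom, c("1", "5", "19", "2"))
  expect_equal(snpInfo(out)$id, snpInfo(G)$id[c(1, 3, 4, 6)])
  ## all anchored -> identity
  G2 <- mkGeno(matrix(1L, 3, 2))
  expect_equal(calls(filterAnchoredSnps(G2)), calls(G2))
})

test_that("missingness filter drops samples first, then SNPs (two-pass)", {
  ## sample with 3/10 missing at threshold 0.2 is removed
  calls <- matrix(0L, 10, 4)
  calls[1:3, 1] <- NA
  G <- mkGeno(calls)
  out <- filterMissingness(G)
  expect_equal(nSamples(out), 3L)
  expect_equal(attr(out, "removedSamples"), "ind1")
  ## fully observed -> identity
  G0 <- mkGeno(matrix(2L, 4, 3))
  expect_equal(dim(calls(filterMissingness(G0))), c(4L, 3L))
  ## crafted 5x6: SNP 1 missing in the bad sample + once elsewhere (2/6 raw
  ## > 0.2) but exactly 1/5 after the bad sample goes -> retained by the
  ## two-pass rule, removed by a one-pass rule
  cl <- matrix(0L, 5, 6)
  cl[, 1] <- NA            # bad sample: 100% missing
  cl[1, 2] <- NA           # SNP 1: one more miss among good samples
  G5 <- mkGeno(cl)
  out5 <- filterMissingness(G5, sampleMax = 0.2, snpMax = 0.2)
  expect_true("s1" %in% snpInfo(out5)$id)          # two-pass keeps it
  expect_true(rowMeans(is.na(cl))[1] > 0.2)        # one-pass would not
  expect_error(filterMissingness(mkGeno(matrix(NA_integer_, 2, 2))),
               "all data filtered")
})

test_that("MAF filter removes monomorphic SNPs, keeps the exact boundary", {
  ## 50 diploids: 1 alt allele = MAF 0.01 exactly -> retained
  cl <- matrix(0L, 3, 50)
  cl[2, 1] <- 1L                     # MAF = 1/100 = 0.01
  cl[3, ] <- c(2L, rep(0L, 49))      # MAF 0.02
  G <- mkGeno(cl)
  out <- filterMaf(G, 0.01)
  expect_equal(snpInfo(out)$id, c("s2", "s3"))  # monomorphic s1 dropped
  ## random fixture against a brute-force MAF scan
  set.seed(11)
  cl2 <- matrix(sample(c(0:2, NA), 40 * 30, TRUE, prob = c(.6, .2, .1, .1)),
                40, 30)
  G2 <- mkGeno(cl2)
  out2 <- filterMaf(G2, 0.05)
  maf <- apply(cl2, 1, function(v) {
    f <- sum(v, na.rm = TRUE) / (2 * sum(!is.na(v)))
    min(f, 1 - f)
  })
  expect_equal(snpInfo(out2)$id, snpInfo(G2)$id[!is.na(maf) & maf >= 0.05])
})

test_that("filters are idempotent", {
  set.seed(2)
  cl <- matrix(sample(c(0:2, NA), 30 * 20, TRUE, prob = c(.5, .2, .2, .1)),
               30, 20)
  G <- mkGeno(cl)
  f1 <- filterMissingness(filterMaf(G, 0.05), 0.25, 0.25)
  f2 <- filterMissingness(filterMaf(f1, 0.05), 0.25, 0.25)
  expect_equal(calls(f2), calls(f1))
})

test_that("exclusion lists drop known samples and warn about unknown ids", {
  G <- mkGeno(matrix(0L, 3, 4))
  out <- applyExclusionList(G, c("ind1", "ind3"))
  expect_equal(sampleIds(out), c("ind2", "ind4"))
  expect_equal(nSamples(applyExclusionList(G, character(0))), 4L)
  expect_warning(out2 <- applyExclusionList(G, c("ind2", "ghost")), "ghost")
  expect_equal(sampleIds(out2), c("ind1", "ind3", "ind4"))
})

test_that("species subsetting composes restrict + mind + within-subset MAF", {
  set.seed(5)
  cl <- matrix(sample(0:2, 20 * 15, TRUE), 20, 15)
  cl[1:6, 1] <- NA                       # species-a sample, 30% missing
  cl[7, 2:5] <- 0L                       # monomorphic within species a
  cl[7, 6:15] <- 1L
  G <- mkGeno(cl)
  pm <- setNames(rep(c("a", "b", "c"), each = 5), sampleIds(G))
  sub <- speciesSubset(G, pm, "a", mind = 0.2, maf = 0.01)
  expect_equal(nSamples(sub), 4L)        # high-missing sample dropped
  expect_false("s7" %in% snpInfo(sub)$id)  # monomorphic-in-subset dropped
  ## equals the sequential oracle
  keep <- which(pm[sampleIds(G)] == "a")
  sub0 <- admixkit:::subsetGenotypes(G, sampleKeep = keep)
  sm <- colMeans(is.na(calls(sub0)))
  sub0 <- admixkit:::subsetGenotypes(sub0, sampleKeep = which(sm <= 0.2))
  oracle <- filterMaf(sub0, 0.01)
  expect_equal(calls(sub), calls(oracle))
  expect_error(speciesSubset(G, pm, "zz"), "not present")
})
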