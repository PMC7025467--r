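test_that("pairwise r2 is 1 for identical SNPs and respects the window", {
  cl <- rbind(c(0L, 1L, 2L, 0L, 1L), c(0L, 1L, 2L, 0L, 1L),
              c(2L, 1L, 0L, 2L, 1L))
  G <- mkGeno(cl, pos = c(1e5L, 2e5L, 6.5e5L))
  pr <- pairwiseLdR2(G, windowKb = 500)
  expect_equal(nrow(pr), 2)                       # s1-s3 is 550 kb: excluded
  r12 <- pr$r2[pr$snp_i == "s1" & pr$snp_j == "s2"]
  expect_equal(r12, 1)
  ## r2 invariant under 0<->2 relabeling at one SNP (s3 = flipped s1)
  r13 <- pr$r2[pr$snp_i == "s2" & pr$snp_j == "s3"]
  expect_equal(r13, 1)
})

test_that("independent SNPs give near-zero mean r2", {
  set.seed(21)
  vals <- replicate(100, {
    cl <- matrix(rbinom(2 * 200, 2, 0.4), 2, 200)
    G <- mkGeno(cl, pos = c(1000L, 2000L))
    pairwiseLdR2(G)$r2
  })
  expect_lt(mean(unlist(vals)), 0.02)
})

test_that("decay bins partition sorted pairs and use the median", {
  pairs <- data.frame(snp_i = "a", snp_j = "b",
                      distance = seq_len(150) * 100, r2 = runif(150))
  expect_equal(nrow(ldDecayBins(pairs, 75)), 2)
  b3 <- ldDecayBins(data.frame(snp_i = "a", snp_j = "b",
                               distance = c(10, 20, 30),
                               r2 = c(0.1, 0.2, 0.9)), 3)
  expect_equal(b3$median_r2, 0.2)
  expect_equal(b3$mean_distance, 20)
})

test_that("simulated within-block LD decays with distance", {
  g <- admixtureGraph(ape::read.tree(text = "(a:0.01,b:0.01);"))
  spec <- simSpec(g, nSnps = 600, chromLengths = 5e6, samplesPerPop = 120,
                  ldBlockSnps = 15, ldRho = 0.9)
  sim <- simulateFrequencies(spec, seed = 31)
  G <- simulateGenotypes(sim, spec, seed = 32)
  Ga <- admixkit:::subsetGenotypes(G, sampleKeep = grep("^a_", sampleIds(G)))
  bins <- ldDecayBins(pairwiseLdR2(Ga, windowKb = 5000), 75)
  rho <- cor(bins$mean_distance, bins$median_r2, method = "spearman")
  expect_lt(rho, 0)
})

test_that("block midpoints follow the range rule and split at chromosomes", {
  snps <- data.frame(id = paste0("s", 1:5), chrom = "1",
                     pos = c(100, 200, 300, 400, 500) * 1000L)
  expect_equal(blockMidpoints(snps, 5)[["1"]], 300000)
  ## 4+1 straddling block: two midpoints, one per chromosome
  snps2 <- data.frame(id = paste0("s", 1:5),
                      chrom = c("1", "1", "1", "1", "2"),
                      pos = c(1e5, 2e5, 3e5, 4e5, 1e4))
  m2 <- blockMidpoints(snps2, 5)
  expect_equal(m2[["1"]], (1e5 + 4e5) / 2)
  expect_equal(m2[["2"]], 1e4)
  ## random map vs brute-force enumeration
  set.seed(41)
  rm <- data.frame(id = paste0("s", 1:137),
                   chrom = as.character(sort(sample(1:4, 137, TRUE))),
                   pos = 0L)
  for (ch in unique(rm$chrom))
    rm$pos[rm$chrom == ch] <- sort(sample.int(3e6, sum(rm$chrom == ch)))
  got <- blockMidpoints(rm, 10)
  want <- midpointOracle(rm, 10)
  for (ch in unique(want$chrom))
    expect_equal(got[[ch]], want$mid[want$chrom == ch])
})

test_that("every SNP belongs to exactly one block for any k", {
  for (k in c(1, 3, 7, 20)) {
    ids <- admixkit:::snpBlockIds(53, k)
    expect_equal(length(ids), 53)
    expect_true(all(table(ids)[-length(table(ids))] == k))
  }
})

test_that("block-size search matches exhaustive enumeration and monotone in
           threshold", {
  ## single chromosome, SNPs every 300 kb, threshold 200 -> k = 5
  snps <- data.frame(id = paste0("s", 1:100), chrom = "1",
                     pos = as.integer(seq(3e5, 3e7, by = 3e5)))
  expect_equal(determineBlockSize(snps, 200, 5, 5)$k, 5)
  ## dense 100-SNP cluster spanning 50 kb forces k beyond 5
  dense <- data.frame(id = paste0("d", 1:160), chrom = "1",
                      pos = as.integer(c(seq(1e6, 1.05e6, length.out = 100),
                                         seq(2e6, 2e7, length.out = 60))))
  got <- determineBlockSize(dense, 200, 5, 5)
  expect_gt(got$k, 5)
  expect_equal(got$k, blockSizeOracle(dense, 200))
  ## 50 random maps against the oracle; monotone in threshold
  set.seed(51)
  for (r in 1:50) {
    nc <- sample(2:4, 1)
    n <- sample(60:140, 1)
    mp <- data.frame(id = paste0("s", 1:n),
                     chrom = as.character(sort(sample(seq_len(nc), n, TRUE))),
                     pos = 0L)
    for (ch in unique(mp$chrom))
      mp$pos[mp$chrom == ch] <- sort(sample.int(2e7, sum(mp$chrom == ch)))
    expect_equal(determineBlockSize(mp, 150, 5, 5)$k,
                 blockSizeOracle(mp, 150))
    k1 <- determineBlockSize(mp, 100, 5, 5)$k
    k2 <- determineBlockSize(mp, 400, 5, 5)$k
    expect_lte(k1, k2)
  }
  ## an extreme threshold is eventually satisfied vacuously (one block
  ## part per chromosome has no consecutive-midpoint gaps)
  expect_lte(determineBlockSize(snps, 1e6, 5, 5)$k, 100)
})
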