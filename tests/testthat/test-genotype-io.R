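test_that("TSV round-trip preserves calls and sorts SNPs into genome order", {
  calls <- matrix(c(0L, 1L, 2L, NA, 2L, 0L, 1L, 1L, 0L, 2L, NA, 0L), 4, 3)
  ## map listed out of position order; chrom 2 before chrom 1
  snps <- data.frame(id = c("d", "c", "b", "a"),
                     chrom = c("2", "1", "1", "2"),
                     pos = c(500L, 900L, 100L, 200L))
  G <- GenotypeMatrix(calls, snps, sort = FALSE)
  colnames(G@calls) <- c("s1", "s2", "s3")
  tsv <- tempfile(fileext = ".tsv")
  writeGenotypeTable(G, tsv)
  G2 <- readGenotypeTable(tsv, "tsv")
  expect_equal(dim(calls(G2)), c(4L, 3L))
  ## sort oracle: order by (chrom, pos)
  o <- order(as.integer(snps$chrom), snps$pos)
  expect_equal(snpInfo(G2)$id, snps$id[o])
  expect_true(all(diff(snpInfo(G2)$pos[snpInfo(G2)$chrom == "1"]) > 0))
  ## values survive the round trip (match rows by id)
  expect_equal(unname(calls(G2)[match(snps$id, snpInfo(G2)$id), ]),
               unname(calls))
})

test_that("malformed genotype rows are rejected with the offending line", {
  tsv <- tempfile(fileext = ".tsv")
  map <- sub("\\.tsv$", ".map", tsv)
  writeLines(c("sample\ts1\ts2", "a\t0\t3", "b\t1\t2"), tsv)
  writeLines(c("id\tchrom\tpos", "s1\t1\t100", "s2\t1\t200"), map)
  expect_error(readGenotypeTable(tsv, "tsv"), "line 2")
  writeLines(c("sample\ts1\ts2", "a\t0\t1", "b\t1"), tsv)
  expect_error(readGenotypeTable(tsv, "tsv"), "line 3")
  ## duplicate SNP id
  writeLines(c("sample\ts1\ts1", "a\t0\t1"), tsv)
  expect_error(readGenotypeTable(tsv, "tsv"), "duplicate")
})

test_that("PLINK-style .ped/.map text reads with minor-allele counting", {
  ped <- tempfile(fileext = ".ped")
  map <- sub("\\.ped$", ".map", ped)
  ## 3 samples, 2 SNPs; SNP1 minor allele = T (freq 2/6), SNP2 has missing
  writeLines(c("f1 i1 0 0 0 -9 A T A A",
               "f2 i2 0 0 0 -9 A A 0 0",
               "f3 i3 0 0 0 -9 A T G A"), ped)
  writeLines(c("1\tsnp1\t0\t100", "3\tsnp2\t0\t50"), map)
  G <- readGenotypeTable(ped, "plink")
  expect_equal(sampleIds(G), c("i1", "i2", "i3"))
  expect_equal(unname(calls(G)["snp1", ]), c(1L, 0L, 1L))
  ## snp2: alleles A (3) and G (1): G minor -> calls 0, NA, 1
  expect_equal(unname(calls(G)["snp2", ]), c(0L, NA, 1L))
})

test_that("stratified allele counts sum calls over non-missing individuals", {
  ## one population, calls (0,2) -> (2,4); (1,missing) -> (1,2)
  G <- mkGeno(rbind(c(0L, 2L), c(1L, NA)))
  pm <- setNames(c("p1", "p1"), sampleIds(G))
  T <- stratifiedAlleleFreqs(G, pm)
  expect_equal(unname(alleleCounts(T)[, 1]), c(2L, 1L))
  expect_equal(unname(alleleTotals(T)[, 1]), c(4L, 2L))
})

test_that("stratified counts equal a brute-force per-population tally", {
  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 25 * 12, TRUE, prob = c(.4, .3, .2, .1)),
                  25, 12)
  G <- mkGeno(calls)
  pm <- setNames(rep(c("a", "b", "c"), each = 4), sampleIds(G))
  T <- stratifiedAlleleFreqs(G, pm)
  flip <- snpInfo(T)$flipped
  kept <- match(snpInfo(T)$id, snpInfo(G)$id)
  for (p in c("a", "b", "c")) {
    sub <- calls[kept, pm[sampleIds(G)] == p, drop = FALSE]
    sub[flip, ] <- 2L - sub[flip, ]
    expect_equal(unname(alleleCounts(T)[, match(p, populations(T))]),
                 unname(as.integer(rowSums(sub, na.rm = TRUE))))
    expect_equal(unname(alleleTotals(T)[, match(p, populations(T))]),
                 unname(as.integer(2 * rowSums(!is.na(sub)))))
  }
  ## allele conservation: counts over populations = non-missing call sum
  cl <- calls[kept, ]; cl[flip, ] <- 2L - cl[flip, ]
  expect_equal(unname(rowSums(alleleCounts(T))),
               unname(rowSums(cl, na.rm = TRUE)))
  expect_error(stratifiedAlleleFreqs(G, pm[-1]), "without population")
})

test_that("TreeMix frequency format writes a,b pairs and round-trips", {
  T <- mkFreqTable(cbind(2L, 0L), cbind(4L, 6L), c("p1", "p2"))
  gz <- tempfile(fileext = ".gz")
  writeTreemixFreqs(T, gz)
  lines <- readLines(gzfile(gz))
  expect_equal(lines[1], "p1 p2")
  expect_equal(lines[2], "2,2 0,6")
  ## round-trip on a simulated 30-population x 1000-SNP table
  set.seed(3)
  tot <- matrix(2L * sample(5:30, 30000, TRUE), 1000, 30)
  cnt <- matrix(rbinom(30000, as.vector(tot), 0.3), 1000, 30)
  big <- mkFreqTable(cnt, tot, paste0("pop", 1:30))
  writeTreemixFreqs(big, gz)
  back <- readTreemixFreqs(gz)
  expect_equal(back@counts, big@counts, ignore_attr = TRUE)
  expect_equal(back@totals, big@totals, ignore_attr = TRUE)
  expect_equal(populations(back), populations(big))
})

test_that("TreeMix reader rejects malformed files", {
  gz <- tempfile(fileext = ".gz")
  con <- gzfile(gz, "wt")
  writeLines(c("p1 p2 p3", "2,2 0,6"), con); close(con)
  expect_error(readTreemixFreqs(gz), "header")
  con <- gzfile(gz, "wt")
  writeLines(c("p1 p2", "2,-1 0,6"), con); close(con)
  expect_error(readTreemixFreqs(gz), "negative|non-integer")
})
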