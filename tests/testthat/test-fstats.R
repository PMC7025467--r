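test_that("f3 matches hand values and a per-SNP enumeration oracle", {
  ## x=0.5, y=0, w=1 at every SNP, no correction -> -0.25
  T <- mkFreqTable(cbind(rep(20L, 40), 0L, 40L), matrix(40L, 40, 3),
                   c("X", "Y", "W"))
  r <- f3Admixture(T, "X", "Y", "W", block = 10, biasCorrect = FALSE)
  expect_equal(r@estimate, -0.25)
  expect_true(is.na(r@z))   # zero-variance blocks: SE 0, Z undefined
  ## Y and W identical -> mean (x-y)^2 >= 0
  set.seed(61)
  cnt <- cbind(rbinom(40, 40, 0.5), rbinom(40, 40, 0.3))
  T2 <- mkFreqTable(cbind(cnt[, 1], cnt[, 2], cnt[, 2]), matrix(40L, 40, 3),
                    c("X", "Y", "W"))
  r2 <- f3Admixture(T2, "X", "Y", "W", block = 10, biasCorrect = FALSE)
  expect_gte(r2@estimate, 0)
  expect_equal(r2@estimate, mean((cnt[, 1] / 40 - cnt[, 2] / 40)^2))
  ## 6-SNP hand table vs direct evaluation, with bias correction
  cx <- c(3L, 10L, 7L, 0L, 12L, 5L); nx <- c(16L, 20L, 18L, 10L, 20L, 12L)
  cy <- c(1L, 8L, 9L, 2L, 15L, 4L); cw <- c(6L, 2L, 7L, 5L, 3L, 9L)
  T3 <- mkFreqTable(cbind(cx, cy, cw),
                    cbind(nx, rep(20L, 6), rep(16L, 6)),
                    c("X", "Y", "W"))
  x <- cx / nx; y <- cy / 20; w <- cw / 16
  u <- (x - y) * (x - w) - x * (1 - x) / (nx - 1)
  r3 <- f3Admixture(T3, "X", "Y", "W", block = 3)
  expect_equal(r3@estimate, mean(u))
  expect_equal(r3@z, r3@estimate / r3@se)
  ## symmetry in the two references
  r3b <- f3Admixture(T3, "X", "W", "Y", block = 3)
  expect_equal(r3b@estimate, r3@estimate)
  expect_error(f3Admixture(T3, "X", "X", "W"), "distinct")
})

test_that("f4 is zero for identical references and antisymmetric in X,Y", {
  set.seed(62)
  cnt <- matrix(rbinom(200 * 4, 30, 0.4), 200, 4)
  T <- mkFreqTable(cbind(cnt[, 1:3], cnt[, 3]), matrix(30L, 200, 4),
                   c("X", "Y", "W", "Z"))
  expect_equal(f4Stat(T, "X", "Y", "W", "Z")@estimate, 0)
  T2 <- mkFreqTable(cnt, matrix(30L, 200, 4), c("X", "Y", "W", "Z"))
  a <- f4Stat(T2, "X", "Y", "W", "Z")
  b <- f4Stat(T2, "Y", "X", "W", "Z")
  d <- f4Stat(T2, "W", "Z", "X", "Y")
  expect_equal(a@estimate, -b@estimate)
  expect_equal(abs(a@z), abs(b@z))
  expect_equal(a@estimate, d@estimate)
})

test_that("f4 additivity holds across an intermediate population", {
  g <- balancedEightTipGraph()
  T <- simTable(g, 2000, 20, seedFreq = 63)
  a <- f4Stat(T, "A", "B", "C", "D")@estimate
  b <- f4Stat(T, "A", "B", "C", "E")@estimate
  d <- f4Stat(T, "A", "B", "E", "D")@estimate
  expect_equal(a, b + d)
})

test_that("outgroup f3 ranks a sister reference above a distant one", {
  ## (((T,R1),R2),O): R1 shares more drift with T than R2 does
  tr <- ape::read.tree(
    text = "(O:0.08,((T:0.02,R1:0.02):0.03,R2:0.05):0.02);")
  g <- admixtureGraph(tr)
  wins <- 0
  for (r in 1:20) {
    T <- simTable(g, 1500, 15, seedFreq = 700 + r)
    f1 <- f3Outgroup(T, "O", "T", "R1")@estimate
    f2 <- f3Outgroup(T, "O", "T", "R2")@estimate
    wins <- wins + (f1 > f2)
  }
  expect_gte(wins, 18)
  ## target = ref upper bound: estimate = mean (o-t)^2 >= 0
  Tt <- simTable(g, 500, 15, seedFreq = 64)
  dup <- mkFreqTable(cbind(alleleCounts(Tt)[, c("O", "T", "T")]),
                     cbind(alleleTotals(Tt)[, c("O", "T", "T")]),
                     c("O", "T", "Tcopy"))
  rs <- f3Outgroup(dup, "O", "T", "Tcopy")
  expect_gte(rs@estimate, 0)
})

test_that("drift-free data give a null outgroup f3 after bias correction", {
  tr0 <- ape::read.tree(text = "(O:0,(T:0,(R1:0,R2:0):0):0);")
  g0 <- admixtureGraph(tr0)
  T0 <- simTable(g0, 3000, 50, seedFreq = 65)
  r <- f3Outgroup(T0, "O", "T", "R1", biasCorrect = TRUE)
  expect_lt(abs(r@z), 3)
})

test_that("zdiff is zero for identical references, large for clear ones", {
  tr <- ape::read.tree(
    text = "(O:0.08,((T:0.02,R1:0.02):0.03,R2:0.05):0.02);")
  g <- admixtureGraph(tr)
  T <- simTable(g, 2000, 15, seedFreq = 66)
  dup <- mkFreqTable(cbind(alleleCounts(T)[, c("O", "T", "R1", "R1")]),
                     cbind(alleleTotals(T)[, c("O", "T", "R1", "R1")]),
                     c("O", "T", "R1", "R1b"))
  expect_equal(zdiffOutgroup(dup, "O", "T", "R1", "R1b")@zdiff, 0)
  big <- 0
  for (r in 1:20) {
    Tr <- simTable(g, 2000, 15, seedFreq = 800 + r)
    big <- big + (zdiffOutgroup(Tr, "O", "T", "R1", "R2")@zdiff > 3)
  }
  expect_gte(big, 18)
})

test_that("weighted block jackknife matches the textbook delete-1 case", {
  ## all blocks identical -> SE = 0, estimate = common value
  jk <- blockJackknife(rep(6, 5), rep(3, 5))
  expect_equal(jk$estimate, 2)
  expect_equal(jk$se, 0)
  ## equal-sized blocks: direct enumeration of the delete-1 jackknife
  set.seed(67)
  v <- rnorm(60)
  sums <- tapply(v, rep(1:6, each = 10), sum)
  jk2 <- blockJackknife(as.numeric(sums), rep(10, 6))
  loo <- sapply(1:6, function(b) mean(v[rep(1:6, each = 10) != b]))
  g <- 6
  seOracle <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  expect_equal(jk2$se, seOracle)
  expect_equal(jk2$loo, unname(loo))
  expect_error(blockJackknife(5, 10), "2 blocks")
})

test_that("Holm-Bonferroni reproduces the hand-enumerated step-down rule", {
  ## m=1: plain alpha test
  expect_true(holmBonferroni(0.04)$reject)
  expect_false(holmBonferroni(0.06)$reject)
  ## p = (0.01, 0.03, 0.04): only 0.01 rejected (0.03 > 0.05/2)
  hb <- holmBonferroni(c(0.01, 0.03, 0.04))
  expect_equal(hb$reject, c(TRUE, FALSE, FALSE))
  expect_equal(hb$p_adjusted, c(0.03, 0.06, 0.06))
  ## all p = 1
  hb1 <- holmBonferroni(rep(1, 4))
  expect_false(any(hb1$reject))
  expect_equal(hb1$p_adjusted, rep(1, 4))
  ## permutation invariance
  p <- c(0.2, 0.001, 0.04, 0.9, 0.012)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(holmBonferroni(p[perm])$p_adjusted,
               holmBonferroni(p)$p_adjusted[perm])
})
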