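## fstats: f3 / f4 statistics with weighted block-jackknife errors.
##
## A SNP enters a statistic only when every argument population has at least
## one sampled allele there (complete-case per statistic); jackknife blocks
## are the same genome-contiguous runs of `block` SNPs used elsewhere in the
## pipeline (TreeMix -k), not per-statistic re-blockings.

#' Weighted delete-one-block jackknife of a ratio-of-sums mean
#'
#' Given per-block sums of a per-SNP quantity and per-block SNP counts,
#' computes the overall mean, the leave-one-block-out estimates, and the
#' weighted jackknife standard error (weights = block sizes; Busing's
#' formula, which reduces to the textbook delete-1 jackknife for equal
#' blocks).
#'
#' @param blockSums numeric vector of per-block sums.
#' @param blockCounts numeric vector of per-block counts (> 0 blocks are
#'   used; zero-count blocks are dropped).
#' @return list with `estimate`, `se`, `loo` (leave-one-out estimates) and
#'   `nBlocks`.
#' @export
blockJackknife <- function(blockSums, blockCounts) {
  keep <- blockCounts > 0
  s <- blockSums[keep]; m <- blockCounts[keep]
  g <- length(s)
  if (g < 2) stop("SE undefined: need at least 2 blocks with data")
  N <- sum(m); S <- sum(s)
  est <- S / N
  loo <- (S - s) / (N - m)
  h <- N / m
  thetaJ <- g * est - sum((1 - m / N) * loo)
  tau <- h * est - (h - 1) * loo
  v <- sum((tau - thetaJ)^2 / (h - 1)) / g
  list(estimate = est, se = sqrt(v), loo = loo, nBlocks = g)
}

## Frequencies, totals and block ids for the argument populations of a
## statistic.  requireN2: population whose total must be >= 2 (bias term).
fstatPrep <- function(T, pops, block, requireN2 = NULL) {
  idx <- match(pops, T@populations)
  if (anyNA(idx)) stop("population not in table: ",
                       paste(pops[is.na(idx)], collapse = ", "))
  tot <- T@totals[, idx, drop = FALSE]
  usable <- rowSums(tot > 0) == length(pops)
  if (!is.null(requireN2)) {
    j <- match(requireN2, pops)
    usable <- usable & tot[, j] >= 2
  }
  if (!any(usable)) stop("no usable SNPs for ",
                         paste(pops, collapse = ", "))
  x <- T@counts[, idx, drop = FALSE] / tot
  list(x = x, tot = tot, usable = usable,
       blockId = snpBlockIds(nrow(tot), block))
}

fstatFromU <- function(u, usable, blockId) {
  sums <- tapply(u[usable], blockId[usable], sum)
  cnts <- tapply(rep(1, sum(usable)), blockId[usable], sum)
  jk <- blockJackknife(as.numeric(sums), as.numeric(cnts))
  jk$nSnps <- sum(usable)
  jk
}

newFStat <- function(statistic, pops, jk, p) {
  z <- if (jk$se > 0) jk$estimate / jk$se else NA_real_
  new("FStatResult", statistic = statistic, populations = pops,
      estimate = jk$estimate, se = jk$se, z = z, p = p(z),
      nBlocks = as.integer(jk$nBlocks), nSnps = as.integer(jk$nSnps),
      loo = as.numeric(jk$loo))
}

#' Admixture f3 statistic: f3(X; Y, W)
#'
#' Per usable SNP, u = (x - y)(x - w), optionally minus the sampling-bias
#' term x(1-x)/(n_X - 1) where n_X is the number of alleles sampled in X
#' (the unbiased three-population estimator).  A significantly negative
#' value is evidence that X is admixed between sources related to Y and W;
#' the reported p is the one-sided lower normal tail of Z = estimate/SE.
#'
#' @param T an [AlleleFreqTable-class].
#' @param X,Y,W distinct population labels (X the test taxon).
#' @param block jackknife block size in SNPs.
#' @param biasCorrect subtract the X sampling-bias term? Default `TRUE`.
#' @return an [FStatResult-class].
#' @export
f3Admixture <- function(T, X, Y, W, block = 20, biasCorrect = TRUE) {
  if (X == Y || X == W || Y == W) stop("populations must be distinct")
  pr <- fstatPrep(T, c(X, Y, W), block,
                  requireN2 = if (biasCorrect) X else NULL)
  x <- pr$x[, 1]; y <- pr$x[, 2]; w <- pr$x[, 3]
  u <- (x - y) * (x - w)
  if (biasCorrect) u <- u - x * (1 - x) / (pr$tot[, 1] - 1)
  jk <- fstatFromU(u, pr$usable, pr$blockId)
  newFStat("f3", c(X, Y, W), jk, p = function(z) pnorm(z))
}

#' f4 statistic: f4(X, Y; W, Z)
#'
#' Per usable SNP, u = (x - y)(w - z).  Zero in expectation under a tree-like
#' history (even with incomplete lineage sorting); significant departures
#' indicate gene flow.  Two-sided normal p.
#'
#' @param T an [AlleleFreqTable-class].
#' @param X,Y,W,Z four distinct population labels.
#' @param block jackknife block size in SNPs.
#' @return an [FStatResult-class].
#' @export
f4Stat <- function(T, X, Y, W, Z, block = 20) {
  pops <- c(X, Y, W, Z)
  if (anyDuplicated(pops)) stop("populations must be distinct")
  pr <- fstatPrep(T, pops, block)
  u <- (pr$x[, 1] - pr$x[, 2]) * (pr$x[, 3] - pr$x[, 4])
  jk <- fstatFromU(u, pr$usable, pr$blockId)
  newFStat("f4", pops, jk, p = function(z) 2 * pnorm(-abs(z)))
}

#' Outgroup f3 statistic: f3(O; target, ref)
#'
#' Measures the drift shared by `target` and `ref` since their common
#' ancestor with the outgroup; always nonnegative in expectation and useful
#' only for ranking references against the same target.  No bias correction
#' is applied by default (the apex O plays the role of X) and no tail
#' probability is attached (`p = NA`).
#'
#' @param T an [AlleleFreqTable-class].
#' @param O,target,ref distinct population labels.
#' @param block jackknife block size in SNPs.
#' @param biasCorrect subtract the O sampling-bias term? Default `FALSE`.
#' @return an [FStatResult-class].
#' @export
f3Outgroup <- function(T, O, target, ref, block = 20, biasCorrect = FALSE) {
  if (anyDuplicated(c(O, target, ref))) stop("populations must be distinct")
  pr <- fstatPrep(T, c(O, target, ref), block,
                  requireN2 = if (biasCorrect) O else NULL)
  o <- pr$x[, 1]
  u <- (o - pr$x[, 2]) * (o - pr$x[, 3])
  if (biasCorrect) u <- u - o * (1 - o) / (pr$tot[, 1] - 1)
  jk <- fstatFromU(u, pr$usable, pr$blockId)
  newFStat("f3_outgroup", c(O, target, ref), jk,
           p = function(z) NA_real_)
}

#' |Z_diff|: paired comparison of two outgroup-f3 statistics
#'
#' Computes f3(O; target, ref1) - f3(O; target, ref2) from per-block paired
#' differences (restricted to SNPs usable for both statistics), so the
#' correlation between the two f3 values is accounted for, and returns the
#' absolute jackknife Z of the difference — the strength of evidence that
#' one reference is closer to the target than the other.
#'
#' @param T an [AlleleFreqTable-class].
#' @param O,target,ref1,ref2 distinct population labels.
#' @param block jackknife block size in SNPs.
#' @param biasCorrect passed through to the two f3 terms.
#' @return a [ZDiff-class].
#' @export
zdiffOutgroup <- function(T, O, target, ref1, ref2, block = 20,
                          biasCorrect = FALSE) {
  if (anyDuplicated(c(O, target, ref1, ref2)))
    stop("populations must be distinct")
  pr <- fstatPrep(T, c(O, target, ref1, ref2), block,
                  requireN2 = if (biasCorrect) O else NULL)
  o <- pr$x[, 1]; t_ <- pr$x[, 2]
  u1 <- (o - t_) * (o - pr$x[, 3])
  u2 <- (o - t_) * (o - pr$x[, 4])
  if (biasCorrect) {
    bias <- o * (1 - o) / (pr$tot[, 1] - 1)
    u1 <- u1 - bias; u2 <- u2 - bias
  }
  jk1 <- fstatFromU(u1, pr$usable, pr$blockId)
  jk2 <- fstatFromU(u2, pr$usable, pr$blockId)
  jkd <- fstatFromU(u1 - u2, pr$usable, pr$blockId)
  zd <- if (jkd$se > 0) abs(jkd$estimate / jkd$se) else 0
  new("ZDiff", outgroup = O, target = target, ref1 = ref1, ref2 = ref2,
      f3_1 = jk1$estimate, f3_2 = jk2$estimate, zdiff = zd,
      nBlocks = as.integer(jkd$nBlocks))
}

#' Holm-Bonferroni step-down familywise error control
#'
#' @param pvalues numeric vector in [0,1].
#' @param alpha familywise error rate.
#' @return data.frame in input order with `p`, `p_adjusted` and `reject`.
#' @export
holmBonferroni <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  adj <- p.adjust(pvalues, method = "holm")
  data.frame(p = pvalues, p_adjusted = adj,
             reject = !is.na(adj) & adj <= alpha)
}
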