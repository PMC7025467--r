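#' @import methods
#' @importFrom stats cor dnorm median optimize p.adjust pnorm quantile rbeta
#'   rbinom rnorm runif sd setNames var complete.cases
#' @importFrom utils read.table write.table head tail
NULL

## Chromosome label used for SNPs without a physical anchor.
UNANCHORED <- "unanchored"

#' GenotypeMatrix: biallelic SNP calls with genomic metadata
#'
#' Stores diploid genotype calls (0/1/2 copies of the counted allele, `NA` =
#' missing) for a set of samples, together with per-SNP metadata (id,
#' chromosome, physical position in bp).  SNPs are rows, samples are columns,
#' following the features-by-samples convention of Bioconductor containers.
#'
#' @slot calls integer matrix, SNPs x samples, values in \{0,1,2,NA\}.
#' @slot snps data.frame with columns `id`, `chrom` (character; `"1"`..`"19"`
#'   or `"unanchored"`) and `pos` (integer bp), one row per SNP, in genome
#'   order (chromosome, then position).
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", snps = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  if (!is.numeric(object@calls) && !is.integer(object@calls))
    msg <- c(msg, "calls must be a numeric matrix")
  if (nrow(object@calls) != nrow(object@snps))
    msg <- c(msg, "nrow(calls) must equal nrow(snps)")
  if (!all(c("id", "chrom", "pos") %in% names(object@snps)))
    msg <- c(msg, "snps needs columns id, chrom, pos")
  v <- object@calls
  bad <- !(is.na(v) | v %in% c(0, 1, 2))
  if (any(bad)) msg <- c(msg, "calls must be 0, 1, 2 or NA")
  if (anyDuplicated(object@snps$id))
    msg <- c(msg, "duplicate SNP ids")
  if (length(msg)) msg else TRUE
})

#' AlleleFreqTable: per-population biallelic allele counts
#'
#' The exchange unit of the pipeline (the TreeMix frequency format): for each
#' SNP and population, the count of the counted allele and the total number of
#' sampled alleles (2 x non-missing diploid individuals).
#'
#' @slot populations character vector of population labels (column order).
#' @slot snps data.frame (`id`, `chrom`, `pos`), one row per SNP, table order.
#' @slot counts integer matrix SNPs x populations: counted-allele counts.
#' @slot totals integer matrix SNPs x populations: total sampled alleles.
#' @exportClass AlleleFreqTable
setClass("AlleleFreqTable",
  representation(populations = "character", snps = "data.frame",
                 counts = "matrix", totals = "matrix"))

setValidity("AlleleFreqTable", function(object) {
  msg <- character(0)
  P <- length(object@populations)
  if (ncol(object@counts) != P || ncol(object@totals) != P)
    msg <- c(msg, "counts/totals must have one column per population")
  if (nrow(object@counts) != nrow(object@snps) ||
      nrow(object@totals) != nrow(object@snps))
    msg <- c(msg, "counts/totals must have one row per SNP")
  if (any(object@counts < 0) || any(object@counts > object@totals))
    msg <- c(msg, "need 0 <= count <= total")
  if (any(object@totals %% 2 != 0))
    msg <- c(msg, "totals must be even (diploid samples)")
  if (nrow(object@totals) > 0 && any(rowSums(object@totals > 0) == 0))
    msg <- c(msg, "each SNP needs at least one population with data")
  if (length(msg)) msg else TRUE
})

#' AdmixtureGraph: rooted drift tree plus weighted migration edges
#'
#' A rooted binary tree over population tips with branch lengths in drift
#' units (variance of allele-frequency change relative to p0(1-p0)), augmented
#' with directed migration edges.  A migration edge runs from an attachment
#' point on a source branch (at fraction `src_frac` of the branch measured
#' from its child end) into the child node of a destination branch, and
#' contributes a fraction `weight` of that node's ancestry.
#'
#' @slot tree a rooted `ape::phylo` with `edge.length` (drift units, >= 0).
#' @slot migrations data.frame with columns `src_edge`, `dst_edge` (row
#'   indices into `tree$edge`), `weight` in (0,1) and `src_frac` in (0,1).
#' @slot outgroup character(1) or character(0): outgroup tip label.
#' @exportClass AdmixtureGraph
setClass("AdmixtureGraph",
  representation(tree = "ANY", migrations = "data.frame",
                 outgroup = "character"))

setValidity("AdmixtureGraph", function(object) {
  msg <- character(0)
  tr <- object@tree
  if (!inherits(tr, "phylo")) msg <- c(msg, "tree must be a phylo object")
  else {
    if (!ape::is.rooted(tr)) msg <- c(msg, "tree must be rooted")
    if (!is.null(tr$edge.length) && any(tr$edge.length < -1e-12))
      msg <- c(msg, "branch lengths must be >= 0")
    mig <- object@migrations
    if (nrow(mig)) {
      need <- c("src_edge", "dst_edge", "weight", "src_frac")
      if (!all(need %in% names(mig)))
        msg <- c(msg, "migrations needs src_edge, dst_edge, weight, src_frac")
      else {
        if (any(mig$weight <= 0 | mig$weight >= 1))
          msg <- c(msg, "migration weights must lie in (0,1)")
        if (any(mig$src_edge < 1 | mig$src_edge > nrow(tr$edge)) ||
            any(mig$dst_edge < 1 | mig$dst_edge > nrow(tr$edge)))
          msg <- c(msg, "migration edge indices out of range")
        ## inbound ancestry at any node must leave a positive tree share
        dst <- tr$edge[mig$dst_edge, 2]
        ws <- tapply(mig$weight, dst, sum)
        if (any(ws >= 1))
          msg <- c(msg, "inbound migration weights at a node must sum to < 1")
      }
    }
    if (length(object@outgroup) > 1)
      msg <- c(msg, "outgroup must be a single label")
    if (length(object@outgroup) == 1 &&
        !(object@outgroup %in% tr$tip.label))
      msg <- c(msg, "outgroup not among tip labels")
  }
  if (length(msg)) msg else TRUE
})

#' CovMatrix: sample covariance of population allele frequencies
#'
#' The centered P x P covariance of population allele frequencies across SNPs
#' (rows centered by the per-SNP across-population mean), with per-entry
#' standard errors from a delete-one-block jackknife.  Per-block sums are kept
#' so downstream fits can re-estimate under leave-one-block-out deletion.
#'
#' @slot populations character vector.
#' @slot W numeric P x P matrix of centered covariances.
#' @slot SE numeric P x P matrix of per-entry jackknife SEs (> 0).
#' @slot blockSums numeric array P x P x B of per-block sums of centered
#'   cross-products.
#' @slot blockN integer vector of SNPs per block.
#' @exportClass CovMatrix
setClass("CovMatrix",
  representation(populations = "character", W = "matrix", SE = "matrix",
                 blockSums = "array", blockN = "integer"))

setValidity("CovMatrix", function(object) {
  msg <- character(0)
  P <- length(object@populations)
  if (!all(dim(object@W) == c(P, P))) msg <- c(msg, "W must be P x P")
  if (!all(dim(object@SE) == c(P, P))) msg <- c(msg, "SE must be P x P")
  if (max(abs(object@W - t(object@W))) > 1e-8)
    msg <- c(msg, "W must be symmetric")
  if (any(object@SE <= 0)) msg <- c(msg, "SE entries must be > 0")
  rs <- rowSums(object@W)
  if (max(abs(rs)) > 1e-8 * P * max(abs(object@W), 1e-12))
    msg <- c(msg, "rows of W must sum to ~0 (centering)")
  if (length(msg)) msg else TRUE
})

#' FStatResult: an f3/f4 estimate with jackknife uncertainty
#'
#' @slot statistic one of "f3", "f3_outgroup", "f4".
#' @slot populations character vector of population arguments, in test order.
#' @slot estimate numeric(1), drift-variance units.
#' @slot se numeric(1) weighted block-jackknife standard error.
#' @slot z numeric(1), estimate / se.
#' @slot p numeric(1): one-sided lower tail for admixture f3, two-sided for
#'   f4, `NA` for outgroup f3 (no natural null).
#' @slot nBlocks integer(1), jackknife blocks with data.
#' @slot nSnps integer(1), SNPs entering the statistic.
#' @slot loo numeric vector of leave-one-block-out estimates.
#' @exportClass FStatResult
setClass("FStatResult",
  representation(statistic = "character", populations = "character",
                 estimate = "numeric", se = "numeric", z = "numeric",
                 p = "numeric", nBlocks = "integer", nSnps = "integer",
                 loo = "numeric"))

#' ZDiff: paired-difference Z score between two outgroup-f3 statistics
#'
#' Strength of evidence that reference `ref1` shares more drift with `target`
#' than `ref2` does, given outgroup `outgroup`; computed from per-block paired
#' differences so the correlation between the two f3s is respected.
#'
#' @slot outgroup,target,ref1,ref2 population labels.
#' @slot f3_1,f3_2 the two outgroup-f3 point estimates.
#' @slot zdiff numeric(1): |Z| of the paired block-jackknife difference.
#' @slot nBlocks integer(1).
#' @exportClass ZDiff
setClass("ZDiff",
  representation(outgroup = "character", target = "character",
                 ref1 = "character", ref2 = "character",
                 f3_1 = "numeric", f3_2 = "numeric",
                 zdiff = "numeric", nBlocks = "integer"))

#' FitReport: a fitted admixture graph with diagnostics
#'
#' @slot graph the fitted [AdmixtureGraph-class].
#' @slot loglik composite log-likelihood of the fit.
#' @slot varianceExplained fraction in [0,1] of covariance variance explained.
#' @slot fitted numeric P x P fitted (centered) covariance.
#' @slot residuals numeric P x P scaled residual matrix (W - C)/SE.
#' @slot migrations data.frame, one row per fitted migration edge: `src_edge`,
#'   `dst_edge`, `weight`, `weightJack`, `se`, `p`, `origin`, `dest`
#'   (tip sets as comma-joined strings).
#' @exportClass FitReport
setClass("FitReport",
  representation(graph = "AdmixtureGraph", loglik = "numeric",
                 varianceExplained = "numeric", fitted = "matrix",
                 residuals = "matrix", migrations = "data.frame"))

#' SimSpec: parameters of the synthetic admixture-graph simulator
#'
#' @slot graph the generating [AdmixtureGraph-class] (drift lengths +
#'   migration edges).
#' @slot nSnps number of SNPs to simulate.
#' @slot chromLengths numeric vector of chromosome lengths (bp); SNP positions
#'   are drawn uniformly per chromosome and sorted.
#' @slot rootDist `"uniform"` or `"beta"`.
#' @slot rootParams length-2 numeric: `c(lo, hi)` or `c(a, b)`.
#' @slot samplesPerPop named integer vector, diploid individuals per
#'   population.
#' @slot missingRate i.i.d. genotype missingness probability.
#' @slot ldBlockSnps SNPs per LD block (1 = no LD emulation).
#' @slot ldRho within-block haplotype copying probability in [0,1).
#' @exportClass SimSpec
setClass("SimSpec",
  representation(graph = "AdmixtureGraph", nSnps = "numeric",
                 chromLengths = "numeric", rootDist = "character",
                 rootParams = "numeric", samplesPerPop = "integer",
                 missingRate = "numeric", ldBlockSnps = "numeric",
                 ldRho = "numeric"))

setValidity("SimSpec", function(object) {
  msg <- character(0)
  if (object@nSnps < 1) msg <- c(msg, "nSnps must be >= 1")
  if (any(object@chromLengths <= 0)) msg <- c(msg, "chromosome lengths > 0")
  if (!object@rootDist %in% c("uniform", "beta"))
    msg <- c(msg, "rootDist must be 'uniform' or 'beta'")
  if (object@missingRate < 0 || object@missingRate > 1)
    msg <- c(msg, "missingRate in [0,1]")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho in [0,1)")
  tips <- object@graph@tree$tip.label
  if (!all(tips %in% names(object@samplesPerPop)))
    msg <- c(msg, "samplesPerPop must name every tip")
  if (length(msg)) msg else TRUE
})
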