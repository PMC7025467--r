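## qc_filters: the data-cleaning cascade applied before covariance and
## f-statistic analyses.  All thresholds use strict inequality (> threshold
## is removed; a fraction exactly at the threshold is retained).

subsetGenotypes <- function(G, snpKeep = NULL, sampleKeep = NULL) {
  cl <- G@calls; sn <- G@snps
  if (!is.null(snpKeep)) {
    cl <- cl[snpKeep, , drop = FALSE]
    sn <- sn[snpKeep, , drop = FALSE]
    rownames(sn) <- NULL
  }
  if (!is.null(sampleKeep)) cl <- cl[, sampleKeep, drop = FALSE]
  new("GenotypeMatrix", calls = cl, snps = sn)
}

#' Keep only SNPs anchored to chromosomes 1-19
#'
#' @param G a [GenotypeMatrix-class]
#' @return the filtered matrix, SNP order preserved.
#' @export
filterAnchoredSnps <- function(G) {
  subsetGenotypes(G, snpKeep = which(G@snps$chrom %in% as.character(1:19)))
}

#' Remove samples, then SNPs, with excess missing data
#'
#' Samples with missing fraction strictly above `sampleMax` are dropped
#' first; SNP missingness is then recomputed on the retained samples and
#' SNPs strictly above `snpMax` are dropped.  The removal lists are attached
#' as attributes `removedSamples` and `removedSnps`.
#'
#' @param G a [GenotypeMatrix-class]
#' @param sampleMax,snpMax missing-fraction thresholds in [0,1].
#' @export
filterMissingness <- function(G, sampleMax = 0.2, snpMax = 0.2) {
  stopifnot(sampleMax >= 0, sampleMax <= 1, snpMax >= 0, snpMax <= 1)
  sm <- colMeans(is.na(G@calls))
  keepS <- sm <= sampleMax
  G2 <- subsetGenotypes(G, sampleKeep = which(keepS))
  fm <- rowMeans(is.na(G2@calls))
  keepSnp <- fm <= snpMax
  out <- subsetGenotypes(G2, snpKeep = which(keepSnp))
  if (nSnps(out) == 0 || nSamples(out) == 0) stop("all data filtered")
  attr(out, "removedSamples") <- sampleIds(G)[!keepS]
  attr(out, "removedSnps") <- G2@snps$id[!keepSnp]
  out
}

## Minor allele frequency over non-missing calls; NA for fully missing SNPs.
mafOf <- function(G) {
  f <- rowSums(G@calls, na.rm = TRUE) / (2 * rowSums(!is.na(G@calls)))
  pmin(f, 1 - f)
}

#' Remove SNPs below a minor-allele-frequency threshold
#'
#' MAF is computed over non-missing calls; SNPs with MAF strictly below
#' `minMaf` (including monomorphic SNPs) are removed, MAF exactly at the
#' threshold is retained.
#'
#' @param G a [GenotypeMatrix-class]
#' @param minMaf threshold in [0, 0.5].
#' @export
filterMaf <- function(G, minMaf = 0.01) {
  stopifnot(minMaf >= 0, minMaf <= 0.5)
  maf <- mafOf(G)
  subsetGenotypes(G, snpKeep = which(!is.na(maf) & maf >= minMaf))
}

#' Remove samples named on an exclusion list
#'
#' Unknown ids produce a warning, not an error (exclusion lists are curated
#' externally and may mention samples already absent).
#'
#' @param G a [GenotypeMatrix-class]
#' @param sampleIds character vector of sample ids to drop.
#' @export
applyExclusionList <- function(G, sampleIds) {
  present <- sampleIds %in% colnames(G@calls)
  if (any(!present))
    warning("exclusion list ids not in data: ",
            paste(sampleIds[!present], collapse = ", "))
  subsetGenotypes(G, sampleKeep = which(!(colnames(G@calls) %in% sampleIds)))
}

#' Restrict to one species and re-filter within the subset
#'
#' Restricts the matrix to the species' samples, drops samples with missing
#' fraction above `mind` (no SNP missingness filter at this stage), then
#' applies the MAF filter within the subset.
#'
#' @param G a [GenotypeMatrix-class]
#' @param pm named character vector: population per sample id.
#' @param species species (population) label.
#' @param mind per-sample missingness threshold.
#' @param maf within-subset MAF threshold.
#' @export
speciesSubset <- function(G, pm, species, mind = 0.2, maf = 0.01) {
  ids <- sampleIds(G)
  sel <- which(pm[ids] == species)
  if (length(sel) == 0) stop("species not present: ", species)
  sub <- subsetGenotypes(G, sampleKeep = sel)
  sm <- colMeans(is.na(sub@calls))
  sub <- subsetGenotypes(sub, sampleKeep = which(sm <= mind))
  if (nSamples(sub) == 0) stop("all samples of ", species, " filtered")
  filterMaf(sub, maf)
}
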