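## Constructors, accessors and show methods.

#' Construct a GenotypeMatrix
#'
#' @param calls SNPs x samples matrix of 0/1/2/NA calls (rownames = SNP ids,
#'   colnames = sample ids).
#' @param snps data.frame with columns `id`, `chrom`, `pos`.
#' @param sort sort SNPs into genome order (chromosome 1..19 then unanchored,
#'   position ascending)?  Default `TRUE`.
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(calls, snps, sort = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$id <- as.character(snps$id)
  if (sort) {
    o <- genomeOrder(snps)
    snps <- snps[o, , drop = FALSE]
    calls <- calls[o, , drop = FALSE]
  }
  rownames(snps) <- NULL
  rownames(calls) <- snps$id
  new("GenotypeMatrix", calls = calls, snps = snps)
}

## Order by chromosome 1..19 numerically, unanchored last, then position.
genomeOrder <- function(snps) {
  cn <- suppressWarnings(as.numeric(snps$chrom))
  cn[is.na(cn)] <- Inf
  order(cn, snps$pos)
}

#' @describeIn GenotypeMatrix number of SNPs
#' @param x a GenotypeMatrix
#' @export
nSnps <- function(x) nrow(x@calls)

#' @describeIn GenotypeMatrix number of samples
#' @export
nSamples <- function(x) ncol(x@calls)

#' Genotype calls matrix (SNPs x samples)
#' @param x a GenotypeMatrix
#' @return integer matrix
#' @export
calls <- function(x) x@calls

#' Per-SNP metadata
#' @param x a GenotypeMatrix or AlleleFreqTable
#' @return data.frame with id, chrom, pos
#' @export
snpInfo <- function(x) x@snps

#' Sample identifiers
#' @param x a GenotypeMatrix
#' @export
sampleIds <- function(x) colnames(x@calls)

#' Population labels
#' @param x an AlleleFreqTable or CovMatrix
#' @export
populations <- function(x) x@populations

#' Counted-allele counts / total sampled alleles
#' @param x an AlleleFreqTable
#' @return integer matrix SNPs x populations
#' @export
alleleCounts <- function(x) x@counts

#' @rdname alleleCounts
#' @export
alleleTotals <- function(x) x@totals

#' Population allele frequencies
#' @param x an AlleleFreqTable
#' @return numeric matrix SNPs x populations; `NaN` where a population has no
#'   data at a SNP.
#' @export
alleleFreqs <- function(x) {
  f <- x@counts / x@totals
  colnames(f) <- x@populations
  f
}

#' Construct an AlleleFreqTable
#' @param populations character vector of labels.
#' @param snps data.frame (`id`, `chrom`, `pos`).
#' @param counts,totals integer matrices SNPs x populations.
#' @export
AlleleFreqTable <- function(populations, snps, counts, totals) {
  counts <- as.matrix(counts); totals <- as.matrix(totals)
  storage.mode(counts) <- "integer"
  storage.mode(totals) <- "integer"
  colnames(counts) <- colnames(totals) <- populations
  snps$id <- as.character(snps$id); snps$chrom <- as.character(snps$chrom)
  rownames(snps) <- NULL
  new("AlleleFreqTable", populations = as.character(populations),
      snps = snps, counts = counts, totals = totals)
}

#' Construct an AdmixtureGraph
#'
#' @param tree a rooted `ape::phylo` with branch lengths in drift units.
#' @param migrations optional data.frame with columns `src_edge`, `dst_edge`,
#'   `weight` and optionally `src_frac` (default 0.5).
#' @param outgroup optional outgroup tip label.
#' @return an [AdmixtureGraph-class].
#' @export
admixtureGraph <- function(tree, migrations = NULL, outgroup = character(0)) {
  if (is.null(migrations) || nrow(migrations) == 0)
    migrations <- data.frame(src_edge = integer(0), dst_edge = integer(0),
                             weight = numeric(0), src_frac = numeric(0))
  if (is.null(migrations$src_frac)) migrations$src_frac <- 0.5
  new("AdmixtureGraph", tree = tree, migrations = migrations,
      outgroup = as.character(outgroup))
}

#' The drift tree of an admixture graph
#' @param x an AdmixtureGraph or FitReport
#' @return an `ape::phylo`
#' @export
driftTree <- function(x) {
  if (is(x, "FitReport")) x <- x@graph
  x@tree
}

#' Migration edges of a graph or fit, with clade descriptors
#'
#' @param x an AdmixtureGraph or FitReport
#' @return data.frame with one row per migration edge; columns include
#'   `weight` and the origin/destination tip sets as comma-joined strings.
#' @export
migrationEdges <- function(x) {
  if (is(x, "FitReport")) return(x@migrations)
  g <- x
  mig <- g@migrations
  if (nrow(mig) == 0)
    return(cbind(mig, data.frame(origin = character(0),
                                 dest = character(0))))
  sets <- migrationTipSets(g)
  mig$origin <- vapply(sets, function(s) paste(sort(s$origin), collapse = ","),
                       character(1))
  mig$dest <- vapply(sets, function(s) paste(sort(s$dest), collapse = ","),
                     character(1))
  mig
}

#' Origin/destination tip sets of each migration edge
#' @param g an AdmixtureGraph
#' @return list, one element per migration, each `list(origin=, dest=)` of tip
#'   label vectors (tips subtended by the source attachment point and by the
#'   destination node).
#' @export
migrationTipSets <- function(g) {
  tr <- g@tree
  lapply(seq_len(nrow(g@migrations)), function(i) {
    srcNode <- tr$edge[g@migrations$src_edge[i], 2]
    dstNode <- tr$edge[g@migrations$dst_edge[i], 2]
    list(origin = tipsBelow(tr, srcNode), dest = tipsBelow(tr, dstNode))
  })
}

## Tip labels subtended by a node (the node itself if a tip).
tipsBelow <- function(tr, node) {
  P <- length(tr$tip.label)
  if (node <= P) return(tr$tip.label[node])
  tr$tip.label[phangorn::Descendants(tr, node, "tips")[[1]]]
}

#' Covariance and SE accessors
#' @param x a CovMatrix
#' @export
covW <- function(x) x@W

#' @rdname covW
#' @export
covSE <- function(x) x@SE

#' Fit diagnostics accessors
#' @param x a FitReport
#' @export
varianceExplainedOf <- function(x) x@varianceExplained

#' @rdname varianceExplainedOf
#' @export
fittedCov <- function(x) x@fitted

#' @rdname varianceExplainedOf
#' @export
logLikOf <- function(x) x@loglik

#' Turn an FStatResult into a one-row data.frame
#' @param x an FStatResult
#' @export
asRow <- function(x) {
  data.frame(statistic = x@statistic,
             populations = paste(x@populations, collapse = ";"),
             estimate = x@estimate, se = x@se, z = x@z, p = x@p,
             n_blocks = x@nBlocks, n_snps = x@nSnps)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nSnps(object), "SNPs x", nSamples(object),
      "samples\n")
  anch <- sum(object@snps$chrom != UNANCHORED)
  cat("  anchored SNPs:", anch, "| missing calls:",
      sprintf("%.1f%%", 100 * mean(is.na(object@calls))), "\n")
})

setMethod("show", "AlleleFreqTable", function(object) {
  cat("AlleleFreqTable:", nrow(object@counts), "SNPs x",
      length(object@populations), "populations\n")
})

setMethod("show", "AdmixtureGraph", function(object) {
  cat("AdmixtureGraph:", length(object@tree$tip.label), "tips,",
      nrow(object@migrations), "migration edge(s)\n")
  if (length(object@outgroup)) cat("  outgroup:", object@outgroup, "\n")
  me <- migrationEdges(object)
  for (i in seq_len(nrow(me)))
    cat(sprintf("  w=%.3f  (%s) -> (%s)\n", me$weight[i], me$origin[i],
                me$dest[i]))
})

setMethod("show", "CovMatrix", function(object) {
  P <- length(object@populations)
  cat("CovMatrix:", P, "populations,", length(object@blockN),
      "jackknife blocks\n")
  cat("  mean |W|:", signif(mean(abs(object@W)), 4),
      " mean SE:", signif(mean(object@SE), 4), "\n")
})

setMethod("show", "FStatResult", function(object) {
  cat(sprintf("%s(%s) = %.6g  SE = %.3g  Z = %.2f",
              object@statistic, paste(object@populations, collapse = ", "),
              object@estimate, object@se, object@z))
  if (!is.na(object@p)) cat(sprintf("  p = %.3g", object@p))
  cat(sprintf("  [%d SNPs, %d blocks]\n", object@nSnps, object@nBlocks))
})

setMethod("show", "ZDiff", function(object) {
  cat(sprintf("|Z_diff| f3(%s; %s, %s vs %s) = %.2f  [%d blocks]\n",
              object@outgroup, object@target, object@ref1, object@ref2,
              object@zdiff, object@nBlocks))
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport: %d tips, %d migration edge(s)\n",
              length(object@graph@tree$tip.label), nrow(object@migrations)))
  cat(sprintf("  loglik = %.3f  variance explained = %.4f\n",
              object@loglik, object@varianceExplained))
  me <- object@migrations
  for (i in seq_len(nrow(me)))
    cat(sprintf("  edge %d: w=%.3f p=%.3g  (%s) -> (%s)\n", i, me$weight[i],
                me$p[i], me$origin[i], me$dest[i]))
})
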