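## ld_blocks: within-species LD decay and the iterative SNP block-size
## determination used to choose the TreeMix -k parameter.

#' Pairwise genotype r-squared within a physical window
#'
#' For every pair of anchored SNPs on the same chromosome no more than
#' `windowKb` apart, computes the squared Pearson correlation of the
#' genotype-call vectors over samples non-missing at both SNPs (the unphased
#' composite measure).  Pairs with fewer than two informative samples or zero
#' variance at either SNP are omitted.
#'
#' @param G a [GenotypeMatrix-class] (typically one species, see
#'   [speciesSubset()]).
#' @param windowKb maximum inter-SNP distance in kb.
#' @return data.frame with columns `snp_i`, `snp_j`, `distance` (bp), `r2`.
#' @export
pairwiseLdR2 <- function(G, windowKb = 500) {
  if (nSamples(G) < 2) stop("need at least 2 samples")
  out <- list()
  for (ch in unique(G@snps$chrom)) {
    if (ch == UNANCHORED) next
    idx <- which(G@snps$chrom == ch)
    if (length(idx) < 2) next
    pos <- G@snps$pos[idx]
    ids <- G@snps$id[idx]
    gm <- t(G@calls[idx, , drop = FALSE])          # samples x SNPs
    cc <- suppressWarnings(cor(gm, use = "pairwise.complete.obs"))
    nobs <- crossprod(!is.na(gm))                  # informative samples/pair
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- abs(pos[pr[, 2]] - pos[pr[, 1]])
    r2 <- cc[pr]^2
    keep <- d <= windowKb * 1000 & is.finite(r2) & nobs[pr] >= 2
    if (any(keep))
      out[[ch]] <- data.frame(snp_i = ids[pr[keep, 1]],
                              snp_j = ids[pr[keep, 2]],
                              distance = d[keep], r2 = r2[keep])
  }
  if (length(out) == 0)
    return(data.frame(snp_i = character(0), snp_j = character(0),
                      distance = numeric(0), r2 = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Median r-squared in sequential distance bins
#'
#' Sorts pairs by distance and partitions them into consecutive bins of
#' `binSize` comparisons (the last bin may be short), reporting the mean
#' physical distance and the median r2 of each bin — the standard LD-decay
#' summary plotted against distance.
#'
#' @param pairs output of [pairwiseLdR2()].
#' @param binSize pairwise comparisons per bin.
#' @return data.frame with `mean_distance` (bp) and `median_r2`, one row per
#'   bin.
#' @export
ldDecayBins <- function(pairs, binSize = 75) {
  if (nrow(pairs) == 0) stop("no LD pairs")
  o <- order(pairs$distance)
  d <- pairs$distance[o]; r2 <- pairs$r2[o]
  bin <- (seq_along(d) - 1L) %/% binSize + 1L
  data.frame(mean_distance = as.numeric(tapply(d, bin, mean)),
             median_r2 = as.numeric(tapply(r2, bin, median)))
}

#' Plot an LD decay curve
#' @param bins output of [ldDecayBins()].
#' @param ... passed to [graphics::plot()].
#' @export
plotLdDecay <- function(bins, ...) {
  graphics::plot(bins$mean_distance / 1000, bins$median_r2,
                 xlab = "distance (kb)", ylab = expression(median ~ r^2),
                 type = "b", pch = 16, ...)
  invisible(bins)
}

#' Physical midpoints of consecutive SNP blocks
#'
#' Blocks are consecutive runs of `k` SNPs over the genome-ordered SNP list
#' (the last block may be short).  A block straddling a chromosome boundary
#' is split into per-chromosome parts, each contributing its own midpoint.
#' The midpoint of a block part is `(min(pos) + max(pos)) / 2` (range
#' midpoint) or the mean position, per `midpoint`.
#'
#' @param snps genome-ordered SNP data.frame (`id`, `chrom`, `pos`).
#' @param k SNPs per block.
#' @param midpoint `"range"` (default) or `"mean"`.
#' @return named list: per chromosome, the ordered vector of block-part
#'   midpoints (bp).
#' @export
blockMidpoints <- function(snps, k, midpoint = c("range", "mean")) {
  midpoint <- match.arg(midpoint)
  stopifnot(k >= 1)
  n <- nrow(snps)
  blk <- (seq_len(n) - 1L) %/% as.integer(k)
  mids <- list()
  for (ch in unique(snps$chrom)) {
    sel <- snps$chrom == ch
    parts <- split(snps$pos[sel], blk[sel])
    m <- vapply(parts, function(p)
      if (midpoint == "range") (min(p) + max(p)) / 2 else mean(p),
      numeric(1))
    mids[[ch]] <- unname(m[order(as.integer(names(parts)))])
  }
  mids
}

#' Iterative SNP block-size determination
#'
#' Starting from `start` SNPs per block and increasing by `step`, computes
#' block midpoints (with chromosome-straddling blocks split) and the
#' distances between consecutive midpoints on each chromosome; returns the
#' smallest block size for which every such distance strictly exceeds
#' `thresholdKb`.
#'
#' @param snps genome-ordered, anchored SNP data.frame (`id`, `chrom`,
#'   `pos`).
#' @param thresholdKb inter-midpoint distance threshold (kb).
#' @param start,step first block size tried and increment.
#' @param midpoint passed to [blockMidpoints()].
#' @return list with `k` (chosen block size) and `trace` (data.frame `k`,
#'   `min_distance` in bp per block size tried, for plotting).
#' @export
determineBlockSize <- function(snps, thresholdKb = 200, start = 5, step = 5,
                               midpoint = "range") {
  stopifnot(thresholdKb > 0, start >= 1, step >= 1)
  if (any(snps$chrom == UNANCHORED)) stop("snps must be anchored")
  n <- nrow(snps)
  ks <- integer(0); mins <- numeric(0)
  k <- as.integer(start)
  repeat {
    if (k > n) stop("no block size up to the SNP count satisfies the ",
                    "distance criterion")
    mids <- blockMidpoints(snps, k, midpoint)
    gaps <- unlist(lapply(mids, function(m) if (length(m) > 1) diff(m)),
                   use.names = FALSE)
    mn <- if (length(gaps)) min(gaps) else Inf
    ks <- c(ks, k); mins <- c(mins, mn)
    if (all(gaps > thresholdKb * 1000)) break
    k <- k + as.integer(step)
  }
  list(k = k, trace = data.frame(k = ks, min_distance = mins))
}

## Contiguous block ids over a SNP list: 1,1,...,2,2,... of width `block`.
snpBlockIds <- function(n, block) (seq_len(n) - 1L) %/% as.integer(block) + 1L
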