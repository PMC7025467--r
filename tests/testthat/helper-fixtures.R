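## Shared fixtures and independent oracles, built in code.

## Small allele-frequency table from explicit count/total matrices.
mkFreqTable <- function(counts, totals, pops, chrom = "1") {
  counts <- as.matrix(counts); totals <- as.matrix(totals)
  AlleleFreqTable(pops,
                  data.frame(id = paste0("s", seq_len(nrow(counts))),
                             chrom = chrom, pos = seq_len(nrow(counts))),
                  counts, totals)
}

## Small genotype matrix from a calls matrix (SNPs x samples).
mkGeno <- function(calls, chrom = NULL, pos = NULL, sort = FALSE) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("ind", seq_len(ncol(calls)))
  GenotypeMatrix(calls, data.frame(id = paste0("s", seq_len(n)),
                                   chrom = chrom, pos = pos), sort = sort)
}

## Fixed balanced 8-tip drift tree (pure tree, no migration).
balancedEightTipGraph <- function() {
  tr <- ape::read.tree(text = paste0(
    "(((A:0.02,B:0.03):0.02,(C:0.025,D:0.02):0.015):0.01,",
    "((E:0.03,F:0.02):0.02,(G:0.02,H:0.03):0.025):0.01);"))
  admixtureGraph(tr)
}

## Edge index of the branch above a tip.
tipEdge <- function(tr, label) {
  which(tr$edge[, 2] == which(tr$tip.label == label))
}

## Fixed 6-tip scenario with one migration edge B -> D (weight w).
migrationScenarioGraph <- function(w = 0.4) {
  tr <- ape::read.tree(text = paste0(
    "(out:0.1,(((A:0.02,B:0.02):0.02,C:0.04):0.02,",
    "(D:0.03,E:0.03):0.03):0.01);"))
  admixtureGraph(tr,
                 data.frame(src_edge = tipEdge(tr, "B"),
                            dst_edge = tipEdge(tr, "D"),
                            weight = w, src_frac = 0.5),
                 outgroup = "out")
}

## 50/50 admixture scenario: X a mixture of the Y-side and W-side parents
## (between-parent drift 0.049, post-admixture drift 0.005), V a pure
## control sister to W with ordinary private drift of its own.
admixtureScenarioGraph <- function(w = 0.5) {
  tr <- ape::read.tree(
    text = "((Y:0.001,X:0.005):0.0245,(W:0.001,V:0.02):0.0245);")
  admixtureGraph(tr,
                 data.frame(src_edge = tipEdge(tr, "W"),
                            dst_edge = tipEdge(tr, "X"),
                            weight = w, src_frac = 0.5))
}

## Simulate an allele-frequency table from a graph in one call.
simTable <- function(graph, nSnps, n, seedFreq, seedCounts = seedFreq + 1,
                     chromLengths = rep(25e6, 19)) {
  spec <- simSpec(graph, nSnps = nSnps, samplesPerPop = n,
                  chromLengths = chromLengths)
  sim <- simulateFrequencies(spec, seed = seedFreq)
  sampleAlleleCounts(sim, spec@samplesPerPop, seed = seedCounts)
}

## ---- independent oracles ------------------------------------------------

## Non-trivial bipartitions of an unrooted tree, as a canonical character
## set (each split keyed by the side not containing the first tip label).
bipartitionSet <- function(tr) {
  tr <- ape::unroot(tr)
  tips <- sort(tr$tip.label)
  P <- length(tr$tip.label)
  out <- character(0)
  ## enumerate by traversal: tips below each internal edge child
  desc <- function(node) {
    if (node <= P) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    if (child <= P) next
    side <- sort(desc(child))
    if (length(side) <= 1 || length(side) >= P - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

## Robinson-Foulds by direct bipartition enumeration.
rfOracle <- function(t1, t2) {
  b1 <- bipartitionSet(t1); b2 <- bipartitionSet(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

## Block midpoints by brute-force enumeration (independent of the package's
## split/tapply implementation).
midpointOracle <- function(snps, k) {
  n <- nrow(snps)
  out <- list()
  b <- 1L
  for (s0 in seq(1, n, by = k)) {
    idx <- s0:min(s0 + k - 1, n)
    for (ch in unique(snps$chrom[idx])) {
      p <- snps$pos[idx][snps$chrom[idx] == ch]
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            mid = (min(p) + max(p)) / 2)
    }
    b <- b + 1L
  }
  do.call(rbind, out)
}

## Smallest block size whose consecutive same-chromosome midpoint gaps all
## exceed the threshold, by exhaustive scan.
blockSizeOracle <- function(snps, thresholdKb, start = 5, step = 5) {
  k <- start
  repeat {
    mids <- midpointOracle(snps, k)
    ok <- TRUE
    for (ch in unique(mids$chrom)) {
      m <- mids$mid[mids$chrom == ch]
      if (length(m) > 1 && any(diff(m) <= thresholdKb * 1000)) ok <- FALSE
    }
    if (ok) return(k)
    k <- k + step
    if (k > nrow(snps)) stop("oracle found no block size")
  }
}
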