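## simdata: allele frequencies by Gaussian drift on an admixture graph,
## genotype sampling with missingness and optional short-range LD — the test
## bed for every other module.

#' Construct a SimSpec
#'
#' @param graph generating [AdmixtureGraph-class] (drift lengths required).
#' @param nSnps SNPs to simulate.
#' @param chromLengths chromosome lengths in bp (positions drawn uniformly
#'   per chromosome, SNPs allocated to chromosomes proportionally to length).
#' @param rootDist `"uniform"` or `"beta"` ancestral-frequency distribution.
#' @param rootParams `c(lo, hi)` or `c(shape1, shape2)`.
#' @param samplesPerPop diploid individuals per population: a single number
#'   or a named vector covering every tip.
#' @param missingRate i.i.d. missing-call probability.
#' @param ldBlockSnps SNPs per LD block (1 disables LD emulation).
#' @param ldRho within-block haplotype copying probability.
#' @return a [SimSpec-class].
#' @export
simSpec <- function(graph, nSnps = 4000, chromLengths = rep(25e6, 19),
                    rootDist = "uniform", rootParams = c(0.05, 0.95),
                    samplesPerPop = 20, missingRate = 0, ldBlockSnps = 1,
                    ldRho = 0) {
  tips <- graph@tree$tip.label
  if (length(samplesPerPop) == 1 && is.null(names(samplesPerPop)))
    samplesPerPop <- setNames(rep(samplesPerPop, length(tips)), tips)
  new("SimSpec", graph = graph, nSnps = nSnps,
      chromLengths = as.numeric(chromLengths), rootDist = rootDist,
      rootParams = as.numeric(rootParams),
      samplesPerPop = setNames(as.integer(samplesPerPop[tips]), tips),
      missingRate = missingRate, ldBlockSnps = ldBlockSnps, ldRho = ldRho)
}

## Random SNP map: positions uniform per chromosome, counts proportional to
## chromosome length, sorted into genome order.
randomSnpMap <- function(nSnps, chromLengths) {
  nChr <- length(chromLengths)
  chr <- sample.int(nChr, nSnps, replace = TRUE,
                    prob = chromLengths / sum(chromLengths))
  pos <- floor(runif(nSnps, 1, chromLengths[chr]))
  m <- data.frame(id = paste0("snp", seq_len(nSnps)),
                  chrom = as.character(chr), pos = as.integer(pos))
  m <- m[genomeOrder(m), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Simulate population allele frequencies by drift on an admixture graph
#'
#' Per SNP: the root frequency p0 is drawn from the spec's distribution;
#' along each branch of drift length c the frequency performs a Gaussian
#' step with variance c * p0(1-p0), clipped to [0,1]; at a migration
#' destination the frequency is the weighted mixture of the source
#' attachment value and the value arriving along the tree branch.  SNP
#' positions are drawn uniformly over the chromosomes and sorted.
#'
#' @param spec a [SimSpec-class].
#' @param seed optional RNG seed.
#' @return list with `freqs` (SNPs x populations latent frequency matrix),
#'   `snps` (genome-ordered SNP map), `p0` (root frequencies) and
#'   `clippedFrac` (fraction of drift steps clipped at the boundary).
#' @export
simulateFrequencies <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- spec@graph
  tr <- g@tree
  mig <- g@migrations
  n <- spec@nSnps
  snps <- randomSnpMap(n, spec@chromLengths)
  p0 <- if (spec@rootDist == "uniform")
    runif(n, spec@rootParams[1], spec@rootParams[2])
  else rbeta(n, spec@rootParams[1], spec@rootParams[2])
  v0 <- p0 * (1 - p0)
  P <- length(tr$tip.label)
  root <- P + 1L
  nNode <- max(tr$edge)
  E <- nrow(tr$edge)
  parentEdgeOf <- rep(NA_integer_, nNode)
  parentEdgeOf[tr$edge[, 2]] <- seq_len(E)
  dstNode <- if (nrow(mig)) tr$edge[mig$dst_edge, 2] else integer(0)
  attachOf <- rep(NA_integer_, E)
  if (nrow(mig)) attachOf[mig$src_edge] <- seq_len(nrow(mig))

  val <- vector("list", nNode)      # per node, frequency vector over SNPs
  attVal <- vector("list", max(nrow(mig), 1))
  val[[root]] <- p0
  nClip <- 0L; nStep <- 0L
  drift <- function(from, c) {
    if (c <= 0) return(from)
    x <- from + rnorm(n, 0, sqrt(c * v0))
    nStep <<- nStep + n
    nClip <<- nClip + sum(x < 0 | x > 1)
    pmin(pmax(x, 0), 1)
  }
  done <- c(rep(FALSE, nNode)); done[root] <- TRUE
  attDone <- rep(FALSE, nrow(mig))
  repeat {
    progress <- FALSE
    ## attachment points: computable once the source edge's parent is done
    for (m in seq_len(nrow(mig))) {
      e <- mig$src_edge[m]
      if (!attDone[m] && done[tr$edge[e, 1]]) {
        attVal[[m]] <- drift(val[[tr$edge[e, 1]]],
                             (1 - mig$src_frac[m]) * tr$edge.length[e])
        attDone[m] <- TRUE
        progress <- TRUE
      }
    }
    for (v in seq_len(nNode)) {
      if (done[v]) next
      e <- parentEdgeOf[v]
      if (!done[tr$edge[e, 1]]) next
      migIn <- which(dstNode == v)
      if (length(migIn) && !all(attDone[migIn])) next
      if (!is.na(attachOf[e]) && !attDone[attachOf[e]]) next
      treePart <- if (!is.na(attachOf[e]))
        drift(attVal[[attachOf[e]]], mig$src_frac[attachOf[e]] *
                tr$edge.length[e])
      else drift(val[[tr$edge[e, 1]]], tr$edge.length[e])
      if (length(migIn)) {
        wsum <- sum(mig$weight[migIn])
        x <- (1 - wsum) * treePart
        for (m in migIn) x <- x + mig$weight[m] * attVal[[m]]
        val[[v]] <- x
      } else val[[v]] <- treePart
      done[v] <- TRUE
      progress <- TRUE
    }
    if (all(done)) break
    if (!progress) stop("migration edges create a cycle")
  }
  freqs <- do.call(cbind, val[seq_len(P)])
  colnames(freqs) <- tr$tip.label
  list(freqs = freqs, snps = snps, p0 = p0,
       clippedFrac = if (nStep > 0) nClip / nStep else 0)
}

#' Binomially sample an allele-frequency table from latent frequencies
#'
#' Each population contributes 2 x n_pop allele draws per SNP (no individual
#' genotypes, no missingness) — the fast path for covariance and f-statistic
#' simulations.
#'
#' @param sim output of [simulateFrequencies()].
#' @param samplesPerPop named integer vector of diploid counts (e.g.
#'   `spec@samplesPerPop`).
#' @param seed optional RNG seed.
#' @return an [AlleleFreqTable-class].
#' @export
sampleAlleleCounts <- function(sim, samplesPerPop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- colnames(sim$freqs)
  n2 <- 2L * as.integer(samplesPerPop[pops])
  counts <- vapply(seq_along(pops), function(k)
    rbinom(nrow(sim$freqs), n2[k], sim$freqs[, k]), integer(nrow(sim$freqs)))
  totals <- matrix(rep(n2, each = nrow(sim$freqs)), ncol = length(pops))
  AlleleFreqTable(pops, sim$snps, counts, totals)
}

#' Sample diploid genotypes from latent population frequencies
#'
#' Each individual's call is Binomial(2, p) on its population's latent
#' frequency; missingness is applied i.i.d.  With LD emulation on
#' (`ldBlockSnps > 1`), haplotypes are built by within-block copying: the
#' latent uniform driving the allele at a SNP is carried over from the
#' previous SNP of the block with probability `ldRho` and redrawn otherwise,
#' giving geometrically decaying within-block genotype correlation.
#'
#' @param sim output of [simulateFrequencies()].
#' @param spec the [SimSpec-class] (sample sizes, missingness, LD settings).
#' @param seed optional RNG seed.
#' @return a [GenotypeMatrix-class]; samples are named `<pop>_<i>`.
#' @export
simulateGenotypes <- function(sim, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- colnames(sim$freqs)
  nSnp <- nrow(sim$freqs)
  blocks <- if (spec@ldBlockSnps > 1)
    snpBlockIds(nSnp, spec@ldBlockSnps) else seq_len(nSnp)
  out <- list()
  for (k in seq_along(pops)) {
    nInd <- spec@samplesPerPop[pops[k]]
    p <- sim$freqs[, k]
    if (spec@ldBlockSnps > 1 && spec@ldRho > 0) {
      ## haplotype copying within blocks
      calls <- matrix(0L, nrow = nSnp, ncol = nInd)
      for (h in 1:2) {
        u <- matrix(runif(nSnp * nInd), nSnp, nInd)
        copy <- matrix(runif(nSnp * nInd) < spec@ldRho, nSnp, nInd)
        newBlock <- c(TRUE, diff(blocks) != 0)
        copy[newBlock, ] <- FALSE
        for (s in seq_len(nSnp))
          if (any(copy[s, ])) u[s, copy[s, ]] <- u[s - 1L, copy[s, ]]
        calls <- calls + (u < p)
      }
    } else {
      calls <- matrix(rbinom(nSnp * nInd, 2, rep(p, nInd)), nSnp, nInd)
    }
    colnames(calls) <- paste0(pops[k], "_", seq_len(nInd))
    out[[k]] <- calls
  }
  cl <- do.call(cbind, out)
  if (spec@missingRate > 0)
    cl[matrix(runif(length(cl)) < spec@missingRate, nrow(cl))] <- NA
  GenotypeMatrix(cl, sim$snps, sort = FALSE)
}

#' Population map of a simulated GenotypeMatrix
#' @param G a [GenotypeMatrix-class] produced by [simulateGenotypes()].
#' @return named character vector sample -> population.
#' @export
simPopulationMap <- function(G) {
  ids <- sampleIds(G)
  setNames(sub("_[0-9]+$", "", ids), ids)
}

#' Random admixture graph
#'
#' A random rooted tree (branch lengths uniform, scaled by `driftScale`)
#' with optional random migration edges.
#'
#' @param nPops ingroup tips (labelled `pop1..popN`).
#' @param nMigrations migration edges to place (acyclic, random endpoints).
#' @param driftScale multiplier on uniform(0,1) branch lengths.
#' @param weights migration weight range, drawn uniformly.
#' @param seed optional RNG seed.
#' @return an [AdmixtureGraph-class].
#' @export
randomAdmixtureGraph <- function(nPops, nMigrations = 0, driftScale = 0.02,
                                 weights = c(0.14, 0.49), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(nPops, tip.label = paste0("pop", seq_len(nPops)))
  tr$edge.length <- runif(nrow(tr$edge)) * driftScale
  addRandomMigrations(admixtureGraph(tr), nMigrations, weights)
}

#' Attach an outgroup tip to the root via a basal branch
#' @param g an [AdmixtureGraph-class] without migrations.
#' @param length drift length of the outgroup branch.
#' @param label outgroup tip label.
#' @export
withOutgroup <- function(g, length = 0.1, label = "out") {
  stopifnot(nrow(g@migrations) == 0)
  inner <- sub(";\\s*$", "", ape::write.tree(g@tree))
  tr2 <- ape::read.tree(text = paste0("(", label, ":", length, ",",
                                      inner, ":", length / 2, ");"))
  admixtureGraph(tr2, outgroup = label)
}

## Add random valid migration edges to a graph.
addRandomMigrations <- function(g, nMigrations, weights = c(0.14, 0.49)) {
  if (nMigrations == 0) return(g)
  tr <- g@tree
  E <- nrow(tr$edge)
  tries <- 0
  while (nrow(g@migrations) < nMigrations && tries < 500) {
    tries <- tries + 1
    src <- sample.int(E, 1); dst <- sample.int(E, 1)
    if (src == dst) next
    if (src %in% g@migrations$src_edge) next
    dstNode <- tr$edge[dst, 2]
    if (dstNode %in% tr$edge[g@migrations$dst_edge, 2]) next
    if (isAncestor(tr, dstNode, tr$edge[src, 1])) next
    ## avoid trivial edges between a node and its own ancestor line
    if (isAncestor(tr, tr$edge[src, 2], dstNode)) next
    mig <- rbind(g@migrations,
                 data.frame(src_edge = src, dst_edge = dst,
                            weight = runif(1, weights[1], weights[2]),
                            src_frac = 0.5))
    g2 <- g; g2@migrations <- mig
    ok <- tryCatch({ graphSegments(g2); TRUE }, error = function(e) FALSE)
    if (ok) g <- g2
  }
  if (nrow(g@migrations) < nMigrations)
    warning("placed only ", nrow(g@migrations), " of ", nMigrations,
            " migration edges")
  g
}

#' A bundled scenario shaped like a wild-grape SNP array study
#'
#' 31 ingroup populations plus one outgroup on a random drift tree with 8
#' migration edges (weights 0.14-0.49), ~4,000 SNPs on 19 chromosomes,
#' 2-40 diploid individuals per population, 5% missing calls and mild
#' short-range LD.  Returns the ground-truth graph alongside the data so
#' recovery can be scored.
#'
#' @param seed RNG seed (fully determines the output).
#' @param nSnps SNPs to simulate.
#' @return list with `spec`, `graph` (truth), `sim` (latent frequencies),
#'   `genotypes`, `popmap`, `freqTable`.
#' @export
paperLikeScenario <- function(seed = 1, nSnps = 4000) {
  set.seed(seed)
  base <- randomAdmixtureGraph(31, nMigrations = 0, driftScale = 0.02)
  g <- withOutgroup(base, length = 0.08)
  g <- addRandomMigrations(g, 8, weights = c(0.14, 0.49))
  sizes <- sample(2:40, length(g@tree$tip.label), replace = TRUE)
  names(sizes) <- g@tree$tip.label
  sizes["out"] <- max(sizes["out"], 10L)
  spec <- simSpec(g, nSnps = nSnps,
                  chromLengths = seq(18e6, 30e6, length.out = 19),
                  rootParams = c(0.05, 0.95), samplesPerPop = sizes,
                  missingRate = 0.05, ldBlockSnps = 5, ldRho = 0.3)
  sim <- simulateFrequencies(spec)
  geno <- simulateGenotypes(sim, spec)
  pm <- simPopulationMap(geno)
  list(spec = spec, graph = g, sim = sim, genotypes = geno, popmap = pm,
       freqTable = stratifiedAlleleFreqs(geno, pm))
}
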