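## tree_utils: best-tree filtering, deduplication, Robinson-Foulds distances
## and strict consensus for collections of ML search results.

asPhylo <- function(x) {
  if (is(x, "AdmixtureGraph")) x@tree
  else if (is(x, "FitReport")) x@graph@tree
  else x
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' unrooted topologies (branch lengths and migration edges ignored).
#'
#' @param t1,t2 `phylo`, [AdmixtureGraph-class] or [FitReport-class] objects
#'   with identical tip sets.
#' @return integer distance.
#' @export
rfDistance <- function(t1, t2) {
  t1 <- asPhylo(t1); t2 <- asPhylo(t2)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different tip sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Filter ML search results to the unique best-scoring trees
#'
#' Keeps results whose log-likelihood is within `relTol` (relative) of the
#' maximum, then collapses topologically identical trees (unrooted RF = 0)
#' to one representative.
#'
#' @param fits list of `list(graph, loglik)` as returned by [fitTree()].
#' @param relTol relative likelihood tie tolerance.
#' @return list with `trees` (representative fits), `nBest` (count before
#'   dedup), `rf` (pairwise RF matrix of the representatives).
#' @export
selectBestTrees <- function(fits, relTol = 1e-6) {
  stopifnot(length(fits) > 0)
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  mx <- max(lls)
  best <- fits[lls >= mx - abs(mx) * relTol]
  reps <- list(best[[1]])
  for (f in best[-1]) {
    dup <- any(vapply(reps, function(r) rfDistance(r$graph, f$graph) == 0,
                      logical(1)))
    if (!dup) reps <- c(reps, list(f))
  }
  k <- length(reps)
  rf <- matrix(0L, k, k)
  if (k > 1)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      rf[i, j] <- rf[j, i] <- rfDistance(reps[[i]]$graph, reps[[j]]$graph)
  list(trees = reps, nBest = length(best), rf = rf)
}

#' Strict consensus of a set of trees
#'
#' The tree containing exactly the bipartitions present in every input tree.
#'
#' @param trees list of `phylo`/[AdmixtureGraph-class] objects on the same
#'   tip set (or a `multiPhylo`).
#' @return a `phylo`.
#' @export
strictConsensus <- function(trees) {
  phys <- lapply(trees, asPhylo)
  tips <- phys[[1]]$tip.label
  for (p in phys[-1])
    if (!setequal(p$tip.label, tips)) stop("trees have different tip sets")
  if (length(phys) == 1) return(phys[[1]])
  ape::consensus(phys, p = 1, rooted = FALSE)
}

#' Annotate a consensus tree with bootstrap percentages
#'
#' Labels each internal node of `tree` with the percentage of `replicates`
#' containing the corresponding clade.
#'
#' @param tree a rooted `phylo`.
#' @param replicates list of replicate trees on the same tips.
#' @return the tree with `node.label` percentages.
#' @export
consensusSupport <- function(tree, replicates) {
  tree <- asPhylo(tree)
  reps <- lapply(replicates, asPhylo)
  cl <- ape::prop.clades(tree, reps, rooted = FALSE)
  cl[is.na(cl)] <- 0
  tree$node.label <- round(100 * cl / length(reps))
  tree
}
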