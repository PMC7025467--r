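## graphfit (search side): maximum composite-likelihood tree search and
## sequential migration-edge fitting.

## Root an unrooted/arbitrary topology on the outgroup and make it binary.
rootAtOutgroup <- function(topo, outgroup) {
  topo <- ape::unroot(topo)
  rt <- ape::root(topo, outgroup = outgroup, resolve.root = TRUE)
  if (!ape::is.binary(rt)) rt <- ape::multi2di(rt)
  ## NJ starts can carry negative lengths; lengths are refit anyway
  if (!is.null(rt$edge.length))
    rt$edge.length <- pmax(rt$edge.length, 0)
  rt$edge.length[is.na(rt$edge.length)] <- 0
  rt
}

## Score one topology: root, fit branch lengths by weighted NNLS.
scoreTopology <- function(topo, W, SE, outgroup) {
  rt <- rootAtOutgroup(topo, outgroup)
  g <- admixtureGraph(rt, outgroup = outgroup)
  fit <- fitBranchLengths(g, W, SE)
  rt$edge.length <- fit$lengths
  g@tree <- rt
  list(graph = g, loglik = fit$loglik, C = fit$C)
}

## Tree distances implied by a centered covariance: d_ij = W_ii+W_jj-2W_ij
## (centering cancels, so this is the additive path distance for tree data).
covToDist <- function(W) {
  d <- outer(diag(W), diag(W), `+`) - 2 * W
  d[d < 0] <- 0
  dimnames(d) <- dimnames(W)
  d
}

#' Maximum composite-likelihood tree search
#'
#' Runs independent searches, each from a random-seeded start (neighbour
#' joining on the covariance-implied distances, multiplicatively jittered, or
#' a random topology), fits branch lengths by weighted nonnegative least
#' squares, and hill-climbs over nearest-neighbour-interchange moves until
#' the composite log-likelihood stops improving.  Trees are returned rooted
#' on the outgroup (the objective itself is root-invariant).
#'
#' @param W observed centered covariance (or a [CovMatrix-class]).
#' @param SE per-entry standard errors (ignored when `W` is a CovMatrix).
#' @param outgroup outgroup population label.
#' @param nSearches number of independent searches.
#' @param seed optional RNG seed.
#' @return list of `list(graph, loglik)` sorted by decreasing loglik.
#' @export
fitTree <- function(W, SE, outgroup, nSearches = 20, seed = NULL) {
  if (is(W, "CovMatrix")) { SE <- W@SE; W <- W@W }
  P <- nrow(W)
  if (P < 4) stop("need at least 4 populations")
  if (!(outgroup %in% rownames(W))) stop("outgroup not among populations")
  if (!is.null(seed)) set.seed(seed)
  d <- covToDist(W)
  results <- vector("list", nSearches)
  for (s in seq_len(nSearches)) {
    start <- if (s == 1) {
      ape::nj(d)
    } else if (s <= max(2, ceiling(0.7 * nSearches))) {
      ape::nj(d * matrix(exp(rnorm(P * P, 0, 0.1)), P, P))
    } else {
      ape::rtree(P, tip.label = sample(rownames(W)))
    }
    cur <- scoreTopology(start, W, SE, outgroup)
    repeat {
      nbs <- tryCatch(phangorn::nni(ape::unroot(cur$graph@tree)),
                      error = function(e) NULL)
      if (is.null(nbs) || length(nbs) == 0) break
      scored <- lapply(nbs, scoreTopology, W = W, SE = SE,
                       outgroup = outgroup)
      lls <- vapply(scored, `[[`, numeric(1), "loglik")
      if (max(lls) > cur$loglik + 1e-9) cur <- scored[[which.max(lls)]]
      else break
    }
    results[[s]] <- cur[c("graph", "loglik")]
  }
  results[order(-vapply(results, `[[`, numeric(1), "loglik"))]
}

## Edge indices on the path from a tip to the root.
rootPathEdges <- function(tr, tip) {
  parentEdgeOf <- rep(NA_integer_, max(tr$edge))
  parentEdgeOf[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
  path <- integer(0)
  v <- tip
  while (!is.na(parentEdgeOf[v])) {
    path <- c(path, parentEdgeOf[v])
    v <- tr$edge[parentEdgeOf[v], 1]
  }
  path
}

## Is `anc` a (non-strict) ancestor node of `node` in the tree?
isAncestor <- function(tr, anc, node) {
  parentEdgeOf <- rep(NA_integer_, max(tr$edge))
  parentEdgeOf[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
  v <- node
  repeat {
    if (v == anc) return(TRUE)
    e <- parentEdgeOf[v]
    if (is.na(e)) return(FALSE)
    v <- tr$edge[e, 1]
  }
}

## Fit a graph with one free migration weight (row `mi`); inner NNLS on
## branch lengths.  Returns list(weight, loglik, fit).
optimizeWeight <- function(graph, mi, W, SE, lower = 0.001, upper = 0.999,
                           tol = 1e-3) {
  obj <- function(w) {
    graph@migrations$weight[mi] <- w
    tryCatch(fitBranchLengths(graph, W, SE)$loglik,
             error = function(e) -1e10)
  }
  op <- optimize(obj, c(lower, upper), maximum = TRUE, tol = tol)
  graph@migrations$weight[mi] <- op$maximum
  fit <- fitBranchLengths(graph, W, SE)
  list(weight = op$maximum, loglik = fit$loglik, fit = fit, graph = graph)
}

## Candidate (src_edge, dst_edge) attachments for a residual pair (i, j):
## all orientations between the two tips' root paths, truncated to `beam`
## edges from the tip end, acyclic only.  On small trees (at most `beam`
## internal splits' worth of branches per path anyway) the residual pair is
## bypassed and every ordered branch pair is proposed.
migrationCandidates <- function(tr, tipI, tipJ, beam) {
  E <- nrow(tr$edge)
  if (E * E <= 420) {
    cand <- expand.grid(src = seq_len(E), dst = seq_len(E))
  } else {
    pI <- head(rootPathEdges(tr, tipI), beam)
    pJ <- head(rootPathEdges(tr, tipJ), beam)
    cand <- rbind(expand.grid(src = pI, dst = pJ),
                  expand.grid(src = pJ, dst = pI))
  }
  cand <- cand[cand$src != cand$dst, , drop = FALSE]
  ok <- vapply(seq_len(nrow(cand)), function(k) {
    srcParent <- tr$edge[cand$src[k], 1]
    dstNode <- tr$edge[cand$dst[k], 2]
    !isAncestor(tr, dstNode, srcParent)
  }, logical(1))
  cand[ok, , drop = FALSE]
}

#' Sequentially fit migration edges onto a tree
#'
#' Starting from a fitted tree, repeatedly (m times) locates the population
#' pair with the largest positive scaled residual, proposes migration
#' attachments between the two tips' root paths (source attachment at the
#' midpoint of a source branch, destination at the child node of a
#' destination branch; all acyclic pairs within a beam), screens each
#' proposal at pilot weights, then optimizes the weight of the best few with
#' branch lengths re-fit by nonnegative least squares, keeping the overall
#' best.  After all edges are placed, each weight is re-optimized jointly.
#' Per-edge p-values come from a weighted block jackknife of the weight
#' (leave-one-block-out covariance, fixed graph structure, weight re-fit).
#'
#' @param graph a fitted [AdmixtureGraph-class] (e.g. from [fitTree()]).
#' @param cov a [CovMatrix-class] (block sums are needed for p-values) or a
#'   plain covariance matrix (then supply `SE`, and p-values are `NA`).
#' @param m number of migration edges to add.
#' @param SE per-entry SEs when `cov` is a plain matrix.
#' @param beam candidate edges per root path (default 8).
#' @param computePvalues jackknife the weights? Default `TRUE`.
#' @param seed optional RNG seed (screening order tie-breaks).
#' @return a [FitReport-class].
#' @export
addMigrationEdges <- function(graph, cov, m, SE = NULL, beam = 8,
                              computePvalues = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  isCov <- is(cov, "CovMatrix")
  W <- if (isCov) cov@W else cov
  if (isCov) SE <- cov@SE
  stopifnot(!is.null(SE))
  tips <- graph@tree$tip.label
  W <- W[tips, tips]; SE <- SE[tips, tips]
  fit <- fitBranchLengths(graph, W, SE)
  graph@tree$edge.length <- fit$lengths
  if (m > 0) {
    for (it in seq_len(m)) {
      R <- scaledResiduals(W, fit$C, SE)
      diag(R) <- -Inf
      if (max(R) <= 0) {
        warning("no positive residual; migration edge ", it, " skipped")
        break
      }
      best <- NULL
      ## consider the top residual pairs (ties and near-ties)
      ord <- order(R, decreasing = TRUE)
      topPairs <- unique(t(apply(which(R >= R[ord[3]] - 1e-12,
                                       arr.ind = TRUE), 1, sort)))
      topPairs <- topPairs[seq_len(min(2, nrow(topPairs))), , drop = FALSE]
      for (tp in seq_len(nrow(topPairs))) {
        cand <- migrationCandidates(graph@tree, topPairs[tp, 1],
                                    topPairs[tp, 2], beam)
        if (nrow(cand) == 0) next
        ## screen at pilot weights
        screen <- vapply(seq_len(nrow(cand)), function(k) {
          g2 <- graph
          g2@migrations <- rbind(g2@migrations,
                                 data.frame(src_edge = cand$src[k],
                                            dst_edge = cand$dst[k],
                                            weight = 0.05, src_frac = 0.5))
          if (anyDuplicated(g2@migrations$src_edge)) return(-Inf)
          mi <- nrow(g2@migrations)
          max(vapply(c(0.05, 0.3), function(w) {
            g2@migrations$weight[mi] <- w
            tryCatch(fitBranchLengths(g2, W, SE)$loglik,
                     error = function(e) -Inf)
          }, numeric(1)))
        }, numeric(1))
        for (k in order(screen, decreasing = TRUE)[
               seq_len(min(3, sum(is.finite(screen))))]) {
          g2 <- graph
          g2@migrations <- rbind(g2@migrations,
                                 data.frame(src_edge = cand$src[k],
                                            dst_edge = cand$dst[k],
                                            weight = 0.05, src_frac = 0.5))
          opt <- tryCatch(optimizeWeight(g2, nrow(g2@migrations), W, SE),
                          error = function(e) NULL)
          if (!is.null(opt) && (is.null(best) || opt$loglik > best$loglik))
            best <- opt
        }
      }
      if (is.null(best) || best$loglik < fit$loglik - 1e-9) {
        warning("no improving migration edge found at step ", it)
        break
      }
      graph <- best$graph
      fit <- best$fit
      graph@tree$edge.length <- fit$lengths
    }
    ## joint refinement: one sweep of per-edge weight re-optimization
    for (mi in seq_len(nrow(graph@migrations))) {
      opt <- optimizeWeight(graph, mi, W, SE)
      graph <- opt$graph
      fit <- opt$fit
    }
    graph@tree$edge.length <- fit$lengths
  }
  buildFitReport(graph, fit, W, SE, cov = if (isCov) cov else NULL,
                 computePvalues = computePvalues)
}

## Jackknife a migration weight over leave-one-block-out covariances.
jackknifeWeights <- function(graph, cov) {
  B <- length(cov@blockN)
  tips <- graph@tree$tip.label
  nm <- nrow(graph@migrations)
  loo <- matrix(NA_real_, nrow = B, ncol = nm)
  SE <- cov@SE[tips, tips]
  for (b in seq_len(B)) {
    Wb <- covLeaveOneOut(cov, b)[tips, tips]
    for (mi in seq_len(nm)) {
      opt <- tryCatch(optimizeWeight(graph, mi, Wb, SE, tol = 5e-3),
                      error = function(e) NULL)
      loo[b, mi] <- if (is.null(opt)) NA else opt$weight
    }
  }
  loo
}

buildFitReport <- function(graph, fit, W, SE, cov = NULL,
                           computePvalues = TRUE) {
  ve <- varianceExplained(W, fit$C)
  R <- scaledResiduals(W, fit$C, SE)
  mig <- graph@migrations
  nm <- nrow(mig)
  sets <- migrationTipSets(graph)
  migdf <- data.frame(src_edge = mig$src_edge, dst_edge = mig$dst_edge,
                      weight = mig$weight,
                      weightJack = rep(NA_real_, nm),
                      se = rep(NA_real_, nm), p = rep(NA_real_, nm),
                      origin = vapply(sets, function(s)
                        paste(sort(s$origin), collapse = ","), character(1)),
                      dest = vapply(sets, function(s)
                        paste(sort(s$dest), collapse = ","), character(1)))
  if (nm > 0 && computePvalues && !is.null(cov) &&
      length(cov@blockN) >= 2) {
    loo <- jackknifeWeights(graph, cov)
    n <- cov@blockN
    for (mi in seq_len(nm)) {
      ok <- !is.na(loo[, mi])
      if (sum(ok) < 2) next
      g <- sum(ok); N <- sum(n[ok]); h <- N / n[ok]
      est <- mig$weight[mi]
      thetaJ <- g * est - sum((1 - n[ok] / N) * loo[ok, mi])
      tau <- h * est - (h - 1) * loo[ok, mi]
      se <- sqrt(sum((tau - thetaJ)^2 / (h - 1)) / g)
      migdf$weightJack[mi] <- thetaJ
      migdf$se[mi] <- se
      migdf$p[mi] <- if (se > 0) 2 * pnorm(-abs(est / se)) else 0
    }
  }
  new("FitReport", graph = graph, loglik = fit$loglik,
      varianceExplained = ve, fitted = fit$C, residuals = R,
      migrations = migdf)
}

#' Fit a full admixture graph from an allele-frequency table
#'
#' Convenience wrapper: covariance, tree search, migration-edge fitting.
#'
#' Admixture pulls the pure-tree optimum away from the true topology, so
#' the best base tree for migration fitting is not always the best
#' tree-only fit.  With `baseTrees > 1`, migrations are fitted on the best
#' tree and on up to `baseTrees - 1` of its nearest-neighbour-interchange
#' variants (ranked by tree-only likelihood), and the graph with the best
#' final composite likelihood wins.
#'
#' @param T an [AlleleFreqTable-class].
#' @param outgroup outgroup population label.
#' @param m migration edges to fit.
#' @param block jackknife block size in SNPs.
#' @param nSearches independent tree searches.
#' @param seed optional RNG seed.
#' @param computePvalues jackknife the migration weights?
#' @param noss skip the covariance sample-size correction? Default `TRUE`.
#' @param baseTrees base topologies to try for migration fitting.
#' @return a [FitReport-class].
#' @export
fitGraph <- function(T, outgroup, m = 0, block = 20, nSearches = 10,
                     seed = NULL, computePvalues = FALSE, noss = TRUE,
                     baseTrees = 1) {
  cov <- covarianceMatrix(T, block = block, noss = noss)
  trees <- fitTree(cov, outgroup = outgroup, nSearches = nSearches,
                   seed = seed)
  bases <- list(trees[[1]]$graph)
  if (m > 0 && baseTrees > 1) {
    nbs <- tryCatch(phangorn::nni(ape::unroot(trees[[1]]$graph@tree)),
                    error = function(e) NULL)
    if (length(nbs)) {
      scored <- lapply(nbs, scoreTopology, W = cov@W, SE = cov@SE,
                       outgroup = outgroup)
      scored <- scored[order(-vapply(scored, `[[`, numeric(1), "loglik"))]
      extra <- lapply(head(scored, baseTrees - 1), `[[`, "graph")
      bases <- c(bases, extra)
    }
  }
  reports <- lapply(bases, function(b)
    tryCatch(addMigrationEdges(b, cov, m = m, computePvalues = FALSE),
             error = function(e) NULL))
  reports <- reports[!vapply(reports, is.null, logical(1))]
  if (length(reports) == 0) stop("no base topology produced a fit")
  best <- reports[[which.max(vapply(reports, logLikOf, numeric(1)))]]
  if (computePvalues && m > 0)
    best <- addMigrationEdges(best@graph, cov, m = 0,
                              computePvalues = TRUE)
  best
}
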