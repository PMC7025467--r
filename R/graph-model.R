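## graphfit (model side): allele-frequency covariance under Gaussian drift on
## an admixture graph, composite likelihood, and fit diagnostics.
##
## Internals.  Every branch of the rooted tree is one or two "segments" (a
## branch carrying a migration attachment is split at the attachment point);
## a tip's ancestry decomposes into weighted root paths, and because segment
## traversal is all-or-nothing the weighted mean traversal vector u(tip)
## suffices: V[i,j] = sum_s mult_s * L_(edge(s)) * U[i,s] * U[j,s].  The
## observable covariance is V passed through the double-centering projection.

## Segment decomposition of an admixture graph.
## Returns U (tips x segments), segParam (edge index per segment), segMult
## (fraction of the edge length per segment).
graphSegments <- function(graph) {
  tr <- graph@tree
  mig <- graph@migrations
  E <- nrow(tr$edge)
  P <- length(tr$tip.label)
  root <- P + 1L
  nNode <- max(tr$edge)
  attachOf <- rep(NA_integer_, E)          # migration row attached on edge
  if (nrow(mig)) {
    if (anyDuplicated(mig$src_edge))
      stop("multiple migration attachments on one source branch")
    attachOf[mig$src_edge] <- seq_len(nrow(mig))
  }
  segParam <- integer(0); segMult <- numeric(0)
  lowerSeg <- upperSeg <- fullSeg <- rep(NA_integer_, E)
  for (e in seq_len(E)) {
    if (!is.na(attachOf[e])) {
      f <- mig$src_frac[attachOf[e]]
      lowerSeg[e] <- length(segParam) + 1L
      segParam <- c(segParam, e); segMult <- c(segMult, f)
      upperSeg[e] <- length(segParam) + 1L
      segParam <- c(segParam, e); segMult <- c(segMult, 1 - f)
    } else {
      fullSeg[e] <- length(segParam) + 1L
      segParam <- c(segParam, e); segMult <- c(segMult, 1)
    }
  }
  S <- length(segParam)
  parentEdgeOf <- rep(NA_integer_, nNode)
  parentEdgeOf[tr$edge[, 2]] <- seq_len(E)
  dstNode <- if (nrow(mig)) tr$edge[mig$dst_edge, 2] else integer(0)

  memo <- vector("list", nNode)
  inStack <- rep(FALSE, nNode)
  uAttach <- function(m) {
    e <- mig$src_edge[m]
    u <- uNode(tr$edge[e, 1])
    u[upperSeg[e]] <- u[upperSeg[e]] + 1
    u
  }
  uNode <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    if (v == root) {
      u <- numeric(S)
    } else {
      if (inStack[v]) stop("migration edges create a cycle")
      inStack[v] <<- TRUE
      e <- parentEdgeOf[v]
      u <- uNode(tr$edge[e, 1])
      segs <- if (!is.na(attachOf[e])) c(lowerSeg[e], upperSeg[e])
              else fullSeg[e]
      u[segs] <- u[segs] + 1
      migIn <- which(dstNode == v)
      if (length(migIn)) {
        wsum <- sum(mig$weight[migIn])
        u <- (1 - wsum) * u
        for (m in migIn) u <- u + mig$weight[m] * uAttach(m)
      }
      inStack[v] <<- FALSE
    }
    memo[[v]] <<- u
    u
  }
  U <- t(vapply(seq_len(P), uNode, numeric(S)))
  rownames(U) <- tr$tip.label
  list(U = U, segParam = segParam, segMult = segMult, nEdges = E)
}

## Double-centering projection C = V - rowmean - colmean + grandmean.
centerMat <- function(V) {
  rm <- rowMeans(V); cm <- colMeans(V); gm <- mean(rm)
  (V - rm) - matrix(cm, nrow(V), ncol(V), byrow = TRUE) + gm
}

#' Predicted (centered) covariance of an admixture graph
#'
#' The model covariance of population allele frequencies implied by a graph:
#' for each pair of tips, the drift shared by their ancestry paths (weighted
#' by products of migration weights), passed through the same
#' double-centering projection applied to the sample covariance.
#'
#' @param graph an [AdmixtureGraph-class] with branch lengths.
#' @param lengths optional replacement branch lengths (per tree edge).
#' @return numeric P x P centered covariance, dimnames = tip labels.
#' @export
predictedCovariance <- function(graph, lengths = NULL) {
  if (nrow(graph@migrations) &&
      any(graph@migrations$weight <= 0 | graph@migrations$weight >= 1))
    stop("migration weights must lie in (0,1)")
  sg <- graphSegments(graph)
  L <- if (is.null(lengths)) graph@tree$edge.length else lengths
  if (is.null(L)) stop("graph has no branch lengths")
  wseg <- sg$segMult * L[sg$segParam]
  V <- sg$U %*% (wseg * t(sg$U))
  C <- centerMat(V)
  dimnames(C) <- list(rownames(sg$U), rownames(sg$U))
  C
}

## Design matrix for branch-length fitting: one column per tree edge, one
## row per unique covariance entry (i <= j), already divided by SE.
## ut: logical upper-tri mask (with diagonal).
covDesign <- function(sg, SE, ut) {
  P <- nrow(sg$U)
  E <- sg$nEdges
  A <- matrix(0, nrow = sum(ut), ncol = E)
  Uc <- sg$U - matrix(colMeans(sg$U), nrow(sg$U), ncol(sg$U), byrow = TRUE)
  for (s in seq_along(sg$segParam)) {
    ## centering an outer product aa' is the outer product of centered a
    M <- tcrossprod(Uc[, s])
    A[, sg$segParam[s]] <- A[, sg$segParam[s]] + sg$segMult[s] * M[ut]
  }
  A / SE[ut]
}

## Weighted nonnegative LS fit of branch lengths for a fixed topology and
## fixed migration weights.  Returns lengths, fitted C, loglik.
fitBranchLengths <- function(graph, W, SE, sg = NULL) {
  if (is.null(sg)) sg <- graphSegments(graph)
  tips <- rownames(sg$U)
  W <- W[tips, tips]; SE <- SE[tips, tips]
  P <- length(tips)
  ut <- upper.tri(matrix(0, P, P), diag = TRUE)
  A <- covDesign(sg, SE, ut)
  b <- W[ut] / SE[ut]
  L <- tryCatch(pracma::lsqnonneg(A, b)$x,
                error = function(e) {
                  ## fall back to clamped ridge LS on rare degeneracies
                  M <- crossprod(A)
                  ridge <- 1e-8 * mean(diag(M)) + 1e-12
                  pmax(solve(M + diag(ridge, ncol(A)), crossprod(A, b)), 0)
                })
  wseg <- sg$segMult * L[sg$segParam]
  C <- centerMat(sg$U %*% (wseg * t(sg$U)))
  dimnames(C) <- list(tips, tips)
  ll <- sum(dnorm(W[ut], C[ut], SE[ut], log = TRUE))
  list(lengths = as.numeric(L), C = C, loglik = ll)
}

#' Composite log-likelihood of a graph given an observed covariance
#'
#' Sum over unique matrix entries (i <= j) of the normal log-density of the
#' observed covariance entry around the graph's predicted entry, with the
#' per-entry jackknife SE as standard deviation.
#'
#' @param W observed centered covariance (or a [CovMatrix-class]).
#' @param SE per-entry standard errors (ignored when `W` is a CovMatrix).
#' @param graph an [AdmixtureGraph-class] with branch lengths.
#' @return numeric(1) log composite likelihood.
#' @export
compositeLogLik <- function(W, SE, graph) {
  if (is(W, "CovMatrix")) { SE <- W@SE; W <- W@W }
  if (any(SE <= 0)) stop("SE entries must be > 0")
  C <- predictedCovariance(graph)
  tips <- rownames(C)
  W <- W[tips, tips]; SE <- SE[tips, tips]
  ut <- upper.tri(W, diag = TRUE)
  sum(dnorm(W[ut], C[ut], SE[ut], log = TRUE))
}

#' Fraction of covariance variance explained by a fitted model
#'
#' 1 - SSE/SST over unique entries (i <= j), SST about the mean observed
#' entry.
#'
#' @param W observed centered covariance (or a [CovMatrix-class]).
#' @param C_fit fitted covariance of the same shape.
#' @return numeric(1).
#' @export
varianceExplained <- function(W, C_fit) {
  if (is(W, "CovMatrix")) W <- W@W
  if (!is.null(rownames(C_fit)) && !is.null(rownames(W)))
    W <- W[rownames(C_fit), colnames(C_fit)]
  ut <- upper.tri(W, diag = TRUE)
  sst <- sum((W[ut] - mean(W[ut]))^2)
  if (sst == 0) stop("constant covariance matrix: variance undefined")
  1 - sum((W[ut] - C_fit[ut])^2) / sst
}

#' Scaled residuals of a covariance fit
#'
#' @param W observed centered covariance (or a [CovMatrix-class], which
#'   supplies `SE`).
#' @param C_fit fitted covariance.
#' @param SE per-entry standard errors.
#' @return numeric P x P matrix (W - C_fit) / SE.
#' @export
scaledResiduals <- function(W, C_fit, SE) {
  if (is(W, "CovMatrix")) { SE <- W@SE; W <- W@W }
  stopifnot(all(SE > 0))
  if (!is.null(rownames(C_fit)) && !is.null(rownames(W))) {
    W <- W[rownames(C_fit), colnames(C_fit)]
    SE <- SE[rownames(C_fit), colnames(C_fit)]
  }
  (W - C_fit) / SE
}

#' Sample covariance of population allele frequencies
#'
#' Per SNP, population frequencies are centered by the unweighted
#' across-population mean; the covariance is the SNP average of the centered
#' cross-products.  With `noss = FALSE` the binomial sampling-variance bias
#' (estimated as x(1-x)/(n-1) per population) is removed from the entries,
#' including the terms the centering spreads across the matrix; the default
#' `noss = TRUE` skips the correction (the paper-recommended behaviour for
#' unequal, small sample sizes).  Per-entry SEs come from a weighted
#' delete-one-block jackknife over contiguous SNP blocks.
#'
#' @param T an [AlleleFreqTable-class]; SNPs where any population has no
#'   sampled alleles are skipped.
#' @param block jackknife block size in SNPs.
#' @param noss skip the sample-size bias correction? Default `TRUE`.
#' @return a [CovMatrix-class].
#' @export
covarianceMatrix <- function(T, block = 20, noss = TRUE) {
  P <- length(T@populations)
  if (P < 3) stop("need at least 3 populations")
  tot <- T@totals
  usable <- rowSums(tot > 0) == P
  if (!noss) usable <- usable & rowSums(tot >= 2) == P
  n <- sum(usable)
  if (n < 2) stop("fewer than 2 usable SNPs")
  x <- (T@counts / tot)[usable, , drop = FALSE]
  xc <- x - rowMeans(x)
  blockId <- snpBlockIds(nrow(tot), block)[usable]
  ublk <- sort(unique(blockId))
  B <- length(ublk)
  sums <- array(0, dim = c(P, P, B))
  cnt <- integer(B)
  for (b in seq_len(B)) {
    sel <- blockId == ublk[b]
    cnt[b] <- sum(sel)
    Sb <- crossprod(xc[sel, , drop = FALSE])
    if (!noss) {
      xb <- x[sel, , drop = FALSE]
      h <- xb * (1 - xb) / (tot[usable, , drop = FALSE][sel, , drop = FALSE] - 1)
      ## E[(e_i - ebar)(e_j - ebar)] = d_ij h_i - (h_i + h_j)/P + sum(h)/P^2
      for (s2 in seq_len(nrow(h))) {
        hh <- h[s2, ]
        corr <- diag(hh, P) - outer(hh, rep(1 / P, P)) -
          outer(rep(1 / P, P), hh) + sum(hh) / P^2
        Sb <- Sb - corr
      }
    }
    sums[, , b] <- Sb
  }
  Stot <- apply(sums, c(1, 2), sum)
  W <- Stot / n
  ## weighted jackknife SE per entry
  SE <- matrix(0, P, P)
  if (B >= 2) {
    for (i in seq_len(P)) for (j in seq_len(P)) {
      jk <- blockJackknife(sums[i, j, ], cnt)
      SE[i, j] <- jk$se
    }
  }
  SE[SE <= 0] <- max(SE, 1e-8) * 1e-4 + 1e-12
  dimnames(W) <- dimnames(SE) <- list(T@populations, T@populations)
  new("CovMatrix", populations = T@populations, W = W, SE = SE,
      blockSums = sums, blockN = as.integer(cnt))
}

## Leave-one-block-out covariance from stored block sums.
covLeaveOneOut <- function(cov, b) {
  Stot <- apply(cov@blockSums, c(1, 2), sum)
  W <- (Stot - cov@blockSums[, , b]) / (sum(cov@blockN) - cov@blockN[b])
  dimnames(W) <- dimnames(cov@W)
  W
}
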