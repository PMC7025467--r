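## edge_support: block bootstrap of the fitted graph and the migration
## support indices MS (strict clade match) and MS_E (containment match).

#' Block-bootstrap resample of an allele-frequency table
#'
#' Partitions SNPs into contiguous blocks of `block` (the final short block,
#' if any, is its own resampling unit), draws blocks with replacement until
#' the original block count is reached, and concatenates them preserving
#' within-block SNP order.  Deterministic given `seed`.
#'
#' @param T an [AlleleFreqTable-class].
#' @param block SNPs per block.
#' @param seed optional RNG seed.
#' @return an [AlleleFreqTable-class] with the same number of blocks.
#' @export
bootstrapBlockResample <- function(T, block = 20, seed = NULL) {
  stopifnot(block >= 1)
  if (!is.null(seed)) set.seed(seed)
  blockId <- snpBlockIds(nrow(T@counts), block)
  B <- max(blockId)
  draw <- sample.int(B, B, replace = TRUE)
  idx <- unlist(lapply(draw, function(b) which(blockId == b)),
                use.names = FALSE)
  snps <- T@snps[idx, , drop = FALSE]
  snps$id <- make.unique(snps$id)
  AlleleFreqTable(T@populations, snps,
                  T@counts[idx, , drop = FALSE],
                  T@totals[idx, , drop = FALSE])
}

splitTips <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]

#' Match two migration edges by their clade descriptors
#'
#' Edges are described by origin and destination tip sets.  `strict` requires
#' both sets to be equal; `extended` requires, for each endpoint, that one
#' set contain the other (non-strict containment), with orientation
#' preserved.
#'
#' @param observed,reference each a `list(origin=, dest=)` of tip-label
#'   vectors, or a one-row slice of a [migrationEdges()] data.frame.
#' @param mode `"strict"` or `"extended"`.
#' @return logical(1).
#' @export
edgeMatch <- function(observed, reference, mode = c("strict", "extended")) {
  mode <- match.arg(mode)
  toSets <- function(e) {
    if (is.data.frame(e))
      list(origin = splitTips(e$origin[1]), dest = splitTips(e$dest[1]))
    else e
  }
  o <- toSets(observed); r <- toSets(reference)
  cmp <- function(a, b) {
    if (mode == "strict") setequal(a, b)
    else all(a %in% b) || all(b %in% a)
  }
  cmp(o$origin, r$origin) && cmp(o$dest, r$dest)
}

#' Migration support (MS) of reference edges over bootstrap replicates
#'
#' For each migration edge of the reference fit, the percentage of replicate
#' fits containing at least one edge matching it under `mode` ("strict" for
#' MS, "extended" for MS_E), rounded to an integer.
#'
#' @param reference a [FitReport-class] (or its [migrationEdges()] frame).
#' @param replicates list of replicate [FitReport-class]s (or edge frames);
#'   replicates with no edges still count in the denominator.
#' @param mode `"strict"` or `"extended"`.
#' @return integer vector, one MS value per reference edge.
#' @export
migrationSupport <- function(reference, replicates,
                             mode = c("strict", "extended")) {
  mode <- match.arg(mode)
  if (length(replicates) == 0) stop("zero replicates")
  refEdges <- if (is(reference, "FitReport")) reference@migrations
              else reference
  repEdges <- lapply(replicates, function(r)
    if (is(r, "FitReport")) r@migrations else r)
  vapply(seq_len(nrow(refEdges)), function(i) {
    ref <- refEdges[i, , drop = FALSE]
    hits <- vapply(repEdges, function(re) {
      if (nrow(re) == 0) return(FALSE)
      any(vapply(seq_len(nrow(re)), function(j)
        edgeMatch(re[j, , drop = FALSE], ref, mode), logical(1)))
    }, logical(1))
    as.integer(round(100 * mean(hits)))
  }, integer(1))
}

#' Bootstrap-refit a graph and compute MS / MS_E
#'
#' Convenience driver: resamples the table `nReps` times, refits tree + `m`
#' migration edges on each replicate, and computes strict and extended
#' migration support for every reference edge.
#'
#' @param T the original [AlleleFreqTable-class].
#' @param reference the reference [FitReport-class].
#' @param outgroup outgroup label.
#' @param m migration edges per replicate fit.
#' @param nReps bootstrap replicates.
#' @param block SNPs per block.
#' @param seed RNG seed (replicate r uses seed + r).
#' @param nSearches tree searches per replicate.
#' @param noss skip the covariance sample-size correction? Default `TRUE`.
#' @param baseTrees base topologies per replicate fit (see [fitGraph()]).
#' @return list with `MS`, `MS_E` (integer vectors per reference edge),
#'   `nConverged`, and `replicates` (the replicate edge frames).
#' @export
bootstrapMigrationSupport <- function(T, reference, outgroup, m,
                                      nReps = 100, block = 20, seed = 1,
                                      nSearches = 2, noss = TRUE,
                                      baseTrees = 1) {
  reps <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    bt <- bootstrapBlockResample(T, block = block, seed = seed + r)
    reps[[r]] <- tryCatch(
      migrationEdges(fitGraph(bt, outgroup = outgroup, m = m, block = block,
                              nSearches = nSearches, seed = seed + r,
                              noss = noss, baseTrees = baseTrees)),
      error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("no bootstrap replicate converged")
  reps <- reps[ok]
  list(MS = migrationSupport(reference, reps, "strict"),
       MS_E = migrationSupport(reference, reps, "extended"),
       nConverged = sum(ok), replicates = reps)
}

#' Summarize equivalent migration edges across final runs
#'
#' Groups edges across runs by strict clade match, reporting how many runs
#' contain each edge (N), the mean weight, and — from the designated best
#' run — the jackknife weight, SE and p; MS/MS_E columns are filled when
#' bootstrap support values are supplied.
#'
#' @param finalRuns list of [FitReport-class]s.
#' @param bestRun index of the run whose jackknife columns are reported.
#' @param support optional result of [bootstrapMigrationSupport()] computed
#'   for the best run's edges.
#' @return data.frame, one row per distinct edge, Table-style columns
#'   `edge`, `origin`, `dest`, `N`, `w_mean`, `w_jack`, `se_jack`, `p`,
#'   `MS`, `MS_E`.
#' @export
summarizeMigrations <- function(finalRuns, bestRun = 1, support = NULL) {
  stopifnot(length(finalRuns) >= 1)
  allEdges <- lapply(finalRuns, migrationEdges)
  groups <- list()   # each: list(rep = first seen row, weights = numeric)
  for (run in allEdges) {
    for (j in seq_len(nrow(run))) {
      e <- run[j, , drop = FALSE]
      hit <- which(vapply(groups, function(g)
        edgeMatch(e, g$rep, "strict"), logical(1)))
      if (length(hit)) {
        groups[[hit[1]]]$weights <- c(groups[[hit[1]]]$weights, e$weight)
        groups[[hit[1]]]$n <- groups[[hit[1]]]$n + 1L
      } else {
        groups[[length(groups) + 1L]] <- list(rep = e, weights = e$weight,
                                              n = 1L)
      }
    }
  }
  bestEdges <- allEdges[[bestRun]]
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    bi <- which(vapply(seq_len(nrow(bestEdges)), function(j)
      edgeMatch(bestEdges[j, , drop = FALSE], g$rep, "strict"), logical(1)))
    data.frame(edge = LETTERS[i], origin = g$rep$origin, dest = g$rep$dest,
               N = g$n, w_mean = mean(g$weights),
               w_jack = if (length(bi)) bestEdges$weightJack[bi[1]] else NA,
               se_jack = if (length(bi)) bestEdges$se[bi[1]] else NA,
               p = if (length(bi)) bestEdges$p[bi[1]] else NA,
               MS = NA_integer_, MS_E = NA_integer_)
  }))
  if (!is.null(support)) {
    for (j in seq_len(nrow(bestEdges))) {
      gi <- which(vapply(groups, function(g)
        edgeMatch(bestEdges[j, , drop = FALSE], g$rep, "strict"),
        logical(1)))
      if (length(gi)) {
        out$MS[gi[1]] <- support$MS[j]
        out$MS_E[gi[1]] <- support$MS_E[j]
      }
    }
  }
  rownames(out) <- NULL
  out
}
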