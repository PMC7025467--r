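## cli_pipeline: one-config orchestration of the full workflow
## (qc -> freqs -> blocksize -> tree fit -> migrations -> bootstrap ->
## f-statistics -> summary), with a stage manifest and resumable outputs.

pipelineDefaults <- function() {
  list(snp_miss = 0.2, sample_miss = 0.2, maf = 0.01,
       window_kb = 500, ld_bin = 75, threshold_kb = 200,
       block_start = 5, block_step = 5, k = NULL,
       m = 8, searches = 10, bootstrap = 0, boot_searches = 2,
       seed = 1, outgroup = NULL)
}

#' Run the full admixture-inference pipeline from one configuration
#'
#' Stages: genotype QC (anchoring, missingness, MAF, optional exclusion
#' list); stratified allele frequencies (TreeMix format); LD-aware SNP
#' block-size determination; covariance + ML tree search; sequential
#' migration-edge fitting; optional block-bootstrap migration support;
#' optional f3/f4 test batch; summary.  Each stage writes plain-text outputs
#' into `outdir` and is skipped on rerun when its outputs already exist, so
#' deleting a late-stage output recomputes only that stage and those after
#' it.
#'
#' @param config a list or path to a YAML file.  Keys: either
#'   `simulate: {seed, n_snps}` (built-in scenario) or
#'   `input: {genotypes, popmap, format, exclude}`; `outdir`; `outgroup`;
#'   and any of the parameter defaults (`snp_miss`, `sample_miss`, `maf`,
#'   `threshold_kb`, `block_start`, `block_step`, `k`, `m`, `searches`,
#'   `bootstrap`, `seed`).  `fstat_tests` may name a TSV with columns
#'   `statistic` (f3, f4, f3_outgroup, zdiff) and `pop1..pop4`.
#' @return the run directory path (invisibly); see `manifest.json` there.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  prm <- pipelineDefaults()
  for (k in intersect(names(config), names(prm))) prm[[k]] <- config[[k]]
  if (is.null(config$outdir)) stop("config key missing: outdir")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = prm, stages = list())
  stamp <- function(stage, outputs, skipped = FALSE) {
    manifest$stages[[stage]] <<- list(outputs = outputs, skipped = skipped)
    message("[", stage, "] ", if (skipped) "cached" else "done")
  }
  pth <- function(...) file.path(outdir, ...)

  ## ---- stage 1: input + QC -------------------------------------------
  qcGeno <- pth("qc_genotypes.tsv")
  qcPop <- pth("qc_popmap.tsv")
  if (file.exists(qcGeno) && file.exists(qcPop)) {
    G <- readGenotypeTable(qcGeno, "tsv")
    pm <- readPopulationMap(qcPop)
    if (is.null(prm$outgroup) && file.exists(pth("params.json")))
      prm$outgroup <- jsonlite::read_json(pth("params.json"))$outgroup
    stamp("qc", c(qcGeno, qcPop), skipped = TRUE)
  } else {
    if (!is.null(config$simulate)) {
      sc <- paperLikeScenario(seed = config$simulate$seed %||% prm$seed,
                              nSnps = config$simulate$n_snps %||% 4000)
      G <- sc$genotypes; pm <- sc$popmap
      if (is.null(prm$outgroup)) prm$outgroup <- sc$graph@outgroup
    } else {
      if (is.null(config$input$genotypes))
        stop("config key missing: input.genotypes")
      G <- readGenotypeTable(config$input$genotypes,
                             config$input$format %||% "tsv")
      pm <- readPopulationMap(config$input$popmap)
    }
    if (!is.null(config$input$exclude))
      G <- applyExclusionList(G, readLines(config$input$exclude))
    G <- filterAnchoredSnps(G)
    G <- filterMissingness(G, sampleMax = prm$sample_miss,
                           snpMax = prm$snp_miss)
    G <- filterMaf(G, minMaf = prm$maf)
    writeGenotypeTable(G, qcGeno)
    write.table(data.frame(sample = sampleIds(G),
                           population = unname(pm[sampleIds(G)])),
                qcPop, sep = "\t", quote = FALSE, row.names = FALSE)
    stamp("qc", c(qcGeno, qcPop))
  }
  if (is.null(prm$outgroup)) stop("config key missing: outgroup")
  jsonlite::write_json(prm[!vapply(prm, is.null, logical(1))],
                       pth("params.json"), auto_unbox = TRUE, digits = NA)

  ## ---- stage 2: stratified frequencies -------------------------------
  fqPath <- pth("freqs.treemix.gz")
  if (file.exists(fqPath)) {
    T <- readTreemixFreqs(fqPath, snps = snpInfo(G)[, c("id", "chrom", "pos")])
    stamp("freqs", fqPath, skipped = TRUE)
  } else {
    T <- stratifiedAlleleFreqs(G, pm)
    writeTreemixFreqs(T, fqPath)
    stamp("freqs", fqPath)
  }

  ## ---- stage 3: block size -------------------------------------------
  bsPath <- pth("blocksize.json")
  if (file.exists(bsPath)) {
    k <- jsonlite::read_json(bsPath)$k
    stamp("blocksize", bsPath, skipped = TRUE)
  } else {
    if (!is.null(prm$k)) {
      k <- prm$k
      jsonlite::write_json(list(k = k, fixed = TRUE), bsPath,
                           auto_unbox = TRUE)
    } else {
      bs <- determineBlockSize(snpInfo(T), thresholdKb = prm$threshold_kb,
                               start = prm$block_start,
                               step = prm$block_step)
      k <- bs$k
      jsonlite::write_json(list(k = k, trace = bs$trace), bsPath,
                           auto_unbox = TRUE, digits = NA)
    }
    stamp("blocksize", bsPath)
  }

  ## ---- stage 4: covariance + tree ------------------------------------
  treePath <- pth("tree.nwk"); fitPath <- pth("fit.json")
  cov <- covarianceMatrix(T, block = k)
  if (file.exists(treePath) && file.exists(fitPath)) {
    tr <- ape::read.tree(treePath)
    graph <- admixtureGraph(tr, outgroup = prm$outgroup)
    fitInfo <- jsonlite::read_json(fitPath)
    stamp("fit", c(treePath, fitPath), skipped = TRUE)
  } else {
    fits <- fitTree(cov, outgroup = prm$outgroup,
                    nSearches = prm$searches, seed = prm$seed)
    best <- selectBestTrees(fits)
    graph <- best$trees[[1]]$graph
    fit0 <- fitBranchLengths(graph, cov@W, cov@SE)
    graph@tree$edge.length <- fit0$lengths
    ape::write.tree(graph@tree, treePath)
    fitInfo <- list(loglik = best$trees[[1]]$loglik,
                    variance_explained = varianceExplained(cov, fit0$C),
                    n_best = best$nBest,
                    n_unique_best = length(best$trees),
                    rf_between_best = if (length(best$trees) > 1)
                      max(best$rf) else 0)
    jsonlite::write_json(fitInfo, fitPath, auto_unbox = TRUE, digits = NA)
    stamp("fit", c(treePath, fitPath))
  }

  ## ---- stage 5: migrations -------------------------------------------
  migPath <- pth("migrations.tsv"); migFit <- pth("fit_migrations.json")
  if (file.exists(migPath) && file.exists(migFit)) {
    migs <- read.table(migPath, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    report <- NULL
    stamp("migrations", c(migPath, migFit), skipped = TRUE)
  } else {
    report <- addMigrationEdges(graph, cov, m = prm$m,
                                computePvalues = prm$m <= 4,
                                seed = prm$seed)
    migs <- migrationEdges(report)
    write.table(migs, migPath, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(loglik = report@loglik,
                              variance_explained = report@varianceExplained),
                         migFit, auto_unbox = TRUE, digits = NA)
    stamp("migrations", c(migPath, migFit))
  }

  ## ---- stage 6: bootstrap migration support --------------------------
  msPath <- pth("migration_support.tsv")
  if (prm$bootstrap > 0 && nrow(migs) > 0) {
    if (file.exists(msPath)) stamp("bootstrap", msPath, skipped = TRUE)
    else {
      sup <- bootstrapMigrationSupport(T, migs, outgroup = prm$outgroup,
                                       m = prm$m, nReps = prm$bootstrap,
                                       block = k, seed = prm$seed,
                                       nSearches = prm$boot_searches)
      migs$MS <- sup$MS; migs$MS_E <- sup$MS_E
      write.table(migs, msPath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      stamp("bootstrap", msPath)
    }
  } else stamp("bootstrap", character(0), skipped = TRUE)

  ## ---- stage 7: f statistics -----------------------------------------
  fsPath <- pth("fstats.tsv")
  if (!is.null(config$fstat_tests)) {
    if (file.exists(fsPath)) stamp("fstats", fsPath, skipped = TRUE)
    else {
      tests <- read.table(config$fstat_tests, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      rows <- lapply(seq_len(nrow(tests)), function(i) {
        tt <- tests[i, ]
        res <- switch(tt$statistic,
          f3 = f3Admixture(T, tt$pop1, tt$pop2, tt$pop3, block = k),
          f4 = f4Stat(T, tt$pop1, tt$pop2, tt$pop3, tt$pop4, block = k),
          f3_outgroup = f3Outgroup(T, tt$pop1, tt$pop2, tt$pop3, block = k),
          zdiff = zdiffOutgroup(T, tt$pop1, tt$pop2, tt$pop3, tt$pop4,
                                block = k),
          stop("unknown statistic: ", tt$statistic))
        if (is(res, "ZDiff"))
          data.frame(statistic = "zdiff",
                     populations = paste(c(res@outgroup, res@target,
                                           res@ref1, res@ref2),
                                         collapse = ";"),
                     estimate = res@f3_1 - res@f3_2, se = NA,
                     z = res@zdiff, p = NA, n_blocks = res@nBlocks,
                     n_snps = NA)
        else asRow(res)
      })
      fsTab <- do.call(rbind, rows)
      hb <- holmBonferroni(ifelse(is.na(fsTab$p), 1, fsTab$p))
      fsTab$p_adjusted <- ifelse(is.na(fsTab$p), NA, hb$p_adjusted)
      fsTab$holm_reject <- ifelse(is.na(fsTab$p), NA, hb$reject)
      write.table(fsTab, fsPath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      stamp("fstats", fsPath)
    }
  } else stamp("fstats", character(0), skipped = TRUE)

  ## ---- summary --------------------------------------------------------
  summary <- list(
    n_snps = nrow(alleleCounts(T)), n_populations = length(populations(T)),
    block_size = k,
    variance_explained_tree = fitInfo$variance_explained,
    variance_explained_migrations =
      if (!is.null(report)) report@varianceExplained
      else jsonlite::read_json(migFit)$variance_explained,
    n_migrations = nrow(migs))
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
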