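## genotype_io: readers/writers for genotype tables, population maps and the
## TreeMix allele-frequency exchange format.

#' Read a genotype table (TSV dialect or PLINK-style .ped/.map text)
#'
#' The TSV dialect has a header row `sample` followed by one SNP id per
#' column, one row per sample with calls 0/1/2 (copies of the counted allele)
#' or `NA`/empty for missing, and a sidecar `.map` file (tab-separated
#' `id`, `chrom`, `pos`).  PLINK-style text is a `.ped` (FID IID PAT MAT SEX
#' PHENO + two allele columns per SNP, `0` = missing) with a 4-column `.map`
#' (`chrom`, `id`, `cM` (ignored), `pos`); the counted allele is the minor
#' allele across the file, ties broken alphabetically.
#'
#' Chromosome labels outside `1..19` are kept with the label `"unanchored"`
#' (use [filterAnchoredSnps()] to drop them).  SNPs are returned in genome
#' order.
#'
#' @param path genotype file (TSV or .ped).
#' @param format `"tsv"` or `"plink"`.
#' @param mapPath sidecar map file; default replaces `path`'s extension with
#'   `.map`.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeTable <- function(path, format = c("tsv", "plink"),
                              mapPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(mapPath)) mapPath <- sub("\\.[^.]*$", ".map", path)
  if (!file.exists(mapPath)) stop("map file not found: ", mapPath)
  if (format == "tsv") readGenotypeTsv(path, mapPath)
  else readGenotypePed(path, mapPath)
}

normChrom <- function(chrom) {
  chrom <- as.character(chrom)
  ok <- chrom %in% as.character(1:19)
  chrom[!ok] <- UNANCHORED
  chrom
}

readSnpMap <- function(mapPath, plink = FALSE) {
  m <- read.table(mapPath, header = !plink, sep = "\t",
                  stringsAsFactors = FALSE)
  if (plink) {
    if (ncol(m) < 4) stop("PLINK .map needs 4 columns: ", mapPath)
    m <- data.frame(id = as.character(m[[2]]), chrom = normChrom(m[[1]]),
                    pos = as.integer(m[[4]]))
  } else {
    if (!all(c("id", "chrom", "pos") %in% names(m)))
      stop("map file needs columns id, chrom, pos: ", mapPath)
    m <- data.frame(id = as.character(m$id), chrom = normChrom(m$chrom),
                    pos = as.integer(m$pos))
  }
  if (anyDuplicated(m$id))
    stop("duplicate SNP id in map: ", m$id[duplicated(m$id)][1])
  m
}

readGenotypeTsv <- function(path, mapPath) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("genotype TSV has no sample rows: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  snpIds <- hdr[-1]
  if (anyDuplicated(snpIds))
    stop("duplicate SNP id in header: ", snpIds[duplicated(snpIds)][1])
  n <- length(lines) - 1L
  callm <- matrix(NA_integer_, nrow = length(snpIds), ncol = n)
  samples <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop("malformed row at line ", i + 1L, " of ", path,
           ": expected ", length(hdr), " fields, got ", length(f))
    samples[i] <- f[1]
    v <- f[-1]
    v[v %in% c("", "NA", ".")] <- NA
    vn <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(vn) | !(vn %in% 0:2)))
    if (length(bad))
      stop("invalid genotype call '", v[bad[1]], "' at line ", i + 1L,
           " of ", path)
    callm[, i] <- vn
  }
  colnames(callm) <- samples
  m <- readSnpMap(mapPath)
  if (!setequal(m$id, snpIds))
    stop("SNP ids in ", path, " and ", mapPath, " disagree")
  m <- m[match(snpIds, m$id), , drop = FALSE]
  GenotypeMatrix(callm, m, sort = TRUE)
}

readGenotypePed <- function(path, mapPath) {
  m <- readSnpMap(mapPath, plink = TRUE)
  lines <- readLines(path)
  nSnp <- nrow(m)
  alle <- matrix(NA_character_, nrow = 2L * nSnp, ncol = length(lines))
  samples <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * nSnp)
      stop("malformed row at line ", i, " of ", path, ": expected ",
           6 + 2 * nSnp, " fields, got ", length(f))
    samples[i] <- f[2]
    alle[, i] <- f[-(1:6)]
  }
  alle[alle == "0"] <- NA
  callm <- matrix(NA_integer_, nrow = nSnp, ncol = length(samples))
  for (s in seq_len(nSnp)) {
    a <- alle[2 * s - 1L, ]; b <- alle[2 * s, ]
    obs <- c(a, b)
    lev <- sort(unique(obs[!is.na(obs)]))
    if (length(lev) > 2)
      stop("SNP ", m$id[s], " has more than two alleles")
    if (length(lev) == 0) next
    cnt <- table(factor(obs, levels = lev))
    counted <- lev[which.min(cnt)]  # minor allele; ties -> alphabetical first
    callm[s, ] <- (a == counted) + (b == counted)
  }
  colnames(callm) <- samples
  GenotypeMatrix(callm, m, sort = TRUE)
}

#' Write a GenotypeMatrix in the TSV dialect
#'
#' @param G a [GenotypeMatrix-class]
#' @param path output genotype TSV; the SNP map is written beside it
#'   (extension `.map`).
#' @export
writeGenotypeTable <- function(G, path) {
  m <- t(G@calls)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(G@snps[, c("id", "chrom", "pos")],
              sub("\\.[^.]*$", ".map", path),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column TSV (header `sample`, `population`).
#' @param path file path
#' @return named character vector: population label per sample id.
#' @export
readPopulationMap <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.character(m$population), as.character(m$sample))
}

#' Stratified per-population allele counts
#'
#' For each population and SNP: count = sum of calls over non-missing
#' individuals, total = 2 x non-missing individuals.  The counted allele is
#' the minor allele computed on the full dataset before stratification:
#' SNPs whose overall counted-allele frequency exceeds 0.5 have their calls
#' flipped (2 - call) so the table always counts the rarer allele; a
#' `flipped` column is added to the SNP metadata.
#'
#' @param G a [GenotypeMatrix-class]
#' @param pm named character vector mapping every sample id to a population.
#' @return an [AlleleFreqTable-class] with populations in first-appearance
#'   order.
#' @export
stratifiedAlleleFreqs <- function(G, pm) {
  ids <- sampleIds(G)
  miss <- setdiff(ids, names(pm))
  if (length(miss))
    stop("samples without population label: ",
         paste(head(miss, 5), collapse = ", "))
  pops <- unique(unname(pm[ids]))
  cl <- G@calls
  overall <- rowSums(cl, na.rm = TRUE) / (2 * rowSums(!is.na(cl)))
  flip <- !is.na(overall) & overall > 0.5
  cl[flip, ] <- 2L - cl[flip, ]
  counts <- totals <- matrix(0L, nrow = nrow(cl), ncol = length(pops))
  for (k in seq_along(pops)) {
    sub <- cl[, pm[ids] == pops[k], drop = FALSE]
    counts[, k] <- as.integer(rowSums(sub, na.rm = TRUE))
    totals[, k] <- as.integer(2L * rowSums(!is.na(sub)))
  }
  snps <- G@snps
  snps$flipped <- flip
  keep <- rowSums(totals) > 0
  if (!all(keep))
    message(sum(!keep), " SNP(s) with no observed calls dropped")
  AlleleFreqTable(pops, snps[keep, , drop = FALSE],
                  counts[keep, , drop = FALSE], totals[keep, , drop = FALSE])
}

#' Write / read the TreeMix frequency format
#'
#' Gzip text: line 1 is the space-separated population labels; each following
#' line holds one SNP as space-separated `a,b` pairs where `a` is the
#' counted-allele count and `b` the count of the other allele
#' (`a + b` = total sampled alleles).
#'
#' @param T an [AlleleFreqTable-class]
#' @param path output `.gz` path (a plain path is gz-compressed anyway).
#' @export
writeTreemixFreqs <- function(T, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(paste(T@populations, collapse = " "), con)
  other <- T@totals - T@counts
  body <- vapply(seq_len(nrow(T@counts)), function(s)
    paste(paste0(T@counts[s, ], ",", other[s, ]), collapse = " "),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeTreemixFreqs
#' @param snps optional SNP metadata data.frame to attach (`id`, `chrom`,
#'   `pos`); the format itself carries none, so by default placeholder ids
#'   `snp1..snpN` with unanchored chromosome labels are used.
#' @return `readTreemixFreqs` returns an [AlleleFreqTable-class].
#' @export
readTreemixFreqs <- function(path, snps = NULL) {
  lines <- readLines(gzfile(path))
  if (length(lines) < 2) stop("empty TreeMix frequency file: ", path)
  pops <- strsplit(trimws(lines[1]), " +")[[1]]
  P <- length(pops)
  n <- length(lines) - 1L
  counts <- totals <- matrix(0L, nrow = n, ncol = P)
  for (s in seq_len(n)) {
    f <- strsplit(trimws(lines[s + 1L]), " +")[[1]]
    if (length(f) != P)
      stop("line ", s + 1L, " of ", path, " has ", length(f),
           " entries, header has ", P, " populations")
    ab <- strsplit(f, ",", fixed = TRUE)
    if (any(lengths(ab) != 2))
      stop("malformed pair on line ", s + 1L, " of ", path)
    a <- suppressWarnings(as.numeric(vapply(ab, `[`, "", 1)))
    b <- suppressWarnings(as.numeric(vapply(ab, `[`, "", 2)))
    if (any(is.na(a) | is.na(b)) || any(a < 0 | b < 0) ||
        any(a != round(a) | b != round(b)))
      stop("pair with negative or non-integer entries on line ", s + 1L,
           " of ", path)
    counts[s, ] <- as.integer(a)
    totals[s, ] <- as.integer(a + b)
  }
  if (is.null(snps))
    snps <- data.frame(id = paste0("snp", seq_len(n)), chrom = UNANCHORED,
                       pos = seq_len(n))
  AlleleFreqTable(pops, snps, counts, totals)
}
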