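# admixkit

Admixture-graph inference and f-statistics for biallelic SNP allele
frequencies, in R.

Population trees are rarely the whole story: hybridisation and
introgression leave covariance between populations that no bifurcating
tree can explain. admixkit implements the standard model-based toolkit for
detecting and quantifying such gene flow from SNP panels of the kind
produced by genotyping arrays — built for, and exercised on, datasets
shaped like wild-species germplasm collections (dozens of populations,
thousands of mapped SNPs, small and unequal sample sizes), but generic to
any diploid biallelic data.

## What it computes

Under the Gaussian drift approximation, a population's allele frequency
drifts along each branch with variance *c·p₀(1−p₀)* (branch length *c* in
units of *t/2Nₑ*), and a migration edge of weight *w* makes a recipient a
*w* : (1−*w*) mixture of a source lineage and its own parent. On that
model the package provides:

* **Covariance engine** — centered sample covariance of population
  frequencies with per-entry block-jackknife standard errors
  (`covarianceMatrix`), the model-predicted covariance of any admixture
  graph (`predictedCovariance`), and a normal composite likelihood
  (`compositeLogLik`).
* **Graph fitting** — maximum composite-likelihood tree search (NJ starts
  + NNI hill climbing, nonnegative least-squares branch lengths,
  `fitTree`), sequential migration-edge placement guided by scaled
  residuals with jackknife SEs and p-values on the weights
  (`addMigrationEdges`, or `fitGraph` for the one-call version), variance
  explained and scaled residual diagnostics.
* **f-statistics** — admixture f3, outgroup f3, f4 and the paired
  |Z_diff| contrast, all with weighted block-jackknife errors
  (`f3Admixture`, `f3Outgroup`, `f4Stat`, `zdiffOutgroup`) and
  Holm-Bonferroni familywise control (`holmBonferroni`).
* **LD-aware blocking** — within-species LD decay (`pairwiseLdR2`,
  `ldDecayBins`) and the iterative SNP block-size determination from
  block-midpoint distances (`determineBlockSize`).
* **Tree post-processing** — best-tree filtering and deduplication,
  Robinson-Foulds distances, strict consensus with bootstrap support
  (`selectBestTrees`, `rfDistance`, `strictConsensus`,
  `consensusSupport`).
* **Migration support** — block-bootstrap refitting with the MS (exact
  clade match) and MS_E (containment) support indices
  (`bootstrapBlockResample`, `migrationSupport`,
  `bootstrapMigrationSupport`, `summarizeMigrations`).
* **QC and I/O** — anchoring/missingness/MAF filters and exclusion lists
  (`filterAnchoredSnps`, `filterMissingness`, `filterMaf`,
  `applyExclusionList`, `speciesSubset`); readers/writers for a TSV
  genotype dialect, PLINK-style `.ped`/`.map` text, and the gzipped
  TreeMix frequency format (`readGenotypeTable`, `stratifiedAlleleFreqs`,
  `writeTreemixFreqs`, `readTreemixFreqs`).
* **Simulator** — allele frequencies by drift on any admixture graph,
  diploid genotype sampling with missingness and optional short-range LD,
  and a bundled array-scale scenario with ground truth
  (`simulateFrequencies`, `simulateGenotypes`, `paperLikeScenario`).
* **Pipeline** — `runPipeline(config)` chains QC → frequencies → block
  size → tree → migrations → bootstrap → f-tests from one YAML/list
  config, with cached, resumable plain-text stage outputs and a manifest.

The methods vignette (`vignettes/admixture-inference.Rmd`) documents the
model, the numerical choices and the simulator's scope.

## Genotype TSV dialect

`readGenotypeTable(path, "tsv")` expects a tab-separated file with header
`sample` followed by one SNP id per column and one row per sample; calls
are 0/1/2 copies of the counted allele, `NA` (or empty, or `.`) for
missing. A sidecar map `<path>.map` (same name, `.map` extension) holds
tab-separated `id`, `chrom`, `pos` with a header. Chromosome labels
outside 1–19 are kept as `"unanchored"`. In `stratifiedAlleleFreqs` the
counted allele is the minor allele of the full dataset, so downstream
statistics follow a single consistent polarisation (f-statistics are
invariant to consistent flips).

## Worked example

Simulate a 6-population panel (20 diploids each, 5,000 SNPs) whose history
contains one migration edge B → D with weight 0.4, then refit it:

```r
library(admixkit)

tr <- ape::read.tree(text =
  "(out:0.1,(((A:0.02,B:0.02):0.02,C:0.04):0.02,(D:0.03,E:0.03):0.03):0.01);")
src <- which(tr$edge[, 2] == which(tr$tip.label == "B"))
dst <- which(tr$edge[, 2] == which(tr$tip.label == "D"))
g <- admixtureGraph(tr, data.frame(src_edge = src, dst_edge = dst,
                                   weight = 0.4, src_frac = 0.5),
                    outgroup = "out")

spec <- simSpec(g, nSnps = 5000, samplesPerPop = 20)
sim  <- simulateFrequencies(spec, seed = 7)
tab  <- sampleAlleleCounts(sim, spec@samplesPerPop, seed = 8)

fit <- fitGraph(tab, outgroup = "out", m = 1, nSearches = 3, seed = 9,
                computePvalues = TRUE, noss = FALSE)
fit
#> FitReport: 6 tips, 1 migration edge(s)
#>   loglik = 160.258  variance explained = 0.9999
#>   edge 1: w=0.353 p=2.16e-25  (B) -> (D)

f3Admixture(tab, "D", "B", "E")
#> f3(D, B, E) = -0.00138201  SE = 0.000273  Z = -5.06  p = 2.08e-07  [5000 SNPs, 250 blocks]

f4Stat(tab, "A", "B", "D", "E")
#> f4(A, B, D, E) = -0.000676125  SE = 0.000254  Z = -2.67  p = 0.00766  [5000 SNPs, 250 blocks]
```

The fit recovers the planted edge with its true clades and a weight near
0.4; the significantly negative f3 confirms D is admixed between sources
related to B and E, and the f4 contrast corroborates gene flow across the
(A,B)/(D,E) split. (`noss = FALSE` enables the sample-size correction,
appropriate for equal moderate samples; the default matches the `-noss`
convention used for small, unequal empirical panels — see the vignette.)

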