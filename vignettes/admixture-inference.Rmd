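---
title: "Admixture-graph inference from SNP allele frequencies"
author: "admixkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture-graph inference from SNP allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixkit)
```

## The model

admixkit infers the demographic history of a set of populations from
biallelic SNP allele frequencies under the Gaussian drift approximation.
Along a branch of drift length $c$, a frequency takes a Gaussian step with
variance $c\,p_0(1-p_0)$, where $p_0$ is the ancestral frequency; drift
lengths are therefore in units of $t/2N_e$.  A migration edge contributes a
fraction $w$ of a recipient node's ancestry from an attachment point on a
source branch; the recipient's frequency is the $w$-weighted mixture of the
source value and the value arriving along its own branch.

Two consequences drive everything in the package:

* The centered covariance of population frequencies across SNPs (each SNP
  centered by its across-population mean) is a linear function of branch
  lengths given the topology and migration weights: each tip's ancestry
  decomposes into weighted root paths, and the expected covariance of two
  tips is the drift length they share, summed over path pairs with weights
  that are products of $w$ and $1-w$ factors.  `predictedCovariance()`
  evaluates this; `fitTree()` and `addMigrationEdges()` maximise a normal
  composite likelihood of the observed covariance around it.
* The f-statistics are moment contrasts of the same frequencies:
  $f_3(X;Y,W) = E[(x-y)(x-w)]$ is negative only if $X$ is a mixture, and
  $f_4(X,Y;W,Z) = E[(x-y)(w-z)]$ is zero for any tree-like history, even
  with incomplete lineage sorting.  `f3Admixture()`, `f3Outgroup()`,
  `f4Stat()` and `zdiffOutgroup()` estimate these with autocorrelation-
  robust errors from a weighted delete-one-block jackknife over contiguous
  SNP blocks.

## Fitting procedure and its numerical choices

`covarianceMatrix()` centers per-SNP frequencies and averages their
cross-products; per-entry standard errors come from the same block
jackknife used by the f-statistics, and per-block sums are retained so any
downstream quantity can be re-estimated under leave-one-block-out deletion.
Zero jackknife SEs (possible in degenerate synthetic data) are floored at
a small positive value so the composite likelihood stays defined.

`fitTree()` starts each search from neighbour joining on the
covariance-implied distances $d_{ij} = W_{ii} + W_{jj} - 2W_{ij}$ (the
double-centering cancels in this combination, so for noise-free tree data
these distances are exactly additive and NJ recovers the topology), with
multiplicative jitter or fully random topologies for later searches.
Branch lengths are fit by weighted nonnegative least squares — the model
covariance is linear in them — and the topology is hill-climbed over
nearest-neighbour-interchange moves until the composite log-likelihood
stops improving.  The objective is root-invariant; trees are rooted on the
declared outgroup for presentation and for orienting migration edges.

`addMigrationEdges()` adds edges greedily: the population pair with the
largest positive scaled residual nominates candidate attachments (on small
trees every ordered branch pair is tried; on large trees a beam of branches
along the two tips' root paths), each candidate is screened at pilot
weights, and the best few are optimised over $w \in [0.001, 0.999]$ by
bounded 1-D search with branch lengths re-fit inside the objective.
Source attachments sit at the midpoint of the source branch and
destinations at the child node of the destination branch; because branch
lengths are free parameters, the attachment fraction is not separately
identifiable and fixing it loses no generality.  After all edges are
placed, each weight is re-optimised once jointly.  Edge weights get
standard errors and p-values from the block jackknife (leave-one-block-out
covariance, fixed structure, weight re-fit).

Admixture biases the pure-tree stage: the maximum-likelihood *tree* for
admixed data often sits one rearrangement away from the true backbone, and
an edge fitted on that distorted backbone can land between neighbouring
clades.  `fitGraph(baseTrees = k)` therefore fits migrations not only on
the best tree but on up to $k-1$ of its nearest-neighbour-interchange
variants, keeping the graph with the best final composite likelihood —
cheap insurance that markedly stabilises edge placement in the package's
recovery studies (reference fits use $k = 7$, bootstrap replicates
$k = 3$).

A deliberate scope note: this engine is a re-implementation of the model
class, not a bit-compatible clone of the original C++ TreeMix — the
likelihood scale differs, so printed TreeMix log-likelihood values are not
comparable; topologies, variance explained, edge placements and weights
are.

### Sample-size correction and `noss`

With $n_i$ sampled alleles, the observed frequency adds binomial noise with
variance $\approx \bar{h}_i = x_i(1-x_i)/(n_i-1)$ to the diagonal of the
covariance (and, through centering, spreads a share of it across the
matrix).  `covarianceMatrix(noss = FALSE)` removes these terms exactly;
the default `noss = TRUE` skips the correction, which is the recommended
setting for empirical panels with very small and unequal samples, where the
correction tends to overshoot.  The distinction matters for migration
weights: at $n = 20$ diploids the sampling variance
($\approx 0.005$) is comparable to typical branch lengths, and under
`noss = TRUE` it is absorbed into tip branches — including the half of a
source branch shared with an admixed tip's migration path — which biases
fitted weights downward by about $0.1$ in our 6-tip recovery study.  The
package's simulation studies therefore fit with the correction enabled,
while empirical-style runs keep the `-noss`-equivalent default.

## LD handling: blocks, not pruning

Both the covariance and the f-statistics assume SNPs are exchangeable
units; linkage disequilibrium violates that, and the pipeline compensates
by blocking rather than pruning.  `pairwiseLdR2()` computes within-species
squared genotype correlations for pairs up to 500 kb apart (the unphased
composite measure), `ldDecayBins()` summarises them as median $r^2$ in
sequential bins of 75 comparisons, and `determineBlockSize()` finds the
smallest SNPs-per-block count (starting at 5, stepping by 5) such that all
distances between consecutive block midpoints — range midpoints, with
chromosome-straddling blocks split into per-chromosome parts — exceed a
threshold chosen to far exceed the observed LD range (200 kb by default).
The resulting block size feeds the covariance, the jackknife and the
bootstrap alike.  The threshold itself is a judgment call made by
inspecting the decay curves; the package reports the per-$k$ minimum-gap
trace but does not automate the choice.

## Support measures

Tree collections from repeated searches are post-processed by
`selectBestTrees()` (likelihood filter at relative tolerance $10^{-6}$,
then topological deduplication at unrooted Robinson–Foulds distance 0),
`rfDistance()` and `strictConsensus()`.  For migration edges,
`bootstrapBlockResample()` draws SNP blocks with replacement (the final
short block is its own unit), each replicate is refit end to end, and
`migrationSupport()` reports MS — the percentage of replicates containing
an edge whose origin and destination clades match the reference edge
exactly — and MS$_E$, the relaxed version requiring only one-sided
containment of each endpoint with orientation preserved.  MS$_E \geq$ MS by
construction.  These definitions are this package's operationalisation of
the indices; the matching predicate is pluggable (`edgeMatch()`) so a
different clade-equivalence rule can be dropped in.  Replicates that fail
to converge are excluded from the denominator and counted in the report.
Because the bootstrap resamples whole blocks, MS is sensitive to whether an
admixture signal is spread across the genome or concentrated in few blocks,
and is deliberately not interchangeable with the jackknife p-values.

## The synthetic-data generator

`simulateFrequencies()` implements the generative side of the same model:
ancestral frequencies uniform on $[0.05, 0.95]$ by default (array-like
spectra; a beta option exists), Gaussian steps down each branch clipped to
$[0,1]$ (clipping is counted and stays below 5% at default drift scales —
the regime where the Gaussian approximation is trustworthy), single-pulse
migration mixtures at nodes, and SNP positions uniform over 19
chromosomes.  `simulateGenotypes()` draws diploid calls as
Binomial(2, $p$), applies i.i.d. missingness, and can emulate short-range
LD by haplotype copying: within a block, the latent uniform driving an
allele is carried over from the previous SNP with probability $\rho$,
giving geometrically decaying within-block $r^2$.  (A perturbed shared
*frequency* cannot produce genotype LD — with independent binomial draws
per individual, equal frequencies give zero cross-SNP correlation — so the
copying construction is used instead.)  `paperLikeScenario()` bundles a
study-shaped instance: 31 ingroup populations plus an outgroup, 2–40
diploids each, ~4,000 SNPs, 5% missingness, mild LD, and 8 migration
edges with weights 0.14–0.49, returning the ground-truth graph for
recovery scoring.

What the generator does *not* emulate: ascertainment bias of array SNPs,
recombination-map structure (LD is statistical, not genealogical),
selection, and mutation.  Passing recovery tests on these simulations
therefore demonstrates correctness of the estimators under the drift
model, not robustness to every feature of real array data.

## Problem sizes used in the test suite

The packaged studies are desk-scale by design: f-statistic calibrations
use 4,000–5,000 SNPs and 20 diploids per population over 10–20 replicates;
tree recovery uses noise-free covariances of 100 random 8-tip trees;
migration recovery uses a fixed 6-tip scenario with one $w = 0.4$ edge;
bootstrap support uses 25–100 replicates.  The array-scale scenario in the
acceptance script runs the full pipeline once at ~4,000 SNPs and 32
populations with $m = 8$.  These sizes were chosen so each study is a
statistically meaningful check that completes in minutes on one CPU.

## Known limitations

* Migration direction is weakly identified by covariance data alone;
  extended (containment) matching is the honest unit for recovery claims,
  and single-edge weights below ~0.1 are often interchangeable with small
  topology changes.
* The greedy residual-guided edge search can place an edge between clades
  adjacent to the true ones when the base tree has already absorbed part of
  the admixture signal into its topology.
* The composite likelihood treats covariance entries as independent
  normals; it is a fitting device, and its absolute value should not be
  compared across datasets.
* `f3Outgroup()` values have no absolute meaning; only contrasts against
  the same target are interpretable, which is what `zdiffOutgroup()`
  formalises.
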