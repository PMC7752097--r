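---
title: "Dissecting a recombination-suppressed inversion locus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a recombination-suppressed inversion locus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invlocus)
```

# The problem

A large chromosomal inversion suppresses recombination in heterozygotes, so
the two arrangements behave as a single Mendelian locus: hundreds of genes
are inherited as one block, classical fine-mapping is powerless inside it,
and any phenotype associated with the locus could be driven by any variant
the block carries. `invlocus` implements an analysis strategy for such loci
built around three ideas:

1. **Population context.** Genotype the inversion from a SNP panel (the
   arrangements separate on PC1), test the genotype counts against
   Hardy-Weinberg proportions, fit the allele-frequency cline along the
   environmental gradient, and profile windowed diversity and
   differentiation (pi, dxy, Hudson's FST) across the locus.
2. **Controlled crosses.** Introgress the rare arrangement into a common
   genetic background (backcross families), map the residual donor genome
   from RNA-seq variant evidence, and estimate the locus's expression
   effects in every tissue-by-temperature condition, in two independent
   donor families. Effects that replicate across families -- same sign,
   significant in both -- are attributed to the locus rather than to
   family-private flanking DNA.
3. **Looking inside.** Scan the genes inside the locus for cis-regulatory
   effects that are consistent across conditions, and for genes whose
   expression predicts the genome-wide "reporter" response over and above
   the karyotype itself -- the signature of a causal mediator.

Every stage runs on a built-in synthetic-data generator with serialized
ground truth, so the whole pipeline is testable end to end without any
external download.

# Models, stage by stage

## Karyotyping and the Hardy-Weinberg test

Locus markers are filtered (< 25% missing, minor allele frequency > 0.05),
mean-imputed and centered, and PC1 is computed. PC1 scores are partitioned
into three groups by **exact one-dimensional 3-means**: because the data are
one-dimensional, the optimal clusters are contiguous slices of the sorted
scores, and the global optimum can be found by scanning all split pairs in
O(n^2) with prefix sums. We deliberately avoid Lloyd-style k-means here:
with a majority homozygote class (common on a cline), a fixed quantile
initialization places two centers inside the majority cluster and converges
to a local optimum that merges the heterozygotes with one homozygote class
(on our simulated panels this costs ~40% accuracy). The exact search is
deterministic and has no such failure mode.

A locus only counts as structured if the smallest gap between adjacent
clusters exceeds 5% of the PC1 score range. This criterion was chosen over
the mean silhouette because the optimal 3-way split of *unstructured*
1-D data already achieves a silhouette near 0.55 (and explains ~80% of the
score variance), while its relative boundary gap is ~0.002; a real
three-cluster signal leaves a gap two orders of magnitude larger. The
smaller extreme cluster is labeled `High/High` (minor-arrangement
convention), making calls invariant to marker order and to flipping any
marker's allele coding.

The Hardy-Weinberg test is the Levene-Haldane exact test: conditional on
the allele counts, the probability of each heterozygote count is evaluated
in log space, and the two-sided p-value sums all outcomes no more likely
than the observed one. The disequilibrium statistic
`D = (observed het - 2*n*p*q) / 2` is half the heterozygote deficit on the
count scale. For small allele counts the enumeration is verified to sum to
one to 1e-12.

## The elevation cline

Plants are binned into 100 m elevation bands; bins with fewer than 10
plants are excluded. Per-bin High-allele frequencies are logit-transformed
(frequencies of exactly 0 or 1 get a half-count continuity adjustment,
`(c + 0.5) / (t + 1)`) and smoothed with loess (span 0.75, degree 2,
weighted by bin size); predictions and pointwise +/- 2 SE bands are
back-transformed. A log-scale transform is available via `transform =
"log"`; the logit is the default because it is symmetric in the two alleles
and keeps the band inside [0, 1].

## Windowed popgen statistics

Per site, within-population diversity is the unbiased heterozygosity
`2*p*q*n/(n-1)`, between-population diversity is
`dxy = p1(1-p2) + p2(1-p1)`, and FST uses **Hudson's estimator** with
sample-size correction -- numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) -
p2(1-p2)/(n2-1)`, denominator `dxy` -- aggregated over 1 Mb windows
(100 kb step) as a **ratio of sums**, which is far less biased than
averaging per-site ratios and is invariant to how a window's sites are
batched. Hudson's form was chosen as the standard low-bias two-population
estimator; the per-site components satisfy `numerator = dxy - (pi1+pi2)/2`
exactly, which the tests verify against a brute-force pairwise-difference
oracle. Windows are anchored at the region start, half-open internally,
printed 1-based inclusive; empty windows are emitted with `n_sites = 0`.

## Introgression mapping

Variant sites from RNA-seq are kept when FS < 30, QD > 2, the recurrent
parent is homozygous reference, and the family alternate-allele frequency
lies strictly in (1/8, 7/8) -- segregating sites in a selfed BC5 family are
expected near 0.25 or 0.5, so the band removes fixed and artifactual sites.
Read counts are pooled across a plant's samples (equivalent to multiplying
per-sample binomial likelihoods) and genotypes called from binomial
likelihoods at alternate fractions {eps, 1/2, 1-eps} with eps = 0.01 and a
flat prior.

Blocks are contiguous runs of 1 Mb windows whose variant density exceeds
five times the genome-wide median window density (with a floor of 5
sites/window), bridging single quiet windows and discarding merged blocks
with fewer than 10 sites -- that last rule keeps isolated "orphan" genes
(genes whose coordinates differ between donor and reference genomes) from
masquerading as blocks. When the total genome size is supplied the
site-free bulk of the genome enters the background median; without it, a
genome dominated by large blocks can inflate the background estimate.
Within blocks, per-plant calls are smoothed along sites by a 3-state
forward-backward chain (emission error 0.2, switch probability 1e-6 per
site): recombination within a residual block of a BC5S1 plant is
negligible, so the chain essentially votes across sites while remaining
robust to isolated miscalls; with clean evidence it changes no calls.

Genes are then partitioned: overlapping the inversion interval -> `locus`;
overlapping any block, or carrying >= 2 filtered SNPs outside all blocks
(the orphan rule, genotype by majority vote, ties -> unknown) ->
`residual`; no coordinates -> `unknown`; otherwise `clean`. Only clean
genes enter the genome-wide response analysis; locus genes are scanned for
candidates; residual genes serve as controls.

## The expression spine

Genes are kept when at least a third of samples have >= 10 reads. Library
normalization is TMM (`edgeR::calcNormFactors`; trims 30% of M-values and
5% of A-values, inverse-variance weights, factors rescaled to geometric
mean 1), expression is `log2((count + 0.5) / (lib*factor + 1) * 1e6)`, and
per-observation precision weights come from the voom mean-variance trend
(`limma::voom`). Batch (experimental replicate) is removed from the
log2CPM matrix by fitting batch jointly with the design and subtracting
only the batch terms (`limma::removeBatchEffect`); correction happens
before the per-condition fits (the correct-then-fit order; fitting batch
inside each condition's model is also possible but spends scarce residual
degrees of freedom 18 times over). Sample structure is visualized by MDS
on the root-mean-square of the top 500 pairwise log-fold-changes.

Per gene, family and condition, the locus effect is estimated by **exact
weighted least squares** of batch-corrected log2CPM on genotype (0 = hom
Low, 1 = hom High; heterozygotes are excluded by the experimental design),
with observation variances proportional to the inverse voom weights and
standard errors from `sigma2 * (X'WX)^-1`. A per-tissue interaction model
adds temperature and genotype-by-temperature terms with a pooled residual
variance. Effect sizes equal what a moderated-t pipeline would report; the
standard errors are exact rather than empirical-Bayes moderated, a
deliberate simplification that keeps the per-gene fits self-contained (the
cross-condition shrinkage below does the information pooling instead).

## Shrinkage across conditions and the local false sign rate

With 18 conditions per family and few replicates per condition, raw
per-condition estimates are noisy but highly correlated. The
`multivariate_shrinkage()` stage is an empirical-Bayes mixture model on
z-scores (z = beta/se): each gene's vector is modeled as drawn from a
mixture over canonical covariance patterns -- the null, condition-specific
singletons, independent effects (identity), and equal effects shared by all
conditions (rank-1) -- each scaled over the geometric grid `2^(-4..6)`.
Working on z-scores (the "EZ" parameterization) makes every component's
marginal likelihood and posterior closed-form (diagonal, rank-1, or point
mass), so no per-gene matrix factorization is needed and 2000 genes x 18
conditions fit in seconds. Mixture weights are estimated by EM with a
null-biased Dirichlet penalty (pseudo-count 10 on the null), which keeps
the procedure conservative when there is no signal; non-convergence after
500 iterations warns and returns the last iterate.

Per gene and condition the posterior is a mixture of normals plus a point
mass at zero. The **local false sign rate** is
`min(P(effect > 0), P(effect < 0)) + P(effect = 0)/2`: mass exactly at
zero is split between the signs, so lfsr lies in [0, 0.5], equals 0.5 for
a fully-null posterior, and a gene passes `lfsr < 0.05` only when the sign
is essentially certain. A gene is **replicated** in a condition when
lfsr < 0.05 in *both* families with the same posterior sign; on fully null
two-family data this compound filter admits well under 0.5% of genes per
condition, and in the calibration test >= 95% of flagged effects carry the
true sign.

Genes unobserved in a condition are imputed with beta = 0, SE = 1000
before shrinkage -- an entry that carries no likelihood information but
keeps the table complete.

## Enrichment and semantic collapse

Replicated gene sets are tested per term with the upper-tail
hypergeometric distribution against the expressed-in-both-families
background, Benjamini-Hochberg corrected, flagged at 1% FDR. Because GO
terms are heavily redundant, enriched terms are grouped within each
namespace by single-linkage clustering at Lin semantic similarity > 0.5
(information content from the ancestor-closed annotation corpus; Resnik
available), and each group is represented by its member with the maximum
enrichment ratio, reported with the group's minimum q (`minq`) and maximum
ratio (`maxRatio`). The ratio was adopted as the ranking "enrichment
score"; `-log q` is a configurable alternative. Annotations are always
closed under is_a ancestors, and the term graph is checked to be acyclic.

## The candidate scan

For each gene inside the locus: (i) the proportion of conditions in which
its cis effect is significant with matching sign in both families
(conditions where either family lacks expression leave the denominator);
and (ii) the proportion of replicated reporter genes -- restricted to
chromosomes other than the locus chromosome -- whose expression the locus
gene predicts (p < 0.05, same coefficient sign in both families) in a
regression that also conditions on karyotype. Conditioning is what makes
the scan informative: every locus gene correlates with every reporter
through the shared genotype, but only a mediator's *residual* expression
variation predicts reporters beyond it. The per-gene score averages the
per-condition proportions (per-condition values are also returned).
Flags are strict: `highly_correlated` requires > 6%, `consistently_DE`
requires > 90% ("more than", not "at least"). Reporters with fewer than 3
residual degrees of freedom are skipped; degenerate reporters (zero
residual variance) never qualify.

Donor divergence complements the scan: per-gene shared-SNP proportion
between the two donors (shared / total observed), per-condition
correlation of the two families' effect estimates, Welch t-tests of both
measures inside vs outside the locus, and the correlation between genetic
divergence (1 - sharing) and expression divergence (mean |effect
difference| across conditions).

## Trait models

Seedling emergence is `y = mu + beta*G + u_replicate + e` fit by REML
(`lme4::lmer`); on balanced designs the variance components match the
closed-form expected-mean-squares solutions to 1e-8, which the tests
assert. The genotype effect is tested with a conditional F at the REML
solution, denominator degrees of freedom by containment
(`N - rank(fixed) - (n_replicates - 1)`). The model is a random
*intercept* for replicate: that is the only random term the data structure
supports, and the conditional F is what the small number of replicates
affords. The agronomic-trait model is
`trait ~ genotype * elevation + tester + (1 + elevation | family)`, and the
reported object is the locus effect as a function of elevation,
`b(e) = beta_G + beta_GxE * e`, with +/- 2 SE from the coefficient
covariance; a sign change of b(e) across the elevation range is the
antagonistic-pleiotropy signature. Elevation is standardized internally
for optimizer stability and the slope is reported per meter. An optional
per-trial covariate (e.g. days to anthesis) enters with an independent
slope per trial, which requires trials to be discrete
(tester-by-elevation-site cells), as in multi-site field designs.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions and were fixed once:

* **Landrace panel**: 600 plants, elevations uniform on 0-3000 m, cline
  midpoint 2200 m with logit slope 0.005/m (near-absence of the High
  arrangement below ~1500 m, near-fixation above ~2700 m, matching a
  highland-adapted allele), 100 locus + 100 flanking markers, 30% of locus
  sites fixed differences, 10% missing data.
* **Divergent populations**: Balding-Nichols frequencies around uniform
  ancestral frequencies, with per-site F following the target profile.
  This model was chosen because the expectation of windowed ratio-of-sums
  Hudson FST then equals the window's mean target F, giving closed-form
  acceptance bounds. A corollary the popgen driver reports: divergence
  manifests as reduced within-population diversity at flat dxy.
* **BC5S1 families**: two families on a 5-chromosome, 60 Mb/chromosome
  genome (2000 genes by default -- the gene and SNP density per Mb is what
  matters for block detection, so the genome is scaled down with the gene
  count), a 14 Mb locus on chromosome 4, fully-linked flanking blocks plus
  family-private blocks, and per family 12 homozygous plants (6 per
  karyotype, 3 biological replicates in each of 2 batches) sampled in all
  9 tissues x 2 temperatures -- 216 samples per family, the published
  design's shape. Counts are negative binomial (dispersion 0.1) around
  log-normal gene means with tissue (SD 1), temperature (SD 0.3) and batch
  (SD 0.2) structure and library sizes of 200-400k reads; planted effects
  are cis (SD 1 log2; shared between families for locus genes, per-block
  otherwise), shared locus-driven trans (SD 0.6, 8% of clean genes), and
  family-private confounders (4%) driven by the family's linked flank --
  exactly the confounding the two-family replication filter exists to
  remove. Donor SNP sites per gene (mean ~7) are shared between donors
  with probability 0.8 inside the locus and 0.4 outside, planting the
  divergence contrast.
* **Mediation panel**: one locus gene drives 30% of reporters with loading
  1.0 on top of a karyotype effect; everything else is noise (SD 0.5).
* **Emergence**: mu = 9 days (a cold-chamber baseline), replicate SD 0.3,
  residual SD 1, 40 plants per genotype, effect -0.75 days.

All generators draw every number through a single integer seed
(`withr::with_seed`, so the global RNG state is untouched) and return a
`truth` object recording every planted effect with sign and magnitude;
identical config + seed gives byte-identical output.

**What the generator does not emulate** -- and hence what passing tests do
not show about real data: read-level artifacts (mapping bias against the
donor haplotype, GC effects), linkage *within* blocks beyond the
block-level genotype, expression networks (trans effects are independent
given genotype except through the planted mediator), isoforms, and
ascertainment bias in the SNP panel. The published genome-scale numbers
(23,428 detected genes, 355 locus genes, per-tissue DE counts) depend on
those real-data properties and on the raw reads, which are deliberately
out of scope; the package's claims are therefore about *method behavior
under known truth*, checked by parameter recovery, calibration and
specificity properties at desk scale.

# Numerical choices and problem sizes

Log-space factorials throughout the exact test; half-count continuity
adjustments at frequency 0/1; half-open window arithmetic printed 1-based
inclusive; EM tolerance 1e-7 relative log-likelihood, 500 iterations;
ties in orphan-gene majority votes return "unknown"; saturated per-gene
fits (zero residual df) return the estimate with NA standard error;
degenerate t-tests are skipped with a warning rather than erroring.

The test suite and drivers run at sizes chosen to finish in minutes on one
core while keeping every property measurable: 600-2000 genes, 432
expression samples, 50 haplotypes per population at 1 site/kb over 20 Mb,
200 emergence replicates, 100 enrichment seeds, 20 mediation seeds. Each
size is stated in the corresponding test or driver.

# Known limitations

* The shrinkage uses canonical covariance components only (no data-driven
  components); patterns like "cold tissues only" are captured by
  combinations of singletons and shared components less efficiently than a
  learned covariance would.
* The EZ (z-score) parameterization ties effect-size units to the standard
  error; genes measured precisely and imprecisely are shrunk on different
  scales. For significance calls via lfsr this is immaterial, which is how
  the pipeline uses it.
* The genotype chain smoother assumes at most negligible recombination
  within a block, appropriate for BC5S1 but not for, say, F2 designs.
* The kinship-corrected genome-wide association machinery behind the
  agronomic-trait analysis is reduced to a family random effect; with real
  panel data a full kinship correction is required before interpreting
  b(e).
* `classify_genes` trusts the supplied annotation; genes truly absent from
  the reference (presence/absence variation) are invisible to the whole
  pipeline.
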