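# invlocus

Transcriptomic and population-genetic dissection of a large chromosomal
inversion that suppresses recombination and segregates along an
environmental cline.

Inversions behave as single Mendelian "supergenes": heterozygotes barely
recombine, so hundreds of linked genes are inherited as one block and
classical fine-mapping cannot resolve which variants inside the block do
the work. `invlocus` implements an analysis strategy for this situation,
aimed at quantitative/population geneticists working with SNP panels and
replicated RNA-seq from segregating families:

* **Karyotyping & population context** — call per-individual inversion
  genotypes from a SNP matrix by PCA + exact 1-D clustering; test genotype
  counts with the Levene–Haldane exact Hardy–Weinberg test and the
  heterozygote-deficit statistic *D* = (obs het − 2*n p̂ q̂*)/2; fit the
  allele-frequency cline over elevation (loess on logit frequencies,
  weighted by bin size); profile π, d<sub>xy</sub> and Hudson's
  F<sub>ST</sub> (ratio-of-sums over 1 Mb windows, 100 kb step).
* **Introgression mapping** — from RNA-seq variant evidence in backcross
  (BC₅S₁) families: quality/segregation filtering, per-plant genotype
  pooling, density-based residual-block detection with 3-state chain
  smoothing, and classification of every gene into clean / locus /
  residual.
* **Replicated differential expression** — TMM + log₂CPM + voom precision
  weights + batch correction; exact weighted least-squares fits of
  *y* = μ + β·Inv + e (var(e) ∝ φ) per gene × condition × family;
  empirical-Bayes shrinkage across the 18 tissue:temperature conditions
  (mixture over canonical covariance patterns on z-scores) with the local
  false sign rate; genes count as locus-regulated only when significant
  (lfsr < 0.05) with the same sign in **both** donor families.
* **Downstream** — hypergeometric GO enrichment with BH control and
  semantic-similarity collapsing to representative terms; a candidate scan
  inside the locus (cross-condition cis-DE consistency and a
  reporter-correlation scan that conditions on karyotype); donor
  divergence contrasts; and mixed-model analysis of seedling emergence
  (random replicate intercept, REML, conditional F) plus a
  genotype-by-elevation trait model.

A synthetic-data generator produces every input with serialized ground
truth, so the complete pipeline runs and is tested end to end with no
external data.

## Worked example

```r
library(invlocus)

# simulate a landrace panel with a diverged inversion on an elevation cline
pan   <- simulate_landrace_panel(panel_config(haplotype_divergence = 0.5, seed = 1))
gm    <- filter_markers(pan$gm, region = panel_config()$locus_interval)
calls <- call_inversion_genotypes(gm)
mean(calls$calls$karyotype == pan$truth$karyotype)   # 1.000
calls$pc1_var_explained                              # 0.592

# exact Hardy-Weinberg test on published genotype counts
hwe_exact_test(1186, 190, 381)
#> Exact Hardy-Weinberg test (n = 1757)
#>   counts (AA/AB/BB): 1186 / 190 / 381
#>   p_hat = 0.7291, expected het = 694.09
#>   D = -252.0438, p = 1.905e-197
hwe_exact_test(42, 78, 45)    # D = -2.2364,   p = 0.5332
hwe_exact_test(59, 97, 43)    # D = -0.928392, p = 0.7769
```

The first triple shows a massive heterozygote deficit — the signature of a
locus near-fixed for alternative arrangements at the two ends of a cline —
while the two segregating-family triples sit comfortably within
Hardy–Weinberg expectations, as selfed heterozygote progeny should.

The numbered drivers under `analysis/` run each stage on the generator and
write their tables under `results/`; the run used here prints, among
others:

```
01: karyotype accuracy vs truth: 1.000; cline crosses 0.5 at 2250 m (midpoint 2200 m)
02: mean FST inside 0.371 (target 0.38); outside 0.051 (target 0.05)
03: orphan genes reassigned to residual: 10 of 10
04: replicated genes: 67 (planted shared: 63 of 100; private leaked: 4 of 84)
05: planted term rank 1 at q = 2.3e-15; retained as representative
06: mediator correlated with 14.9% of reporters; runner-up 0.3%
07: emergence beta = -0.730 d (planted -0.75), F(1,77) = 13.05
```

i.e. the two-family replication filter keeps locus-driven effects and
drops family-private confounders, and the reporter-correlation scan
separates the planted mediator from the rest of the locus by two orders of
magnitude.

## Layout

```
R/                  implementation (simulators, karyotyping, popgen,
                    introgression, expression, shrinkage, enrichment,
                    candidate scan, trait models, orchestration)
analysis/01..07     numbered narrative drivers; write results/ tables
scripts/acceptance.R  headline-number reproduction (JSON)
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette: models, assumptions, design choices
```
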