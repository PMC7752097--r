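# Generator contracts: determinism, truth consistency, validation errors.

test_that("identical config and seed give identical output", {
  a <- simulate_landrace_panel(panel_config(n_plants = 80, seed = 5))
  b <- simulate_landrace_panel(panel_config(n_plants = 80, seed = 5))
  expect_identical(a, b)
  c <- simulate_landrace_panel(panel_config(n_plants = 80, seed = 6))
  expect_false(identical(a$gm$geno, c$gm$geno))

  e1 <- simulate_bc5s1_experiment(family_config(n_genes = 120, seed = 2))
  e2 <- simulate_bc5s1_experiment(family_config(n_genes = 120, seed = 2))
  expect_identical(e1, e2)

  g1 <- simulate_go_universe(n_genes = 100, n_terms = 12, seed = 3)
  g2 <- simulate_go_universe(n_genes = 100, n_terms = 12, seed = 3)
  expect_identical(g1, g2)
})

test_that("generators do not disturb the global random state", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_emergence(seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("truth tables agree with the data they describe", {
  pan <- simulate_landrace_panel(panel_config(n_plants = 60, seed = 8))
  expect_equal(length(pan$truth$karyotype), nrow(pan$gm$geno))

  exp <- simulate_bc5s1_experiment(family_config(n_genes = 150, seed = 8))
  expect_equal(nrow(exp$counts), nrow(exp$annotation))
  expect_equal(ncol(exp$counts), nrow(exp$samples))
  expect_equal(length(exp$truth$cis_locus), nrow(exp$annotation))
  # planted cis effects only on locus genes
  expect_true(all(exp$truth$cis_locus[exp$truth$class != "locus"] == 0))
  # planted trans effects only on clean genes
  expect_true(all(exp$truth$trans_shared[exp$truth$class != "clean"] == 0))
  # samples: both families, all conditions
  expect_setequal(unique(exp$samples$family), c("PT", "Mi21"))
  expect_equal(length(unique(exp$samples$condition)), 18)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(panel_config(haplotype_divergence = 1.2), "probabilities")
  expect_error(panel_config(n_plants = 0), "counts")
  expect_error(family_config(prop_cis = -0.1), "probabilities")
  overlapping <- list(
    PT = data.frame(chrom = "chr4", start = 25e6, end = 30e6,
                    donor_freq = 0.5),
    Mi21 = data.frame(chrom = "chr3", start = 1e6, end = 2e6,
                      donor_freq = 0.5))
  expect_error(family_config(residual_blocks = overlapping), "overlap")
  expect_error(simulate_go_universe(planted_term = "T9999", seed = 1),
               "exist")
})

test_that("a flat cline leaves High-allele frequency flat across bins", {
  pan <- simulate_landrace_panel(panel_config(cline_slope = 0,
                                              n_plants = 3000, seed = 12))
  dos <- pan$truth$karyotype_dosage
  elev <- pan$gm$plants$elevation
  bin <- cut(elev, seq(0, 3000, by = 500))
  freq <- tapply(dos, bin, mean) / 2
  # all bins near 0.5 within binomial error (n ~ 500 plants per bin)
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / (2 * 400))))
})

test_that("NB counts carry the planted cis effects for carriers", {
  exp <- simulate_bc5s1_experiment(family_config(n_genes = 300,
                                                 cis_effect_sd = 2,
                                                 seed = 14))
  cis <- exp$truth$cis_locus
  g <- names(cis)[which.max(abs(cis))]
  sm <- exp$samples[exp$samples$family == "PT", ]
  lc <- log2(exp$counts[g, sm$sample] + 0.5)
  obs <- mean(lc[sm$genotype == 1]) - mean(lc[sm$genotype == 0])
  expect_equal(sign(obs), sign(cis[[g]]))
  expect_lt(abs(obs - cis[[g]]), 1.5)
})

test_that("emergence generator hits its moments", {
  sim <- simulate_emergence(n_per_group = 2000, genotype_effect_days = -0.75,
                            replicate_effect_sd = 0, residual_sd = 1,
                            seed = 15)
  d <- sim$data
  diff_obs <- mean(d$emergence[d$genotype == 1]) -
    mean(d$emergence[d$genotype == 0])
  expect_lt(abs(diff_obs + 0.75), 0.1)
})
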