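# Marker filtering, PCA karyotyping and the elevation cline.

make_small_gm <- function() {
  geno <- matrix(c(0L, 1L, 2L, 0L,
                   2L, 2L, 2L, 2L,      # monomorphic
                   0L, NA, NA, 1L,      # 50% missing
                   1L, 0L, 2L, 1L), nrow = 4)
  genotype_matrix(geno,
                  data.frame(chrom = "chr4", pos = c(10, 20, 30, 40)),
                  data.frame(id = paste0("p", 1:4)))
}

test_that("marker filter applies missingness, MAF and region rules", {
  gm <- make_small_gm()
  out <- filter_markers(gm, max_missing = 0.25, min_maf = 0.05)
  expect_equal(out$markers$pos, c(10, 40))   # monomorphic + missing dropped
  expect_equal(nrow(out$geno), 4)            # plants unchanged
  out2 <- filter_markers(gm, region = list(chrom = "chr4", start = 35,
                                           end = 45))
  expect_equal(out2$markers$pos, 40)
  expect_error(filter_markers(gm, region = list(chrom = "chr1", start = 1,
                                                end = 2)),
               "insufficient markers")
})

test_that("marker filter agrees with a brute-force re-filter", {
  set.seed(3)
  n <- 60; m <- 40
  geno <- matrix(rbinom(n * m, 2, runif(m)[rep(1:m, each = n)]), n, m)
  geno[runif(n * m) < 0.2] <- NA
  gm <- genotype_matrix(geno, data.frame(chrom = "chr1", pos = 1:m),
                        data.frame(id = paste0("p", 1:n)))
  out <- filter_markers(gm, max_missing = 0.25, min_maf = 0.05)
  keep <- logical(m)
  for (j in 1:m) {
    g <- geno[, j]
    miss <- mean(is.na(g))
    p <- mean(g, na.rm = TRUE) / 2
    keep[j] <- miss < 0.25 && min(p, 1 - p) > 0.05
  }
  expect_equal(out$markers$pos, (1:m)[keep])
})

test_that("karyotyper recovers simulated truth at >= 99% accuracy", {
  pan <- simulate_landrace_panel(panel_config(haplotype_divergence = 0.5,
                                              n_plants = 600, seed = 21))
  gm <- filter_markers(pan$gm, region = panel_config()$locus_interval)
  calls <- call_inversion_genotypes(gm)
  acc <- mean(calls$calls$karyotype == pan$truth$karyotype)
  expect_gte(acc, 0.99)
  expect_gt(calls$pc1_var_explained, 0.1)
})

test_that("heterozygote cluster lies midway between the homozygote clusters", {
  pan <- simulate_landrace_panel(panel_config(haplotype_divergence = 0.5,
                                              seed = 22))
  gm <- filter_markers(pan$gm, region = panel_config()$locus_interval)
  calls <- call_inversion_genotypes(gm)
  mu <- calls$cluster_means
  spread <- mu[3] - mu[1]
  expect_lt(abs(mu[2] - (mu[1] + mu[3]) / 2), 0.1 * spread)
})

test_that("unstructured locus raises a 'no karyotype structure' error", {
  geno <- matrix(1L, nrow = 10, ncol = 5)
  gm <- genotype_matrix(geno, data.frame(chrom = "c", pos = 1:5),
                        data.frame(id = paste0("p", 1:10)))
  expect_error(call_inversion_genotypes(gm), "no karyotype structure")
  # no haplotype divergence: three clusters must not be declared
  pan0 <- simulate_landrace_panel(panel_config(haplotype_divergence = 0,
                                               seed = 4))
  gm0 <- filter_markers(pan0$gm, region = panel_config()$locus_interval)
  expect_error(call_inversion_genotypes(gm0), "no karyotype structure")
})

test_that("karyotype calls are invariant to marker order and allele flips", {
  pan <- simulate_landrace_panel(panel_config(haplotype_divergence = 0.5,
                                              n_plants = 200, seed = 30))
  gm <- filter_markers(pan$gm, region = panel_config()$locus_interval)
  base <- call_inversion_genotypes(gm)$calls$karyotype

  set.seed(1)
  perm <- sample(ncol(gm$geno))
  gm_perm <- genotype_matrix(gm$geno[, perm][, order(gm$markers$pos[perm])],
                             gm$markers[perm, ][order(gm$markers$pos[perm]), ],
                             gm$plants)
  expect_equal(call_inversion_genotypes(gm_perm)$calls$karyotype, base)

  flip <- runif(ncol(gm$geno)) < 0.5
  geno_f <- gm$geno
  geno_f[, flip] <- 2L - geno_f[, flip]
  gm_flip <- genotype_matrix(geno_f, gm$markers, gm$plants)
  expect_equal(call_inversion_genotypes(gm_flip)$calls$karyotype, base)
})

test_that("elevation cline bins, excludes small bins and fits the midpoint", {
  # constant frequency 0.5: flat fit at 0.5
  set.seed(8)
  n <- 3000
  elev <- runif(n, 0, 2000)
  karyo <- sample(c("Low/Low", "Low/High", "High/High"), n, TRUE,
                  prob = c(0.25, 0.5, 0.25))
  cf <- elevation_cline(karyo, elev)
  expect_true(all(abs(cf$fit$freq - 0.5) < 0.06))

  # simulated logistic cline: monotone fit, midpoint near truth
  pan <- simulate_landrace_panel(panel_config(haplotype_divergence = 0.5,
                                              n_plants = 2000, seed = 13))
  gm <- filter_markers(pan$gm, region = panel_config()$locus_interval)
  calls <- call_inversion_genotypes(gm)
  cf2 <- elevation_cline(calls, pan$gm$plants$elevation)
  expect_true(all(diff(cf2$fit$freq) > -0.02))
  crossing <- cf2$fit$midpoint[which.min(abs(cf2$fit$freq - 0.5))]
  expect_lt(abs(crossing - pan$truth$cline_midpoint), 150)

  # a bin with n = 9 is excluded from the fit
  elev3 <- c(rep(50, 9), rep(150, 30), rep(250, 30), rep(350, 30))
  karyo3 <- rep(c("Low/Low", "Low/High"), length.out = length(elev3))
  cf3 <- elevation_cline(karyo3, elev3, min_bin_n = 10)
  expect_false(cf3$bins$used[cf3$bins$midpoint == 50])
  expect_false(50 %in% cf3$fit$midpoint)

  expect_error(elevation_cline(karyo3[1:20], elev3[1:20]), "bins")
})
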