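# Candidate-gene scanning inside the locus and donor-divergence analyses.

stub_pair <- function(lfsr1, lfsr2, sign1 = 1, sign2 = 1) {
  genes <- rownames(lfsr1)
  conds <- colnames(lfsr1)
  s1 <- make_shrink_stub(matrix(sign1, nrow(lfsr1), ncol(lfsr1),
                                dimnames = dimnames(lfsr1)), lfsr1)
  s2 <- make_shrink_stub(matrix(sign2, nrow(lfsr2), ncol(lfsr2),
                                dimnames = dimnames(lfsr2)), lfsr2)
  list(s1, s2)
}

test_that("DE-condition proportion counts replicated same-sign conditions", {
  conds <- paste0("c", 1:18)
  l <- matrix(0.01, 2, 18, dimnames = list(c("gA", "gB"), conds))
  st <- stub_pair(l, l)
  out <- de_condition_proportion(st[[1]], st[[2]],
                                 locus_genes = c("gA", "gB"))
  expect_equal(out$prop, c(1, 1))          # DE everywhere, same direction

  # significant in one family only: proportion 0
  l2 <- l; l2[] <- 0.9
  st2 <- stub_pair(l, l2)
  out2 <- de_condition_proportion(st2[[1]], st2[[2]],
                                  locus_genes = c("gA", "gB"))
  expect_equal(out2$prop, c(0, 0))

  # unexpressed conditions leave the denominator
  ex <- matrix(TRUE, 2, 18, dimnames = dimnames(l)); ex[, 10:18] <- FALSE
  out3 <- de_condition_proportion(st[[1]], st[[2]], expressed1 = ex,
                                  locus_genes = c("gA", "gB"))
  expect_equal(out3$n_conditions, c(9, 9))
  expect_equal(out3$prop, c(1, 1))

  expect_error(de_condition_proportion(st[[1]], st[[2]],
                                       locus_genes = "gA"),
               "not in locus")
})

test_that("planted cis effect active in half the conditions scores ~0.5", {
  conds <- paste0("c", 1:18)
  l <- matrix(0.5, 1, 18, dimnames = list("g", conds))
  l[, 1:9] <- 0.001                       # DE in 9 of 18 conditions
  st <- stub_pair(l, l)
  out <- de_condition_proportion(st[[1]], st[[2]], locus_genes = "g")
  expect_equal(out$prop, 0.5)
})

test_that("reporter scan finds the planted mediator and conditioning on
           karyotype suppresses genotype-only correlation", {
  sim <- simulate_mediator_panel(seed = 41)
  scan <- reporter_correlation_scan(
    sim$PT$locus_expr, sim$Mi21$locus_expr,
    sim$PT$reporter_expr, sim$Mi21$reporter_expr,
    sim$PT$genotype, sim$Mi21$genotype,
    sim$PT$condition, sim$Mi21$condition)
  sc <- scan$scores
  med <- sc$prop_reporters_correlated[sc$gene == sim$truth$mediator]
  others <- sc$prop_reporters_correlated[sc$gene != sim$truth$mediator]
  expect_gt(med, 0.06)
  expect_gt(med, max(others))

  # a reporter equal to the karyotype indicator is never counted
  rep_k <- matrix(rep(sim$PT$genotype, 1), 1,
                  dimnames = list("k", colnames(sim$PT$reporter_expr)))
  rep_k2 <- matrix(rep(sim$Mi21$genotype, 1), 1,
                   dimnames = list("k", colnames(sim$Mi21$reporter_expr)))
  scan_k <- reporter_correlation_scan(
    sim$PT$locus_expr[1:3, , drop = FALSE],
    sim$Mi21$locus_expr[1:3, , drop = FALSE],
    rep_k, rep_k2,
    sim$PT$genotype, sim$Mi21$genotype,
    sim$PT$condition, sim$Mi21$condition)
  expect_true(all(scan_k$scores$prop_reporters_correlated == 0))
})

test_that("permuting reporter samples collapses the proportion to chance", {
  sim <- simulate_mediator_panel(seed = 42)
  set.seed(1)
  perm1 <- sample(ncol(sim$PT$reporter_expr))
  perm2 <- sample(ncol(sim$Mi21$reporter_expr))
  scan <- reporter_correlation_scan(
    sim$PT$locus_expr, sim$Mi21$locus_expr,
    sim$PT$reporter_expr[, perm1], sim$Mi21$reporter_expr[, perm2],
    sim$PT$genotype, sim$Mi21$genotype,
    sim$PT$condition, sim$Mi21$condition)
  # two-family 5% tests with matching sign: chance rate ~0.05^2/2
  expect_lt(mean(scan$scores$prop_reporters_correlated), 0.01)
})

test_that("candidate flags use strict threshold inequalities", {
  de <- data.frame(gene = c("a", "b", "c"), n_conditions = 18, n_de = 1,
                   prop = c(0.5, 0.95, 0.90))
  cr <- data.frame(gene = c("a", "b", "c"),
                   prop_reporters_correlated = c(0.07, 0.01, 0.06))
  fl <- flag_candidates(de, cr)
  expect_equal(fl$highly_correlated, c(TRUE, FALSE, FALSE))
  expect_equal(fl$consistently_DE, c(FALSE, TRUE, FALSE))  # 0.90 not > 0.90
  fl2 <- flag_candidates(de, cr, tf_list = "b")
  expect_equal(fl2$is_TF, c(FALSE, TRUE, FALSE))
})

test_that("donor divergence: identical SNP sets share fully; Welch test
           matches the textbook formula; planted contrast detected", {
  s1 <- data.frame(gene = rep(c("a", "b"), each = 2), chrom = "c4",
                   pos = c(1, 2, 10, 11))
  s2 <- s1
  inside <- c(a = TRUE, b = FALSE)
  dv <- suppressWarnings(donor_divergence(s1, s2, inside))
  expect_equal(dv$records$shared_prop, c(1, 1))

  # hand-checked Welch statistic on a 5 + 5 toy
  x <- c(0.9, 0.85, 0.8, 0.95, 0.9); y <- c(0.5, 0.4, 0.6, 0.45, 0.55)
  tt <- stats::t.test(x, y)
  sx <- var(x) / 5; sy <- var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df_hand <- (sx + sy)^2 / (sx^2 / 4 + sy^2 / 4)
  expect_equal(unname(tt$statistic), t_hand, tolerance = 1e-12)
  expect_equal(unname(tt$parameter), df_hand, tolerance = 1e-12)

  # planted sharing contrast inside vs outside the locus
  exp <- simulate_bc5s1_experiment(family_config(n_genes = 600, seed = 11))
  s <- unique(exp$snps[exp$snps$chrom == "chr4",
                       c("gene", "chrom", "pos", "family")])
  sA <- s[s$family == "PT", ]; sB <- s[s$family == "Mi21", ]
  shared_g <- intersect(sA$gene, sB$gene)
  inside2 <- stats::setNames(exp$truth$class == "locus",
                             names(exp$truth$cis_locus))
  dv2 <- donor_divergence(sA[sA$gene %in% shared_g, ],
                          sB[sB$gene %in% shared_g, ], inside2)
  in_mean <- mean(dv2$records$shared_prop[dv2$records$inside])
  out_mean <- mean(dv2$records$shared_prop[!dv2$records$inside])
  expect_gt(in_mean, out_mean)
  expect_lt(dv2$t_shared$p.value, 0.01)
})

test_that("effect correlations and the divergence correlation are wired", {
  set.seed(13)
  genes <- paste0("g", 1:40)
  inside <- stats::setNames(rep(c(TRUE, FALSE), each = 20), genes)
  conds <- paste0("c", 1:6)
  base <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(genes, conds))
  e1 <- base
  # inside genes: effects agree; outside: independent
  e2 <- rbind(base[1:20, ] + matrix(rnorm(120, 0, 0.1), 20),
              matrix(rnorm(120), 20, dimnames = list(genes[21:40], conds)))
  s1 <- data.frame(gene = genes, chrom = "c4", pos = seq_along(genes))
  s2 <- data.frame(gene = genes, chrom = "c4",
                   pos = c(seq_len(20), 100 + seq_len(20)))
  dv <- donor_divergence(s1, s2, inside, e1, e2)
  expect_gt(mean(dv$effect_cor$r_inside), 0.9)
  expect_lt(mean(abs(dv$effect_cor$r_outside)), 0.5)
  expect_lt(dv$t_effect_cor$p.value, 0.01)
  expect_s3_class(dv$divergence_cor, "htest")
})
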