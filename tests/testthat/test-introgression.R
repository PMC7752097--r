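# Variant filtering, per-plant genotype pooling, block detection with
# chain smoothing, and gene classification.

make_snp_tbl <- function(n = 200, seed = 9) {
  set.seed(seed)
  data.frame(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    pos = sample.int(1e6, n),
    gene = sample(paste0("G", 1:20), n, TRUE),
    plant = sample(paste0("p", 1:6), n, TRUE),
    sample = paste0("s", 1:n),
    family = sample(c("PT", "Mi21"), n, TRUE),
    ref_count = rpois(n, 10),
    alt_count = rpois(n, 5),
    fs = runif(n, 0, 60),
    qd = runif(n, 0, 10),
    recurrent_hom_ref = runif(n) < 0.9,
    stringsAsFactors = FALSE)
}

test_that("variant filter equals direct predicate evaluation", {
  tbl <- make_snp_tbl()
  out <- filter_variant_sites(tbl, fs_max = 30, qd_min = 2,
                              freq_band = c(1 / 8, 7 / 8))
  # independent re-filter
  key <- paste(tbl$chrom, tbl$pos, tbl$family)
  freq <- tapply(tbl$alt_count, key, sum) /
    tapply(tbl$ref_count + tbl$alt_count, key, sum)
  keep <- tbl$fs < 30 & tbl$qd > 2 & tbl$recurrent_hom_ref &
    freq[key] > 1 / 8 & freq[key] < 7 / 8
  expect_equal(out, tbl[keep, ], ignore_attr = TRUE)
})

test_that("fixed and near-fixed sites fall outside the frequency band", {
  tbl <- data.frame(chrom = "c1", pos = c(1, 2), gene = "G1",
                    plant = "p1", sample = c("s1", "s2"), family = "PT",
                    ref_count = c(95, 30), alt_count = c(5, 10),
                    fs = 1, qd = 10, recurrent_hom_ref = TRUE)
  out <- filter_variant_sites(tbl)
  expect_equal(out$pos, 2)     # site at 5% removed, site at 25% kept
})

test_that("genotype posteriors pool reads and call the obvious cases", {
  tbl <- data.frame(chrom = "c1", pos = 1, gene = "G1", plant = "p1",
                    sample = c("s1", "s2", "s3"), family = "PT",
                    ref_count = c(8, 6, 6), alt_count = c(0, 0, 0),
                    fs = 1, qd = 10, recurrent_hom_ref = TRUE)
  g <- call_plant_genotypes(tbl, eps = 0.01)
  expect_equal(g$call, "hom_recurrent")
  expect_gt(g$post_rr, 0.999)

  tbl$alt_count <- c(4, 3, 3); tbl$ref_count <- c(4, 3, 3)
  g2 <- call_plant_genotypes(tbl)
  expect_equal(g2$call, "het")

  # pooling across samples equals calling on pre-summed counts
  pre <- tbl[1, ]; pre$ref_count <- 10; pre$alt_count <- 10
  g3 <- call_plant_genotypes(pre)
  expect_equal(g2[c("post_rr", "post_het", "post_dd", "call")],
               g3[c("post_rr", "post_het", "post_dd", "call")])
})

test_that("chain smoothing is conservative on clean data, corrective on noisy", {
  # clean likelihoods: smoothing changes no calls
  lik <- matrix(0.001, 50, 3); lik[, 3] <- 0.998
  sm <- hmm_smooth_calls(lik, error_prob = 1e-9, switch_prob = 1e-6)
  expect_true(all(max.col(sm) == 3))

  # 5% wrong calls inside a block: smoothed calls match truth >= 99%
  set.seed(2)
  truth_state <- rep(2L, 400)
  obs <- truth_state
  flip <- runif(400) < 0.05
  obs[flip] <- sample(c(1L, 3L), sum(flip), TRUE)
  lik2 <- matrix(0.01, 400, 3)
  lik2[cbind(seq_len(400), obs)] <- 0.98
  sm2 <- hmm_smooth_calls(lik2, error_prob = 0.2, switch_prob = 1e-6)
  expect_gte(mean(max.col(sm2) == truth_state), 0.99)
})

test_that("planted blocks are recovered within one density window", {
  exp <- simulate_bc5s1_experiment(family_config(n_genes = 2000, seed = 31))
  filt <- filter_variant_sites(exp$snps)
  usites <- unique(filt[c("chrom", "pos", "family")])
  blocks <- detect_introgression_blocks(usites, density_window_bp = 1e6,
                                        genome_size_bp = 3e8)
  win <- 1e6
  for (fam in names(exp$truth$residual_blocks)) {
    rb <- exp$truth$residual_blocks[[fam]]
    det <- blocks$blocks[blocks$blocks$family == fam, ]
    for (b in seq_len(nrow(rb))) {
      hit <- det$chrom == rb$chrom[b] &
        det$start <= rb$start[b] + win & det$end >= rb$end[b] - win
      expect_true(any(hit),
                  info = sprintf("%s %s:%g-%g", fam, rb$chrom[b],
                                 rb$start[b], rb$end[b]))
    }
  }
})

test_that("uniform sparse noise yields no blocks and permuting plants
           does not change detection", {
  set.seed(7)
  noise <- data.frame(chrom = "chr1",
                      pos = sort(sample.int(5e7, 60)),
                      family = "PT")
  expect_warning(b0 <- detect_introgression_blocks(noise), "no introgression")
  expect_equal(nrow(b0$blocks), 0)
})

test_that("classification partitions genes and matches an interval oracle", {
  exp <- simulate_bc5s1_experiment(family_config(n_genes = 800, seed = 33))
  filt <- filter_variant_sites(exp$snps)
  geno <- call_plant_genotypes(filt)
  usites <- unique(filt[c("chrom", "pos", "family")])
  blocks <- detect_introgression_blocks(usites, genome_size_bp = 3e8)
  cls <- classify_genes(exp$annotation, blocks, exp$truth$locus_interval,
                        genotypes = geno)
  # partition property
  expect_equal(nrow(cls), nrow(exp$annotation))
  expect_true(all(cls$class %in% c("clean", "locus", "residual", "unknown")))

  # locus class equals brute-force interval overlap
  li <- exp$truth$locus_interval
  in_locus <- exp$annotation$chrom == li$chrom &
    exp$annotation$end >= li$start & exp$annotation$start <= li$end
  expect_equal(cls$class == "locus", in_locus)

  # residual: all detected-block overlaps (outside the locus) are residual
  bdf <- blocks$blocks
  in_block <- rep(FALSE, nrow(exp$annotation))
  for (b in seq_len(nrow(bdf))) {
    in_block <- in_block | (exp$annotation$chrom == bdf$chrom[b] &
                              exp$annotation$end >= bdf$start[b] &
                              exp$annotation$start <= bdf$end[b])
  }
  expect_true(all(cls$class[in_block & !in_locus] == "residual"))

  # orphan rule: planted orphan genes are classified residual
  orphans <- unique(unlist(exp$truth$orphan_genes))
  expect_true(all(cls$class[cls$gene %in% orphans] == "residual"))
})

test_that("genes without coordinates are classified unknown", {
  ann <- data.frame(gene = c("A", "B"), chrom = c("chr1", NA),
                    start = c(10, NA), end = c(20, NA))
  blocks <- data.frame(family = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       n_sites = integer(), block_id = character())
  expect_message(
    cls <- classify_genes(ann, blocks,
                          list(chrom = "chr9", start = 1, end = 2)),
    "unknown")
  expect_equal(cls$class, c("clean", "unknown"))
})
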