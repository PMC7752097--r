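# Normalization, precision weights, batch handling, MDS and the per-gene
# weighted model fits.

test_that("gene filter keeps genes expressed in a third of samples", {
  counts <- rbind(a = c(10, 10, 0, 0, 0, 0),    # 10 reads in exactly 1/3
                  b = rep(0, 6),
                  c = c(9, 9, 9, 9, 9, 9),
                  d = rep(50, 6))
  out <- filter_genes(counts, min_count = 10, min_fraction = 1 / 3)
  expect_equal(rownames(out), c("a", "d"))
  # random matrix vs direct recount
  set.seed(1)
  m <- matrix(rpois(300, 8), 30, 10)
  out2 <- filter_genes(m)
  expect_equal(nrow(out2), sum(rowSums(m >= 10) >= ceiling(10 / 3)))
})

test_that("TMM factors are 1 for identical or depth-scaled libraries and
           have geometric mean 1", {
  set.seed(2)
  base <- rpois(500, 20) + 1
  counts <- cbind(base, base, base)
  expect_equal(tmm_factors(counts), rep(1, 3), tolerance = 1e-12)
  # pure depth change leaves M-values unchanged
  counts2 <- cbind(base, 2 * base, 5 * base)
  expect_equal(tmm_factors(counts2), rep(1, 3), tolerance = 1e-12)
  # geometric mean 1 on arbitrary data
  counts3 <- matrix(rpois(500 * 4, rexp(500, 1 / 30)), 500, 4)
  f <- tmm_factors(counts3)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
})

test_that("TMM factors equal the hand-computed trimmed-mean formula", {
  set.seed(4)
  counts <- matrix(rnbinom(200 * 5, mu = 40, size = 2) + 1, 200, 5)
  counts[1:20, 3] <- counts[1:20, 3] * 8          # asymmetric DE
  expect_equal(tmm_factors(counts), tmm_oracle(counts), tolerance = 1e-10)
})

test_that("log2cpm matches its closed form", {
  cm <- matrix(0, 2, 1); cm[2, 1] <- 1e6
  expect_equal(round(log2cpm(cm, factors = 1)[1, 1], 3), -1.000)
  set.seed(5)
  m <- matrix(rpois(60, 50), 10, 6)
  f <- tmm_factors(m)
  lib <- colSums(m)
  expected <- log2(sweep(m + 0.5, 2, lib * f + 1, "/") * 1e6)
  expect_equal(log2cpm(m, f), expected, ignore_attr = TRUE)
})

test_that("precision weights are positive, near-constant for homoscedastic
           data, and larger at better-predicted counts on a decreasing trend", {
  set.seed(6)
  G <- 300; S <- 16
  mu <- runif(G, 6, 14)
  E <- matrix(2^(mu + rnorm(G * S, 0, 0.4)), G, S)
  counts <- matrix(rpois(G * S, E), G, S)
  design <- cbind(1, rep(0:1, each = S / 2))
  pw <- precision_weights(counts, rep(1, S), design)
  expect_true(all(pw$weights > 0 & is.finite(pw$weights)))
  expect_lt(stats::sd(pw$weights) / mean(pw$weights), 0.2)

  # counting noise only: variance falls with expression, so high-count
  # genes get larger weights
  counts2 <- matrix(rpois(G * S, 2^rep(mu, S)), G, S)
  pw2 <- precision_weights(counts2, rep(1, S), design)
  w_by_gene <- rowMeans(pw2$weights)
  expect_gt(stats::cor(mu, w_by_gene, method = "spearman"), 0.8)

  expect_error(precision_weights(counts, rep(1, S), matrix(1, S, S + 1)),
               "full rank")
})

test_that("batch removal removes planted offsets, is idempotent and flags
           confounding", {
  set.seed(7)
  G <- 100; S <- 12
  x <- matrix(rnorm(G * S, 8), G, S)
  x[, 7:12] <- x[, 1:6]           # batches identical: estimated effect 0
  design <- cbind(1, rep(0:1, S / 2))
  batch <- rep(1:2, each = S / 2)
  out0 <- remove_batch(x, batch, design)
  expect_lt(max(abs(out0 - x)), 1e-8)
  x1 <- x; x1[, batch == 2] <- x1[, batch == 2] + 1
  out1 <- remove_batch(x1, batch, design)
  # planted +1 offset removed
  expect_lt(max(abs(rowMeans(out1[, batch == 2]) -
                      rowMeans(out1[, batch == 1]))), 0.05)
  # genotype contrast unchanged
  g <- design[, 2]
  d_before <- rowMeans(x[, g == 1]) - rowMeans(x[, g == 0])
  d_after <- rowMeans(out1[, g == 1]) - rowMeans(out1[, g == 0])
  expect_equal(d_before, d_after, tolerance = 1e-8)
  # idempotence
  expect_equal(remove_batch(out1, batch, design), out1, tolerance = 1e-8)
  # perfect confounding errors with column names
  expect_error(remove_batch(x, rep(1:2, 6), cbind(1, rep(1:2, 6) == 2)),
               "confounded")
})

test_that("MDS distances are symmetric, zero for identical samples, and
           separate planted clusters", {
  set.seed(8)
  G <- 600
  base <- rnorm(G, 8)
  x <- cbind(s1 = base, s2 = base,
             s3 = base + c(rnorm(G / 2, 3), rep(0, G / 2)),
             s4 = base + c(rnorm(G / 2, 3), rep(0, G / 2)) + rnorm(G, 0, .1))
  xy <- mds_coordinates(x, top_n = 100)
  expect_lt(sqrt(sum((xy["s1", ] - xy["s2", ])^2)), 1e-6)
  between <- sqrt(sum((xy["s1", ] - xy["s3", ])^2))
  within <- sqrt(sum((xy["s3", ] - xy["s4", ])^2))
  expect_gt(between, 3 * within)
})

test_that("weighted fits equal OLS at equal weights and solve the toy", {
  y <- c(0, 1); w <- c(1, 1); g <- c(0, 1)
  f <- fit_gene_models(matrix(y, 1), matrix(2, 1, 2), g)
  expect_equal(f$beta, 1)

  set.seed(9)
  n <- 12
  g <- rep(0:1, each = n / 2)
  y <- rnorm(n)
  f1 <- fit_gene_models(matrix(y, 1), matrix(1, 1, n), g)
  ols <- stats::lm(y ~ g)
  expect_equal(f1$beta, unname(stats::coef(ols)[2]), tolerance = 1e-12)
  expect_equal(f1$se, unname(sqrt(diag(stats::vcov(ols)))[2]),
               tolerance = 1e-12)
})

test_that("weighted fits match the normal-equations oracle", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) g[1:2] <- 0:1
    y <- rnorm(n); w <- runif(n, 0.2, 3)
    f <- fit_gene_models(matrix(y, 1), matrix(w, 1), g)
    orc <- wls_oracle(y, w, cbind(1, g))
    expect_equal(f$beta, orc$beta[2], tolerance = 1e-10)
    expect_equal(f$se, orc$se[2], tolerance = 1e-10)
    expect_equal(f$df, orc$df)
  }
})

test_that("planted effects are recovered across simulated genes", {
  set.seed(11)
  G <- 200; n <- 12
  g <- rep(0:1, each = n / 2)
  y <- matrix(rnorm(G * n, 0, 0.3), G, n) +
    outer(rep(1, G), g)                       # beta = 1 everywhere
  f <- fit_gene_models(y, matrix(1, G, n), g)
  expect_lt(abs(mean(f$beta) - 1), 0.1)
})

test_that("interaction model returns pooled-variance temperature terms", {
  set.seed(12)
  n <- 24
  g <- rep(0:1, n / 2)
  temp <- rep(c("cold", "warm"), each = n / 2)
  y <- 1 + 0.5 * g + 1 * (temp == "warm") + 0.8 * g * (temp == "warm") +
    rnorm(n, 0, 0.2)
  f <- fit_gene_models(matrix(y, 1), matrix(1, 1, n), g,
                       model = "interaction", temperature = temp)
  expect_lt(abs(f$beta_int - 0.8), 0.35)
  ref <- stats::lm(y ~ g * I(temp == "warm"))
  expect_equal(f$beta_int, unname(stats::coef(ref)[4]), tolerance = 1e-10)
})

test_that("rank-deficient designs return NA rather than failing", {
  y <- rnorm(6)
  f <- fit_gene_models(matrix(y, 1), matrix(1, 1, 6), rep(0, 6))
  expect_true(is.na(f$beta))
})

test_that("effect imputation completes the table with uninformative entries", {
  eff <- data.frame(gene = c("a", "a", "b"), condition = c("c1", "c2", "c1"),
                    beta = c(1, 2, 3), se = c(0.1, 0.2, 0.3))
  imp <- impute_effects(eff, conditions = c("c1", "c2"))
  expect_equal(imp$beta["b", "c2"], 0)
  expect_equal(imp$se["b", "c2"], 1000)
  expect_equal(imp$beta["a", "c2"], 2)
})

test_that("replication set requires both-family significance with matching
           sign and is symmetric in family order", {
  genes <- paste0("g", 1:4)
  conds <- c("c1", "c2")
  mk <- function(m, l) make_shrink_stub(
    matrix(m, 4, 2, dimnames = list(genes, conds)),
    matrix(l, 4, 2, dimnames = list(genes, conds)))
  m1 <- matrix(c(1, 1, -1, 0.5, 1, 1, -1, 0.5), 4, 2,
               dimnames = list(genes, conds))
  l1 <- matrix(0.01, 4, 2, dimnames = list(genes, conds)); l1[4, ] <- 0.4
  m2 <- m1; m2[3, ] <- 1                     # gene 3: opposite sign
  l2 <- l1
  s1 <- make_shrink_stub(m1, l1); s2 <- make_shrink_stub(m2, l2)
  rs <- consensus_replicated_set(s1, s2)
  expect_setequal(rs$genes, c("g1", "g2"))
  rs_swapped <- consensus_replicated_set(s2, s1)
  expect_setequal(rs_swapped$genes, rs$genes)
  expect_equal(sort(rs$union1), sort(rs_swapped$union2))
})
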