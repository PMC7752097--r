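#' Filter lowly expressed genes
#'
#' Keeps genes with at least `min_count` reads in at least
#' `ceiling(min_fraction * n_samples)` samples.
#'
#' @param counts genes x samples nonnegative integer matrix.
#' @param min_count Minimum read count (default 10).
#' @param min_fraction Minimum fraction of samples (default 1/3).
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_count = 10, min_fraction = 1 / 3) {
  counts <- as.matrix(counts)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values: the reference sample is the library
#' whose upper quartile is closest to the mean upper quartile; each
#' sample's factor is 2^(weighted trimmed mean of gene-wise log2 ratios
#' against the reference), trimming the most extreme M-values and
#' A-values and weighting by inverse asymptotic binomial variances;
#' factors are rescaled to geometric mean 1. Computed by
#' `edgeR::calcNormFactors`.
#'
#' @param counts genes x samples count matrix.
#' @param trim_M Fraction of M-values trimmed from each tail (default 0.30).
#' @param trim_A Fraction of A-values trimmed from each tail (default 0.05).
#' @return Numeric vector of per-sample normalization factors.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(colSums(counts) <= 0)) stop("library sizes must be positive")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  unname(f)
}

#' log2 counts per million
#'
#' `log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6)`, the
#' same offset convention used by voom.
#'
#' @param counts genes x samples count matrix.
#' @param factors Per-sample normalization factors (default 1).
#' @param prior Prior count added to the numerator (default 0.5).
#' @return genes x samples matrix of log2CPM values.
#' @export
log2cpm <- function(counts, factors = rep(1, ncol(counts)), prior = 0.5) {
  counts <- as.matrix(counts)
  lib <- colSums(counts) * factors
  t(log2(t(counts + prior) / (lib + 2 * prior) * 1e6))
}

#' Per-observation precision weights from the mean-variance trend
#'
#' Fits gene-wise linear models on log2CPM, smooths the square-root
#' residual standard deviations against average log-count with lowess, and
#' assigns each observation the inverse fourth power of its predicted
#' square-root standard deviation as a weight (the voom procedure; computed
#' with `limma::voom`). Downstream model fits treat observation variances
#' as proportional to 1/weight.
#'
#' @param counts genes x samples count matrix (already expression-filtered).
#' @param factors Per-sample normalization factors.
#' @param design Sample-level design matrix (must be full rank).
#' @return List with `E` (log2CPM matrix) and `weights` (same dim).
#' @export
precision_weights <- function(counts, factors, design) {
  counts <- as.matrix(counts)
  if (qr(design)$rank < ncol(design)) stop("design is not full rank")
  if (nrow(design) - ncol(design) <= 0) stop("no residual degrees of freedom")
  v <- limma::voom(counts, design = design,
                   lib.size = colSums(counts) * factors)
  list(E = v$E, weights = v$weights)
}

#' Remove batch effects from a log-expression matrix
#'
#' Fits batch jointly with the design of interest per gene and subtracts
#' only the fitted batch terms (`limma::removeBatchEffect`). Errors out,
#' naming the columns, if batch is perfectly confounded with the design.
#'
#' @param x genes x samples log-expression matrix.
#' @param batch Factor of batch labels (e.g. experimental replicate).
#' @param design Design matrix of effects to protect.
#' @return Corrected matrix of the same dimensions.
#' @export
remove_batch <- function(x, batch, design) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) return(as.matrix(x))
  B <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  full <- cbind(design, B)
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    aliased <- colnames(full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    stop("batch is confounded with the design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  limma::removeBatchEffect(as.matrix(x), batch = batch, design = design)
}

#' MDS sample coordinates from leading log-fold-changes
#'
#' Pairwise sample distance is the root-mean-square of the `top_n` largest
#' absolute log-fold-changes between each pair of samples ("pairwise" gene
#' selection, as in `limma::plotMDS`), followed by classical
#' multidimensional scaling.
#'
#' @param x genes x samples log-expression matrix.
#' @param top_n Number of top genes per pair (default 500).
#' @param dims Number of dimensions to return (default 2).
#' @return samples x dims coordinate matrix.
#' @export
mds_coordinates <- function(x, top_n = 500, dims = 2) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("need at least 3 samples")
  mds <- limma::plotMDS(x, top = top_n, plot = FALSE,
                        gene.selection = "pairwise")
  d2 <- mds$distance.matrix.squared
  if (is.null(d2)) d2 <- mds$distance.matrix^2
  d <- sqrt(pmax(d2, 0))
  k <- min(dims, ncol(x) - 1)
  cmd <- stats::cmdscale(stats::as.dist(d), k = k)
  rownames(cmd) <- colnames(x)
  cmd
}

# exact weighted least squares for one response; returns beta, se, df
wls_fit <- function(y, w, X) {
  ok <- is.finite(y) & is.finite(w) & w > 0
  y <- y[ok]; w <- w[ok]; X <- X[ok, , drop = FALSE]
  p <- ncol(X)
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < p)
    return(list(beta = rep(NA_real_, p), se = rep(NA_real_, p),
                df = NA_integer_, reason = "rank_deficient"))
  fit <- stats::lm.wfit(X, y, w)
  df <- length(y) - p
  if (df >= 1) {
    sigma2 <- sum(w * fit$residuals^2) / df
    XtWX_inv <- chol2inv(chol(crossprod(X, w * X)))
    se <- sqrt(sigma2 * diag(XtWX_inv))
  } else se <- rep(NA_real_, p)      # saturated fit: estimable, no SE
  list(beta = unname(fit$coefficients), se = se, df = df, reason = NA)
}

#' Fit per-gene weighted linear models for locus effects
#'
#' Fits, for every gene, an exact weighted least squares model of
#' (batch-corrected) log2CPM on the locus genotype. Three model shapes are
#' supported: `"genotype"` (one condition: y ~ genotype, run separately per
#' tissue:temperature condition), `"interaction"` (both temperatures of a
#' tissue jointly: y ~ genotype + temperature + genotype:temperature with a
#' pooled residual variance), and `"cis"` (y ~ local genotype of the gene,
#' for genes in residual blocks). Genotype is coded 0 (hom Low) / 1 (hom
#' High); heterozygous plants are excluded by the experimental design.
#' Standard errors are exact WLS standard errors,
#' sqrt(sigma2 * (X'WX)^-1).
#'
#' @param expr genes x samples matrix for one family/condition subset.
#' @param weights Matching precision-weight matrix.
#' @param genotype Numeric 0/1 vector per sample.
#' @param model One of "genotype", "interaction", "cis".
#' @param temperature Factor (needed for `"interaction"`).
#' @param cis_genotype genes x samples 0/1 matrix of local genotypes
#'   (needed for `"cis"`, row order matching `expr`).
#' @return data.frame with one row per gene: beta (High minus Low, log2),
#'   se, df; for `"interaction"` additionally beta_temp, se_temp, beta_int,
#'   se_int.
#' @export
fit_gene_models <- function(expr, weights, genotype,
                            model = c("genotype", "interaction", "cis"),
                            temperature = NULL, cis_genotype = NULL) {
  model <- match.arg(model)
  expr <- as.matrix(expr); weights <- as.matrix(weights)
  stopifnot(all(dim(expr) == dim(weights)),
            length(genotype) == ncol(expr))
  G <- nrow(expr)
  if (model == "interaction") {
    stopifnot(!is.null(temperature))
    tnum <- as.numeric(as.factor(temperature)) - 1
    X <- cbind(1, genotype, tnum, genotype * tnum)
  } else if (model == "genotype") {
    X <- cbind(1, genotype)
  }
  out <- vector("list", G)
  for (g in seq_len(G)) {
    Xg <- if (model == "cis") cbind(1, cis_genotype[g, ]) else X
    f <- wls_fit(expr[g, ], weights[g, ], Xg)
    out[[g]] <- f
  }
  beta <- vapply(out, function(f) f$beta[2], numeric(1))
  se <- vapply(out, function(f) f$se[2], numeric(1))
  df <- vapply(out, function(f) as.integer(f$df), integer(1))
  res <- data.frame(gene = rownames(expr) %||% seq_len(G),
                    beta = beta, se = se, df = df,
                    stringsAsFactors = FALSE)
  if (model == "interaction") {
    res$beta_temp <- vapply(out, function(f) f$beta[3], numeric(1))
    res$se_temp <- vapply(out, function(f) f$se[3], numeric(1))
    res$beta_int <- vapply(out, function(f) f$beta[4], numeric(1))
    res$se_int <- vapply(out, function(f) f$se[4], numeric(1))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit locus effects in every condition of a family
#'
#' Convenience driver: loops over the tissue:temperature conditions of one
#' family's samples and fits the per-condition genotype model (or the
#' per-tissue interaction model) with [fit_gene_models()].
#'
#' @param expr genes x samples (one family), batch-corrected log2CPM.
#' @param weights Matching precision weights.
#' @param samples data.frame with columns sample, tissue, temperature,
#'   genotype (0/1); rows match columns of `expr`.
#' @param model "genotype" (per condition) or "interaction" (per tissue).
#' @return Long data.frame: gene, condition (tissue:temperature or tissue),
#'   beta, se, df (+ interaction columns for the interaction model).
#' @export
fit_all_conditions <- function(expr, weights, samples,
                               model = c("genotype", "interaction")) {
  model <- match.arg(model)
  key <- if (model == "genotype") {
    paste(samples$tissue, samples$temperature, sep = ":")
  } else samples$tissue
  res <- lapply(unique(key), function(k) {
    idx <- key == k
    if (length(unique(samples$genotype[idx])) < 2) return(NULL)
    f <- fit_gene_models(expr[, idx, drop = FALSE],
                         weights[, idx, drop = FALSE],
                         samples$genotype[idx], model = model,
                         temperature = samples$temperature[idx])
    f$condition <- k
    f
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

#' Impute missing gene x condition effects for shrinkage
#'
#' Reshapes a long effect table into complete genes x conditions matrices
#' of estimates and standard errors; conditions in which a gene was not
#' testable are imputed as beta = 0 with a standard error of 1000, which
#' conveys no information about the effect while keeping the table
#' complete.
#'
#' @param effects Long data.frame from [fit_all_conditions()].
#' @param conditions Character vector fixing condition order (default: the
#'   sorted conditions present).
#' @param se_missing Imputation standard error (default 1000).
#' @return List with matrices `beta` and `se` (genes x conditions).
#' @export
impute_effects <- function(effects, conditions = NULL, se_missing = 1000) {
  if (is.null(conditions)) conditions <- sort(unique(effects$condition))
  genes <- sort(unique(effects$gene))
  beta <- matrix(0, length(genes), length(conditions),
                 dimnames = list(genes, conditions))
  se <- matrix(se_missing, length(genes), length(conditions),
               dimnames = list(genes, conditions))
  i <- cbind(match(effects$gene, genes), match(effects$condition, conditions))
  b <- effects$beta; s <- effects$se
  bad <- !is.finite(b) | !is.finite(s) | s <= 0
  b[bad] <- 0; s[bad] <- se_missing
  beta[i] <- b; se[i] <- s
  list(beta = beta, se = se)
}

#' Two-family replicated gene sets
#'
#' A gene is replicated in a condition when its local false sign rate is
#' below `lfsr_max` in both families and the posterior effect signs agree.
#' Also reports each family's union set (significant in any condition) and
#' is symmetric in family order.
#'
#' @param shrink1,shrink2 [multivariate_shrinkage()] results for the two
#'   families (shared condition set).
#' @param lfsr_max Significance threshold (default 0.05).
#' @return List of class `replicated_set`: `per_condition` (long
#'   data.frame gene, condition, direction), `union1`, `union2` (character
#'   vectors), `genes` (all replicated genes).
#' @export
consensus_replicated_set <- function(shrink1, shrink2, lfsr_max = 0.05) {
  genes <- intersect(rownames(shrink1$lfsr), rownames(shrink2$lfsr))
  conds <- intersect(colnames(shrink1$lfsr), colnames(shrink2$lfsr))
  l1 <- shrink1$lfsr[genes, conds, drop = FALSE]
  l2 <- shrink2$lfsr[genes, conds, drop = FALSE]
  m1 <- shrink1$posterior_mean[genes, conds, drop = FALSE]
  m2 <- shrink2$posterior_mean[genes, conds, drop = FALSE]
  rep_mat <- l1 < lfsr_max & l2 < lfsr_max & sign(m1) == sign(m2) &
    sign(m1) != 0
  idx <- which(rep_mat, arr.ind = TRUE)
  per_condition <- data.frame(
    gene = genes[idx[, 1]], condition = conds[idx[, 2]],
    direction = ifelse(m1[idx] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  structure(list(
    per_condition = per_condition,
    union1 = genes[rowSums(l1 < lfsr_max) > 0],
    union2 = genes[rowSums(l2 < lfsr_max) > 0],
    genes = unique(per_condition$gene),
    lfsr_max = lfsr_max), class = "replicated_set")
}
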