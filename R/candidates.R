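#' Proportion of conditions with replicated cis differential expression
#'
#' For each gene inside the inversion locus, the fraction of
#' tissue:temperature conditions in which the gene's locus-genotype effect
#' is significant (lfsr below `lfsr_max`) in both donor families with the
#' same sign. Conditions in which the gene is not expressed in either
#' family are removed from the denominator.
#'
#' @param shrink1,shrink2 Per-family shrinkage results for locus genes
#'   (objects with `lfsr` and `posterior_mean` matrices).
#' @param expressed1,expressed2 Optional logical genes x conditions
#'   matrices marking where the gene is expressed in each family (default:
#'   everywhere).
#' @param locus_genes Character vector of genes inside the locus; any gene
#'   in the shrinkage objects outside this set raises an error.
#' @param lfsr_max Significance threshold (default 0.05).
#' @return data.frame: gene, n_conditions (denominator), n_de, prop.
#' @export
de_condition_proportion <- function(shrink1, shrink2,
                                    expressed1 = NULL, expressed2 = NULL,
                                    locus_genes = NULL, lfsr_max = 0.05) {
  genes <- intersect(rownames(shrink1$lfsr), rownames(shrink2$lfsr))
  conds <- intersect(colnames(shrink1$lfsr), colnames(shrink2$lfsr))
  if (!is.null(locus_genes) && !all(genes %in% locus_genes))
    stop("gene not in locus: ",
         paste(utils::head(setdiff(genes, locus_genes)), collapse = ", "))
  l1 <- shrink1$lfsr[genes, conds, drop = FALSE]
  l2 <- shrink2$lfsr[genes, conds, drop = FALSE]
  m1 <- shrink1$posterior_mean[genes, conds, drop = FALSE]
  m2 <- shrink2$posterior_mean[genes, conds, drop = FALSE]
  ex <- matrix(TRUE, length(genes), length(conds),
               dimnames = list(genes, conds))
  if (!is.null(expressed1)) ex <- ex & expressed1[genes, conds, drop = FALSE]
  if (!is.null(expressed2)) ex <- ex & expressed2[genes, conds, drop = FALSE]
  de <- l1 < lfsr_max & l2 < lfsr_max & sign(m1) == sign(m2) &
    sign(m1) != 0 & ex
  n_cond <- rowSums(ex)
  data.frame(gene = genes, n_conditions = n_cond, n_de = rowSums(de),
             prop = ifelse(n_cond > 0, rowSums(de) / n_cond, NA_real_),
             stringsAsFactors = FALSE)
}

# vectorized per-reporter regression: reporter ~ locus gene expression +
# karyotype; returns p-value and sign of the locus-gene coefficient
reporter_coef_tests <- function(Y, locus_expr, genotype) {
  X <- cbind(1, locus_expr, genotype)
  n <- nrow(X); p <- qr(X)$rank
  if (p < ncol(X) || n - ncol(X) < 3) return(NULL)   # < 3 residual df
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - ncol(X))
  se <- sqrt(sigma2 * XtXi[2, 2])
  tval <- B[2, ] / se
  pval <- 2 * stats::pt(abs(tval), df = n - ncol(X), lower.tail = FALSE)
  pval[!is.finite(pval)] <- 1       # degenerate reporters never qualify
  list(p = pval, sign = sign(B[2, ]))
}

#' Reporter-correlation scan for candidate driver genes in the locus
#'
#' For each locus gene and each condition, regresses every replicated
#' reporter gene (a locus-regulated gene on another chromosome) on the
#' locus gene's expression plus the locus karyotype, separately in each
#' family. A reporter "qualifies" for a locus gene when the
#' locus-gene-expression coefficient is significant (p below `p_max`) with
#' matching sign in both families; conditioning on karyotype removes the
#' correlation that every locus gene shares through the genotype itself.
#' The per-gene score is the mean over conditions of the per-condition
#' qualifying-reporter proportion.
#'
#' @param locus_expr1,locus_expr2 Locus-gene expression matrices
#'   (locus genes x samples), one per family.
#' @param reporter_expr1,reporter_expr2 Reporter expression matrices
#'   (reporters x samples).
#' @param genotype1,genotype2 0/1 karyotype per sample.
#' @param condition1,condition2 Condition labels per sample.
#' @param p_max Per-reporter significance threshold (default 0.05).
#' @return List: `scores` data.frame (gene, prop_reporters_correlated),
#'   `per_condition` matrix (locus genes x conditions of qualifying
#'   proportions).
#' @export
reporter_correlation_scan <- function(locus_expr1, locus_expr2,
                                      reporter_expr1, reporter_expr2,
                                      genotype1, genotype2,
                                      condition1, condition2,
                                      p_max = 0.05) {
  lgenes <- intersect(rownames(locus_expr1), rownames(locus_expr2))
  rgenes <- intersect(rownames(reporter_expr1), rownames(reporter_expr2))
  conds <- intersect(unique(condition1), unique(condition2))
  prop <- matrix(NA_real_, length(lgenes), length(conds),
                 dimnames = list(lgenes, conds))
  for (cn in conds) {
    i1 <- condition1 == cn; i2 <- condition2 == cn
    Y1 <- t(reporter_expr1[rgenes, i1, drop = FALSE])
    Y2 <- t(reporter_expr2[rgenes, i2, drop = FALSE])
    for (g in lgenes) {
      t1 <- reporter_coef_tests(Y1, locus_expr1[g, i1], genotype1[i1])
      t2 <- reporter_coef_tests(Y2, locus_expr2[g, i2], genotype2[i2])
      if (is.null(t1) || is.null(t2)) next
      qual <- t1$p < p_max & t2$p < p_max & t1$sign == t2$sign & t1$sign != 0
      prop[g, cn] <- mean(qual)
    }
  }
  scores <- data.frame(
    gene = lgenes,
    prop_reporters_correlated = rowMeans(prop, na.rm = TRUE),
    stringsAsFactors = FALSE)
  list(scores = scores, per_condition = prop)
}

#' Flag candidate causal genes inside the locus
#'
#' A gene is `highly_correlated` when its reporter-correlation proportion
#' strictly exceeds `corr_min`, and `consistently_DE` when its
#' DE-condition proportion strictly exceeds `de_min` (strict inequalities:
#' a gene exactly at a threshold is not flagged).
#'
#' @param de_prop data.frame from [de_condition_proportion()].
#' @param corr_scores data.frame from [reporter_correlation_scan()]
#'   (`$scores`).
#' @param corr_min Correlation-proportion threshold (default 0.06).
#' @param de_min DE-proportion threshold (default 0.90).
#' @param tf_list Character vector of transcription-factor gene ids.
#' @return data.frame of class `candidate_scores`: gene,
#'   prop_conditions_DE, prop_reporters_correlated, highly_correlated,
#'   consistently_DE, is_TF.
#' @export
flag_candidates <- function(de_prop, corr_scores, corr_min = 0.06,
                            de_min = 0.90, tf_list = character()) {
  genes <- union(de_prop$gene, corr_scores$gene)
  de <- de_prop$prop[match(genes, de_prop$gene)]
  cr <- corr_scores$prop_reporters_correlated[match(genes, corr_scores$gene)]
  out <- data.frame(
    gene = genes,
    prop_conditions_DE = de,
    prop_reporters_correlated = cr,
    highly_correlated = !is.na(cr) & cr > corr_min,
    consistently_DE = !is.na(de) & de > de_min,
    is_TF = genes %in% tf_list,
    stringsAsFactors = FALSE)
  class(out) <- c("candidate_scores", "data.frame")
  out
}

#' Donor divergence inside versus outside the inversion
#'
#' Quantifies how similar the two donor haplotypes are, per gene, as the
#' proportion of SNP sites shared between the donors (shared / total
#' observed), and how concordant their expression effects are, per
#' condition, as the Pearson correlation of the two families' effect
#' estimates. Both measures are contrasted between genes inside the locus
#' and genes outside it (Welch two-sample t-tests), and per-gene genetic
#' divergence (1 - shared proportion) is correlated with expression
#' divergence (mean absolute effect difference across conditions).
#'
#' @param snp1,snp2 data.frames of donor SNP sites per family with columns
#'   gene, chrom, pos (restricted to the shared introgressed region).
#' @param inside Named logical vector: gene -> TRUE if inside the locus.
#' @param effects1,effects2 Optional genes x conditions effect matrices
#'   for the two families.
#' @return List of class `donor_divergence`: `records` (gene, shared_prop,
#'   inside), `t_shared` (Welch test on shared proportions), `effect_cor`
#'   (per-condition inside/outside correlations), `t_effect_cor`,
#'   `divergence_cor` (cor.test of genetic vs expression divergence).
#' @export
donor_divergence <- function(snp1, snp2, inside,
                             effects1 = NULL, effects2 = NULL) {
  key1 <- split(paste(snp1$chrom, snp1$pos), snp1$gene)
  key2 <- split(paste(snp2$chrom, snp2$pos), snp2$gene)
  genes <- union(names(key1), names(key2))
  shared_prop <- vapply(genes, function(g) {
    a <- unique(key1[[g]] %||% character())
    b <- unique(key2[[g]] %||% character())
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  records <- data.frame(gene = genes, shared_prop = shared_prop,
                        inside = unname(inside[genes]),
                        stringsAsFactors = FALSE)

  t_shared <- NULL
  if (sum(records$inside, na.rm = TRUE) >= 2 &&
      sum(!records$inside, na.rm = TRUE) >= 2) {
    t_shared <- tryCatch(stats::t.test(shared_prop ~ inside, data = records),
                         error = function(e) {
                           warning("shared-SNP test skipped: ",
                                   conditionMessage(e))
                           NULL
                         })
  } else warning("too few genes per stratum; shared-SNP test skipped")

  effect_cor <- NULL; t_effect_cor <- NULL; divergence_cor <- NULL
  if (!is.null(effects1) && !is.null(effects2)) {
    gg <- intersect(intersect(rownames(effects1), rownames(effects2)),
                    records$gene)
    conds <- intersect(colnames(effects1), colnames(effects2))
    ins <- inside[gg]
    r_in <- r_out <- rep(NA_real_, length(conds))
    for (i in seq_along(conds)) {
      e1 <- effects1[gg, conds[i]]; e2 <- effects2[gg, conds[i]]
      if (sum(ins) >= 3) r_in[i] <- stats::cor(e1[ins], e2[ins],
                                               use = "complete.obs")
      if (sum(!ins) >= 3) r_out[i] <- stats::cor(e1[!ins], e2[!ins],
                                                 use = "complete.obs")
    }
    effect_cor <- data.frame(condition = conds, r_inside = r_in,
                             r_outside = r_out)
    if (sum(is.finite(r_in)) >= 2 && sum(is.finite(r_out)) >= 2)
      t_effect_cor <- tryCatch(stats::t.test(r_in, r_out),
                               error = function(e) NULL)
    expr_div <- rowMeans(abs(effects1[gg, conds, drop = FALSE] -
                               effects2[gg, conds, drop = FALSE]))
    gen_div <- 1 - records$shared_prop[match(gg, records$gene)]
    if (length(gg) >= 4)
      divergence_cor <- stats::cor.test(gen_div, expr_div)
  }
  structure(list(records = records, t_shared = t_shared,
                 effect_cor = effect_cor, t_effect_cor = t_effect_cor,
                 divergence_cor = divergence_cor),
            class = "donor_divergence")
}
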