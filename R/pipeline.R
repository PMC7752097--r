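#' Default pipeline configuration
#'
#' Every stage threshold has the analysis default; unknown keys in
#' `overrides` are rejected so configuration typos fail loudly.
#'
#' @param overrides Named list (or YAML-loaded list) of keys to replace.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    panel = list(n_plants = 600, divergence = 0.5, missing_rate = 0.1),
    popgen = list(n_hap = 50, region_bp = 2e7, fst_out = 0.05,
                  fst_in = 0.38, inside = c(8e6, 1.4e7),
                  window_bp = 1e6, step_bp = 1e5),
    experiment = list(n_genes = 600, n_reps = 3),
    lfsr_max = 0.05, fdr_max = 0.01, similarity_min = 0.5,
    corr_min = 0.06, de_min = 0.90,
    emergence = list(n_per_group = 40, effect = -0.75),
    stages = list(panel = TRUE, popgen = TRUE, experiment = TRUE,
                  enrichment = TRUE, emergence = TRUE))
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  for (k in names(overrides)) {
    if (is.list(cfg[[k]]) && is.list(overrides[[k]])) {
      bad <- setdiff(names(overrides[[k]]), names(cfg[[k]]))
      if (length(bad)) stop("unknown config keys: ",
                            paste(paste0(k, "$", bad), collapse = ", "))
      cfg[[k]][names(overrides[[k]])] <- overrides[[k]]
    } else cfg[[k]] <- overrides[[k]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Executes every stage in dependency order on simulated inputs:
#' landrace-panel karyotyping + HWE + elevation cline; windowed FST/pi on
#' divergent populations; the two-family expression experiment
#' (introgression mapping, normalization, per-condition fits, shrinkage,
#' two-family replication); GO enrichment on a toy universe; candidate
#' scanning inside the locus; and the emergence mixed model. Writes CSV
#' outputs, the echoed config, and a JSON manifest with md5 checksums to
#' `out_dir`. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with each stage's in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("run"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  results <- list()

  if (cfg$stages$panel) {
    say("stage panel: karyotyping, HWE, elevation cline")
    pan <- simulate_landrace_panel(panel_config(
      n_plants = cfg$panel$n_plants,
      haplotype_divergence = cfg$panel$divergence,
      missing_rate = cfg$panel$missing_rate, seed = cfg$seed))
    gm <- filter_markers(pan$gm, region = panel_config()$locus_interval)
    calls <- call_inversion_genotypes(gm)
    k <- table(factor(calls$calls$karyotype,
                      c("Low/Low", "Low/High", "High/High")))
    hwe <- hwe_exact_test(k[1], k[2], k[3])
    cline <- elevation_cline(calls, pan$gm$plants$elevation)
    emit(calls$calls, "karyotype_calls.csv")
    emit(data.frame(stat = c("D", "p"), value = c(hwe$D, hwe$p_value)),
         "hwe.csv")
    emit(cline$fit, "cline_fit.csv")
    results$panel <- list(calls = calls, hwe = hwe, cline = cline,
                          truth = pan$truth)
  }

  if (cfg$stages$popgen) {
    say("stage popgen: windowed pi / dxy / FST")
    pg <- cfg$popgen
    prof <- data.frame(start = c(1, pg$inside[1], pg$inside[2] + 1),
                       end = c(pg$inside[1] - 1, pg$inside[2], pg$region_bp),
                       fst = c(pg$fst_out, pg$fst_in, pg$fst_out))
    sim <- simulate_divergent_populations(pg$n_hap, pg$region_bp, prof,
                                          seed = cfg$seed + 1)
    ss <- site_statistics(sim$panel1, sim$panel2, sim$positions)
    win <- windowed_stats(ss, pg$window_bp, pg$step_bp,
                          region_end = pg$region_bp)
    emit(win, "windows.csv")
    results$popgen <- list(windows = win, truth = sim$truth, profile = prof)
  }

  if (cfg$stages$experiment) {
    say("stage experiment: BC5S1 families, introgression, expression")
    exp <- simulate_bc5s1_experiment(family_config(
      n_genes = cfg$experiment$n_genes, n_reps = cfg$experiment$n_reps,
      seed = cfg$seed + 2))
    filt <- filter_variant_sites(exp$snps)
    geno <- call_plant_genotypes(filt)
    usites <- unique(filt[c("chrom", "pos", "family")])
    blocks <- detect_introgression_blocks(usites, genome_size_bp = 3e8,
                                           genotypes = geno)
    fams <- unique(exp$samples$family)
    karyo <- unlist(lapply(exp$truth$karyotype, function(k) k))
    names(karyo) <- unlist(lapply(exp$truth$karyotype, names))
    cls <- classify_genes(exp$annotation, blocks,
                          exp$truth$locus_interval, genotypes = geno,
                          karyotype = karyo)
    emit(blocks$blocks, "introgression_blocks.csv")
    emit(cls, "gene_classes.csv")
    write_bed(blocks$blocks, file.path(out_dir, "blocks.bed"))
    outputs <- c(outputs, file.path(out_dir, "blocks.bed"))

    counts <- filter_genes(exp$counts)
    shr <- list(); eff <- list(); expr_mats <- list(); samp <- list()
    clean_genes <- cls$gene[cls$class == "clean"]
    locus_genes <- cls$gene[cls$class == "locus"]
    for (fam in fams) {
      sm <- exp$samples[exp$samples$family == fam, ]
      cm <- counts[, sm$sample, drop = FALSE]
      f <- tmm_factors(cm)
      design <- stats::model.matrix(~ genotype + condition, sm)
      pw <- precision_weights(cm, f, design)
      E <- remove_batch(pw$E, sm$batch, design)
      expr_mats[[fam]] <- E
      samp[[fam]] <- sm
      eff_clean <- fit_all_conditions(
        E[rownames(E) %in% clean_genes, , drop = FALSE],
        pw$weights[rownames(E) %in% clean_genes, , drop = FALSE], sm)
      eff_locus <- fit_all_conditions(
        E[rownames(E) %in% locus_genes, , drop = FALSE],
        pw$weights[rownames(E) %in% locus_genes, , drop = FALSE], sm)
      imp <- impute_effects(eff_clean, conditions = exp$truth$conditions)
      shr[[fam]] <- multivariate_shrinkage(imp$beta, imp$se)
      impl <- impute_effects(eff_locus, conditions = exp$truth$conditions)
      shr[[paste0(fam, "_locus")]] <- multivariate_shrinkage(impl$beta,
                                                             impl$se)
      eff[[fam]] <- eff_clean
      eff[[paste0(fam, "_locus")]] <- eff_locus
      eff_clean$family <- fam
      emit(eff_clean, sprintf("effects_%s.csv", fam))
    }
    repset <- consensus_replicated_set(shr[[fams[1]]], shr[[fams[2]]],
                                       cfg$lfsr_max)
    emit(repset$per_condition, "replicated_genes.csv")

    say("stage candidates: within-locus scan")
    de_prop <- de_condition_proportion(shr[[paste0(fams[1], "_locus")]],
                                       shr[[paste0(fams[2], "_locus")]],
                                       locus_genes = locus_genes)
    locus_chrom <- exp$truth$locus_interval$chrom
    reporters <- intersect(
      repset$genes,
      exp$annotation$gene[exp$annotation$chrom != locus_chrom])
    cand <- NULL
    if (length(reporters) >= 3 && length(locus_genes)) {
      avail <- intersect(locus_genes, rownames(expr_mats[[fams[1]]]))
      scan <- reporter_correlation_scan(
        expr_mats[[fams[1]]][avail, , drop = FALSE],
        expr_mats[[fams[2]]][avail, , drop = FALSE],
        expr_mats[[fams[1]]][reporters, , drop = FALSE],
        expr_mats[[fams[2]]][reporters, , drop = FALSE],
        samp[[fams[1]]]$genotype, samp[[fams[2]]]$genotype,
        samp[[fams[1]]]$condition, samp[[fams[2]]]$condition)
      cand <- flag_candidates(de_prop, scan$scores,
                              corr_min = cfg$corr_min, de_min = cfg$de_min)
      emit(cand, "candidates.csv")
    }
    results$experiment <- list(sim = exp, classes = cls, blocks = blocks,
                               shrinkage = shr, effects = eff,
                               replicated = repset, candidates = cand)

    if (cfg$stages$enrichment) {
      say("stage enrichment: toy GO universe")
      go <- simulate_go_universe(seed = cfg$seed + 3)
      enr <- hypergeom_enrich(go$foreground, go$background, go$universe,
                              fdr_max = cfg$fdr_max)
      reps <- semantic_collapse(enr[enr$enriched, , drop = FALSE],
                                go$universe,
                                similarity_min = cfg$similarity_min)
      emit(enr, "go_enrichment.csv")
      emit(reps, "go_representatives.csv")
      results$enrichment <- list(enrichment = enr, representatives = reps,
                                 truth = go$truth)
    }
  } else if (cfg$stages$enrichment) {
    stop("stage 'enrichment' requires stage 'experiment'")
  }

  if (cfg$stages$emergence) {
    say("stage emergence: mixed model")
    em <- simulate_emergence(n_per_group = cfg$emergence$n_per_group,
                             genotype_effect_days = cfg$emergence$effect,
                             seed = cfg$seed + 4)
    fit <- fit_emergence(em$data)
    emit(data.frame(term = c("mu", "beta", "se", "var_rep", "var_res",
                             "F", "p"),
                    value = c(fit$mu, fit$beta, fit$se, fit$var_replicate,
                              fit$var_residual, fit$F, fit$p_value)),
         "emergence_fit.csv")
    results$emergence <- list(fit = fit, truth = em$truth)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  outputs <- c(outputs, cfg_path)
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  results$manifest <- manifest
  say("done: %d output files in %s", length(outputs), out_dir)
  invisible(results)
}
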