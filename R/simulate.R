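#' Configuration for the landrace-panel simulator
#'
#' Defaults describe a panel resembling a Mexican landrace collection with
#' a diverged inversion haplotype whose frequency follows a logistic
#' elevation cline: 600 plants, 100 markers inside the locus and 100 in
#' the flanks, a cline centered at 2200 m rising ~0.5% per logit-meter,
#' 30% of locus sites carrying fixed haplotype differences, and 10%
#' missing genotypes.
#'
#' @param n_plants,n_markers_locus,n_markers_flank Positive counts.
#' @param cline_midpoint Elevation (m) where the High-allele frequency is
#'   0.5.
#' @param cline_slope Logit slope per meter of elevation.
#' @param haplotype_divergence Probability that a locus site is a fixed
#'   difference between haplotypes, in [0,1].
#' @param missing_rate Uniform missingness probability in [0,1].
#' @param elevation_range Range (m) plants are drawn from.
#' @param locus_interval list(chrom, start, end) of the inversion.
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @return List of class `panel_config`.
#' @export
panel_config <- function(n_plants = 600, n_markers_locus = 100,
                         n_markers_flank = 100, cline_midpoint = 2200,
                         cline_slope = 0.005, haplotype_divergence = 0.3,
                         missing_rate = 0.1,
                         elevation_range = c(0, 3000),
                         locus_interval = list(chrom = "chr4",
                                               start = 171771502,
                                               end = 185951149),
                         seed = 1L) {
  cfg <- list(n_plants = n_plants, n_markers_locus = n_markers_locus,
              n_markers_flank = n_markers_flank,
              cline_midpoint = cline_midpoint, cline_slope = cline_slope,
              haplotype_divergence = haplotype_divergence,
              missing_rate = missing_rate,
              elevation_range = elevation_range,
              locus_interval = locus_interval, seed = as.integer(seed))
  probs <- c(haplotype_divergence, missing_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]")
  if (any(c(n_plants, n_markers_locus, n_markers_flank) < 1))
    stop("counts must be positive")
  class(cfg) <- "panel_config"
  cfg
}

#' Simulate a landrace panel segregating for a diverged inversion
#'
#' Each plant gets an elevation, a karyotype drawn with
#' P(High allele) = logistic(cline_slope * (elevation - cline_midpoint)),
#' and genotypes at locus and flanking markers. A fraction
#' `haplotype_divergence` of locus sites are fixed differences between the
#' Low and High haplotypes (these carry the karyotype signal); the rest,
#' and all flanking markers, are ordinary cline-independent polymorphisms.
#' Missingness is applied uniformly.
#'
#' @param cfg A [panel_config()].
#' @return List: `gm` (a [genotype_matrix()] with plant metadata including
#'   elevation) and `truth` (per-plant karyotype dosage and the cline
#'   parameters).
#' @export
simulate_landrace_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_plants
    elev <- stats::runif(n, cfg$elevation_range[1], cfg$elevation_range[2])
    p_high <- stats::plogis(cfg$cline_slope * (elev - cfg$cline_midpoint))
    dosage <- stats::rbinom(n, 2, p_high)      # copies of the High haplotype

    m_loc <- cfg$n_markers_locus
    diverged <- stats::runif(m_loc) < cfg$haplotype_divergence
    shared_p <- stats::runif(m_loc, 0.1, 0.9)
    geno_loc <- matrix(0L, n, m_loc)
    for (j in seq_len(m_loc)) {
      if (diverged[j]) {
        geno_loc[, j] <- dosage                # High haplotype carries alt
      } else {
        geno_loc[, j] <- stats::rbinom(n, 2, shared_p[j])
      }
    }
    m_fl <- cfg$n_markers_flank
    flank_p <- stats::runif(m_fl, 0.05, 0.95)
    geno_fl <- vapply(flank_p, function(p) stats::rbinom(n, 2, p),
                      integer(n))
    geno <- cbind(geno_loc, geno_fl)
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA

    li <- cfg$locus_interval
    pos_loc <- sort(round(stats::runif(m_loc, li$start, li$end)))
    span <- li$end - li$start
    pos_fl <- sort(round(stats::runif(m_fl, max(1, li$start - span),
                                      li$start - 1)))
    markers <- data.frame(chrom = li$chrom, pos = c(pos_loc, pos_fl))
    ord <- order(markers$pos)
    markers <- markers[ord, ]
    geno <- geno[, ord, drop = FALSE]
    is_locus <- c(rep(TRUE, m_loc), rep(FALSE, m_fl))[ord]

    plants <- data.frame(id = sprintf("P%04d", seq_len(n)),
                         country = "MX", latitude = NA_real_,
                         longitude = NA_real_, elevation = elev)
    gm <- genotype_matrix(geno, markers, plants)
    truth <- list(karyotype_dosage = stats::setNames(dosage, plants$id),
                  karyotype = c("Low/Low", "Low/High",
                                "High/High")[dosage + 1],
                  cline_midpoint = cfg$cline_midpoint,
                  cline_slope = cfg$cline_slope,
                  locus_markers = markers$pos[is_locus])
    list(gm = gm, truth = truth)
  })
}

#' Simulate two populations with a target windowed-FST profile
#'
#' Balding-Nichols model: for each site, an ancestral frequency is drawn
#' uniformly and each population's frequency is drawn from a Beta with
#' mean equal to the ancestral frequency and variance F*p*(1-p), where F
#' is the target FST at that position; haplotypes are then Bernoulli draws.
#' Under this model the expectation of Hudson's ratio-of-sums FST in a
#' window equals the mean target F across its sites, which is what makes
#' the profile recoverable.
#'
#' @param n_hap_per_pop Haplotypes per population.
#' @param region_bp Region length in bp.
#' @param target_fst_profile Either a function(pos) -> F in [0,1), or a
#'   data.frame with columns start, end, fst.
#' @param site_spacing_bp Average spacing between polymorphic sites
#'   (default 1000).
#' @param seed Integer seed.
#' @return List: `panel1`, `panel2` (haplotype x site 0/1 matrices),
#'   `positions`, `truth` (per-site target F).
#' @export
simulate_divergent_populations <- function(n_hap_per_pop, region_bp,
                                           target_fst_profile,
                                           site_spacing_bp = 1000,
                                           seed = 1L) {
  f_of <- if (is.function(target_fst_profile)) {
    target_fst_profile
  } else {
    prof <- target_fst_profile
    function(pos) {
      i <- findInterval(pos, prof$start)
      ifelse(i >= 1 & pos <= prof$end[pmax(i, 1)], prof$fst[pmax(i, 1)], 0)
    }
  }
  withr::with_seed(seed, {
    n_sites <- max(2, round(region_bp / site_spacing_bp))
    pos <- sort(sample.int(region_bp, n_sites))
    Fv <- f_of(pos)
    if (any(Fv < 0 | Fv >= 1)) stop("target FST must be in [0, 1)")
    p_anc <- stats::runif(n_sites, 0.05, 0.95)
    draw_pop <- function() {
      pf <- p_anc
      bn <- Fv > 0
      a <- p_anc[bn] * (1 - Fv[bn]) / Fv[bn]
      b <- (1 - p_anc[bn]) * (1 - Fv[bn]) / Fv[bn]
      pf[bn] <- stats::rbeta(sum(bn), a, b)
      pf
    }
    p1 <- draw_pop(); p2 <- draw_pop()
    panel1 <- vapply(p1, function(p) stats::rbinom(n_hap_per_pop, 1, p),
                     integer(n_hap_per_pop))
    panel2 <- vapply(p2, function(p) stats::rbinom(n_hap_per_pop, 1, p),
                     integer(n_hap_per_pop))
    list(panel1 = panel1, panel2 = panel2, positions = pos,
         truth = data.frame(pos = pos, target_fst = Fv, p1 = p1, p2 = p2))
  })
}

#' Configuration for the backcross-family expression experiment
#'
#' Defaults emulate the BC5S1 design: two donor families, each segregating
#' for the inversion on chromosome 4 plus residual donor blocks (shared
#' chromosome-4 flanks fully linked to the locus, plus family-private
#' blocks elsewhere); 9 tissues x 2 temperatures x 2 genotypes x 3
#' replicates x 2 batches of negative-binomial counts per family, with
#' planted cis effects on locus/block genes and trans effects on clean
#' genes.
#'
#' @param n_plants_per_family Plants genotyped per family (default 160).
#' @param n_genes Number of annotated genes (default 2000).
#' @param locus_interval list(chrom, start, end).
#' @param residual_blocks Named list (one element per family) of
#'   data.frames with columns chrom, start, end, donor_freq; blocks on the
#'   locus chromosome are treated as fully linked to the locus. Blocks may
#'   not overlap the locus.
#' @param n_tissues,n_temperatures Condition grid (defaults 9 and 2).
#' @param n_reps Biological replicates per batch (default 3; 2 batches are
#'   always generated).
#' @param cis_effect_sd,trans_effect_sd Planted effect SDs (log2 units).
#' @param prop_cis Probability a locus/block gene carries a cis effect.
#' @param prop_trans Probability a clean gene carries a locus-driven trans
#'   effect (shared between families).
#' @param prop_trans_private Probability a clean gene carries a
#'   family-private effect (driven by that family's linked flank).
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param lib_size_range Library size range (reads).
#' @param batch_effect_sd Per-gene batch offset SD (log2).
#' @param n_orphans "Orphan" genes per family whose coordinates are wrong
#'   in the reference (donor SNPs off-block).
#' @param shared_snp_inside,shared_snp_outside Probability a donor SNP
#'   site is shared between the two donors for genes inside / outside the
#'   locus.
#' @param seed Integer seed.
#' @return List of class `family_config`.
#' @export
family_config <- function(n_plants_per_family = 160, n_genes = 2000,
                          locus_interval = list(chrom = "chr4",
                                                start = 20e6, end = 34e6),
                          residual_blocks = NULL,
                          n_tissues = 9, n_temperatures = 2, n_reps = 3,
                          cis_effect_sd = 1.0, trans_effect_sd = 0.6,
                          prop_cis = 0.7, prop_trans = 0.08,
                          prop_trans_private = 0.04,
                          dispersion = 0.1,
                          lib_size_range = c(2e5, 4e5),
                          batch_effect_sd = 0.2, n_orphans = 5,
                          shared_snp_inside = 0.8,
                          shared_snp_outside = 0.4,
                          seed = 1L) {
  if (is.null(residual_blocks)) {
    residual_blocks <- list(
      PT = data.frame(
        chrom = c("chr4", "chr4", "chr5", "chr2"),
        start = c(5e6, 34.2e6, 10e6, 5e6),
        end = c(19.8e6, 48e6, 40e6, 8e6),
        donor_freq = c(0.5, 0.5, 0.5, 0.5)),
      Mi21 = data.frame(
        chrom = c("chr4", "chr4", "chr3"),
        start = c(12e6, 34.2e6, 20e6),
        end = c(19.8e6, 40e6, 50e6),
        donor_freq = c(0.5, 0.5, 0.5)))
  }
  cfg <- list(n_plants_per_family = n_plants_per_family, n_genes = n_genes,
              locus_interval = locus_interval,
              residual_blocks = residual_blocks,
              n_tissues = n_tissues, n_temperatures = n_temperatures,
              n_reps = n_reps, cis_effect_sd = cis_effect_sd,
              trans_effect_sd = trans_effect_sd, prop_cis = prop_cis,
              prop_trans = prop_trans,
              prop_trans_private = prop_trans_private,
              dispersion = dispersion, lib_size_range = lib_size_range,
              batch_effect_sd = batch_effect_sd, n_orphans = n_orphans,
              shared_snp_inside = shared_snp_inside,
              shared_snp_outside = shared_snp_outside,
              seed = as.integer(seed))
  probs <- c(prop_cis, prop_trans, prop_trans_private,
             shared_snp_inside, shared_snp_outside)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]")
  li <- locus_interval
  for (fam in names(residual_blocks)) {
    rb <- residual_blocks[[fam]]
    ov <- rb$chrom == li$chrom & rb$end >= li$start & rb$start <= li$end
    if (any(ov)) stop("residual blocks must not overlap the locus")
  }
  class(cfg) <- "family_config"
  cfg
}

#' Simulate the two-family BC5S1 expression experiment
#'
#' Generates, for two donor families (PT-like and Mi21-like): annotated
#' gene models; per-plant locus genotypes (segregating 1:2:1) and residual
#' block genotypes; negative-binomial RNA-seq counts for homozygous plants
#' across all tissue:temperature conditions, with planted cis effects
#' (shared between families for locus genes, per-block for residual
#' genes), shared locus-driven trans effects, family-private confounder
#' effects, tissue/temperature structure and per-batch offsets; and a
#' per-gene donor SNP table (read-count evidence only inside planted
#' blocks plus a configurable number of relocated "orphan" genes). The
#' `truth` element records every planted effect with sign and magnitude.
#'
#' @param cfg A [family_config()].
#' @return List: `counts` (genes x samples), `samples` (sample table),
#'   `snps` (long SNP table for both families), `annotation` (gene,
#'   chrom, start, end), `truth`.
#' @export
simulate_bc5s1_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "family_config"))
  withr::with_seed(cfg$seed, {
    li <- cfg$locus_interval
    fams <- names(cfg$residual_blocks)

    # ---- gene annotation: 5 chromosomes at transcriptome-like gene density
    chroms <- paste0("chr", 1:5)
    chrom_len <- 6e7
    g_chrom <- sample(chroms, cfg$n_genes, replace = TRUE)
    g_start <- round(stats::runif(cfg$n_genes, 1, chrom_len - 5e3))
    ann <- data.frame(gene = sprintf("G%05d", seq_len(cfg$n_genes)),
                      chrom = g_chrom, start = g_start,
                      end = g_start + 3000, stringsAsFactors = FALSE)
    ann <- ann[order(ann$chrom, ann$start), ]
    ann$gene <- sprintf("G%05d", seq_len(cfg$n_genes))  # ids follow position
    rownames(ann) <- NULL

    in_locus <- ann$chrom == li$chrom & ann$end >= li$start &
      ann$start <= li$end
    gene_block <- lapply(fams, function(fam) {
      rb <- cfg$residual_blocks[[fam]]
      bid <- rep(NA_integer_, nrow(ann))
      for (b in seq_len(nrow(rb))) {
        hit <- ann$chrom == rb$chrom[b] & ann$end >= rb$start[b] &
          ann$start <= rb$end[b] & !in_locus
        bid[hit & is.na(bid)] <- b
      }
      bid
    })
    names(gene_block) <- fams

    # ---- per-family plant genotypes
    plant_geno <- list(); expr_plants <- list()
    for (fam in fams) {
      n <- cfg$n_plants_per_family
      ids <- sprintf("%s_%03d", fam, seq_len(n))
      locus_dos <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                          prob = c(0.25, 0.5, 0.25))
      rb <- cfg$residual_blocks[[fam]]
      block_dos <- matrix(0L, n, nrow(rb))
      for (b in seq_len(nrow(rb))) {
        if (rb$chrom[b] == li$chrom) {
          block_dos[, b] <- locus_dos        # fully linked flank
        } else {
          f <- rb$donor_freq[b]
          block_dos[, b] <- stats::rbinom(n, 2, f)
        }
      }
      plant_geno[[fam]] <- list(ids = ids, locus = locus_dos,
                                blocks = block_dos)
      # pick 6 hom-Low and 6 hom-High plants for the expression experiment
      lows <- ids[locus_dos == 0L][1:6]
      highs <- ids[locus_dos == 2L][1:6]
      expr_plants[[fam]] <- data.frame(
        plant = c(lows, highs), genotype = rep(c(0, 1), each = 6),
        batch = rep(rep(1:2, each = 3), 2), stringsAsFactors = FALSE)
    }

    # ---- planted effects
    tissues <- paste0("T", seq_len(cfg$n_tissues))
    temps <- c("cold", "warm")[seq_len(cfg$n_temperatures)]
    conds <- as.vector(outer(tissues, temps, paste, sep = ":"))

    cis_locus <- rep(0, nrow(ann))
    pick <- in_locus & stats::runif(nrow(ann)) < cfg$prop_cis
    cis_locus[pick] <- stats::rnorm(sum(pick), 0, cfg$cis_effect_sd)

    cis_block <- lapply(fams, function(fam) {
      e <- rep(0, nrow(ann))
      inb <- !is.na(gene_block[[fam]])
      pick <- inb & stats::runif(nrow(ann)) < cfg$prop_cis
      e[pick] <- stats::rnorm(sum(pick), 0, cfg$cis_effect_sd)
      e
    })
    names(cis_block) <- fams

    clean <- !in_locus &
      is.na(gene_block[[1]]) & is.na(gene_block[[2]])
    trans_shared <- rep(0, nrow(ann))
    pick <- clean & stats::runif(nrow(ann)) < cfg$prop_trans
    trans_shared[pick] <- stats::rnorm(sum(pick), 0, cfg$trans_effect_sd)
    trans_private <- lapply(fams, function(fam) {
      e <- rep(0, nrow(ann))
      pick <- clean & trans_shared == 0 &
        stats::runif(nrow(ann)) < cfg$prop_trans_private
      e[pick] <- stats::rnorm(sum(pick), 0, cfg$trans_effect_sd)
      e
    })
    names(trans_private) <- fams

    mu <- stats::rnorm(nrow(ann), 5, 2)                 # log2 CPM baseline
    tissue_eff <- matrix(stats::rnorm(nrow(ann) * cfg$n_tissues, 0, 1),
                         nrow(ann))
    temp_eff <- stats::rnorm(nrow(ann), 0, 0.3)
    batch_eff <- matrix(stats::rnorm(nrow(ann) * 2, 0, cfg$batch_effect_sd),
                        nrow(ann))

    # ---- counts
    all_counts <- list(); all_samples <- list()
    for (fam in fams) {
      ep <- expr_plants[[fam]]
      sm <- expand.grid(plant_i = seq_len(nrow(ep)),
                        tissue = tissues, temp = temps,
                        stringsAsFactors = FALSE)
      sm$plant <- ep$plant[sm$plant_i]
      sm$genotype <- ep$genotype[sm$plant_i]
      sm$batch <- ep$batch[sm$plant_i]
      sm$sample <- sprintf("%s_%s_%s_%s", sm$plant, sm$tissue, sm$temp,
                           sm$batch)
      cnt <- matrix(0L, nrow(ann), nrow(sm),
                    dimnames = list(ann$gene, sm$sample))
      pg <- plant_geno[[fam]]
      bdos <- pg$blocks[match(sm$plant, pg$ids), , drop = FALSE]
      for (s in seq_len(nrow(sm))) {
        ti <- match(sm$tissue[s], tissues)
        tw <- as.numeric(sm$temp[s] == "warm")
        g <- sm$genotype[s]
        lfc <- mu + tissue_eff[, ti] + tw * temp_eff +
          batch_eff[, sm$batch[s]] +
          g * (cis_locus + trans_shared + trans_private[[fam]])
        # block cis effects follow the block dosage of this plant
        bids <- gene_block[[fam]]
        has_b <- !is.na(bids)
        lfc[has_b] <- lfc[has_b] +
          (bdos[s, bids[has_b]] / 2) * cis_block[[fam]][has_b]
        r <- 2^lfc
        lib <- stats::runif(1, cfg$lib_size_range[1], cfg$lib_size_range[2])
        mu_s <- lib * r / sum(r)
        cnt[, s] <- stats::rnbinom(nrow(ann), mu = mu_s,
                                   size = 1 / cfg$dispersion)
      }
      all_counts[[fam]] <- cnt
      all_samples[[fam]] <- data.frame(
        sample = sm$sample, plant = sm$plant, family = fam,
        tissue = sm$tissue, temperature = sm$temp,
        genotype = sm$genotype, batch = sm$batch,
        condition = paste(sm$tissue, sm$temp, sep = ":"),
        stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, all_counts)
    samples <- do.call(rbind, all_samples)
    rownames(samples) <- NULL

    # ---- donor SNP evidence
    snp_rows <- list()
    orphan_genes <- list()
    site_shared <- list()   # per gene: site offsets shared between donors
    for (i in which(in_locus | !is.na(gene_block[[1]]) |
                      !is.na(gene_block[[2]]))) {
      n_sites <- 3 + stats::rpois(1, 4)
      offs <- sort(sample.int(3000, n_sites))
      p_share <- if (in_locus[i]) cfg$shared_snp_inside else
        cfg$shared_snp_outside
      shared <- stats::runif(n_sites) < p_share
      site_shared[[ann$gene[i]]] <- list(
        offs = offs, shared = shared,
        owner = fams[1 + (stats::runif(n_sites) < 0.5)])  # private sites
    }
    for (fam in fams) {
      pg <- plant_geno[[fam]]
      ep <- expr_plants[[fam]]
      use_plants <- ep$plant
      pl_idx <- match(use_plants, pg$ids)
      genes_fam <- which(in_locus | !is.na(gene_block[[fam]]))
      for (i in genes_fam) {
        ss <- site_shared[[ann$gene[i]]]
        offs <- ss$offs[ss$shared | ss$owner == fam]
        if (!length(offs)) next
        dos <- if (in_locus[i]) pg$locus[pl_idx] else
          pg$blocks[pl_idx, gene_block[[fam]][i]]
        for (k in seq_along(offs)) {
          depth <- stats::rpois(length(use_plants) * 2, 12)
          f <- c(0.01, 0.5, 0.99)[rep(dos, each = 2) + 1]
          alt <- stats::rbinom(length(depth), depth, f)
          snp_rows[[length(snp_rows) + 1]] <- data.frame(
            chrom = ann$chrom[i], pos = ann$start[i] + offs[k],
            gene = ann$gene[i],
            plant = rep(use_plants, each = 2),
            sample = paste0(rep(use_plants, each = 2), "_s", 1:2),
            family = fam, ref_count = depth - alt, alt_count = alt,
            fs = abs(stats::rnorm(length(depth), 5, 4)),
            qd = pmax(stats::rnorm(length(depth), 20, 5), 0.1),
            recurrent_hom_ref = TRUE, stringsAsFactors = FALSE)
        }
      }
      # orphan genes: clean genes whose donor copy sits inside a block
      orphan_pool <- which(clean)
      orphans <- sample(orphan_pool, min(cfg$n_orphans, length(orphan_pool)))
      orphan_genes[[fam]] <- ann$gene[orphans]
      for (i in orphans) {
        dos <- pg$locus[pl_idx]       # orphans ride along with the locus
        offs <- sort(sample.int(3000, 3))
        for (k in seq_along(offs)) {
          depth <- stats::rpois(length(use_plants) * 2, 12)
          f <- c(0.01, 0.5, 0.99)[rep(dos, each = 2) + 1]
          alt <- stats::rbinom(length(depth), depth, f)
          snp_rows[[length(snp_rows) + 1]] <- data.frame(
            chrom = ann$chrom[i], pos = ann$start[i] + offs[k],
            gene = ann$gene[i],
            plant = rep(use_plants, each = 2),
            sample = paste0(rep(use_plants, each = 2), "_s", 1:2),
            family = fam, ref_count = depth - alt, alt_count = alt,
            fs = abs(stats::rnorm(length(depth), 5, 4)),
            qd = pmax(stats::rnorm(length(depth), 20, 5), 0.1),
            recurrent_hom_ref = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    snps <- do.call(rbind, snp_rows)

    truth <- list(
      locus_interval = li,
      residual_blocks = cfg$residual_blocks,
      karyotype = lapply(plant_geno, function(p)
        stats::setNames(p$locus, p$ids)),
      cis_locus = stats::setNames(cis_locus, ann$gene),
      cis_block = lapply(cis_block, function(e)
        stats::setNames(e, ann$gene)),
      trans_shared = stats::setNames(trans_shared, ann$gene),
      trans_private = lapply(trans_private, function(e)
        stats::setNames(e, ann$gene)),
      orphan_genes = orphan_genes,
      class = ifelse(in_locus, "locus",
                     ifelse(!is.na(gene_block[[1]]) |
                              !is.na(gene_block[[2]]), "residual", "clean")),
      conditions = conds)
    stopifnot(nrow(counts) == nrow(ann),
              ncol(counts) == nrow(samples))
    list(counts = counts, samples = samples, snps = snps,
         annotation = ann, truth = truth)
  })
}

#' Simulate a toy GO universe with a planted enrichment
#'
#' Builds a random is_a DAG (`dag_depth` levels under a single root per
#' namespace), annotates genes to leaf-ward terms, closes the annotation
#' over ancestors, and draws a foreground gene set in which members of
#' `planted_term` are over-represented `enrichment_fold`-fold relative to
#' other genes.
#'
#' @param n_genes,n_terms Universe sizes.
#' @param dag_depth Levels below the root (default 3).
#' @param planted_term Term id to enrich (default the first level-1 term,
#'   "T0002"); must exist.
#' @param enrichment_fold Sampling weight multiplier for planted-term
#'   genes in the foreground (1 = no enrichment).
#' @param planted_term_size Genes annotated to the planted term
#'   (default 50).
#' @param n_foreground Foreground size (default 100).
#' @param mean_term_size Mean genes per ordinary term (default 20).
#' @param seed Integer seed.
#' @return List: `universe` (a [go_universe()]), `foreground`,
#'   `background`, `truth` (planted term, fold).
#' @export
simulate_go_universe <- function(n_genes = 1000, n_terms = 60,
                                 dag_depth = 3, planted_term = "T0002",
                                 enrichment_fold = 10,
                                 planted_term_size = 50,
                                 n_foreground = 100,
                                 mean_term_size = 20, seed = 1L) {
  withr::with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_terms))
    if (!planted_term %in% ids) stop("planted_term does not exist")
    levels_ <- c(0, 1 + ((seq_len(n_terms - 1) - 1) %% dag_depth))
    levels_ <- sort(levels_)
    parents <- list(); parents[[ids[1]]] <- character()
    for (i in 2:n_terms) {
      pool <- ids[levels_ == levels_[i] - 1]
      if (!length(pool)) pool <- ids[1]
      parents[[ids[i]]] <- unique(sample(pool,
                                         min(length(pool),
                                             1 + (stats::runif(1) < 0.3))))
    }
    genes <- sprintf("g%04d", seq_len(n_genes))
    ann_rows <- list()
    for (i in 2:n_terms) {
      sz <- if (ids[i] == planted_term) planted_term_size else
        max(2, stats::rpois(1, mean_term_size))
      ann_rows[[i]] <- data.frame(gene = sample(genes, min(sz, n_genes)),
                                  term = ids[i], stringsAsFactors = FALSE)
    }
    annotation <- do.call(rbind, ann_rows)
    # every gene gets at least the root
    annotation <- rbind(annotation,
                        data.frame(gene = genes, term = ids[1]))
    terms <- data.frame(id = ids, name = paste("term", ids),
                        namespace = "BP", stringsAsFactors = FALSE)
    uni <- go_universe(terms, parents, annotation)
    in_planted <- genes %in%
      uni$annotation$gene[uni$annotation$term == planted_term]
    w <- ifelse(in_planted, enrichment_fold, 1)
    fg <- sample(genes, n_foreground, prob = w)
    list(universe = uni, foreground = fg, background = genes,
         truth = list(planted_term = planted_term,
                      enrichment_fold = enrichment_fold))
  })
}

#' Simulate a mediation structure for the reporter-correlation scan
#'
#' Generates expression for two families in which one locus gene (the
#' "mediator") causally drives a fraction of the genome-wide reporter
#' genes: reporters load on the mediator's expression noise (beyond the
#' karyotype effect everything in the locus shares), while the other locus
#' genes carry cis effects but no downstream influence. This is the ground
#' truth the reporter-correlation scan is designed to detect.
#'
#' @param n_locus Locus genes (default 20; gene 1, "L001", is the
#'   mediator).
#' @param n_reporters Reporter genes (default 100).
#' @param med_frac Fraction of reporters driven by the mediator
#'   (default 0.3).
#' @param gamma Mediation loading (log2 expression per unit mediator
#'   expression; default 1.0).
#' @param n_tissues,n_temperatures,n_reps Condition grid and replicates
#'   per genotype (defaults 9, 2, 6: three biological replicates in each
#'   of two experimental batches).
#' @param beta_g Karyotype effect SD applied to all genes (default 0.5).
#' @param noise_sd Residual expression SD (default 0.5).
#' @param seed Integer seed.
#' @return List with one element per family ("PT", "Mi21"): `locus_expr`,
#'   `reporter_expr` (genes x samples), `genotype`, `condition`; plus
#'   `truth` (mediator id, driven reporters).
#' @export
simulate_mediator_panel <- function(n_locus = 20, n_reporters = 100,
                                    med_frac = 0.3, gamma = 1.0,
                                    n_tissues = 9, n_temperatures = 2,
                                    n_reps = 6, beta_g = 0.5,
                                    noise_sd = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    conds <- as.vector(outer(paste0("T", seq_len(n_tissues)),
                             c("cold", "warm")[seq_len(n_temperatures)],
                             paste, sep = ":"))
    lgenes <- sprintf("L%03d", seq_len(n_locus))
    rgenes <- sprintf("R%03d", seq_len(n_reporters))
    driven <- stats::runif(n_reporters) < med_frac
    gload <- ifelse(driven, gamma * sample(c(-1, 1), n_reporters, TRUE), 0)
    bL <- stats::rnorm(n_locus, 0, beta_g)
    bR <- stats::rnorm(n_reporters, 0, beta_g)
    out <- list()
    for (fam in c("PT", "Mi21")) {
      g <- rep(rep(c(0, 1), each = n_reps), length(conds))
      cond <- rep(conds, each = 2 * n_reps)
      n <- length(g)
      L <- matrix(stats::rnorm(n_locus * n, 0, noise_sd), n_locus, n,
                  dimnames = list(lgenes, NULL))
      L <- L + outer(bL, g)
      R <- matrix(stats::rnorm(n_reporters * n, 0, noise_sd),
                  n_reporters, n, dimnames = list(rgenes, NULL))
      med_resid <- L[1, ] - bL[1] * g       # mediator beyond karyotype
      R <- R + outer(bR, g) + outer(gload, med_resid)
      colnames(L) <- colnames(R) <- sprintf("%s_s%03d", fam, seq_len(n))
      out[[fam]] <- list(locus_expr = L, reporter_expr = R, genotype = g,
                         condition = cond)
    }
    out$truth <- list(mediator = lgenes[1], driven = rgenes[driven])
    out
  })
}

#' Simulate seedling emergence times
#'
#' y = mu + effect * G + u_replicate + e, with two experimental
#' replicates, equal group sizes per genotype, and the stated standard
#' deviations.
#'
#' @param n_per_group Plants per genotype group (>= 2).
#' @param genotype_effect_days Planted effect of the High genotype (days).
#' @param replicate_effect_sd SD of the replicate random intercept.
#' @param residual_sd Residual SD.
#' @param mu Baseline emergence time (default 9 days, a cold-chamber
#'   figure).
#' @param seed Integer seed.
#' @return List: `data` (plant, genotype 0/1, replicate, emergence),
#'   `truth`.
#' @export
simulate_emergence <- function(n_per_group = 40, genotype_effect_days = -0.75,
                               replicate_effect_sd = 0.3, residual_sd = 1,
                               mu = 9, seed = 1L) {
  stopifnot(n_per_group >= 2)
  withr::with_seed(seed, {
    g <- rep(c(0, 1), each = n_per_group)
    rep_id <- rep(rep(1:2, length.out = n_per_group), 2)
    u <- stats::rnorm(2, 0, replicate_effect_sd)
    y <- mu + genotype_effect_days * g + u[rep_id] +
      stats::rnorm(length(g), 0, residual_sd)
    list(data = data.frame(plant = seq_along(g), genotype = g,
                           replicate = factor(rep_id), emergence = y),
         truth = list(mu = mu, effect = genotype_effect_days,
                      replicate_effects = u))
  })
}
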