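#' Filter RNA-seq variant sites for introgression mapping
#'
#' Site-level quality and segregation filter for SNPs called from RNA-seq
#' reads in backcross (BC5S1) families. A site is retained, within a family,
#' when its Fisher-strand score is below `fs_max`, its quality-by-depth is
#' above `qd_min`, the recurrent parent is homozygous reference, and the
#' family alternate-allele frequency lies strictly inside `freq_band`
#' (segregating sites are expected near 0.25 or 0.5 in a selfed BC5
#' family, so the band removes fixed and artifactual sites).
#'
#' @param tbl SNP table: data.frame with columns chrom, pos, gene, plant,
#'   sample, family, ref_count, alt_count, fs, qd, recurrent_hom_ref
#'   (logical).
#' @param fs_max Retain sites with FS strictly below this (default 30).
#' @param qd_min Retain sites with QD strictly above this (default 2.0).
#' @param freq_band Open interval for the family alternate-allele
#'   frequency (default c(1/8, 7/8)).
#' @return The retained rows of `tbl` (may be empty, with a message).
#' @export
filter_variant_sites <- function(tbl, fs_max = 30, qd_min = 2.0,
                                 freq_band = c(1 / 8, 7 / 8)) {
  need <- c("chrom", "pos", "family", "ref_count", "alt_count", "fs", "qd",
            "recurrent_hom_ref")
  stopifnot(all(need %in% names(tbl)))
  key <- interaction(tbl$chrom, tbl$pos, tbl$family, drop = TRUE)
  alt <- tapply(tbl$alt_count, key, sum)
  tot <- tapply(tbl$ref_count + tbl$alt_count, key, sum)
  freq <- alt / pmax(tot, 1)
  freq_ok <- freq > freq_band[1] & freq < freq_band[2]
  keep <- tbl$fs < fs_max & tbl$qd > qd_min & tbl$recurrent_hom_ref &
    freq_ok[as.character(key)]
  out <- tbl[keep & !is.na(keep), , drop = FALSE]
  if (nrow(out) == 0) message("filter_variant_sites: no sites retained")
  rownames(out) <- NULL
  out
}

#' Pool read counts per plant and call site genotypes
#'
#' Sums reference/alternate read counts across all RNA-seq samples of each
#' plant at each site, then computes genotype posteriors from binomial
#' likelihoods at expected alternate-read fractions {eps, 1/2, 1 - eps}
#' (hom-recurrent, het, hom-donor) under a flat prior. Pooling counts first
#' is equivalent to multiplying per-sample binomial likelihoods.
#'
#' @param tbl (Filtered) SNP table; see [filter_variant_sites()].
#' @param eps Sequencing/mapping error rate (default 0.01).
#' @return data.frame with one row per plant x site: chrom, pos, gene,
#'   plant, family, ref_count, alt_count, post_rr, post_het, post_dd and the
#'   MAP `call` in {"hom_recurrent","het","hom_donor","unknown"}.
#' @export
call_plant_genotypes <- function(tbl, eps = 0.01) {
  key <- interaction(tbl$chrom, tbl$pos, tbl$plant, drop = TRUE)
  agg <- data.frame(
    chrom = tapply(tbl$chrom, key, `[`, 1),
    pos = as.numeric(tapply(tbl$pos, key, `[`, 1)),
    gene = tapply(as.character(tbl$gene), key, `[`, 1),
    plant = tapply(as.character(tbl$plant), key, `[`, 1),
    family = tapply(as.character(tbl$family), key, `[`, 1),
    ref_count = as.numeric(tapply(tbl$ref_count, key, sum)),
    alt_count = as.numeric(tapply(tbl$alt_count, key, sum)),
    stringsAsFactors = FALSE)
  n <- agg$ref_count + agg$alt_count
  f <- c(eps, 0.5, 1 - eps)
  ll <- vapply(f, function(p) stats::dbinom(agg$alt_count, n, p, log = TRUE),
               numeric(nrow(agg)))
  ll <- matrix(ll, nrow = nrow(agg))
  ll <- ll - apply(ll, 1, max)
  post <- exp(ll) / rowSums(exp(ll))
  call <- c("hom_recurrent", "het", "hom_donor")[max.col(post, "first")]
  call[n == 0] <- "unknown"
  agg$post_rr <- post[, 1]; agg$post_het <- post[, 2]; agg$post_dd <- post[, 3]
  agg$call <- call
  agg <- agg[order(agg$plant, agg$chrom, agg$pos), ]
  rownames(agg) <- NULL
  agg
}

#' Detect residual introgression blocks from variant density
#'
#' Tiles each chromosome into `density_window_bp` windows, counts filtered
#' variant sites per window, and flags windows whose density exceeds a
#' data-driven threshold: `density_mult` times the family's genome-wide
#' median window density (zeros included; robust to sequencing depth), with
#' a floor of `min_sites`. Flagged windows separated by at most
#' `gap_windows` quiet windows are merged into blocks, trimmed to the
#' outermost sites they contain; blocks with fewer than `min_block_sites`
#' sites are dropped (this keeps isolated relocated "orphan" genes from
#' masquerading as blocks). Optionally, per-plant genotype calls inside
#' each block are smoothed along sites with a 3-state chain (see
#' [hmm_smooth_calls()]).
#'
#' @param sites Unique filtered site table (one row per chrom x pos x
#'   family), e.g. `unique(filtered[c("chrom","pos","family")])`.
#' @param density_window_bp Window size for the density profile (default 1e6).
#' @param min_sites Minimum sites per window for a window to be flagged
#'   (default 5).
#' @param density_mult Multiple of the genome-wide median density required
#'   (default 5).
#' @param gap_windows Maximum quiet windows bridged when merging
#'   (default 1).
#' @param min_block_sites Minimum sites for a merged block to be reported
#'   (default 10).
#' @param genome_size_bp Optional total genome length; when given, windows
#'   of the genome that carry no sites at all enter the background median
#'   (recommended -- without it, a genome dominated by large blocks can
#'   inflate the background estimate).
#' @param genotypes Optional output of [call_plant_genotypes()]; when given,
#'   per-plant smoothed block genotypes are attached.
#' @param error_prob,switch_prob Smoothing parameters passed to
#'   [hmm_smooth_calls()].
#' @return List of class `introgression_blocks`: `blocks` data.frame
#'   (family, chrom, start, end, n_sites) and, when `genotypes` is supplied,
#'   `plant_calls` (family, block, plant, genotype, posterior).
#' @export
detect_introgression_blocks <- function(sites, density_window_bp = 1e6,
                                        min_sites = 5, density_mult = 5,
                                        gap_windows = 1,
                                        min_block_sites = 10,
                                        genome_size_bp = NULL,
                                        genotypes = NULL,
                                        error_prob = 0.2,
                                        switch_prob = 1e-6) {
  blocks <- list()
  for (fam in unique(sites$family)) {
    sf <- sites[sites$family == fam, ]
    # genome-wide median window density for this family (zeros included;
    # when the genome size is known, windows without any site count too)
    counts_all <- unlist(lapply(split(sf$pos, sf$chrom), function(pos) {
      win <- floor((pos - 1) / density_window_bp)
      tabulate(factor(win, levels = 0:max(win)), nbins = max(win) + 1)
    }))
    if (!is.null(genome_size_bp)) {
      n_windows <- ceiling(genome_size_bp / density_window_bp)
      counts_all <- c(counts_all,
                      rep(0L, max(0, n_windows - length(counts_all))))
    }
    thresh <- max(density_mult * stats::median(counts_all), min_sites)
    for (ch in unique(sf$chrom)) {
      pos <- sort(sf$pos[sf$chrom == ch])
      win <- floor((pos - 1) / density_window_bp)
      full <- seq(0, max(win))
      cnt <- tabulate(factor(win, levels = full), nbins = length(full))
      hot <- cnt >= thresh
      if (!any(hot)) next
      # bridge short gaps between flagged windows
      if (gap_windows > 0) {
        hi <- which(hot)
        for (k in seq_len(length(hi) - 1)) {
          if (hi[k + 1] - hi[k] - 1 <= gap_windows)
            hot[hi[k]:hi[k + 1]] <- TRUE
        }
      }
      r <- rle(hot)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        w0 <- full[starts[k]]; w1 <- full[ends[k]]
        lo <- w0 * density_window_bp + 1; hi <- (w1 + 1) * density_window_bp
        inb <- pos >= lo & pos <= hi
        if (sum(inb) < min_block_sites) next
        blocks[[length(blocks) + 1]] <- data.frame(
          family = fam, chrom = ch, start = min(pos[inb]),
          end = max(pos[inb]), n_sites = sum(inb),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(blocks) == 0) {
    warning("no introgression blocks found")
    blocks <- data.frame(family = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         n_sites = integer())
  } else blocks <- do.call(rbind, blocks)
  if (nrow(blocks)) {
    blocks$block_id <- paste0(blocks$family, "_", blocks$chrom, "_",
                              seq_len(nrow(blocks)))
  } else blocks$block_id <- character()

  plant_calls <- NULL
  if (!is.null(genotypes) && nrow(blocks)) {
    out <- list()
    for (b in seq_len(nrow(blocks))) {
      g <- genotypes[genotypes$family == blocks$family[b] &
                       genotypes$chrom == blocks$chrom[b] &
                       genotypes$pos >= blocks$start[b] &
                       genotypes$pos <= blocks$end[b], ]
      for (pl in unique(g$plant)) {
        gp <- g[g$plant == pl, ]
        gp <- gp[order(gp$pos), ]
        lik <- as.matrix(gp[, c("post_rr", "post_het", "post_dd")])
        sm <- hmm_smooth_calls(lik, error_prob = error_prob,
                               switch_prob = switch_prob)
        maj <- c("hom_recurrent", "het", "hom_donor")[
          which.max(tabulate(max.col(sm, "first"), 3))]
        out[[length(out) + 1]] <- data.frame(
          family = blocks$family[b], block = blocks$block_id[b], plant = pl,
          genotype = maj, posterior = mean(apply(sm, 1, max)),
          stringsAsFactors = FALSE)
      }
    }
    plant_calls <- do.call(rbind, out)
  }
  structure(list(blocks = blocks, plant_calls = plant_calls),
            class = "introgression_blocks")
}

#' Smooth per-site genotype evidence with a 3-state chain
#'
#' Forward-backward smoothing of per-site genotype likelihoods along a
#' block. The hidden state is the true genotype in {hom-recurrent, het,
#' hom-donor}; emissions mix the site likelihood with a genotyping error
#' rate (`error_prob` mass spread over the other two states), and
#' transitions allow a small per-site switch probability -- recombination
#' within a residual block of a BC5S1 plant is essentially negligible, so
#' the chain mostly votes across sites.
#'
#' @param lik sites x 3 matrix of per-site genotype likelihoods (rows need
#'   not be normalized).
#' @param error_prob Probability that a site's evidence points to a wrong
#'   state (default 0.2).
#' @param switch_prob Per-site state switch probability (default 1e-6).
#' @return sites x 3 matrix of smoothed posterior state probabilities.
#' @export
hmm_smooth_calls <- function(lik, error_prob = 0.2, switch_prob = 1e-6) {
  lik <- as.matrix(lik)
  stopifnot(ncol(lik) == 3)
  n <- nrow(lik)
  emis <- (1 - error_prob) * lik +
    (error_prob / 2) * (rowSums(lik) - lik)
  trans <- matrix(switch_prob / 2, 3, 3)
  diag(trans) <- 1 - switch_prob
  fwd <- matrix(0, n, 3); bwd <- matrix(0, n, 3)
  f <- emis[1, ] / 3
  fwd[1, ] <- f / sum(f)
  if (n > 1) {
    for (i in 2:n) {
      f <- (fwd[i - 1, ] %*% trans) * emis[i, ]
      fwd[i, ] <- f / sum(f)
    }
  }
  bwd[n, ] <- 1
  if (n > 1) {
    for (i in (n - 1):1) {
      b <- trans %*% (emis[i + 1, ] * bwd[i + 1, ])
      bwd[i, ] <- b / sum(b)
    }
  }
  post <- fwd * bwd
  post / rowSums(post)
}

#' Classify genes into clean / locus / residual regions
#'
#' Partitions annotated genes by position: genes overlapping the inversion
#' interval are class `locus`; genes overlapping any residual introgression
#' block, or "orphan" genes carrying at least `orphan_min_snps` filtered
#' SNPs outside all blocks (genes whose coordinates likely differ between
#' donor and reference genomes), are class `residual`; genes without
#' coordinates are `unknown`; everything else is `clean`. Orphan genes get
#' a donor genotype per plant by majority vote over their variant loci
#' (ties -> "unknown"). When per-plant genotypes and a locus karyotype
#' vector are supplied, a per-residual-gene correlation `rho` between gene
#' donor dosage and karyotype dosage is reported.
#'
#' @param annotation data.frame with columns gene, chrom, start, end
#'   (NA coordinates allowed).
#' @param blocks `introgression_blocks` object or its `blocks` data.frame.
#' @param locus_interval list(chrom, start, end) of the inversion.
#' @param genotypes Optional [call_plant_genotypes()] output used for the
#'   orphan rule and for `rho`.
#' @param orphan_min_snps Minimum off-block SNPs for the orphan rule
#'   (default 2).
#' @param karyotype Optional named numeric vector (plant -> dosage 0/1/2)
#'   for computing `rho`.
#' @return data.frame of class `region_classification`: gene, class, block,
#'   rho.
#' @export
classify_genes <- function(annotation, blocks, locus_interval,
                           genotypes = NULL, orphan_min_snps = 2,
                           karyotype = NULL) {
  if (inherits(blocks, "introgression_blocks")) blocks <- blocks$blocks
  ann <- annotation
  cls <- rep("clean", nrow(ann))
  blk <- rep(NA_character_, nrow(ann))
  no_coord <- is.na(ann$chrom) | is.na(ann$start) | is.na(ann$end)
  if (any(no_coord)) message(sprintf(
    "classify_genes: %d gene(s) without coordinates -> unknown",
    sum(no_coord)))
  cls[no_coord] <- "unknown"
  in_locus <- !no_coord & ann$chrom == locus_interval$chrom &
    ann$end >= locus_interval$start & ann$start <= locus_interval$end
  cls[in_locus] <- "locus"
  if (nrow(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      hit <- !no_coord & !in_locus & ann$chrom == blocks$chrom[b] &
        ann$end >= blocks$start[b] & ann$start <= blocks$end[b]
      cls[hit & cls == "clean"] <- "residual"
      blk[hit & is.na(blk)] <- blocks$block_id[b]
    }
  }
  # orphan rule: off-block genes with enough donor SNP evidence
  if (!is.null(genotypes)) {
    g <- genotypes
    offblock <- rep(TRUE, nrow(g))
    if (nrow(blocks)) {
      for (b in seq_len(nrow(blocks))) {
        offblock <- offblock & !(g$chrom == blocks$chrom[b] &
                                   g$pos >= blocks$start[b] &
                                   g$pos <= blocks$end[b])
      }
    }
    offblock <- offblock & !(g$chrom == locus_interval$chrom &
                               g$pos >= locus_interval$start &
                               g$pos <= locus_interval$end)
    snps_per_gene <- tapply(paste(g$chrom, g$pos)[offblock],
                            g$gene[offblock],
                            function(x) length(unique(x)))
    orphan <- names(snps_per_gene)[snps_per_gene >= orphan_min_snps]
    is_orph <- ann$gene %in% orphan & cls == "clean"
    cls[is_orph] <- "residual"
    blk[is_orph] <- "orphan"
  }
  rho <- rep(NA_real_, nrow(ann))
  if (!is.null(genotypes) && !is.null(karyotype)) {
    dosage <- c(hom_recurrent = 0, het = 1, hom_donor = 2,
                unknown = NA_real_)
    for (i in which(cls == "residual")) {
      gg <- genotypes[genotypes$gene == ann$gene[i], ]
      if (nrow(gg) == 0) next
      d <- tapply(dosage[gg$call], gg$plant, function(z)
        stats::median(z, na.rm = TRUE))
      k <- karyotype[names(d)]
      if (sum(stats::complete.cases(d, k)) >= 3 &&
          stats::sd(d, na.rm = TRUE) > 0 && stats::sd(k, na.rm = TRUE) > 0)
        rho[i] <- stats::cor(d, k, use = "complete.obs")
    }
  }
  out <- data.frame(gene = ann$gene, class = cls, block = blk, rho = rho,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_classification", "data.frame")
  out
}
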