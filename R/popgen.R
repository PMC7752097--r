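#' Per-site diversity and differentiation statistics for two populations
#'
#' Computes, for every polymorphic site shared by two haplotype panels:
#' within-population nucleotide diversity `pi` (unbiased per-site
#' heterozygosity, 2*p*q*n/(n-1)), between-population diversity `dxy`
#' (p1*(1-p2) + p2*(1-p1)), and the per-site numerator and denominator of
#' Hudson's FST estimator with sample-size correction
#' (Bhatia et al.'s "estimator of choice" for two populations):
#' numerator = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' denominator = dxy. Sites with fewer than two sampled alleles in either
#' population are skipped (recorded in the `skipped` attribute).
#'
#' @param panel1,panel2 haplotypes x sites binary (0/1) matrices, NA allowed;
#'   both panels must cover the same sites in the same order.
#' @param positions 1-based bp positions of the sites (default: column index).
#' @return data.frame with columns pos, n1, n2, p1, p2, pi1, pi2, dxy,
#'   fst_num, fst_den; attribute `skipped` holds dropped positions.
#' @export
site_statistics <- function(panel1, panel2, positions = NULL) {
  panel1 <- as.matrix(panel1); panel2 <- as.matrix(panel2)
  stopifnot(ncol(panel1) == ncol(panel2))
  if (is.null(positions)) positions <- seq_len(ncol(panel1))
  stopifnot(length(positions) == ncol(panel1), !is.unsorted(positions))

  n1 <- colSums(!is.na(panel1)); n2 <- colSums(!is.na(panel2))
  ok <- n1 >= 2 & n2 >= 2
  skipped <- positions[!ok]
  if (length(skipped))
    message(sprintf("site_statistics: skipped %d site(s) with < 2 alleles",
                    length(skipped)))
  p1 <- colMeans(panel1, na.rm = TRUE)[ok]
  p2 <- colMeans(panel2, na.rm = TRUE)[ok]
  n1 <- n1[ok]; n2 <- n2[ok]
  pi1 <- 2 * p1 * (1 - p1) * n1 / (n1 - 1)
  pi2 <- 2 * p2 * (1 - p2) * n2 / (n2 - 1)
  dxy <- p1 * (1 - p2) + p2 * (1 - p1)
  fst_num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  out <- data.frame(pos = positions[ok], n1 = n1, n2 = n2, p1 = p1, p2 = p2,
                    pi1 = pi1, pi2 = pi2, dxy = dxy,
                    fst_num = fst_num, fst_den = dxy)
  attr(out, "skipped") <- skipped
  out
}

#' Sliding-window summaries of per-site statistics
#'
#' Aggregates [site_statistics()] output into sliding windows (default 1 Mb
#' advancing by 100 kb). Window FST is the ratio of sums (sum of per-site
#' numerators over sum of denominators), which is far less biased than
#' averaging per-site ratios; pi and dxy are means over sites with data.
#' Windows are anchored at `region_start` and emitted even when empty
#' (`n_sites = 0`, statistics `NA`). Coordinates are half-open internally
#' and reported 1-based inclusive (`start`, `end`).
#'
#' @param sites data.frame from [site_statistics()].
#' @param window_bp,step_bp Window and step size in bp (step must not exceed
#'   window).
#' @param region_start,region_end Window anchoring; defaults cover the sites.
#' @param chrom Chromosome label carried into the output.
#' @return data.frame with chrom, start, end, n_sites, pi1, pi2, dxy, fst.
#' @export
windowed_stats <- function(sites, window_bp = 1e6, step_bp = 1e5,
                           region_start = 1, region_end = NULL,
                           chrom = "chr") {
  if (step_bp > window_bp) stop("step_bp must not exceed window_bp")
  if (is.null(region_end)) region_end <- max(sites$pos)
  starts <- seq(region_start, max(region_start, region_end - 1), by = step_bp)
  res <- lapply(starts, function(s) {
    e <- s + window_bp            # half-open [s, e)
    idx <- sites$pos >= s & sites$pos < e
    k <- sum(idx)
    if (k == 0)
      return(data.frame(chrom = chrom, start = s, end = e - 1, n_sites = 0L,
                        pi1 = NA_real_, pi2 = NA_real_, dxy = NA_real_,
                        fst = NA_real_))
    den <- sum(sites$fst_den[idx])
    data.frame(chrom = chrom, start = s, end = e - 1, n_sites = k,
               pi1 = mean(sites$pi1[idx]), pi2 = mean(sites$pi2[idx]),
               dxy = mean(sites$dxy[idx]),
               fst = if (den > 0) sum(sites$fst_num[idx]) / den else NA_real_)
  })
  do.call(rbind, res)
}
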