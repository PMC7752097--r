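#' Construct a plants x markers genotype matrix
#'
#' Container for integer-coded genotypes (0 = hom reference, 1 = het,
#' 2 = hom alternate, NA = missing) with marker coordinates and plant
#' metadata. Markers must be position-sorted within chromosome.
#'
#' @param geno plants x markers integer matrix with values in {0,1,2,NA}.
#' @param markers data.frame with columns `chrom` and `pos` (1-based bp),
#'   one row per marker column.
#' @param plants data.frame with at least a column `id`; typically also
#'   `country`, `latitude`, `longitude` and `elevation` (m).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, markers, plants) {
  geno <- as.matrix(geno)
  stopifnot(nrow(markers) == ncol(geno), nrow(plants) == nrow(geno))
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p)) stop("marker positions must be sorted within chromosome")
  }
  structure(list(geno = geno, markers = as.data.frame(markers),
                 plants = as.data.frame(plants)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d plants x %d markers (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Filter markers by region, missingness and minor allele frequency
#'
#' Keeps markers inside `region` with less than `max_missing` missing data
#' and minor allele frequency above `min_maf`. The plant set is unchanged.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction per marker
#'   (strictly-less-than; default 0.25).
#' @param min_maf Minimum minor allele frequency (strictly-greater-than;
#'   default 0.05), computed from non-missing calls.
#' @param region Optional list with `chrom`, `start`, `end` (1-based,
#'   inclusive); `NULL` keeps all chromosomes.
#' @return A filtered `genotype_matrix`.
#' @export
filter_markers <- function(gm, max_missing = 0.25, min_maf = 0.05,
                           region = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- rep(TRUE, ncol(gm$geno))
  if (!is.null(region)) {
    keep <- gm$markers$chrom == region$chrom &
      gm$markers$pos >= region$start & gm$markers$pos <= region$end
    if (!any(keep)) stop("insufficient markers: region overlaps no markers")
  }
  miss <- colMeans(is.na(gm$geno))
  p <- colMeans(gm$geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- keep & miss < max_missing & maf > min_maf
  if (!any(keep)) stop("insufficient markers: no marker passes the filters")
  genotype_matrix(gm$geno[, keep, drop = FALSE],
                  gm$markers[keep, , drop = FALSE], gm$plants)
}

#' Call per-plant inversion karyotypes by PCA clustering
#'
#' Runs a mean-imputed, centered principal components analysis on the locus
#' markers and partitions PC1 scores into three groups with exact
#' one-dimensional 3-means (a deterministic search over contiguous
#' partitions of the sorted scores, so no clustering local optima). Because
#' recombination is suppressed across the locus, the two
#' haplotype classes and their heterozygotes separate into three PC1
#' clusters; the minor homozygote cluster (fewer plants) is labeled
#' `High/High`, the middle cluster `Low/High`, the major extreme `Low/Low`.
#'
#' @param gm A [genotype_matrix()] already restricted to the locus.
#' @param min_gap Minimum separation between adjacent clusters, as a
#'   fraction of the PC1 score range, for the locus to count as
#'   structured (default 0.05). On unstructured data the optimal 3-way
#'   split of PC1 scores leaves essentially no gap between clusters
#'   (relative gaps around 0.002), while a genuine karyotype signal
#'   leaves a wide corridor (around 0.3), so this criterion separates the
#'   two regimes by two orders of magnitude.
#' @return A list of class `inversion_calls`: `calls` data.frame (plant
#'   `id`, `pc1`, `karyotype`, `confidence`), `pc1_var_explained`,
#'   `cluster_means` (sorted), `silhouette`, `rel_gap`.
#' @export
call_inversion_genotypes <- function(gm, min_gap = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  X <- gm$geno
  if (nrow(X) < 3 || ncol(X) < 2)
    stop("need at least 3 plants and 2 markers")
  # mean imputation and centering
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
  X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < 1e-12)) stop("no karyotype structure: all plants identical")
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  s <- pc$x[, 1]
  var_expl <- pc$sdev[1]^2 / sum(pc$sdev^2)

  grp <- kmeans1d_exact(s, 3)  # 1 = lowest mean, 3 = highest

  sil <- silhouette_1d(s, grp)
  gap12 <- min(s[grp == 2]) - max(s[grp == 1])
  gap23 <- min(s[grp == 3]) - max(s[grp == 2])
  rel_gap <- min(gap12, gap23) / (max(s) - min(s))
  if (length(unique(grp)) < 3 || !is.finite(rel_gap) || rel_gap < min_gap)
    stop("no karyotype structure: PC1 scores do not form three clusters")

  # minor-allele convention: the smaller extreme cluster is High/High
  n_lo <- sum(grp == 1); n_hi <- sum(grp == 3)
  labels <- if (n_hi <= n_lo) {
    c("Low/Low", "Low/High", "High/High")
  } else {
    c("High/High", "Low/High", "Low/Low")
  }
  karyo <- labels[grp]

  mu <- as.vector(tapply(s, grp, mean))
  d <- abs(outer(s, mu, "-"))
  d_sorted <- t(apply(d, 1, sort))
  confidence <- d_sorted[, 2] / (d_sorted[, 1] + d_sorted[, 2])

  structure(list(
    calls = data.frame(id = gm$plants$id, pc1 = s, karyotype = karyo,
                       confidence = confidence, stringsAsFactors = FALSE),
    pc1_var_explained = var_expl,
    cluster_means = mu,
    silhouette = sil, rel_gap = rel_gap), class = "inversion_calls")
}

# exact k-means for 1-D data with k = 3: minimizes within-cluster sum of
# squares over all contiguous 3-way partitions of the sorted scores.
# Deterministic and globally optimal, unlike Lloyd iterations from a fixed
# start. Returns group index (1 = lowest mean) per observation.
kmeans1d_exact <- function(x, k = 3) {
  stopifnot(k == 3)
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  seg_ss <- function(i, j) {           # within-SS of xs[i..j], vectorized
    s <- cs[j] - ifelse(i > 1, cs[i - 1], 0)
    s2 <- cs2[j] - ifelse(i > 1, cs2[i - 1], 0)
    s2 - s^2 / (j - i + 1)
  }
  best <- Inf; bi <- 1L; bj <- 2L
  for (i in 1:(n - 2)) {               # cluster 1 = 1..i
    j <- (i + 1):(n - 1)               # cluster 2 = (i+1)..j, 3 = rest
    tot <- seg_ss(1, i) + seg_ss(i + 1, j) + seg_ss(j + 1, n)
    m <- which.min(tot)
    if (tot[m] < best) { best <- tot[m]; bi <- i; bj <- j[m] }
  }
  grp <- integer(n)
  grp[ord[1:bi]] <- 1L
  grp[ord[(bi + 1):bj]] <- 2L
  grp[ord[(bj + 1):n]] <- 3L
  grp
}

# mean silhouette width for a 1-D clustering
silhouette_1d <- function(x, grp) {
  ks <- sort(unique(grp))
  if (length(ks) < 2) return(NA_real_)
  sil <- numeric(length(x))
  for (i in seq_along(x)) {
    own <- grp[i]
    a <- mean(abs(x[i] - x[grp == own & seq_along(x) != i]))
    if (is.nan(a)) a <- 0
    b <- min(vapply(ks[ks != own],
                    function(k) mean(abs(x[i] - x[grp == k])), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}

#' Fit an elevation cline to High-allele frequencies
#'
#' Bins plants by elevation, computes the frequency of the High allele per
#' bin as (2 n_HH + n_LH) / (2 n_bin), drops bins with fewer than
#' `min_bin_n` plants, and fits a locally weighted regression to the
#' transformed frequencies against bin midpoints, weighted by bin size.
#' Predictions and pointwise +/- 2 SE bands are back-transformed to the
#' frequency scale.
#'
#' @param calls An `inversion_calls` object or a character vector of
#'   karyotypes in {"Low/Low","Low/High","High/High"}.
#' @param elevations Numeric elevations (m), one per plant.
#' @param bin_width Elevation bin width in meters (default 100).
#' @param min_bin_n Minimum plants per bin for the bin to enter the fit
#'   (default 10).
#' @param transform "logit" (default) or "log"; frequencies at 0 or 1 get a
#'   half-count continuity adjustment before transforming.
#' @param span,degree Loess span and degree.
#' @return List of class `cline_fit`: `bins` data.frame (midpoint, n, freq,
#'   used), `fit` data.frame (midpoint, freq, lower, upper) for the
#'   qualifying bins, plus the fitted loess object.
#' @export
elevation_cline <- function(calls, elevations, bin_width = 100,
                            min_bin_n = 10, transform = c("logit", "log"),
                            span = 0.75, degree = 2) {
  transform <- match.arg(transform)
  karyo <- if (inherits(calls, "inversion_calls")) calls$calls$karyotype else calls
  stopifnot(length(karyo) == length(elevations), all(is.finite(elevations)))
  bin <- floor(elevations / bin_width)
  tab <- split(karyo, bin)
  mids <- (as.numeric(names(tab)) + 0.5) * bin_width
  n <- vapply(tab, length, integer(1))
  high_alleles <- vapply(tab, function(k)
    2L * sum(k == "High/High") + sum(k == "Low/High"), integer(1))
  freq <- high_alleles / (2 * n)
  used <- n >= min_bin_n
  if (sum(used) < 3) stop("fewer than 3 elevation bins pass min_bin_n")

  cnt <- high_alleles[used]; tot <- 2 * n[used]
  adj <- cnt == 0 | cnt == tot
  f_adj <- ifelse(adj, (cnt + 0.5) / (tot + 1), cnt / tot)
  y <- if (transform == "logit") stats::qlogis(f_adj) else log(f_adj)
  df <- data.frame(mid = mids[used], y = y, w = n[used])
  lo <- stats::loess(y ~ mid, data = df, weights = df$w, span = span,
                     degree = degree,
                     control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(lo, newdata = df, se = TRUE)
  inv <- if (transform == "logit") stats::plogis else exp
  fit <- data.frame(midpoint = df$mid,
                    freq = inv(pr$fit),
                    lower = inv(pr$fit - 2 * pr$se.fit),
                    upper = inv(pr$fit + 2 * pr$se.fit))
  structure(list(
    bins = data.frame(midpoint = mids, n = n, freq = freq, used = used),
    fit = fit, loess = lo, transform = transform), class = "cline_fit")
}
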