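#' Exact Hardy-Weinberg test with heterozygote-deficit statistic D
#'
#' Tests observed genotype counts at a biallelic locus against Hardy-Weinberg
#' proportions using the Levene-Haldane exact distribution of the heterozygote
#' count conditional on the allele counts. The disequilibrium statistic D is
#' half the difference between observed and expected heterozygote counts, so
#' negative D indicates a heterozygote deficit (as expected for a locus with
#' assortative mating or population structure, e.g. an inversion segregating
#' along a cline).
#'
#' The two-sided p-value sums the conditional probabilities of all heterozygote
#' counts whose probability does not exceed that of the observed count
#' ("equally or less likely" convention). All factorials are evaluated in log
#' space so the test is stable for thousands of plants.
#'
#' @param n_AA,n_AB,n_BB Nonnegative integer genotype counts (hom-ref, het,
#'   hom-alt).
#' @return An object of class `hwe_result`: a list with `counts`, `n`, `p_hat`
#'   (sample frequency of the A allele), `expected_het`, `D` (count scale),
#'   and `p_value`.
#' @examples
#' hwe_exact_test(42, 78, 45)
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  counts <- c(n_AA, n_AB, n_BB)
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one individual required")
  n_A <- 2L * n_AA + n_AB
  n_B <- 2L * n_BB + n_AB
  p_hat <- n_A / (2 * n)
  expected_het <- 2 * n * p_hat * (1 - p_hat)
  D <- (n_AB - expected_het) / 2

  if (n_A == 0L || n_B == 0L) {
    # monomorphic: HWE trivially satisfied
    res <- list(counts = counts, n = n, p_hat = p_hat,
                expected_het = expected_het, D = 0, p_value = 1)
    class(res) <- "hwe_result"
    return(res)
  }

  dist <- hwe_het_distribution(n_A, n_B)
  obs_pr <- dist$prob[dist$het == n_AB]
  # sum outcomes no more likely than the observed one; small relative slack
  # guards against ties lost to floating point
  p_value <- min(1, sum(dist$prob[dist$prob <= obs_pr * (1 + 1e-12)]))

  res <- list(counts = counts, n = n, p_hat = p_hat,
              expected_het = expected_het, D = D, p_value = p_value)
  class(res) <- "hwe_result"
  res
}

#' Conditional distribution of the heterozygote count given allele counts
#'
#' Levene-Haldane distribution: P(het = h | n_A, n_B) over all h compatible
#' with the allele counts (same parity as n_A, 0 <= h <= min(n_A, n_B)).
#' Exposed mainly so the enumeration can be checked to sum to one.
#'
#' @param n_A,n_B Allele counts (n_A + n_B must be even).
#' @return data.frame with columns `het` and `prob`.
#' @export
hwe_het_distribution <- function(n_A, n_B) {
  stopifnot(n_A >= 0, n_B >= 0, (n_A + n_B) %% 2 == 0)
  n <- (n_A + n_B) / 2
  hs <- seq.int(n_A %% 2L, min(n_A, n_B), by = 2L)
  logp <- lfactorial(n) - lfactorial((n_A - hs) / 2) - lfactorial(hs) -
    lfactorial((n_B - hs) / 2) + hs * log(2) +
    lfactorial(n_A) + lfactorial(n_B) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  data.frame(het = hs, prob = pr)
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("Exact Hardy-Weinberg test (n = %d)\n", x$n))
  cat(sprintf("  counts (AA/AB/BB): %d / %d / %d\n",
              x$counts[1], x$counts[2], x$counts[3]))
  cat(sprintf("  p_hat = %.4f, expected het = %.2f\n", x$p_hat, x$expected_het))
  cat(sprintf("  D = %.4f, p = %.4g\n", x$D, x$p_value))
  invisible(x)
}
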