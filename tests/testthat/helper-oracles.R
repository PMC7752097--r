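# Independent oracles used across the suite. These re-derive quantities by
# brute force or from the defining formulas, staying independent of the
# package code paths they check.

# normal-equations weighted least squares
wls_oracle <- function(y, w, X) {
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * res^2) / df
  se <- unname(sqrt(sigma2 * diag(solve(XtWX))))
  list(beta = as.vector(beta), se = se, df = df)
}

# TMM factors from the defining formulas (weighted trimmed mean of
# M-values against an upper-quartile-selected reference)
tmm_oracle <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j] / lib[j], 0.75, names = FALSE), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; nO <- lib[j]
    rf <- counts[, ref]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  fac / exp(mean(log(fac)))
}

# per-site pi / dxy by brute-force averaging over haplotype pairs
pairwise_site_oracle <- function(h1, h2) {
  n_sites <- ncol(h1)
  out <- data.frame(pi1 = numeric(n_sites), pi2 = numeric(n_sites),
                    dxy = numeric(n_sites), num = numeric(n_sites))
  for (s in seq_len(n_sites)) {
    a <- h1[, s]; b <- h2[, s]
    pairs_within <- function(x) {
      cb <- utils::combn(length(x), 2)
      mean(x[cb[1, ]] != x[cb[2, ]])
    }
    out$pi1[s] <- pairs_within(a)
    out$pi2[s] <- pairs_within(b)
    out$dxy[s] <- mean(outer(a, b, "!="))
    out$num[s] <- out$dxy[s] - (out$pi1[s] + out$pi2[s]) / 2
  }
  out
}

# balanced-design method-of-moments variance components for the
# random-replicate emergence model
mom_emergence_oracle <- function(d) {
  m_full <- stats::lm(emergence ~ factor(genotype) + factor(replicate), d)
  m_red <- stats::lm(emergence ~ factor(genotype), d)
  mse <- sum(stats::resid(m_full)^2) / stats::df.residual(m_full)
  n_rep <- length(unique(d$replicate))
  ms_rep <- (sum(stats::resid(m_red)^2) - sum(stats::resid(m_full)^2)) /
    (n_rep - 1)
  k <- nrow(d) / n_rep
  list(var_rep = (ms_rep - mse) / k, var_res = mse)
}

# small deterministic effect-table pair for replication tests
make_shrink_stub <- function(post_mean, lfsr) {
  list(posterior_mean = post_mean, posterior_sd = abs(post_mean) * 0 + 1,
       lfsr = lfsr)
}
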