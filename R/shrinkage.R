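#' Empirical-Bayes multivariate shrinkage across conditions
#'
#' Borrows strength across the 18 tissue:temperature conditions to improve
#' per-condition effect estimates, in the spirit of multivariate adaptive
#' shrinkage. Effects are standardized (z = beta/se) and modeled as draws
#' from a mixture over canonical covariance patterns -- the null (no
#' effect), condition-specific effects (one singleton component per
#' condition), independent effects (identity), and equal effects shared
#' across all conditions (rank-1) -- each scaled over a geometric grid.
#' Mixture weights are estimated by EM on the marginal likelihoods with a
#' null-biased Dirichlet penalty; posteriors are then computed per gene and
#' condition as mixtures of conjugate normal posteriors, and the local
#' false sign rate (lfsr) summarizes sign confidence.
#'
#' All component likelihoods and posteriors have closed forms (each
#' canonical pattern is diagonal, rank-1, or a point mass), so no
#' per-gene matrix factorizations are needed.
#'
#' The lfsr here is `min(P(effect > 0), P(effect < 0)) + P(effect = 0)/2`:
#' posterior mass exactly at zero is split between the two signs, so the
#' lfsr lies in [0, 0.5] and equals 0.5 when the posterior is entirely
#' null.
#'
#' @param beta,se genes x conditions matrices of effect estimates and
#'   standard errors (complete; impute missing entries first with
#'   [impute_effects()]).
#' @param grid Scaling grid on the z scale (default `2^(seq(-4, 6))`).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance; non-convergence produces a warning and returns the last
#'   iterate.
#' @param null_weight Dirichlet pseudo-count biasing the null component
#'   (default 10).
#' @return List of class `shrinkage_result`: `posterior_mean`,
#'   `posterior_sd`, `lfsr` (genes x conditions, on the scale of `beta`),
#'   `pi` (named mixture weights), `loglik`, `converged`.
#' @export
multivariate_shrinkage <- function(beta, se, grid = 2^seq(-4, 6),
                                   max_iter = 500, tol = 1e-7,
                                   null_weight = 10) {
  beta <- as.matrix(beta); se <- as.matrix(se)
  stopifnot(all(dim(beta) == dim(se)), all(se > 0))
  G <- nrow(beta); R <- ncol(beta)
  z <- beta / se
  conds <- colnames(beta) %||% paste0("cond", seq_len(R))

  # component table: type in {null, identity, singleton_j, shared}, scale w
  comp <- data.frame(type = "null", j = NA_integer_, w = 0,
                     stringsAsFactors = FALSE)
  for (w in grid) {
    comp <- rbind(comp,
                  data.frame(type = "identity", j = NA_integer_, w = w),
                  data.frame(type = "shared", j = NA_integer_, w = w),
                  data.frame(type = "singleton", j = seq_len(R), w = w))
  }
  K <- nrow(comp)

  base_ll <- rowSums(stats::dnorm(z, log = TRUE))     # z ~ N(0, I)
  zsum <- rowSums(z); zsq <- z^2
  L <- matrix(0, G, K)                                # loglik per component
  for (k in seq_len(K)) {
    w <- comp$w[k]
    L[, k] <- switch(comp$type[k],
      null = base_ll,
      identity = rowSums(stats::dnorm(z, sd = sqrt(1 + w), log = TRUE)),
      singleton = {
        j <- comp$j[k]
        base_ll + stats::dnorm(z[, j], sd = sqrt(1 + w), log = TRUE) -
          stats::dnorm(z[, j], log = TRUE)
      },
      shared = base_ll - 0.5 * log1p(w * R) +
        0.5 * (w / (1 + w * R)) * zsum^2)
  }

  # EM for mixture weights with null-biased penalty
  lambda <- c(null_weight, rep(1, K - 1))
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- sweep(L, 2, log(pi_k), "+")
    m <- apply(A, 1, max)
    resp <- exp(A - m)
    rs <- rowSums(resp)
    ll <- sum(m + log(rs)) + sum((lambda - 1) * log(pmax(pi_k, 1e-300)))
    resp <- resp / rs
    nk <- colSums(resp) + lambda - 1
    pi_k <- pmax(nk, 0) / sum(pmax(nk, 0))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  if (!converged) warning("EM did not converge; returning last iterate")

  # posterior moments and sign probabilities on the z scale
  post_mean <- matrix(0, G, R)
  post_m2 <- matrix(0, G, R)       # E[z^2]
  p_pos <- matrix(0, G, R)
  p_neg <- matrix(0, G, R)
  p_zero <- matrix(0, G, R)
  for (k in seq_len(K)) {
    r <- resp[, k]; w <- comp$w[k]
    if (comp$type[k] == "null") {
      p_zero <- p_zero + r
    } else if (comp$type[k] == "identity") {
      s <- w / (1 + w)
      mu <- s * z; v <- s
      post_mean <- post_mean + r * mu
      post_m2 <- post_m2 + r * (mu^2 + v)
      sd_ <- sqrt(v)
      p_pos <- p_pos + r * stats::pnorm(mu / sd_)
      p_neg <- p_neg + r * stats::pnorm(-mu / sd_)
    } else if (comp$type[k] == "singleton") {
      j <- comp$j[k]
      s <- w / (1 + w)
      mu <- s * z[, j]; v <- s
      post_mean[, j] <- post_mean[, j] + r * mu
      post_m2[, j] <- post_m2[, j] + r * (mu^2 + v)
      sd_ <- sqrt(v)
      p_pos[, j] <- p_pos[, j] + r * stats::pnorm(mu / sd_)
      p_neg[, j] <- p_neg[, j] + r * stats::pnorm(-mu / sd_)
      p_zero[, -j] <- p_zero[, -j] + r
    } else {                        # shared: z = a * 1, a ~ N(0, w)
      va <- w / (1 + w * R)
      mu_a <- va * zsum
      post_mean <- post_mean + r * mu_a
      post_m2 <- post_m2 + r * (mu_a^2 + va)
      sd_ <- sqrt(va)
      p_pos <- p_pos + r * stats::pnorm(mu_a / sd_)
      p_neg <- p_neg + r * stats::pnorm(-mu_a / sd_)
    }
  }
  post_var <- pmax(post_m2 - post_mean^2, 0)
  lfsr <- pmin(p_pos, p_neg) + p_zero / 2

  dn <- list(rownames(beta), conds)
  out <- list(posterior_mean = se * post_mean,
              posterior_sd = se * sqrt(post_var),
              lfsr = structure(lfsr, dimnames = dn),
              pi = stats::setNames(pi_k, paste0(comp$type,
                ifelse(is.na(comp$j), "", paste0("_", comp$j)),
                "_w", signif(comp$w, 3))),
              loglik = ll_old, converged = converged)
  dimnames(out$posterior_mean) <- dn
  dimnames(out$posterior_sd) <- dn
  class(out) <- "shrinkage_result"
  out
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf("shrinkage_result: %d genes x %d conditions\n",
              nrow(x$lfsr), ncol(x$lfsr)))
  cat(sprintf("  null weight: %.3f; significant at lfsr<0.05: %d gene(s)\n",
              x$pi[["null_w0"]], sum(rowSums(x$lfsr < 0.05) > 0)))
  invisible(x)
}
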