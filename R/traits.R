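#' Mixed-model analysis of seedling emergence time
#'
#' Fits `emergence ~ genotype + (1 | replicate)` by REML: a fixed genotype
#' effect (days, High minus Low) with a random intercept for experimental
#' replicate. The genotype effect is tested with a conditional F-test at
#' the REML variance-component estimates; the denominator degrees of
#' freedom use the containment rule (N - fixed-effect rank -
#' (n_replicates - 1)), with Satterthwaite-style behavior available by
#' treating the replicate variance as known.
#'
#' @param data data.frame with the emergence times.
#' @param response,genotype,replicate Column names (defaults "emergence",
#'   "genotype", "replicate"). Genotype may be numeric 0/1 or a two-level
#'   factor.
#' @return List of class `emergence_fit`: `mu`, `beta` (genotype effect),
#'   `se`, `var_replicate`, `var_residual`, `F`, `df1`, `df2`, `p_value`,
#'   and the underlying `lme4` fit.
#' @export
fit_emergence <- function(data, response = "emergence",
                          genotype = "genotype", replicate = "replicate") {
  df <- data.frame(y = data[[response]],
                   g = as.numeric(data[[genotype]]),
                   rep = as.factor(data[[replicate]]))
  if (length(unique(df$g)) != 2) stop("genotype must have two levels")
  df$g <- as.numeric(df$g == max(df$g))
  if (nlevels(df$rep) < 2) stop("need at least 2 replicates")
  fit <- suppressMessages(lme4::lmer(y ~ g + (1 | rep), data = df,
                                     REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rep <- vc$vcov[vc$grp == "rep"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  Fstat <- (b[["g"]] / se[2])^2
  df2 <- nrow(df) - 2 - (nlevels(df$rep) - 1)
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  structure(list(mu = unname(b[1]), beta = unname(b[2]), se = unname(se[2]),
                 var_replicate = var_rep, var_residual = var_res,
                 F = unname(Fstat), df1 = 1, df2 = df2, p_value = unname(p),
                 fit = fit), class = "emergence_fit")
}

#' @export
print.emergence_fit <- function(x, ...) {
  cat(sprintf("emergence: beta = %+.3f d (SE %.3f), F(1,%d) = %.2f, p = %.3g\n",
              x$beta, x$se, x$df2, x$F, x$p_value))
  cat(sprintf("  var(replicate) = %.4f, var(residual) = %.4f\n",
              x$var_replicate, x$var_residual))
  invisible(x)
}

#' Genotype-by-elevation interaction model for agronomic traits
#'
#' Fits `trait ~ genotype * elevation + tester + (1 + elevation | family)`
#' by REML and returns the estimated locus effect as a function of trial
#' elevation, b(e) = beta_G + beta_GxE * e, with pointwise +/- 2 SE from
#' the coefficient covariance. A crossing b(e) (negative at low elevation,
#' positive at high) is the signature of antagonistic pleiotropy. An
#' optional per-trial covariate (e.g. days to anthesis) can be included to
#' test whether the genotype effect is mediated by it.
#'
#' @param data data.frame of trial records.
#' @param trait,genotype,elevation,tester,family Column names.
#' @param covariate Optional column name; when given it enters with an
#'   independent slope per tester:elevation trial.
#' @param grid Elevations at which to evaluate b(e) (default: 25 points
#'   over the observed range).
#' @return List of class `elevation_fit`: `curve` data.frame (elevation,
#'   effect, lower, upper), `beta_G`, `beta_GxE`, `p_interaction`, `fit`.
#' @export
fit_elevation_interaction <- function(data, trait = "trait",
                                      genotype = "genotype",
                                      elevation = "elevation",
                                      tester = "tester", family = "family",
                                      covariate = NULL, grid = NULL) {
  df <- data.frame(y = data[[trait]],
                   g = as.numeric(data[[genotype]]),
                   e = as.numeric(data[[elevation]]),
                   tester = as.factor(data[[tester]]),
                   fam = as.factor(data[[family]]))
  if (stats::sd(df$e) == 0) stop("no elevation variation")
  df$es <- (df$e - mean(df$e)) / stats::sd(df$e)   # scaled for the optimizer
  form <- y ~ g * es + tester + (1 + es | fam)
  if (!is.null(covariate)) {
    df$cov <- as.numeric(data[[covariate]])
    df$trial <- interaction(df$tester, round(df$e))
    form <- y ~ g * es + tester + trial:cov + (1 + es | fam)
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  ig <- which(names(b) == "g")
  ii <- which(names(b) == "g:es")
  if (is.null(grid)) grid <- seq(min(df$e), max(df$e), length.out = 25)
  gs <- (grid - mean(df$e)) / stats::sd(df$e)
  eff <- b[ig] + b[ii] * gs
  se <- sqrt(V[ig, ig] + gs^2 * V[ii, ii] + 2 * gs * V[ig, ii])
  tstat <- b[ii] / sqrt(V[ii, ii])
  df2 <- nrow(df) - length(b) - 1
  structure(list(
    curve = data.frame(elevation = grid, effect = unname(eff),
                       lower = unname(eff - 2 * se),
                       upper = unname(eff + 2 * se)),
    beta_G = unname(b[ig]), beta_GxE = unname(b[ii] / stats::sd(df$e)),
    p_interaction = 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE),
    fit = fit), class = "elevation_fit")
}
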