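#' Random-intercept mixed model for a cardiac metric
#'
#' Fits `y = b0 + b1 * incubation_C + (1 | clutch)` by REML, the model used
#' for every per-individual cardiac index. Reports the fixed-effect table
#' (Satterthwaite t and p), variance components, marginal and conditional
#' R-squared by variance partition
#' (R2m = var_fixed / (var_fixed + s2_clutch + s2_resid); R2c adds
#' s2_clutch to the numerator), and a likelihood-ratio test of the clutch
#' random effect against the no-random-effect model on chi-square(1) with
#' the usual boundary correction (p halved).
#'
#' @param values metric values (one per individual; `NA` dropped).
#' @param incubation_C incubation temperature (degC) per individual.
#' @param clutch_id clutch label per individual.
#' @return A list of class `lmm_fit`: `beta` (data.frame with estimate, se,
#'   df, t, p per fixed effect), `sigma2_clutch`, `sigma2_resid`,
#'   `R2_marginal`, `R2_conditional`, `lrt_p_random`, `fallback` (TRUE when
#'   a single clutch forced an ordinary least-squares fit), and `model`.
#' @export
fit_random_intercept_lmm <- function(values, incubation_C, clutch_id) {
  keep <- is.finite(values) & is.finite(incubation_C) & !is.na(clutch_id)
  d <- data.frame(y = values[keep], inc = incubation_C[keep],
                  clutch = factor(clutch_id[keep]))
  if (nrow(d) < 3) stop("need at least 3 observations")
  if (nlevels(droplevels(d$clutch)) < 2) {
    fit0 <- stats::lm(y ~ inc, data = d)
    s <- summary(fit0)$coefficients
    beta <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                       df = fit0$df.residual, t = s[, 3], p = s[, 4],
                       row.names = NULL)
    var_f <- stats::var(stats::fitted(fit0))
    s2e <- summary(fit0)$sigma^2
    return(structure(list(beta = beta, sigma2_clutch = 0, sigma2_resid = s2e,
                          R2_marginal = var_f / (var_f + s2e),
                          R2_conditional = var_f / (var_f + s2e),
                          lrt_p_random = NA_real_, fallback = TRUE,
                          model = fit0),
                     class = "lmm_fit"))
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lmerTest::lmer(y ~ inc + (1 | clutch), data = d, REML = TRUE,
                        control = ctrl)
  s <- stats::coef(summary(fit))
  beta <- data.frame(term = rownames(s), estimate = s[, "Estimate"],
                     se = s[, "Std. Error"], df = s[, "df"],
                     t = s[, "t value"], p = s[, "Pr(>|t|)"],
                     row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2c <- vc$vcov[vc$grp == "clutch"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  var_f <- stats::var(as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)))
  tot <- var_f + s2c + s2e
  # boundary-corrected LRT of the random effect (ML fits on both sides)
  m1 <- lme4::lmer(y ~ inc + (1 | clutch), data = d, REML = FALSE,
                   control = ctrl)
  m0 <- stats::lm(y ~ inc, data = d)
  lr <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                      as.numeric(stats::logLik(m0))))
  p_rand <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(beta = beta, sigma2_clutch = s2c, sigma2_resid = s2e,
                 R2_marginal = var_f / tot,
                 R2_conditional = (var_f + s2c) / tot,
                 lrt_p_random = p_rand, fallback = FALSE, model = fit),
            class = "lmm_fit")
}

#' Tukey-adjusted pairwise contrasts between incubation groups
#'
#' Treats incubation temperature as a factor, fits the same random-intercept
#' model, and compares all group pairs with studentized-range (Tukey)
#' adjustment via estimated marginal means.
#'
#' @param values metric values per individual.
#' @param group incubation group label per individual.
#' @param clutch_id clutch label per individual.
#' @return Data frame of contrasts: `contrast`, `estimate`, `se`, `df`,
#'   `t`, `p_adj`.
#' @export
pairwise_contrasts <- function(values, group, clutch_id) {
  keep <- is.finite(values) & !is.na(group) & !is.na(clutch_id)
  d <- data.frame(y = values[keep], grp = factor(group[keep]),
                  clutch = factor(clutch_id[keep]))
  if (nlevels(droplevels(d$grp)) < 2) stop("need at least 2 groups")
  fit <- if (nlevels(droplevels(d$clutch)) >= 2)
    lme4::lmer(y ~ grp + (1 | clutch), data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  else stats::lm(y ~ grp, data = d)
  em <- emmeans::emmeans(fit, "grp")
  ct <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  data.frame(contrast = as.character(ct$contrast), estimate = ct$estimate,
             se = ct$SE, df = ct$df, t = ct$t.ratio, p_adj = ct$p.value,
             row.names = NULL)
}
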