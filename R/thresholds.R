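#' Long-format reached indicators for an endpoint
#'
#' For every individual and protocol step, `reached = 1` iff the step
#' temperature is at or above the individual's endpoint temperature
#' (`T_peak` or `T_Arr`). Individuals with right-censored `T_Arr`
#' (no arrhythmia by the final step) contribute 0 at every observed step;
#' individuals with a missing, non-censored endpoint are dropped.
#'
#' @param metrics metrics table from [extract_metrics()].
#' @param endpoint `"T_peak"` or `"T_Arr"`.
#' @param steps protocol step temperatures (degC).
#' @return Long data frame: `individual_id`, `clutch_id`, `incubation_C`,
#'   `step_temp_C`, `reached` (0/1).
#' @export
reached_indicators <- function(metrics, endpoint = c("T_peak", "T_Arr"),
                               steps = make_protocol()$steps) {
  endpoint <- match.arg(endpoint)
  e <- metrics[[endpoint]]
  censored <- if (endpoint == "T_Arr") metrics$censored else FALSE
  censored <- rep_len(censored, nrow(metrics))
  keep <- is.finite(e) | censored
  if (!any(keep)) stop("endpoint missing for all individuals")
  m <- metrics[keep, ]
  e <- e[keep]; censored <- censored[keep]
  n <- nrow(m); k <- length(steps)
  reached <- ifelse(rep(censored, each = k), 0L,
                    as.integer(rep(steps, times = n) >= rep(e, each = k)))
  data.frame(individual_id = rep(m$individual_id, each = k),
             clutch_id = rep(m$clutch_id, each = k),
             incubation_C = rep(m$incubation_C, each = k),
             step_temp_C = rep(steps, times = n),
             reached = reached)
}

#' Logistic model of the proportion of individuals past an endpoint
#'
#' Fits `reached ~ temperature * incubation` (or `reached ~ temperature`
#' within a single group when `per_group = TRUE`) by binomial logistic
#' regression. Clutch structure is handled as a cluster-robust covariance
#' correction on the fixed-effect fit rather than a random intercept: the
#' clutch variance component in these curves is tiny, and the fixed-effect
#' fit with clustered errors is deterministic and keeps the inverse
#' prediction closed-form. Complete separation is detected, flagged, and
#' resolved with a small ridge penalty.
#'
#' @param indicators output of [reached_indicators()].
#' @param per_group fit temperature-only models (call once per group subset)
#'   instead of the joint interaction model.
#' @param ridge ridge penalty used only under separation.
#' @return A list of class `reached_curve`: `endpoint_formula`, `coef`
#'   (named vector), `vcov` (cluster-robust), `separation`, `per_group`,
#'   `incubation_C` (when `per_group`), and `model` (NULL for ridge fits).
#' @export
fit_reached_curve <- function(indicators, per_group = FALSE, ridge = 1e-4) {
  y <- indicators$reached
  if (all(y == 0) || all(y == 1))
    stop("need both 0 and 1 indicators to fit a logistic curve")
  if (per_group) {
    inc <- unique(indicators$incubation_C)
    if (length(inc) != 1)
      stop("per_group fit expects indicators from a single incubation group")
    X <- cbind(`(Intercept)` = 1, temperature = indicators$step_temp_C)
  } else {
    inc <- NA_real_
    X <- cbind(`(Intercept)` = 1, temperature = indicators$step_temp_C,
               incubation = indicators$incubation_C,
               `temperature:incubation` =
                 indicators$step_temp_C * indicators$incubation_C)
  }
  cl <- indicators$clutch_id
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 30) ||
    all(abs(fit$fitted.values - y) < 1e-8)
  if (!separated) {
    gfit <- suppressWarnings(stats::glm(y ~ X - 1, family = stats::binomial()))
    names(gfit$coefficients) <- colnames(X)
    V <- sandwich::vcovCL(gfit, cluster = cl)
    dimnames(V) <- list(colnames(X), colnames(X))
    coefs <- gfit$coefficients
    model <- gfit
  } else {
    r <- ridge_logistic(X, y, lambda = ridge, cluster = cl)
    coefs <- r$coef
    V <- r$vcov
    model <- NULL
  }
  structure(list(coef = coefs, vcov = V, separation = separated,
                 per_group = per_group, incubation_C = inc, model = model),
            class = "reached_curve")
}

# ridge-penalized logistic IRLS with cluster-robust sandwich covariance;
# only used when the unpenalized fit separates
ridge_logistic <- function(X, y, lambda, cluster, max_iter = 100) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(X * sqrt(w)) + lambda * diag(p)
    g <- crossprod(X, y - mu) - lambda * beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  mu <- stats::plogis(drop(X %*% beta))
  bread <- solve(crossprod(X * sqrt(mu * (1 - mu))) + lambda * diag(p))
  scores <- X * (y - mu)
  cl_scores <- rowsum(scores, group = as.character(cluster))
  meat <- crossprod(as.matrix(cl_scores))
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = stats::setNames(drop(beta), colnames(X)), vcov = V)
}

# effective intercept/slope of a reached_curve at a given incubation, with
# the gradient of each wrt the full coefficient vector
curve_linear_predictor <- function(curve, incubation_C) {
  b <- curve$coef
  if (curve$per_group) {
    list(a = b[["(Intercept)"]], s = b[["temperature"]],
         grad_a = c(1, 0), grad_s = c(0, 1))
  } else {
    if (is.null(incubation_C) || !is.finite(incubation_C))
      stop("incubation_C required for the joint interaction model")
    list(a = b[["(Intercept)"]] + b[["incubation"]] * incubation_C,
         s = b[["temperature"]] +
           b[["temperature:incubation"]] * incubation_C,
         grad_a = c(1, 0, incubation_C, 0),
         grad_s = c(0, 1, 0, incubation_C))
  }
}

#' Predicted proportion reached at given temperatures
#'
#' @param curve a `reached_curve`.
#' @param temp_C temperatures (degC).
#' @param incubation_C incubation temperature for joint models.
#' @return Fitted proportions in (0, 1).
#' @export
predict_reached <- function(curve, temp_C, incubation_C = NULL) {
  lp <- curve_linear_predictor(curve, incubation_C)
  stats::plogis(lp$a + lp$s * temp_C)
}

#' Inverse prediction: temperature at which a proportion is reached
#'
#' Solves `logit(p_level) = a + s * T` for T at the given incubation and
#' propagates coefficient uncertainty by the delta method on the
#' cluster-robust covariance (the same construction as classical LD50-style
#' dose estimation).
#'
#' @param curve a `reached_curve`.
#' @param p_level proportions in (0, 1), e.g. `c(0.10, 0.50, 0.95)`.
#' @param incubation_C incubation temperature (degC); required for joint
#'   models, ignored for per-group fits.
#' @return Data frame of class `threshold_estimate`: `p_level`,
#'   `temperature` (degC), `se` (degC).
#' @export
inverse_predict <- function(curve, p_level = c(0.10, 0.50, 0.95),
                            incubation_C = NULL) {
  stopifnot(all(p_level > 0 & p_level < 1))
  lp <- curve_linear_predictor(curve, incubation_C)
  if (lp$s <= 0)
    stop("effective temperature slope must be positive for inverse prediction")
  L <- stats::qlogis(p_level)
  temperature <- (L - lp$a) / lp$s
  se <- vapply(temperature, function(Tt) {
    g <- (-lp$grad_a - Tt * lp$grad_s) / lp$s
    sqrt(drop(t(g) %*% curve$vcov %*% g))
  }, 0)
  out <- data.frame(p_level = p_level, temperature = temperature, se = se)
  class(out) <- c("threshold_estimate", "data.frame")
  out
}
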