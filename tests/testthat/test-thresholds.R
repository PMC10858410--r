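fake_metrics <- function(T_peak, T_Arr = NULL, censored = NULL,
                         incubation_C = 12) {
  n <- length(T_peak)
  data.frame(individual_id = sprintf("i%03d", seq_len(n)),
             clutch_id = rep_len(paste0("C", 1:4), n),
             incubation_C = rep_len(incubation_C, n),
             T_peak = T_peak,
             T_Arr = if (is.null(T_Arr)) T_peak + 2 else T_Arr,
             censored = if (is.null(censored)) rep(FALSE, n) else censored)
}

test_that("reached indicators implement the step CDF", {
  m <- fake_metrics(T_peak = c(19, 13))
  ind <- reached_indicators(m, "T_peak", steps = c(9, 13, 17, 19, 25))
  i1 <- ind[ind$individual_id == "i001", ]
  expect_equal(i1$reached, c(0, 0, 0, 1, 1))
  # empirical proportion at each step equals the hand-computed CDF
  prop <- tapply(ind$reached, ind$step_temp_C, mean)
  expect_equal(as.numeric(prop), c(0, 0.5, 0.5, 1, 1))
})

test_that("censored individuals contribute zeros at every step", {
  m <- fake_metrics(T_peak = c(19, 20), T_Arr = c(NA, 22),
                    censored = c(TRUE, FALSE))
  ind <- reached_indicators(m, "T_Arr", steps = c(9, 22, 25))
  expect_equal(ind$reached[ind$individual_id == "i001"], c(0, 0, 0))
  expect_equal(ind$reached[ind$individual_id == "i002"], c(0, 1, 1))
  expect_error(reached_indicators(fake_metrics(NA_real_), "T_peak"),
               "missing for all")
})

sim_logistic_cohort <- function(n = 400, a = -18, b = 0.92, seed = 1,
                                incubation_C = 12,
                                steps = seq(9, 25, by = 1)) {
  # endpoints drawn from the logistic law Pr(reached by T) = plogis(a + bT)
  set.seed(seed)
  endpoint <- (stats::qlogis(runif(n)) - a) / b
  m <- fake_metrics(T_peak = endpoint, incubation_C = incubation_C)
  # individuals are the independent unit here: cluster on them, so the
  # robust covariance accounts for the within-individual step dependence
  m$clutch_id <- m$individual_id
  list(metrics = m,
       indicators = reached_indicators(m, "T_peak", steps = steps),
       endpoint = endpoint)
}

test_that("logistic fit recovers a known temperature coefficient", {
  co <- sim_logistic_cohort(n = 400, b = 0.92, seed = 3)
  fit <- fit_reached_curve(co$indicators, per_group = TRUE)
  expect_false(fit$separation)
  b_hat <- fit$coef[["temperature"]]
  se <- sqrt(fit$vcov["temperature", "temperature"])
  expect_lt(abs(b_hat - 0.92), 2 * se)
  # fitted curve non-decreasing in temperature
  p <- predict_reached(fit, seq(9, 25, by = 0.5))
  expect_true(all(diff(p) >= 0))
})

test_that("the joint model finds no interaction when none was simulated", {
  set.seed(5)
  parts <- lapply(c(9, 12, 15), function(g) {
    co <- sim_logistic_cohort(n = 150, a = -18 + 0.3 * g, b = 0.9,
                              seed = g, incubation_C = g)
    co$indicators
  })
  ind <- do.call(rbind, parts)
  fit <- fit_reached_curve(ind)
  est <- fit$coef[["temperature:incubation"]]
  se <- sqrt(fit$vcov["temperature:incubation", "temperature:incubation"])
  expect_lt(abs(est), 2 * se)
})

test_that("complete separation is flagged and resolved with a ridge", {
  m <- fake_metrics(T_peak = rep(17, 40))
  ind <- reached_indicators(m, "T_peak", steps = c(9, 13, 21, 25))
  fit <- fit_reached_curve(ind, per_group = TRUE)
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coef)))
  expect_gt(fit$coef[["temperature"]], 0)
})

test_that("inverse prediction is the closed form, round-trips, and is monotone", {
  co <- sim_logistic_cohort(n = 400, seed = 7)
  fit <- fit_reached_curve(co$indicators, per_group = TRUE)
  th <- inverse_predict(fit, c(0.10, 0.50, 0.95))
  a <- fit$coef[["(Intercept)"]]; s <- fit$coef[["temperature"]]
  expect_equal(th$temperature[th$p_level == 0.5], -a / s)
  for (i in seq_len(nrow(th)))
    expect_equal(predict_reached(fit, th$temperature[i]), th$p_level[i],
                 tolerance = 1e-9)
  expect_true(all(diff(th$temperature) > 0))
  expect_true(all(th$se > 0))
})

test_that("inverse prediction matches classical dose estimation", {
  co <- sim_logistic_cohort(n = 300, seed = 11)
  g <- glm(reached ~ step_temp_C, binomial, data = co$indicators)
  dp <- MASS::dose.p(g, p = c(0.1, 0.5, 0.95))
  curve <- structure(list(coef = c(`(Intercept)` = unname(coef(g)[1]),
                                   temperature = unname(coef(g)[2])),
                          vcov = unname(vcov(g)), per_group = TRUE,
                          separation = FALSE, incubation_C = 12),
                     class = "reached_curve")
  th <- inverse_predict(curve, c(0.1, 0.5, 0.95))
  expect_equal(th$temperature, unname(as.vector(dp)), tolerance = 1e-10)
  expect_equal(th$se, unname(attr(dp, "SE")[, 1]), tolerance = 1e-8)
})

test_that("a non-positive effective slope is refused", {
  curve <- structure(list(coef = c(`(Intercept)` = 2, temperature = -0.5),
                          vcov = diag(2), per_group = TRUE,
                          separation = FALSE, incubation_C = 12),
                     class = "reached_curve")
  expect_error(inverse_predict(curve, 0.5), "positive")
})
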