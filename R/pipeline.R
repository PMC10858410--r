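#' Run the full assay analysis pipeline
#'
#' Orchestrates the four stages: simulate (or load) a population dataset,
#' extract per-individual cardiac metrics, run the population analyses
#' (mixed models per metric, Tukey contrasts, logistic reached curves with
#' 10/50/95% inverse prediction, T_AB kernel densities, delta-N overlays and
#' their penalized-spline decline breakpoints), and optionally write a
#' results bundle of delimited tables plus a diff-friendly summary.
#'
#' @param config a [population_config()]; ignored when `data` is supplied.
#' @param data optional pre-existing dataset data frame (skips simulation).
#' @param protocol a [make_protocol()] object.
#' @param p_levels inverse-prediction proportions.
#' @param tol delta-N maximal-range tolerance.
#' @param k_peak,k_arr spline basis dimensions for the T_peak and T_Arr
#'   delta-N smooths.
#' @param out_dir directory for the results bundle; `NULL` writes nothing.
#' @return A list with `data`, `truth` (when simulated), `metrics`,
#'   `lmm` (per metric), `contrasts` (per metric), `curves` (per endpoint),
#'   `thresholds` (long data frame endpoint x incubation x p_level),
#'   `densities` (T_AB KDE per group), `delta_n` (per endpoint x group) and
#'   `breakpoints` (per endpoint x group).
#' @export
run_pipeline <- function(config = NULL, data = NULL,
                         protocol = make_protocol(),
                         p_levels = c(0.10, 0.50, 0.95), tol = 0.10,
                         k_peak = 4, k_arr = 9, out_dir = NULL) {
  truth <- NULL
  seed <- if (!is.null(config)) config$seed else NA
  if (is.null(data)) {
    if (is.null(config)) stop("supply either a config or a dataset")
    sim <- generate_dataset(config, protocol)
    data <- sim$data
    truth <- sim$truth
  }
  report <- validate_dataset(data)
  if (!report$valid)
    stop("dataset invariants violated: ", paste(report$violations, collapse = "; "))

  metrics <- extract_metrics(data)
  groups <- sort(unique(metrics$incubation_C))

  metric_cols <- c("f_H0", "f_Hpeak", "delta_f", "dfdT", "T_AB", "T_peak",
                   "T_Arr")
  lmm <- lapply(stats::setNames(metric_cols, metric_cols), function(mc)
    fit_random_intercept_lmm(metrics[[mc]], metrics$incubation_C,
                             metrics$clutch_id))
  contrasts <- lapply(stats::setNames(metric_cols, metric_cols), function(mc)
    pairwise_contrasts(metrics[[mc]], metrics$incubation_C,
                       metrics$clutch_id))

  endpoints <- c(T_peak = "T_peak", T_Arr = "T_Arr")
  curves <- lapply(endpoints, function(ep) {
    ind <- reached_indicators(metrics, ep, steps = protocol$steps)
    fit_reached_curve(ind)
  })
  thresholds <- do.call(rbind, lapply(names(curves), function(ep) {
    do.call(rbind, lapply(groups, function(g) {
      th <- inverse_predict(curves[[ep]], p_levels, incubation_C = g)
      data.frame(endpoint = ep, incubation_C = g, th)
    }))
  }))

  densities <- lapply(stats::setNames(groups, paste0("inc", groups)),
                      function(g)
    kde_tab(metrics$T_AB[metrics$incubation_C == g]))

  delta_n <- list()
  breakpoints <- list()
  for (ep in names(curves)) {
    kk <- if (ep == "T_peak") k_peak else k_arr
    for (g in groups) {
      key <- paste0(ep, "_inc", g)
      dn <- delta_n_curve(densities[[paste0("inc", g)]], curves[[ep]],
                          incubation_C = g, endpoint = ep, tol = tol)
      delta_n[[key]] <- dn
      # smooth the overlay sampled at the protocol steps
      dn_steps <- density_at(densities[[paste0("inc", g)]], protocol$steps) -
        predict_reached(curves[[ep]], protocol$steps, incubation_C = g)
      breakpoints[[key]] <- smooth_decline_breakpoint(protocol$steps,
                                                      dn_steps, k = kk)
    }
  }

  res <- list(data = data, truth = truth, metrics = metrics, lmm = lmm,
              contrasts = contrasts, curves = curves,
              thresholds = thresholds, densities = densities,
              delta_n = delta_n, breakpoints = breakpoints,
              protocol = protocol, report = report)
  if (!is.null(out_dir)) write_results(res, out_dir, seed = seed,
                                       config = config)
  invisible(res)
}

#' Write the results bundle of a pipeline run
#'
#' @param res result list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param seed,config recorded in file header comments.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(res, out_dir, seed = NA, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(res$data, file.path(out_dir, "dataset.csv"), seed, config)
  if (!is.null(res$truth))
    write_table_stamped(res$truth, file.path(out_dir, "truth.csv"),
                        seed, config, "truth")
  write_table_stamped(res$metrics, file.path(out_dir, "metrics.csv"),
                      seed, config, "extract")
  fixef_tab <- do.call(rbind, lapply(names(res$lmm), function(mc)
    data.frame(metric = mc, res$lmm[[mc]]$beta,
               sigma2_clutch = res$lmm[[mc]]$sigma2_clutch,
               sigma2_resid = res$lmm[[mc]]$sigma2_resid,
               R2_marginal = res$lmm[[mc]]$R2_marginal,
               R2_conditional = res$lmm[[mc]]$R2_conditional,
               lrt_p_random = res$lmm[[mc]]$lrt_p_random)))
  write_table_stamped(fixef_tab, file.path(out_dir, "lmm_fixed_effects.csv"),
                      seed, config, "analyze")
  write_table_stamped(res$thresholds, file.path(out_dir, "thresholds.csv"),
                      seed, config, "analyze")
  for (key in names(res$delta_n)) {
    dn <- res$delta_n[[key]]
    write_table_stamped(data.frame(temp_C = dn$grid, delta_n = dn$delta_n),
                        file.path(out_dir, paste0("delta_n_", key, ".csv")),
                        seed, config, "analyze")
  }
  summary_lines <- c(
    sprintf("individuals: %d", res$report$n_individuals),
    sprintf("rows: %d", res$report$n_rows),
    vapply(names(res$delta_n), function(key) {
      dn <- res$delta_n[[key]]
      rng <- paste(sprintf("[%.2f, %.2f]", dn$max_range$lo, dn$max_range$hi),
                   collapse = " ")
      sprintf("delta_n %s: max=%.4f at %.2f degC; max_range %s; decline_breakpoint=%.2f",
              key, dn$max_value, dn$argmax_C,
              rng, res$breakpoints[[key]]$breakpoint_C)
    }, ""))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
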