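#' @name reporting
#' @title High-level analysis drivers and table writers
#' @description
#' These drivers tie the stages together into the full analysis: robust and
#' quantile fits across data subsets with derived summaries
#' ([run_fixed_effects_analysis()]), mixed-effects structures
#' ([run_mixed_effects_analysis()]), extrapolation scoring
#' ([run_extrapolation_analysis()]), and the zone/year multimodel-inference
#' arm ([run_chernobyl_analysis()]).  Results are plain data frames;
#' `out_dir` writes them as CSV plus a JSON mirror for programmatic use.
NULL

#' One-row summary of a fitted model
#'
#' Ecological half-life with CI, seasonal amplitude `exp(A)` with CI, phase
#' shift in months with CI, and the peak-to-trough fold change `exp(2A)`.
#'
#' @param fit an `rc_fit` or `rc_mixed_fit`.
#' @param label optional row label.
#' @return One-row data frame.
#' @export
summarize_fit <- function(fit, label = NULL) {
  p <- fit$params; s <- fit$se
  hl <- ecological_half_life(p[["mu"]], s[["mu"]])
  ss <- seasonal_summaries(p[["A"]], p[["P"]], s[["A"]], s[["P"]])
  data.frame(
    label = if (is.null(label)) class(fit)[1L] else label,
    half_life = hl$estimate, half_life_lo = hl$lower,
    half_life_hi = hl$upper,
    amplitude = ss$amplitude_metric,
    amplitude_lo = ss$amplitude_ci[1L], amplitude_hi = ss$amplitude_ci[2L],
    phase_months = ss$phase_months,
    phase_months_lo = ss$phase_months_ci[1L],
    phase_months_hi = ss$phase_months_ci[2L],
    fold_peak_trough = ss$fold_change_peak_trough,
    row.names = NULL)
}

.param_rows <- function(fit, label) {
  data.frame(label = label, parameter = names(fit$params),
             estimate = unname(fit$params), se = unname(fit$se),
             row.names = NULL)
}

.write_outputs <- function(tables, out_dir, stem) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables))
    write.csv(tables[[nm]], file.path(out_dir,
                                      paste0(stem, "_", nm, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(tables, file.path(out_dir, paste0(stem, ".json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Robust and quantile fits across data subsets
#'
#' @param records analysis-ready data frame.
#' @param env an [environment_spec()].
#' @param species species the subset rules apply to.
#' @param subsets subset rules to run.
#' @param taus quantile levels (`NULL` skips quantile fits).
#' @param n_restarts,seed estimation controls.
#' @param n_boot bootstrap resamples for quantile standard errors.
#' @param out_dir optional output directory.
#' @return List with `parameters` (long parameter table) and `summaries`
#'   (half-life/amplitude/phase table).
#' @export
run_fixed_effects_analysis <- function(records, env, species = "boar",
                                       subsets = c("full"),
                                       taus = c(0.25, 0.5, 0.75),
                                       n_restarts = 50, seed = 1,
                                       n_boot = 200, out_dir = NULL) {
  params <- list(); sums <- list()
  for (sub in subsets) {
    rec <- subset_records(records, sub, species)
    if (nrow(rec) < 10) stop("subset '", sub, "' has too few records")
    rob <- fit_robust(rec, env, "nu1", n_restarts = n_restarts,
                      seed = seed)
    lab <- paste0(sub, "/robust")
    params[[lab]] <- .param_rows(rob, lab)
    sums[[lab]] <- summarize_fit(rob, lab)
    for (tau in taus) {
      qf <- fit_quantile(rec, env, tau, "nu1", init = rob,
                         n_boot = n_boot, seed = seed)
      lab <- paste0(sub, "/q", round(100 * tau))
      params[[lab]] <- .param_rows(qf, lab)
      sums[[lab]] <- summarize_fit(qf, lab)
    }
  }
  out <- list(parameters = do.call(rbind, params),
              summaries = do.call(rbind, sums))
  rownames(out$parameters) <- rownames(out$summaries) <- NULL
  .write_outputs(out, out_dir, "fixed_effects")
  out
}

#' Mixed-effects analysis with structure comparison
#'
#' Removes outliers, fits the candidate random-effects structures, compares
#' them, and summarises the preferred fit (performance metrics evaluated on
#' the unfiltered records).
#'
#' @inheritParams run_fixed_effects_analysis
#' @param structures named list of `list(random_terms=, grouping=)`
#'   candidates.
#' @param outlier_method passed to [detect_outliers()].
#' @return List with `comparison`, `preferred` (its name), `fit` (the
#'   preferred `rc_mixed_fit`), `summary` row and `outliers`.
#' @export
run_mixed_effects_analysis <- function(records, env,
                                       structures = list(
                                         Qmu_district = list(
                                           random_terms = c("Q", "mu"),
                                           grouping = "district"),
                                         QmuA_district = list(
                                           random_terms = c("Q", "mu",
                                                            "seasonal"),
                                           grouping = "district")),
                                       outlier_method = "robust_distance",
                                       seed = 1, out_dir = NULL) {
  out_rep <- detect_outliers(records, outlier_method, seed = seed)
  keep <- setdiff(seq_len(nrow(records)), out_rep$flagged_indices)
  filtered <- records[keep, , drop = FALSE]
  fits <- lapply(structures, function(st)
    fit_mixed(filtered, env, random_terms = st$random_terms,
              grouping = st$grouping, full_records = records))
  cmp <- compare_mixed(fits)
  pref <- attr(cmp, "preferred")
  fit <- fits[[pref]]
  out <- list(comparison = cmp, preferred = pref, fit = fit,
              summary = summarize_fit(fit, pref), outliers = out_rep)
  .write_outputs(list(comparison = cmp, summary = out$summary),
                 out_dir, "mixed_effects")
  out
}

#' Extrapolation scoring across model variants
#'
#' @inheritParams run_fixed_effects_analysis
#' @param variants model variants to score.
#' @param mode split mode.
#' @return Data frame with one row per variant: test RMSEs and their ratio.
#' @export
run_extrapolation_analysis <- function(records, env,
                                       variants = c("nu1", "nu2",
                                                    "nu_free"),
                                       mode = "by_time", n_restarts = 20,
                                       seed = 1, out_dir = NULL) {
  split <- split_records(records, mode, seed = seed)
  rows <- lapply(variants, function(v) {
    sc <- score_extrapolation(records, env, split, "robust", variant = v,
                              n_restarts = n_restarts, seed = seed)
    data.frame(variant = v, rmse_test_trainfit = sc$rmse_test_trainfit,
               rmse_test_fullfit = sc$rmse_test_fullfit,
               rmse_ratio = sc$rmse_ratio, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  .write_outputs(list(scores = out), out_dir, "extrapolation")
  out
}

#' Weighted-regression multimodel inference on zone/year summaries
#'
#' @param records zone/year summary records (see [read_chernobyl()]).
#' @param out_dir optional output directory.
#' @return List with `models` (AICc table), `mmi` (the `mmi_result`).
#' @export
run_chernobyl_analysis <- function(records, out_dir = NULL) {
  if (!"weight" %in% names(records)) records <- compute_weights(records)
  ms <- enumerate_models(records)
  mmi <- mmi_average(ms)
  .write_outputs(list(aicc = ms$table, coefficients = mmi$coefficients),
                 out_dir, "chernobyl")
  list(models = ms, mmi = mmi)
}
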