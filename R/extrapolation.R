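#' @name extrapolation_eval
#' @title Train/test splitting and forward-extrapolation scoring
#' @description
#' To judge how well a fitted model extrapolates beyond the fitted time
#' range, records are split into an early-time training half and a late-time
#' testing half (or at random, as a sensitivity check).  The model is fitted
#' to the training half and to the full data, both are scored on the testing
#' half, and the ratio of the two test RMSEs measures extrapolation quality
#' (a well-specified model gives a ratio near 1).
NULL

#' Split records into training and testing sets
#'
#' `"by_time"` assigns records with `T <= threshold` to training; the
#' default threshold is the sample median of `T`, which puts about half the
#' samples on each side.  `"random"` assigns each record to training with
#' probability `fraction`, reproducibly from `seed`; both halves then span
#' the full time range.
#'
#' @param records analysis-ready data frame.
#' @param mode `"by_time"` or `"random"`.
#' @param fraction training fraction (random mode).
#' @param threshold_t optional explicit time threshold (by_time mode).
#' @param seed integer seed (required for random mode).
#' @return List with `train`, `test` and `spec` (the resolved split
#'   specification).
#' @export
split_records <- function(records, mode = c("by_time", "random"),
                          fraction = 0.5, threshold_t = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  if (mode == "by_time") {
    thr <- if (is.null(threshold_t)) median(records$t_years) else threshold_t
    in_train <- records$t_years <= thr
    spec <- list(mode = mode, threshold_t = thr)
  } else {
    if (is.null(seed)) stop("random split requires a seed")
    n <- nrow(records)
    in_train <- with_seed(seed, {
      idx <- sample.int(n, size = round(fraction * n))
      seq_len(n) %in% idx
    })
    spec <- list(mode = mode, fraction = fraction, seed = seed)
  }
  if (!any(in_train) || all(in_train))
    stop("degenerate split: one side is empty")
  list(train = records[in_train, , drop = FALSE],
       test = records[!in_train, , drop = FALSE],
       spec = spec)
}

#' Score forward extrapolation of a fitted model
#'
#' Fits the chosen estimator to the training set and to the full data,
#' evaluates both on the testing set, and reports
#' `rmse_ratio = RMSE(test | train fit) / RMSE(test | full fit)` together
#' with per-parameter train/full ratios.  Ratio standard errors use
#' first-order error propagation assuming independence of the two fits
#' (they share data, so this is an approximation, flagged in the output).
#'
#' @param records analysis-ready data frame.
#' @param env an [environment_spec()].
#' @param split a list as returned by [split_records()]; alternatively pass
#'   `mode`/`fraction`/`seed` to split internally.
#' @param estimator `"robust"`, `"ols"` or `"quantile"`.
#' @param variant model variant passed to the estimator.
#' @param tau quantile level (quantile estimator only).
#' @param n_restarts,seed passed to the estimator.
#' @param ... further arguments for the estimator.
#' @return List with `rmse_test_trainfit`, `rmse_test_fullfit`,
#'   `rmse_ratio`, `parameter_ratios` (data frame), and the two fits.
#' @export
score_extrapolation <- function(records, env, split = NULL,
                                estimator = c("robust", "ols", "quantile"),
                                variant = "nu1", tau = 0.5,
                                n_restarts = 20, seed = 1, ...) {
  estimator <- match.arg(estimator)
  if (is.null(split)) split <- split_records(records, "by_time")
  fit_fun <- switch(estimator,
    robust = function(d) fit_robust(d, env, variant,
                                    n_restarts = n_restarts, seed = seed,
                                    ...),
    ols = function(d) fit_ols(d, env, variant, n_restarts = n_restarts,
                              seed = seed, ...),
    quantile = function(d) fit_quantile(d, env, tau = tau,
                                        variant = variant, n_boot = 0,
                                        seed = seed, ...))
  fit_train <- tryCatch(fit_fun(split$train), error = function(e)
    stop("estimator failed on training data: ", conditionMessage(e)))
  fit_full <- tryCatch(fit_fun(records), error = function(e)
    stop("estimator failed on full data: ", conditionMessage(e)))

  test_rmse <- function(fit) {
    pred <- predict(fit, split$test$t_years)
    sqrt(mean((split$test$lncs_c - pred)^2))
  }
  r_train <- test_rmse(fit_train)
  r_full <- test_rmse(fit_full)

  nm <- intersect(names(fit_train$params), names(fit_full$params))
  pt <- fit_train$params[nm]; pf <- fit_full$params[nm]
  st <- fit_train$se[nm]; sf <- fit_full$se[nm]
  ratio <- pt / pf
  se_ratio <- abs(ratio) * sqrt((st / pt)^2 + (sf / pf)^2)
  list(rmse_test_trainfit = r_train,
       rmse_test_fullfit = r_full,
       rmse_ratio = r_train / r_full,
       parameter_ratios = data.frame(
         parameter = nm, train = unname(pt), full = unname(pf),
         ratio = unname(ratio), se_ratio = unname(se_ratio),
         row.names = NULL),
       se_note = "ratio SEs assume independent train/full fits",
       fit_train = fit_train, fit_full = fit_full, spec = split$spec)
}

#' Export prediction curves over a time grid
#'
#' Figure-data export: model predictions for a list of fits over a regular
#' grid of times, in long format.
#'
#' @param fits named list of `rc_fit` objects.
#' @param t_grid numeric vector of times (years).
#' @return Data frame with `fit`, `t_years`, `lncs_pred`.
#' @export
prediction_curves <- function(fits, t_grid = seq(0, 7, by = 0.02)) {
  do.call(rbind, lapply(names(fits), function(nm) {
    data.frame(fit = nm, t_years = t_grid,
               lncs_pred = predict(fits[[nm]], t_grid))
  }))
}
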