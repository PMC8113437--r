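#' @name chernobyl_mmi
#' @title Weighted regression and multimodel inference for zone/year
#'   summaries
#' @description
#' When only per-zone, per-year summary statistics of 137Cs burdens are
#' available (number of animals, mean, minimum, maximum), the full seasonal
#' model cannot be fitted.  Instead, the land-contamination-adjusted mean
#' burden `LnMeanCs_c` is analysed by weighted linear regression on `Time`
#' and `Zone`, with approximately inverse-variance weights
#' `n / (ln(max) - ln(min))^2` normalised to mean 1.  All admissible
#' formulas over `{Time, Zone, Time:Zone}` (interaction only with both main
#' effects) are ranked by AICc, and multimodel inference averages the
#' coefficients over the model set with Akaike weights, unconditional
#' variances and per-term importance scores.
NULL

ZONE_LEVELS <- c("Alienation", "Permanent_control", "Periodic_control")

.zone_factor <- function(z) {
  z <- gsub("[ -]+", "_", trimws(as.character(z)))
  bad <- !z %in% ZONE_LEVELS
  if (any(bad)) stop("unknown zone label(s): ",
                     paste(unique(z[bad]), collapse = ", "))
  factor(z, levels = ZONE_LEVELS)  # Alienation is the reference level
}

#' Regression weights for zone/year summary records
#'
#' `weight = n_animals / (ln_max_cs - ln_min_cs)^2`, normalised so that the
#' mean weight across the analysis set is exactly 1.
#'
#' @param records data frame with `n_animals`, `ln_min_cs`, `ln_max_cs`.
#' @return `records` with a `weight` column.
#' @export
compute_weights <- function(records) {
  rng <- records$ln_max_cs - records$ln_min_cs
  if (any(!is.finite(rng) | rng <= 0)) {
    bad <- which(!is.finite(rng) | rng <= 0)
    stop("non-positive ln range in record(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  stopifnot(all(records$n_animals >= 1))
  raw <- records$n_animals / rng^2
  records$weight <- raw / mean(raw)
  records
}

#' Read a zone/year summary table
#'
#' Expects CSV columns `Zone, Time, N, LnMeanCs, LnMinCs, LnMaxCs,
#' LnMeanCs_c` and optionally `Weight` (recomputed when absent).
#'
#' @param path CSV path.
#' @return Data frame with normalised column names and a `weight` column.
#' @export
read_chernobyl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("Zone", "Time", "N", "LnMeanCs", "LnMinCs", "LnMaxCs",
            "LnMeanCs_c")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  rec <- data.frame(zone = as.character(raw$Zone),
                    time = as.numeric(raw$Time),
                    n_animals = as.integer(raw$N),
                    ln_mean_cs = as.numeric(raw$LnMeanCs),
                    ln_min_cs = as.numeric(raw$LnMinCs),
                    ln_max_cs = as.numeric(raw$LnMaxCs),
                    ln_mean_cs_c = as.numeric(raw$LnMeanCs_c),
                    stringsAsFactors = FALSE)
  .zone_factor(rec$zone)  # validates labels
  if ("Weight" %in% names(raw)) rec$weight <- as.numeric(raw$Weight)
  else rec <- compute_weights(rec)
  rec
}

.candidate_formulas <- function() {
  list(null = ln_mean_cs_c ~ 1,
       time = ln_mean_cs_c ~ time,
       zone = ln_mean_cs_c ~ zone,
       time_zone = ln_mean_cs_c ~ time + zone,
       time_x_zone = ln_mean_cs_c ~ time * zone)
}

#' Enumerate weighted regression models with AICc
#'
#' Fits every admissible formula over `{Time, Zone, Time:Zone}` (the
#' interaction only alongside both main effects) by weighted least squares
#' and ranks them by the small-sample-corrected Akaike criterion
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with `k` the number of estimated
#' parameters including the residual variance.  Models with too few residual
#' degrees of freedom are skipped with a warning.
#'
#' @param records data frame with `time`, `zone`, `ln_mean_cs_c`, `weight`.
#' @param use_weights fit weighted (default) or ordinary least squares.
#' @return Object of class `mmi_models`: a list of fitted models with an
#'   AICc table in `$table`.
#' @export
enumerate_models <- function(records, use_weights = TRUE) {
  stopifnot(length(unique(records$zone)) >= 2,
            length(unique(records$time)) >= 3)
  records$zone <- .zone_factor(records$zone)
  if (use_weights && is.null(records$weight))
    stop("records carry no weights; call compute_weights()")
  # lm() evaluates `weights` inside `data`, so carry them as a column
  records$.fit_weight <- if (use_weights) records$weight
  else rep(1, nrow(records))
  n <- nrow(records)
  fits <- list()
  for (nm in names(.candidate_formulas())) {
    f <- .candidate_formulas()[[nm]]
    k_mean <- qr(stats::model.matrix(f, records))$rank
    k <- k_mean + 1  # + residual variance
    if (n - k - 1 <= 0) {
      warning("skipping model '", nm, "': n too small for AICc")
      next
    }
    fit <- lm(f, data = records, weights = .fit_weight)
    aic <- AIC(fit)
    fits[[nm]] <- list(name = nm, formula = f, fit = fit, k = k,
                       aicc = aic + 2 * k * (k + 1) / (n - k - 1))
  }
  if (!length(fits)) stop("no admissible models")
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, `[[`, 0, "k"),
                    aicc = vapply(fits, `[[`, 0, "aicc"),
                    stringsAsFactors = FALSE)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$akaike_weight <- exp(-tab$delta_aicc / 2)
  tab$akaike_weight <- tab$akaike_weight / sum(tab$akaike_weight)
  tab <- tab[order(tab$aicc), , drop = FALSE]
  structure(list(models = fits, table = tab, n = n),
            class = "mmi_models")
}

#' @export
print.mmi_models <- function(x, ...) {
  cat("Weighted-regression model set (n =", x$n, "):\n")
  print(transform(x$table, aicc = round(aicc, 2),
                  delta_aicc = round(delta_aicc, 2),
                  akaike_weight = round(akaike_weight, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Multimodel-inference averaging over an AICc model set
#'
#' Computes Akaike weights from the AICc deltas and averages each
#' coefficient over the model set.  By default absent terms contribute zero
#' (full-model-set averaging); `conditional = TRUE` averages only over the
#' models containing the term.  Unconditional standard errors follow the
#' model-selection-uncertainty formula
#' `SE = sum_m w_m * sqrt(var_m + (beta_m - beta_bar)^2)`; importance is the
#' summed Akaike weight of models containing the term.  The ecological
#' decline rate is defined as the negative of the `time` slope on the
#' land-adjusted ln burden, and the derived half-life is `ln(2)/rate` with
#' an infinite bound whenever the rate's interval reaches zero; half-lives
#' are reported both for the averaged slope and for the single best model.
#'
#' @param models an `mmi_models` object from [enumerate_models()].
#' @param conf confidence level for the unconditional intervals.
#' @param conditional use conditional (subset) averaging instead of
#'   full-model-set averaging.
#' @return Object of class `mmi_result` with `coefficients` (data frame:
#'   estimate, unconditional SE and CI, importance), `akaike_weights`,
#'   `decline_rate`, `half_life` (averaged) and `half_life_best_model`.
#' @export
mmi_average <- function(models, conf = 0.95, conditional = FALSE) {
  stopifnot(inherits(models, "mmi_models"), length(models$models) >= 1)
  tab <- models$table
  w <- setNames(tab$akaike_weight, tab$model)
  all_terms <- unique(unlist(lapply(models$models, function(m)
    names(coef(m$fit)))))
  z <- qnorm(1 - (1 - conf) / 2)

  est <- se <- imp <- setNames(numeric(length(all_terms)), all_terms)
  for (term in all_terms) {
    bm <- vm <- wm <- numeric(0)
    for (nm in names(models$models)) {
      cf <- coef(models$models[[nm]]$fit)
      has <- term %in% names(cf)
      if (has) {
        bm <- c(bm, cf[[term]])
        vm <- c(vm, vcov(models$models[[nm]]$fit)[term, term])
        wm <- c(wm, w[[nm]])
      } else if (!conditional) {
        bm <- c(bm, 0); vm <- c(vm, 0); wm <- c(wm, w[[nm]])
      }
      if (has) imp[term] <- imp[term] + w[[nm]]
    }
    wm <- wm / sum(wm)
    b_bar <- sum(wm * bm)
    est[term] <- b_bar
    se[term] <- sum(wm * sqrt(vm + (bm - b_bar)^2))
  }

  coefs <- data.frame(term = all_terms, estimate = unname(est),
                      se_unconditional = unname(se),
                      lower = unname(est - z * se),
                      upper = unname(est + z * se),
                      importance = unname(pmin(imp, 1)),
                      row.names = NULL)

  slope_avg <- if ("time" %in% all_terms) est[["time"]] else 0
  slope_se <- if ("time" %in% all_terms) se[["time"]] else 0
  best_nm <- tab$model[1L]
  best_fit <- models$models[[best_nm]]$fit
  slope_best <- if ("time" %in% names(coef(best_fit)))
    coef(best_fit)[["time"]] else 0
  slope_best_se <- if ("time" %in% names(coef(best_fit)))
    sqrt(vcov(best_fit)["time", "time"]) else 0

  # decline rate: burdens decline when the time slope is negative
  rate_avg <- -slope_avg
  rate_best <- -slope_best
  structure(list(
    coefficients = coefs,
    akaike_weights = w,
    averaging = if (conditional) "conditional" else "full_model_set",
    decline_rate = list(estimate = rate_avg, se = slope_se),
    half_life = ecological_half_life(rate_avg, slope_se, conf),
    decline_rate_best_model = list(estimate = rate_best,
                                   se = slope_best_se, model = best_nm),
    half_life_best_model = ecological_half_life(rate_best, slope_best_se,
                                                conf),
    best_model = best_nm), class = "mmi_result")
}

#' @export
print.mmi_result <- function(x, ...) {
  cat("Multimodel inference (", x$averaging, " averaging); best model: ",
      x$best_model, "\n", sep = "")
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se_unconditional = round(se_unconditional, 4),
                  lower = round(lower, 4), upper = round(upper, 4),
                  importance = round(importance, 3)), row.names = FALSE)
  hl <- x$half_life
  cat(sprintf("Averaged decline rate: %.4f /y; half-life %.1f y (%.1f, %s)\n",
              x$decline_rate$estimate, hl$estimate, hl$lower,
              if (is.infinite(hl$upper)) "Inf" else sprintf("%.1f", hl$upper)))
  invisible(x)
}
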