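#' @name fit_mixed
#' @title Mixed-effects estimation with location random effects
#' @description
#' The `nu = 1` burden model is linear in `(Q, mu, a, b)` on the design
#' `(1, -T, sin(2*pi*T), cos(2*pi*T))`; [fit_mixed()] fits it by maximum
#' likelihood with `nlme::lme`, placing (diagonal) random effects on a
#' chosen subset of `{Q, mu, seasonal}` grouped by district or by
#' municipality nested in district, and optionally letting the residual
#' variance differ by district (`varIdent`).  Random-effect standard
#' deviations for the seasonal pair are mapped back to the `(A, P)` scale by
#' the delta method (an approximation, flagged in the output).  Model
#' performance (`R^2`, RMSE) is assessed on the full data set even when
#' outliers were removed before fitting.
NULL

#' Flag outlying records
#'
#' `"robust_distance"` computes robust Mahalanobis distances of
#' `(T, LnCs_c)` using the minimum covariance determinant estimate
#' (`MASS::cov.rob`) and flags records beyond the chi-square quantile
#' `threshold` (default 0.975, 2 degrees of freedom).  `"external_list"`
#' loads a verbatim exclusion list (CSV with a `Row` column of 1-based
#' indices into `records`).
#'
#' @param records analysis-ready data frame.
#' @param method `"robust_distance"` or `"external_list"`.
#' @param threshold chi-square probability for the cutoff.
#' @param path exclusion-list path (external_list only).
#' @param seed seed for the MCD subsampling.
#' @return List with `flagged_indices`, `method`, `scores` (squared robust
#'   distances; `NA` for external lists) and `cutoff`.
#' @export
detect_outliers <- function(records, method = c("robust_distance",
                                                "external_list"),
                            threshold = 0.975, path = NULL, seed = 1) {
  method <- match.arg(method)
  stopifnot(nrow(records) > 0)
  if (method == "external_list") {
    if (is.null(path) || !file.exists(path))
      stop("external exclusion list not found: ",
           if (is.null(path)) "<missing path>" else path)
    idx <- read.csv(path)$Row
    stopifnot(all(idx >= 1 & idx <= nrow(records)))
    return(list(flagged_indices = as.integer(idx), method = method,
                scores = rep(NA_real_, nrow(records)), cutoff = NA_real_))
  }
  x <- cbind(records$t_years, records$lncs_c)
  rob <- with_seed(seed, MASS::cov.rob(x, method = "mcd"))
  d2 <- mahalanobis(x, rob$center, rob$cov)
  cut <- qchisq(threshold, df = 2)
  list(flagged_indices = which(d2 > cut), method = method, scores = d2,
       cutoff = cut)
}

.varcorr_sd <- function(fit) {
  vc <- nlme::VarCorr(fit)
  rn <- rownames(vc)
  sd_col <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  names(sd_col) <- rn
  sd_col
}

#' Mixed-effects fit of the nu = 1 burden model
#'
#' @param records outlier-filtered analysis-ready data frame (needs
#'   `t_years`, `lncs_c`, `district`, and `municipality` for nested
#'   grouping).
#' @param env an [environment_spec()].
#' @param random_terms subset of `c("Q", "mu", "seasonal")` given random
#'   effects (diagonal covariance).
#' @param grouping `"district"` or `"district_municipality"` (municipality
#'   nested within district).
#' @param variance_by_district allow per-district residual variances
#'   (`varIdent`).
#' @param full_records optional unfiltered records on which `r_squared` and
#'   `rmse_full` are evaluated (defaults to `records`).
#' @param max_iter optimizer iteration caps.
#' @return Object of class `rc_mixed_fit`: fixed-effect `params`/`se`
#'   (Q, mu, A, P), `random_sd` per level, `district_variance_multipliers`,
#'   `loglik`, `aic`, `r_squared`, `rmse_full`, `structure`, and the
#'   underlying `lme` fit as `$fit`.
#' @export
fit_mixed <- function(records, env,
                      random_terms = c("Q", "mu", "seasonal"),
                      grouping = c("district", "district_municipality"),
                      variance_by_district = TRUE,
                      full_records = NULL, max_iter = 200) {
  grouping <- match.arg(grouping)
  stopifnot(all(random_terms %in% c("Q", "mu", "seasonal")),
            length(random_terms) >= 1)
  if (length(unique(records$district)) < 2)
    stop("need at least 2 districts for mixed-effects fitting")
  if (is.null(full_records)) full_records <- records

  build_df <- function(rec) {
    data.frame(y = rec$lncs_c - environment_term(rec$t_years, env),
               negt = -rec$t_years,
               s = sin(2 * pi * rec$t_years),
               c = cos(2 * pi * rec$t_years),
               district = factor(rec$district),
               municipality = factor(paste(rec$district, rec$municipality,
                                           sep = ":")))
  }
  df <- build_df(records)

  re_terms <- c(if ("Q" %in% random_terms) "1" else NULL,
                if ("mu" %in% random_terms) "negt" else NULL,
                if ("seasonal" %in% random_terms) c("s", "c") else NULL)
  re_form <- as.formula(paste("~",
                              if ("Q" %in% random_terms)
                                paste(re_terms, collapse = " + ")
                              else paste("-1 +",
                                         paste(re_terms, collapse = " + "))))
  random <- if (grouping == "district")
    list(district = nlme::pdDiag(re_form))
  else list(district = nlme::pdDiag(re_form),
            municipality = nlme::pdDiag(~1))
  wts <- if (variance_by_district) nlme::varIdent(form = ~1 | district)
  else NULL
  ctrl <- nlme::lmeControl(maxIter = max_iter, msMaxIter = max_iter,
                           niterEM = 50, opt = "optim",
                           returnObject = TRUE)
  fit <- try(nlme::lme(y ~ negt + s + c, data = df, random = random,
                       weights = wts, method = "ML", control = ctrl),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("mixed-effects fit failed: ", attr(fit, "condition")$message)

  fe <- nlme::fixed.effects(fit)
  Vfe <- vcov(fit)
  beta_ab <- setNames(fe[c("(Intercept)", "negt", "s", "c")],
                      c("q", "mu", "a", "b"))
  fin <- .finalize_params(beta_ab,
                          Vfe[c("(Intercept)", "negt", "s", "c"),
                              c("(Intercept)", "negt", "s", "c")],
                          nu = 1, nu_free = FALSE)

  # random-effect SDs, mapped to the reporting scale
  sds <- .varcorr_sd(fit)
  pick <- function(nm) if (nm %in% names(sds)) unname(sds[[nm]]) else NA_real_
  rand <- c(Q = pick("(Intercept)"), mu = pick("negt"))
  if ("seasonal" %in% random_terms) {
    sa <- pick("s"); sb <- pick("c")
    a <- beta_ab[["a"]]; b <- beta_ab[["b"]]
    amp <- sqrt(a^2 + b^2)
    # delta-method projection of the (a, b) random SDs onto (A, P)
    rand <- c(rand,
              A = sqrt((a^2 * sa^2 + b^2 * sb^2)) / amp,
              P = sqrt(b^2 * sa^2 + a^2 * sb^2) / (2 * pi * amp^2))
  } else rand <- c(rand, A = NA_real_, P = NA_real_)

  vmul <- if (variance_by_district) {
    cf <- coef(fit$modelStruct$varStruct, unconstrained = FALSE,
               allCoef = TRUE)
    setNames(as.numeric(cf), names(cf))
  } else NULL

  # performance on the full (unfiltered) data
  dff <- build_df(full_records)
  lev <- if (grouping == "district") 1 else 2
  preds <- tryCatch(as.numeric(predict(fit, newdata = dff, level = lev)),
                    error = function(e)
                      as.numeric(predict(fit, newdata = dff, level = 1)))
  obs <- full_records$lncs_c
  pred_ln <- preds + environment_term(full_records$t_years, env)
  rss <- sum((obs - pred_ln)^2)
  r2 <- 1 - rss / sum((obs - mean(obs))^2)

  structure(list(
    params = fin$params, se = fin$se, vcov = fin$vcov,
    coef_ab = beta_ab, random_sd = rand,
    district_variance_multipliers = vmul,
    loglik = as.numeric(logLik(fit)), aic = AIC(fit),
    r_squared = r2, rmse_full = sqrt(rss / length(obs)),
    structure = paste0("random {", paste(random_terms, collapse = ","),
                       "} by ", grouping,
                       if (variance_by_district) "; varIdent(district)"
                       else ""),
    n = nrow(df), n_full = nrow(dff),
    converged = TRUE, fit = fit, env = env,
    random_sd_note = "A/P random SDs are delta-method projections of the sin/cos pair",
    fingerprint = c(n = nrow(df), ysum = round(sum(df$y), 8))),
    class = "rc_mixed_fit")
}

#' @export
print.rc_mixed_fit <- function(x, ...) {
  cat("Mixed-effects fit:", x$structure, "\n")
  print(round(cbind(estimate = x$params, se = x$se,
                    random_sd = x$random_sd[names(x$params)]), 4))
  cat(sprintf("logLik = %.2f, AIC = %.2f; on full data R^2 = %.3f, RMSE = %.3f\n",
              x$loglik, x$aic, x$r_squared, x$rmse_full))
  invisible(x)
}

#' Compare mixed-effects structures
#'
#' Builds a comparison table (log-likelihood, AIC, delta AIC) over fits to
#' the same records, with likelihood-ratio p-values where one model's
#' random-effects structure is a declared subset of the next (compared by
#' degrees of freedom); non-nested pairs are reported by AIC only.  The
#' preferred model is the converged fit with the lowest AIC.
#'
#' @param results named list of `rc_mixed_fit` objects.
#' @return Data frame, with the preferred structure in
#'   `attr(, "preferred")`.
#' @export
compare_mixed <- function(results) {
  stopifnot(length(results) >= 1)
  fps <- vapply(results, function(f) paste(f$fingerprint, collapse = "/"), "")
  if (length(unique(fps)) != 1L)
    stop("mixed fits were not computed on the same records")
  df_mod <- vapply(results, function(f)
    attr(logLik(f$fit), "df"), 0)
  tab <- data.frame(
    structure = if (!is.null(names(results)) &&
                    all(nzchar(names(results)))) names(results)
    else vapply(results, `[[`, "", "structure"),
    df = df_mod,
    loglik = vapply(results, `[[`, 0, "loglik"),
    aic = vapply(results, `[[`, 0, "aic"),
    stringsAsFactors = FALSE)
  tab$delta_aic <- tab$aic - min(tab$aic)
  o <- order(tab$df)
  tab <- tab[o, , drop = FALSE]
  tab$lr_stat <- tab$lr_p <- NA_real_
  if (nrow(tab) > 1) {
    for (i in 2:nrow(tab)) {
      ddf <- tab$df[i] - tab$df[i - 1]
      lr <- max(2 * (tab$loglik[i] - tab$loglik[i - 1]), 0)
      tab$lr_stat[i] <- lr
      if (ddf > 0)
        tab$lr_p[i] <- pchisq(lr, df = ddf, lower.tail = FALSE)
    }
  }
  attr(tab, "preferred") <- tab$structure[which.min(tab$aic)]
  tab
}

#' Fligner-Killeen test of variance homogeneity by district
#'
#' @param records analysis-ready data frame with `district` and `lncs_c`.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
variance_homogeneity_test <- function(records) {
  g <- factor(records$district)
  if (nlevels(g) < 2) stop("need at least 2 districts")
  if (any(table(g) < 3)) stop("need at least 3 records per district")
  v <- tapply(records$lncs_c, g, var)
  if (all(v == 0)) stop("degenerate data: zero variance in every district")
  ft <- fligner.test(records$lncs_c, g)
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       df = unname(ft$parameter))
}
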