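#' @name fit_fixed
#' @title Fixed-effects estimation of the burden model
#' @description
#' For a fixed power `nu` the burden model is linear in `(Q, mu, a, b)` on
#' the design `(1, -T^nu, sin(2*pi*T), cos(2*pi*T))`, where `(a, b)` are the
#' harmonic coefficients equivalent to the canonical amplitude/phase pair
#' `(A, P)`.  [fit_ols()] exploits this: the multi-start nonlinear search is
#' accompanied by the closed-form linearised solution, which must agree.
#' [fit_robust()] performs M-estimation by iteratively reweighted least
#' squares (Huber or bisquare), selecting the restart winner by the smallest
#' absolute median residual.  [fit_quantile()] minimises the pinball (check)
#' loss.  Free `nu` is handled by profiling: the inner linear (or IRLS)
#' solve is nested inside a one-dimensional search over `nu` in `[0.1, 10]`.
NULL

NU_BOUNDS <- c(0.1, 10)

.variant_nu <- function(variant) {
  switch(variant, nu1 = 1, nu2 = 2, nu_free = NA_real_,
         stop("unknown variant: ", variant))
}

.design <- function(t_years, nu) {
  cbind(q = 1, mu = -(t_years^nu),
        a = sin(2 * pi * t_years), b = cos(2 * pi * t_years))
}

.prepare_xy <- function(records, env) {
  stopifnot(is.data.frame(records), nrow(records) >= 10,
            all(c("t_years", "lncs_c") %in% names(records)))
  t_years <- records$t_years
  list(t = t_years, y = records$lncs_c - environment_term(t_years, env))
}

.aic_rss <- function(rss, n, k) n * log(rss / n) + 2 * k

# closed-form weighted/ordinary LS on the linearised design
.ols_closed <- function(t_years, y, nu) {
  X <- .design(t_years, nu)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  r <- y - X %*% beta
  rss <- sum(r^2)
  p <- ncol(X)
  sigma2 <- rss / (length(y) - p)
  xtxi <- chol2inv(chol(crossprod(X)))
  list(beta = beta, rss = rss, resid = as.numeric(r),
       vcov = sigma2 * xtxi, sigma2 = sigma2, X = X)
}

# Gauss-Newton jacobian of the mean wrt (Q, mu, nu, a, b) at the optimum
.jacobian_free_nu <- function(t_years, mu, nu) {
  dnu <- ifelse(t_years > 0, -mu * t_years^nu * log(t_years), 0)
  cbind(q = 1, mu = -(t_years^nu), nu = dnu,
        a = sin(2 * pi * t_years), b = cos(2 * pi * t_years))
}

# Map a fit in (Q, mu, [nu], a, b) space with covariance to the reported
# (Q, mu, [nu], A, P) parameterisation via the delta method.
.finalize_params <- function(beta_ab, vcov_ab, nu, nu_free) {
  a <- beta_ab[["a"]]; b <- beta_ab[["b"]]
  ap <- ab_to_amp_phase(a, b)
  nm_in <- if (nu_free) c("q", "mu", "nu", "a", "b") else c("q", "mu", "a", "b")
  nm_out <- if (nu_free) c("Q", "mu", "nu", "A", "P") else c("Q", "mu", "A", "P")
  p <- length(nm_in)
  J <- diag(p)
  J[(p - 1):p, (p - 1):p] <- ab_jacobian(a, b)
  V <- J %*% vcov_ab %*% t(J)
  dimnames(V) <- list(nm_out, nm_out)
  params <- c(beta_ab[["q"]], beta_ab[["mu"]],
              if (nu_free) nu, ap[["amp"]], ap[["phase"]])
  names(params) <- nm_out
  se <- sqrt(pmax(diag(V), 0))
  list(params = params, se = se, vcov = V)
}

.new_fit <- function(method, variant, nu, nu_free, beta_ab, vcov_ab,
                     t_years, y, resid, env, n_restarts_used, converged,
                     objective, extra = list()) {
  fin <- .finalize_params(beta_ab, vcov_ab, nu, nu_free)
  n <- length(y)
  k <- length(beta_ab) + if (nu_free) 2L else 1L  # + sigma (+ nu)
  rss <- sum(resid^2)
  out <- c(list(
    method = method, variant = variant, nu = nu,
    params = fin$params, se = fin$se, vcov = fin$vcov,
    coef_ab = beta_ab,
    residuals = as.numeric(resid),
    fitted = as.numeric(y - resid + environment_term(t_years, env)),
    t_years = t_years, rss = rss, rmse = sqrt(rss / n),
    aic = .aic_rss(rss, n, k), n = n, k = k,
    n_restarts_used = n_restarts_used, converged = converged,
    objective = objective, env = env,
    fingerprint = c(n = n, ysum = round(sum(y), 8))),
    extra)
  class(out) <- c(paste0("rc_", method, "_fit"), "rc_fit")
  out
}

#' @export
print.rc_fit <- function(x, ...) {
  cat(sprintf("%s fit of the burden model (variant %s%s), n = %d\n",
              x$method, x$variant,
              if (!is.null(x$tau)) paste0(", tau = ", x$tau) else "", x$n))
  tab <- cbind(estimate = x$params, se = x$se)
  print(round(tab, 4))
  cat(sprintf("RMSE = %.4f; AIC = %.2f; converged: %s (%d restarts)\n",
              x$rmse, x$aic, x$converged, x$n_restarts_used))
  invisible(x)
}

#' Extract model parameters from a fit
#' @param fit an `rc_fit` object.
#' @return A [model_parameters()] object.
#' @export
as_model_parameters <- function(fit) {
  p <- fit$params
  model_parameters(q = p[["Q"]], mu = p[["mu"]], nu = fit$nu,
                   amp = p[["A"]], phase = p[["P"]])
}

#' Predict ln burdens from a fitted model
#' @param object an `rc_fit` object.
#' @param t_years times at which to predict.
#' @param ... unused.
#' @export
predict.rc_fit <- function(object, t_years, ...) {
  model_mean(t_years, as_model_parameters(object), object$env)
}

# ---------------------------------------------------------------- OLS -----

#' Multi-start nonlinear ordinary least squares
#'
#' Minimises the residual sum of squares of the burden model.  The fitting is
#' repeated from randomly perturbed initial values (multiplicative
#' `N(1, 0.1^2)` noise on each parameter of the linearised solution) and the
#' solution with the smallest RMSE is kept.  For fixed `nu` the closed-form
#' linearised solution is also computed (returned as `$closed_form`) and the
#' two must agree; for `nu = "nu_free"` the profile over `nu` in
#' `[0.1, 10]` is searched, seeded additionally from a coarse grid.
#'
#' @param records analysis-ready data frame (needs `t_years`, `lncs_c`).
#' @param env an [environment_spec()].
#' @param variant `"nu1"`, `"nu2"` or `"nu_free"`.
#' @param n_restarts number of random restarts (study profile: 2000; small
#'   values suffice for the convex fixed-`nu` case).
#' @param seed integer seed for the restart perturbations.
#' @return An `rc_fit` object.
#' @export
fit_ols <- function(records, env, variant = c("nu1", "nu2", "nu_free"),
                    n_restarts = 200, seed = 1) {
  variant <- match.arg(variant)
  xy <- .prepare_xy(records, env)
  t_years <- xy$t; y <- xy$y
  nu_free <- is.na(.variant_nu(variant))

  if (!nu_free) {
    nu <- .variant_nu(variant)
    cf <- .ols_closed(t_years, y, nu)
    X <- cf$X
    obj <- function(b) sum((y - X %*% b)^2)
    grad <- function(b) as.numeric(-2 * crossprod(X, y - X %*% b))
    best <- NULL
    with_seed(seed, {
      for (i in seq_len(max(1L, n_restarts))) {
        b0 <- cf$beta * if (i == 1L) 1 else rnorm(4, 1, 0.1)
        op <- optim(b0, obj, grad, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
        if (is.null(best) || op$value < best$value) best <- op
      }
    })
    beta <- setNames(best$par, colnames(X))
    r <- y - X %*% beta
    fit <- .new_fit("ols", variant, nu, FALSE, beta, cf$vcov, t_years, y,
                    r, env, max(1L, n_restarts), best$convergence == 0,
                    sqrt(best$value / length(y)))
    fit$closed_form <- .finalize_params(setNames(cf$beta, colnames(X)),
                                        cf$vcov, nu, FALSE)
    return(fit)
  }

  # free nu: profile RSS(nu) with inner closed-form solve
  prof <- function(nu) .ols_closed(t_years, y, nu)$rss
  grid <- seq(NU_BOUNDS[1], NU_BOUNDS[2], length.out = 25)
  nu_grid <- grid[which.min(vapply(grid, prof, 0))]
  best <- NULL
  with_seed(seed, {
    starts <- c(nu_grid, 1, pmin(pmax(1 * rnorm(max(0L, n_restarts - 2L),
                                                1, 0.1),
                                      NU_BOUNDS[1]), NU_BOUNDS[2]))
    for (nu0 in starts) {
      op <- optim(nu0, prof, method = "L-BFGS-B",
                  lower = NU_BOUNDS[1], upper = NU_BOUNDS[2],
                  control = list(factr = 1e4))
      if (is.null(best) || op$value < best$value) best <- op
    }
  })
  nu_hat <- best$par
  cf <- .ols_closed(t_years, y, nu_hat)
  beta <- setNames(c(cf$beta, nu_hat), c("q", "mu", "a", "b", "nu"))
  beta <- beta[c("q", "mu", "nu", "a", "b")]
  J <- .jacobian_free_nu(t_years, beta[["mu"]], nu_hat)
  sigma2 <- cf$rss / (length(y) - 5)
  V <- sigma2 * chol2inv(chol(crossprod(J)))
  .new_fit("ols", variant, nu_hat, TRUE, beta, V, t_years, y, cf$resid,
           env, length(best), best$convergence == 0,
           sqrt(cf$rss / length(y)))
}

# ------------------------------------------------------------- robust -----

.psi_fun <- function(psi, tuning) {
  if (psi == "huber") {
    k <- if (is.null(tuning)) 1.345 else tuning
    list(wt = function(u) pmin(1, k / pmax(abs(u), 1e-12)),
         psi = function(u) pmax(-k, pmin(k, u)),
         dpsi = function(u) as.numeric(abs(u) <= k),
         rho = function(u) ifelse(abs(u) <= k, u^2 / 2, k * abs(u) - k^2 / 2))
  } else if (psi == "bisquare") {
    cc <- if (is.null(tuning)) 4.685 else tuning
    list(wt = function(u) ifelse(abs(u) < cc, (1 - (u / cc)^2)^2, 0),
         psi = function(u) ifelse(abs(u) < cc, u * (1 - (u / cc)^2)^2, 0),
         dpsi = function(u) ifelse(abs(u) < cc,
                                   (1 - (u / cc)^2) * (1 - 5 * (u / cc)^2), 0),
         rho = function(u) ifelse(abs(u) < cc,
                                  cc^2 / 6 * (1 - (1 - (u / cc)^2)^3),
                                  cc^2 / 6))
  } else stop("unknown psi: ", psi)
}

.irls <- function(X, y, beta0, fam, max_iter = 50, tol = 1e-9) {
  beta <- beta0
  converged <- FALSE
  s <- 1; r <- y - X %*% beta
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    s <- max(mad(r), 1e-8 * (sd(y) + 1e-12))
    w <- fam$wt(as.numeric(r) / s)
    newb <- lm.wfit(X, y, pmax(w, 1e-10))$coefficients
    if (max(abs(newb - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- newb; converged <- TRUE; break
    }
    beta <- newb
  }
  r <- as.numeric(y - X %*% beta)
  s <- max(mad(r), 1e-8 * (sd(y) + 1e-12))
  list(beta = beta, resid = r, scale = s,
       weights = fam$wt(r / s), converged = converged, iter = it)
}

# M-estimation covariance (Huber 1981 / MASS-style, with the finite-sample
# correction factor K).
.robust_vcov <- function(J, resid, scale, fam) {
  n <- nrow(J); p <- ncol(J)
  u <- resid / scale
  psiu <- fam$psi(u); dpsiu <- fam$dpsi(u)
  mdp <- mean(dpsiu)
  K <- 1 + p * var(dpsiu) / (n * mdp^2)
  s2 <- scale^2 * sum(psiu^2) / (n - p) / mdp^2
  K^2 * s2 * chol2inv(chol(crossprod(J)))
}

#' Robust M-regression of the burden model
#'
#' Iteratively reweighted least squares with a median-absolute-deviation
#' residual scale and a Huber (default, tuning 1.345) or Tukey bisquare
#' (tuning 4.685) weight function.  The procedure is restarted from randomly
#' perturbed initial values and the restart winner is the solution with the
#' smallest absolute value of the median residual.  Standard errors use the
#' standard M-estimation sandwich with a finite-sample correction.
#'
#' @inheritParams fit_ols
#' @param psi `"huber"` or `"bisquare"`.
#' @param tuning optional tuning constant overriding the default.
#' @param max_iter IRLS iteration cap; non-convergence is flagged on the
#'   result, and the best iterate is returned.
#' @return An `rc_fit` with robustness `weights`, `scale` and
#'   `median_abs_residual` fields.
#' @export
fit_robust <- function(records, env, variant = c("nu1", "nu2", "nu_free"),
                       psi = c("huber", "bisquare"), n_restarts = 50,
                       seed = 1, tuning = NULL, max_iter = 50) {
  variant <- match.arg(variant)
  psi <- match.arg(psi)
  fam <- .psi_fun(psi, tuning)
  xy <- .prepare_xy(records, env)
  t_years <- xy$t; y <- xy$y
  nu_free <- is.na(.variant_nu(variant))

  run_at_nu <- function(nu, beta0) .irls(.design(t_years, nu), y, beta0,
                                         fam, max_iter = max_iter)

  if (!nu_free) {
    nu <- .variant_nu(variant)
    cf <- .ols_closed(t_years, y, nu)
    best <- NULL
    with_seed(seed, {
      for (i in seq_len(max(1L, n_restarts))) {
        b0 <- cf$beta * if (i == 1L) 1 else rnorm(4, 1, 0.1)
        res <- run_at_nu(nu, b0)
        score <- abs(median(res$resid))
        if (is.null(best) || score < best$score)
          best <- c(res, list(score = score))
      }
    })
    X <- .design(t_years, nu)
    V <- .robust_vcov(X, best$resid, best$scale, fam)
    fit <- .new_fit("robust", variant, nu, FALSE,
                    setNames(best$beta, colnames(X)), V, t_years, y,
                    best$resid, env, max(1L, n_restarts), best$converged,
                    best$score,
                    extra = list(psi = psi, weights = best$weights,
                                 scale = best$scale,
                                 median_abs_residual = best$score))
    return(fit)
  }

  # free nu: robust criterion profiled over nu
  crit <- function(nu) {
    res <- run_at_nu(nu, .ols_closed(t_years, y, nu)$beta)
    res$scale^2 * sum(fam$rho(res$resid / res$scale))
  }
  grid <- seq(NU_BOUNDS[1], NU_BOUNDS[2], length.out = 25)
  nu_grid <- grid[which.min(vapply(grid, crit, 0))]
  best_nu <- NULL
  with_seed(seed, {
    starts <- c(nu_grid, 1,
                pmin(pmax(rnorm(max(0L, n_restarts - 2L), 1, 0.1),
                          NU_BOUNDS[1]), NU_BOUNDS[2]))
    for (nu0 in starts) {
      op <- optim(nu0, crit, method = "L-BFGS-B", lower = NU_BOUNDS[1],
                  upper = NU_BOUNDS[2], control = list(factr = 1e6))
      if (is.null(best_nu) || op$value < best_nu$value) best_nu <- op
    }
  })
  nu_hat <- best_nu$par
  res <- run_at_nu(nu_hat, .ols_closed(t_years, y, nu_hat)$beta)
  beta <- setNames(c(res$beta[1:2], nu_hat, res$beta[3:4]),
                   c("q", "mu", "nu", "a", "b"))
  J <- .jacobian_free_nu(t_years, beta[["mu"]], nu_hat)
  V <- .robust_vcov(J, res$resid, res$scale, fam)
  .new_fit("robust", variant, nu_hat, TRUE, beta, V, t_years, y, res$resid,
           env, length(best_nu), res$converged, abs(median(res$resid)),
           extra = list(psi = psi, weights = res$weights, scale = res$scale,
                        median_abs_residual = abs(median(res$resid))))
}

# ----------------------------------------------------------- quantile -----

.pinball <- function(r, tau) mean(r * (tau - (r < 0)))

.quantile_irls <- function(X, y, beta0, tau, max_iter = 100, tol = 1e-10) {
  beta <- beta0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- as.numeric(y - X %*% beta)
    eps <- 1e-6 * max(1, mad(r))
    w <- abs(tau - (r < 0)) / pmax(abs(r), eps)
    newb <- lm.wfit(X, y, w)$coefficients
    if (max(abs(newb - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- newb; converged <- TRUE; break
    }
    beta <- newb
  }
  list(beta = beta, converged = converged)
}

#' Nonlinear quantile regression by pinball loss
#'
#' Estimates the conditional `tau`-quantile of the burden model by
#' minimising the asymmetric absolute (pinball/check) loss, via iteratively
#' reweighted least squares followed by a Nelder-Mead polish on the exact
#' loss.  Initial estimates come from the robust fit (study procedure).
#' Standard errors are by nonparametric case-resampling bootstrap; the
#' bootstrap draws are transformed to the canonical `(A, P)` scale with the
#' phase unwrapped around the point estimate.
#'
#' @inheritParams fit_ols
#' @param tau quantile level, e.g. 0.25, 0.5, 0.75.
#' @param init an `rc_fit`, [model_parameters()] or `NULL` (robust fit is
#'   then computed internally).
#' @param n_boot bootstrap resamples for standard errors (study profile:
#'   500); `0` skips bootstrap (SEs `NA`).
#' @param seed integer seed for the bootstrap.
#' @return An `rc_fit` (AIC is `NA`: the pinball loss has no RSS-based AIC).
#' @export
fit_quantile <- function(records, env, tau, variant = c("nu1", "nu2"),
                         init = NULL, n_boot = 500, seed = 1) {
  variant <- match.arg(variant)
  stopifnot(length(tau) == 1, tau > 0, tau < 1)
  nu <- .variant_nu(variant)
  xy <- .prepare_xy(records, env)
  t_years <- xy$t; y <- xy$y
  if (length(unique(y)) < 8) stop("too few distinct values for quantile fit")
  X <- .design(t_years, nu)

  beta0 <- if (is.null(init)) {
    rf <- fit_robust(records, env, variant, n_restarts = 10, seed = seed)
    rf$coef_ab
  } else if (inherits(init, "rc_fit")) init$coef_ab
  else if (inherits(init, "model_parameters"))
    c(q = init$q, mu = init$mu, amp_phase_to_ab(init$amp, init$phase))
  else stop("unsupported 'init'")
  beta0 <- beta0[c("q", "mu", "a", "b")]

  solve_once <- function(Xm, ym, b0, polish = TRUE) {
    qi <- .quantile_irls(Xm, ym, b0, tau)
    beta <- qi$beta
    if (polish) {
      op <- optim(beta, function(b) .pinball(as.numeric(ym - Xm %*% b), tau),
                  method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
      if (op$value <= .pinball(as.numeric(ym - Xm %*% beta), tau))
        beta <- op$par
    }
    setNames(beta, colnames(Xm))
  }

  beta <- solve_once(X, y, beta0)
  r <- as.numeric(y - X %*% beta)
  obj <- .pinball(r, tau)

  # bootstrap SEs on the reported (Q, mu, A, P) scale
  se <- rep(NA_real_, 4); V <- matrix(NA_real_, 4, 4)
  ap_hat <- ab_to_amp_phase(beta[["a"]], beta[["b"]])
  if (n_boot > 0) {
    draws <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(length(y), replace = TRUE)
        bb <- solve_once(X[idx, , drop = FALSE], y[idx], beta,
                         polish = FALSE)
        ap <- ab_to_amp_phase(bb[["a"]], bb[["b"]])
        # unwrap phase around the point estimate
        ph <- ap_hat[["phase"]] +
          (((ap[["phase"]] - ap_hat[["phase"]]) + 0.5) %% 1) - 0.5
        c(Q = bb[["q"]], mu = bb[["mu"]], A = ap[["amp"]], P = ph)
      }, numeric(4))
    })
    V <- stats::cov(t(draws))
    se <- sqrt(diag(V))
  }

  fin_names <- c("Q", "mu", "A", "P")
  params <- setNames(c(beta[["q"]], beta[["mu"]], ap_hat[["amp"]],
                       ap_hat[["phase"]]), fin_names)
  dimnames(V) <- list(fin_names, fin_names)
  out <- list(method = "quantile", variant = variant, nu = nu, tau = tau,
              params = params, se = setNames(se, fin_names), vcov = V,
              coef_ab = beta, residuals = r,
              fitted = y - r + environment_term(t_years, env),
              t_years = t_years, rss = sum(r^2),
              rmse = sqrt(mean(r^2)), aic = NA_real_, n = length(y),
              k = 5L, n_restarts_used = 1L, converged = TRUE,
              objective = obj, env = env, n_boot = n_boot,
              fingerprint = c(n = length(y), ysum = round(sum(y), 8)))
  class(out) <- c("rc_quantile_fit", "rc_fit")
  out
}

# --------------------------------------------------- comparison, checks ---

#' Compare model variants by AIC
#'
#' AIC is computed as `n*log(RSS/n) + 2k` with `k` counting the mean
#' parameters plus the residual scale; only differences between variants fit
#' to the same records are meaningful, and the records are checked to match.
#'
#' @param fits named list of `rc_fit` objects on identical records.
#' @return Data frame with `variant`, `k`, `rss`, `aic`, `delta_aic`
#'   (against the best), ordered by AIC.
#' @export
compare_variants <- function(fits) {
  stopifnot(length(fits) >= 1)
  fps <- vapply(fits, function(f) paste(f$fingerprint, collapse = "/"), "")
  if (length(unique(fps)) != 1L)
    stop("fits were not computed on the same records")
  tab <- data.frame(
    variant = if (!is.null(names(fits)) && all(nzchar(names(fits))))
      names(fits) else vapply(fits, `[[`, "", "variant"),
    k = vapply(fits, `[[`, 0L, "k"),
    rss = vapply(fits, `[[`, 0, "rss"),
    aic = vapply(fits, `[[`, 0, "aic"),
    stringsAsFactors = FALSE)
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab[order(tab$aic), , drop = FALSE]
}

#' Residual diagnostics for a fitted model
#'
#' Computes the Shapiro-Wilk normality p-value, moment skewness and
#' (non-excess) kurtosis, autocorrelations with `±1.96/sqrt(n)` bands, the
#' slope of residuals regressed on time, and (when districts are available)
#' the Fligner-Killeen homogeneity-of-variances p-value by district.
#'
#' @param fit an `rc_fit`.
#' @param records the records the fit was computed on (for `t_years` and
#'   `district`); defaults to the times stored in the fit.
#' @param lag_max maximum autocorrelation lag.
#' @return Object of class `diagnostics_report`.
#' @export
diagnose <- function(fit, records = NULL, lag_max = 20) {
  r <- fit$residuals
  n <- length(r)
  if (n < 3) stop("need at least 3 residuals")
  z <- (r - mean(r)) / sd(r)
  sw <- if (n <= 5000) shapiro.test(r)$p.value
  else shapiro.test(r[round(seq(1, n, length.out = 5000))])$p.value
  ac <- acf(r, lag.max = min(lag_max, n - 1), plot = FALSE)
  tt <- if (!is.null(records)) records$t_years else fit$t_years
  trend <- unname(coef(lm(r ~ tt))[2L])
  fk <- NA_real_
  if (!is.null(records) && "district" %in% names(records) &&
      length(unique(records$district)) >= 2) {
    fk <- tryCatch(fligner.test(r, factor(records$district))$p.value,
                   error = function(e) NA_real_)
  }
  structure(list(shapiro_wilk_p = sw,
                 skewness = mean(z^3),
                 kurtosis = mean(z^4),
                 acf = as.numeric(ac$acf)[-1L],
                 acf_band = 1.96 / sqrt(n),
                 residual_trend_slope = trend,
                 fligner_killeen_p = fk, n = n),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("Residual diagnostics (n = %d):\n", x$n))
  cat(sprintf("  Shapiro-Wilk p = %.3g; skewness = %.3f; kurtosis = %.3f\n",
              x$shapiro_wilk_p, x$skewness, x$kurtosis))
  cat(sprintf("  trend slope = %.4f /y; lag-1 acf = %.3f (band +/- %.3f)\n",
              x$residual_trend_slope, x$acf[1L], x$acf_band))
  if (!is.na(x$fligner_killeen_p))
    cat(sprintf("  Fligner-Killeen by district: p = %.3g\n",
                x$fligner_killeen_p))
  invisible(x)
}
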