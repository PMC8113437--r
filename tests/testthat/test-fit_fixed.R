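test_that("noiseless data are recovered exactly and restarts agree with the closed form", {
  env <- default_env()
  tr <- model_parameters(q = -5.2, mu = 0.21, nu = 1, amp = 0.55,
                         phase = 0.31)
  rec <- generate_fukushima(simulation_config(
    truth = tr, n_samples = 200, noise_sd_by_district = 0, seed = 2))$records
  fit <- fit_ols(rec, env, "nu1", n_restarts = 10, seed = 1)
  expect_equal(unname(fit$params[c("Q", "mu", "A", "P")]),
               c(tr$q, tr$mu, tr$amp, tr$phase), tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-8)

  # multi-start nonlinear optimum vs linear-algebra closed form
  for (s in 1:5) {
    fx <- random_fixture(s)
    f <- fit_ols(fx$records, env, "nu1", n_restarts = 10, seed = s)
    expect_lt(max(abs(f$params - f$closed_form$params)), 1e-6)
    expect_lt(max(abs(f$se - f$closed_form$se)), 1e-6)
  }
})

test_that("free-nu profile fit finds strong curvature and its uncertainty", {
  env <- default_env()
  tr2 <- model_parameters(q = -4.8, mu = 0.12, nu = 2, amp = 0.6,
                          phase = 0.4)
  rec <- generate_fukushima(simulation_config(
    truth = tr2, n_samples = 800, noise_sd_by_district = 0.5,
    seed = 31))$records
  f <- fit_ols(rec, env, "nu_free", n_restarts = 10, seed = 1)
  expect_equal(f$params[["nu"]], 2, tolerance = 0.15)
  expect_true(f$se[["nu"]] > 0)
  # the fixed nu2 variant must agree with the free fit at its optimum
  f2 <- fit_ols(rec, env, "nu2", n_restarts = 5, seed = 1)
  expect_lt(f$rss, f2$rss + 1e-6)
})

test_that("hand-rolled robust IRLS matches MASS::rlm on the linearised design", {
  env <- default_env()
  rec <- quick_records(n = 400, seed = 12, outlier_fraction = 0.08)
  fit <- fit_robust(rec, env, "nu1", psi = "huber", n_restarts = 10,
                    seed = 1)
  y <- rec$lncs_c - environment_term(rec$t_years, env)
  X <- radcesium:::.design(rec$t_years, 1)
  oracle <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                      scale.est = "MAD", maxit = 100)
  expect_equal(unname(fit$coef_ab), unname(coef(oracle)), tolerance = 1e-3)
  # scale and standard errors in the same ballpark as the oracle's
  expect_equal(fit$scale, oracle$s, tolerance = 0.05)
  expect_equal(unname(fit$se[c("Q", "mu")]),
               unname(sqrt(diag(vcov(oracle)))[1:2]), tolerance = 0.08)
})

test_that("robustness weights are 1 at zero residual and non-increasing", {
  env <- default_env()
  rec <- quick_records(n = 300, seed = 9, outlier_fraction = 0.05)
  for (psi in c("huber", "bisquare")) {
    fit <- fit_robust(rec, env, "nu1", psi = psi, n_restarts = 5, seed = 1)
    expect_true(all(fit$weights >= 0 & fit$weights <= 1))
    o <- order(abs(fit$residuals))
    expect_true(all(diff(fit$weights[o]) <= 1e-12))
    expect_equal(fit$weights[o][1], 1, tolerance = 0.05)
    expect_equal(fit$objective, abs(median(fit$residuals)))
  }
})

test_that("robust fit resists gross contamination better than least squares", {
  env <- default_env()
  wins <- logical(40)
  err_r <- err_o <- numeric(40)
  for (i in seq_len(40)) {
    rec <- quick_records(n = 700, seed = 600 + i, outlier_fraction = 0.1)
    fr <- fit_robust(rec, env, "nu1", n_restarts = 3, seed = i)
    fo <- fit_ols(rec, env, "nu1", n_restarts = 1, seed = i)
    err_r[i] <- abs(fr$params[["mu"]] - 0.173)
    err_o[i] <- abs(fo$params[["mu"]] - 0.173)
    wins[i] <- err_r[i] < err_o[i]
  }
  expect_gt(mean(wins), 0.5)
  expect_lt(sqrt(mean(err_r^2)), sqrt(mean(err_o^2)))

  # and on clean data robust is close to OLS
  rec <- quick_records(n = 700, seed = 77)
  fr <- fit_robust(rec, env, "nu1", n_restarts = 3, seed = 1)
  fo <- fit_ols(rec, env, "nu1", n_restarts = 1, seed = 1)
  expect_true(all(abs(fr$params - fo$params) < 2 * fo$se))
})

test_that("quantile fits estimate conditional quantiles and their spread", {
  env <- default_env()
  rec <- quick_records(n = 900, seed = 15)
  rob <- fit_robust(rec, env, "nu1", n_restarts = 5, seed = 1)
  q50 <- fit_quantile(rec, env, 0.5, "nu1", init = rob, n_boot = 60,
                      seed = 1)
  # symmetric noise: median fit agrees with the central fit
  expect_true(all(abs(q50$params[c("Q", "mu")] -
                        rob$params[c("Q", "mu")]) <
                    2.5 * sqrt(q50$se[c("Q", "mu")]^2 +
                                 rob$se[c("Q", "mu")]^2)))
  expect_true(all(is.finite(q50$se)))

  # Gaussian noise of SD 1 shifts the conditional quantile surfaces by
  # 2*qnorm(.75); the intercept gap carries more simulation noise than the
  # averaged prediction gap, so both are checked at matching tolerances
  q25 <- fit_quantile(rec, env, 0.25, "nu1", init = rob, n_boot = 0)
  q75 <- fit_quantile(rec, env, 0.75, "nu1", init = rob, n_boot = 0)
  gap <- q75$params[["Q"]] - q25$params[["Q"]]
  expect_lt(abs(gap - 2 * qnorm(0.75)), 0.35)
  pred_gap <- mean(predict(q75, rec$t_years) - predict(q25, rec$t_years))
  expect_lt(abs(pred_gap - 2 * qnorm(0.75)), 0.12)
  # each fit is a genuine sample quantile: tau of residuals lie below it
  expect_equal(mean(q25$residuals < 0), 0.25, tolerance = 0.02)
  expect_equal(mean(q75$residuals < 0), 0.75, tolerance = 0.02)

  # fitted quantile curves are ordered in tau at the mean time
  tbar <- mean(rec$t_years)
  preds <- c(predict(q25, tbar), predict(q50, tbar), predict(q75, tbar))
  expect_true(all(diff(preds) > 0))

  # pinball objective at tau=0.5 is half the mean absolute residual
  expect_equal(q50$objective, mean(abs(q50$residuals)) / 2,
               tolerance = 1e-12)
  expect_error(fit_quantile(rec, env, 0.5, "nu_free"))
})

test_that("AIC comparison ranks variants fitted to the same records", {
  env <- default_env()
  rec <- quick_records(n = 1200, seed = 41, noise_sd = 0.3)
  f1 <- fit_ols(rec, env, "nu1", n_restarts = 3, seed = 1)
  f1b <- fit_ols(rec, env, "nu1", n_restarts = 7, seed = 2)
  ff <- fit_ols(rec, env, "nu_free", n_restarts = 5, seed = 1)
  tab <- compare_variants(list(a = f1, b = f1b, free = ff))
  expect_equal(tab$delta_aic[tab$variant == "a"],
               tab$delta_aic[tab$variant == "b"], tolerance = 1e-6)
  # truth has nu = 1: the extra free parameter cannot help much
  expect_equal(ff$params[["nu"]], 1, tolerance = 0.25)
  expect_lt(abs(tab$delta_aic[tab$variant == "free"] -
                  tab$delta_aic[tab$variant == "a"]), 4)

  # strong nu=2 truth: nu2 variant wins by a wide AIC margin
  tr2 <- model_parameters(q = -4.8, mu = 0.12, nu = 2, amp = 0.6,
                          phase = 0.4)
  rec2 <- generate_fukushima(simulation_config(
    truth = tr2, n_samples = 1000, noise_sd_by_district = 0.8,
    seed = 19))$records
  g1 <- fit_ols(rec2, env, "nu1", n_restarts = 3, seed = 1)
  g2 <- fit_ols(rec2, env, "nu2", n_restarts = 3, seed = 1)
  tab2 <- compare_variants(list(nu1 = g1, nu2 = g2))
  expect_equal(tab2$variant[1], "nu2")
  expect_gt(tab2$delta_aic[tab2$variant == "nu1"], 10)

  expect_error(compare_variants(list(f1, fit_ols(rec2, env, "nu1"))),
               "same records")
})

test_that("residual diagnostics flag non-normality and autocorrelation", {
  env <- default_env()
  rec <- quick_records(n = 1000, seed = 55)
  fit <- fit_ols(rec, env, "nu1", n_restarts = 2, seed = 1)
  d <- diagnose(fit, rec)
  expect_true(d$shapiro_wilk_p > 1e-4)       # Gaussian noise by design
  expect_lt(abs(d$skewness), 0.25)
  expect_true(d$kurtosis > 2.5 && d$kurtosis < 3.6)
  expect_lt(abs(d$residual_trend_slope), 0.05)
  expect_true(is.finite(d$fligner_killeen_p))

  # plant strong lag-1 structure
  fit2 <- fit
  fit2$residuals <- as.numeric(stats::arima.sim(list(ar = 0.8), n = fit$n))
  d2 <- diagnose(fit2, rec)
  expect_gt(abs(d2$acf[1]), d2$acf_band)

  fit3 <- fit; fit3$residuals <- fit$residuals[1:2]
  expect_error(diagnose(fit3), "at least 3")
})
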