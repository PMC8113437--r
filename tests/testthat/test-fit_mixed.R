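test_that("robust-distance outlier detection flags planted points only", {
  set.seed(8)
  n <- 500
  clean <- data.frame(t_years = runif(n, 0.2, 7),
                      lncs_c = rnorm(n, 8, 1))
  rep_clean <- detect_outliers(clean, "robust_distance")
  expect_lt(length(rep_clean$flagged_indices) / n, 0.08)

  planted <- clean
  planted$lncs_c[1:5] <- planted$lncs_c[1:5] + 8  # 8 SDs off
  rep_pl <- detect_outliers(planted, "robust_distance")
  expect_true(all(1:5 %in% rep_pl$flagged_indices))
  expect_true(all(rep_pl$scores[1:5] > rep_pl$cutoff))

  # external list path loads a verbatim exclusion list
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(Row = c(2L, 9L)), f, row.names = FALSE)
  rep_ext <- detect_outliers(clean, "external_list", path = f)
  expect_identical(rep_ext$flagged_indices, c(2L, 9L))
  expect_error(detect_outliers(clean, "external_list"), "not found")
})

test_that("with no district variation the mixed model collapses to the fixed fit", {
  env <- default_env()
  rec <- quick_records(n = 800, seed = 23, noise_sd = 0.8)
  mf <- fit_mixed(rec, env, random_terms = c("Q", "mu"),
                  grouping = "district", variance_by_district = FALSE)
  ols <- fit_ols(rec, env, "nu1", n_restarts = 2, seed = 1)
  expect_lt(max(abs(mf$params - ols$params[c("Q", "mu", "A", "P")])), 1e-3)
  expect_true(all(mf$random_sd[c("Q", "mu")] < 0.05))
  expect_true(mf$r_squared <= 1)
  # frozen R^2 definition: 1 - RSS/TSS on the ln burden scale
  pred <- predict(mf$fit, level = 1) + environment_term(rec$t_years, env)
  r2_manual <- 1 - sum((rec$lncs_c - pred)^2) /
    sum((rec$lncs_c - mean(rec$lncs_c))^2)
  expect_equal(mf$r_squared, r2_manual, tolerance = 1e-10)
})

test_that("known district intercept variation is recovered", {
  env <- default_env()
  ok <- logical(5)
  for (i in seq_len(5)) {
    rec <- quick_records(n = 1200, seed = 400 + i, noise_sd = 0.7,
                         n_districts = 20,
                         district_sd = c(q = 0.5))
    mf <- fit_mixed(rec, env, random_terms = "Q", grouping = "district",
                    variance_by_district = FALSE)
    ok[i] <- mf$random_sd[["Q"]] > 0.32 && mf$random_sd[["Q"]] < 0.68
  }
  expect_gte(sum(ok), 4)
})

test_that("structure comparison prefers real hierarchy and reports LR tests", {
  env <- default_env()
  rec <- quick_records(n = 900, seed = 61, noise_sd = 0.7,
                       n_districts = 12, district_sd = c(q = 0.6))
  m0 <- fit_mixed(rec, env, random_terms = "Q", grouping = "district",
                  variance_by_district = FALSE)
  m1 <- fit_mixed(rec, env, random_terms = c("Q", "mu"),
                  grouping = "district", variance_by_district = FALSE)
  cmp <- compare_mixed(list(q_only = m0, q_mu = m1))
  expect_equal(cmp$delta_aic[cmp$structure == attr(cmp, "preferred")], 0)
  expect_true(all(is.finite(cmp$loglik)))
  # identical structures tie exactly
  cmp2 <- compare_mixed(list(a = m0, b = m0))
  expect_equal(diff(cmp2$aic), 0)
  expect_equal(cmp2$lr_stat[2], 0)

  # district variation present: random-intercept model beats plain OLS by a
  # likelihood-ratio test (chi-square vs the linear model likelihood)
  lin <- lm(I(rec$lncs_c - environment_term(rec$t_years, env)) ~
              I(-rec$t_years) + sin(2 * pi * rec$t_years) +
              cos(2 * pi * rec$t_years))
  lr <- 2 * (m0$loglik - as.numeric(logLik(lin)))
  expect_gt(lr, qchisq(0.95, 1))
})

test_that("per-district variances are detected and estimated", {
  env <- default_env()
  rec <- quick_records(n = 1200, seed = 71,
                       noise_sd = c(0.5, 0.5, 1.5, 0.5, 0.5, 0.5, 0.5))
  vt <- variance_homogeneity_test(rec)
  expect_lt(vt$p_value, 0.01)

  mf <- fit_mixed(rec, env, random_terms = "Q", grouping = "district",
                  variance_by_district = TRUE)
  vm <- mf$district_variance_multipliers
  # the inflated district (Kenchu, third in the layout) stands out ~3x
  expect_gt(vm[["Kenchu"]] / median(vm), 2)

  # homogeneous data: test well calibrated (no tiny p), degenerate errors
  rec0 <- quick_records(n = 600, seed = 72)
  expect_gt(variance_homogeneity_test(rec0)$p_value, 0.001)
  rec0$lncs_c <- 1
  expect_error(variance_homogeneity_test(rec0), "zero variance")
  rec1 <- rec0[rec0$district == "Soso", ]
  expect_error(variance_homogeneity_test(rec1), "2 districts")
})

test_that("municipality nesting and seasonal random terms fit cleanly", {
  env <- default_env()
  rec <- quick_records(n = 1000, seed = 81, noise_sd = 0.8,
                       district_sd = c(q = 0.4),
                       municipality_sd = c(q = 0.3))
  mf <- fit_mixed(rec, env, random_terms = c("Q", "mu", "seasonal"),
                  grouping = "district_municipality",
                  variance_by_district = TRUE, full_records = rec)
  expect_true(all(is.finite(mf$params)))
  expect_true(all(is.finite(mf$random_sd)))
  expect_gt(mf$random_sd[["Q"]], 0.1)
  expect_gt(mf$r_squared, 0.3)
  expect_match(mf$structure, "district_municipality")
})
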