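test_that("regression weights follow n over squared ln range, mean 1", {
  rec <- data.frame(zone = c("Alienation", "Alienation"), time = c(5, 6),
                    n_animals = c(10, 5), ln_mean_cs = c(8, 8),
                    ln_min_cs = c(7, 7.5), ln_max_cs = c(9, 8.5),
                    ln_mean_cs_c = c(-5, -5))
  # raw weights 10/4 = 2.5 and 5/1 = 5; normalised to mean 1 -> 2/3, 4/3
  w <- compute_weights(rec)$weight
  expect_equal(w, c(2 / 3, 4 / 3))
  expect_equal(mean(w), 1)

  # identical records: all weights exactly 1
  rec2 <- rec; rec2$n_animals <- 10; rec2$ln_min_cs <- 7; rec2$ln_max_cs <- 9
  expect_equal(compute_weights(rec2)$weight, c(1, 1))

  # scale invariance in n
  rec3 <- rec; rec3$n_animals <- rec$n_animals * 2
  expect_equal(compute_weights(rec3)$weight, w)

  rec4 <- rec; rec4$ln_max_cs[1] <- rec4$ln_min_cs[1]
  expect_error(compute_weights(rec4), "non-positive ln range")
})

test_that("equal weights reduce weighted regression to ordinary least squares", {
  g <- generate_chernobyl(seed = 1)
  rec <- g$records
  rec$weight <- 1
  ms_w <- enumerate_models(rec)
  ms_o <- enumerate_models(rec, use_weights = FALSE)
  for (nm in names(ms_w$models))
    expect_equal(coef(ms_w$models[[nm]]$fit), coef(ms_o$models[[nm]]$fit),
                 tolerance = 1e-10)
})

test_that("model enumeration respects marginality and AICc accounting", {
  g <- generate_chernobyl(seed = 2)
  ms <- enumerate_models(g$records)
  expect_setequal(ms$table$model,
                  c("null", "time", "zone", "time_zone", "time_x_zone"))
  # the interaction model carries both main effects
  expect_true(all(c("time", "zonePermanent_control") %in%
                    names(coef(ms$models$time_x_zone$fit))))
  # AICc = AIC + 2k(k+1)/(n-k-1), here with k counting sigma as well
  m <- ms$models$time_zone
  expect_equal(m$aicc, AIC(m$fit) + 2 * m$k * (m$k + 1) / (ms$n - m$k - 1))
  expect_equal(sum(ms$table$akaike_weight), 1, tolerance = 1e-12)
  # Akaike weights are invariant to a constant shift of all AICc values
  d <- ms$table$delta_aicc
  w_shift <- exp(-(d + 123) / 2) / sum(exp(-(d + 123) / 2))
  expect_equal(w_shift, ms$table$akaike_weight, tolerance = 1e-12)

  # AICc correction vanishes for large n
  big <- do.call(rbind, replicate(200, g$records, simplify = FALSE))
  msb <- enumerate_models(big)
  expect_lt(abs(msb$models$time_zone$aicc - AIC(msb$models$time_zone$fit)),
            0.01)
})

test_that("zone coding and slope recovery match the generating truth", {
  # huge cells, tiny noise: weighted regression pins down the slope
  g <- generate_chernobyl(seed = 5, n_per_cell = 200, poisson_n = FALSE,
                          sd_ln = 0.05, rate = 0.08)
  ms <- enumerate_models(g$records)
  fit <- ms$models$time_zone$fit
  expect_lt(abs(coef(fit)[["time"]] - g$truth$slope), 1e-3)
  # Alienation is the reference level: zone coefficients read as offsets
  expect_equal(coef(fit)[["zonePermanent_control"]],
               g$truth$zone_offsets[["Permanent_control"]],
               tolerance = 0.05)
  expect_equal(coef(fit)[["zonePeriodic_control"]],
               g$truth$zone_offsets[["Periodic_control"]],
               tolerance = 0.05)
  # sign convention: declining burdens give a positive decline rate
  mmi <- mmi_average(ms)
  expect_gt(mmi$decline_rate$estimate, 0)

  expect_error(generate_chernobyl(n_zones = 1), "2 zones")
  expect_error(generate_chernobyl(n_per_cell = 1, poisson_n = FALSE),
               "fewer than 2")
})

test_that("multimodel averaging weights, importance and half-life behave", {
  g <- generate_chernobyl(seed = 11)
  ms <- enumerate_models(g$records)
  mmi <- mmi_average(ms)
  expect_equal(sum(mmi$akaike_weights), 1)
  expect_true(all(mmi$coefficients$importance >= 0 &
                    mmi$coefficients$importance <= 1))
  expect_true(all(mmi$coefficients$lower <= mmi$coefficients$estimate &
                    mmi$coefficients$estimate <= mmi$coefficients$upper))

  # single-model set: averaging returns that model verbatim, importance 1
  ms1 <- ms
  ms1$models <- ms$models["time_zone"]
  ms1$table <- ms$table[ms$table$model == "time_zone", ]
  ms1$table$akaike_weight <- 1
  mmi1 <- mmi_average(ms1)
  cf <- coef(ms$models$time_zone$fit)
  got <- setNames(mmi1$coefficients$estimate, mmi1$coefficients$term)
  expect_equal(got[names(cf)], cf, tolerance = 1e-12)
  expect_true(all(mmi1$coefficients$importance == 1))

  # strong-slope Time-only truth: every competitive model contains Time
  for (i in 1:10) {
    gg <- generate_chernobyl(seed = 100 + i, zone_offsets = c(0, 0, 0),
                             rate = 0.3, sd_ln = 0.5, n_per_cell = 8,
                             poisson_n = FALSE)
    mm <- mmi_average(enumerate_models(gg$records))
    expect_true(mm$best_model %in% c("time", "time_zone", "time_x_zone"))
    imp <- setNames(mm$coefficients$importance, mm$coefficients$term)
    expect_gt(imp[["time"]], 0.95)
  }

  # zero slope with large zone offsets: Zone matters, Time does not
  g0 <- generate_chernobyl(seed = 21, rate = 0, sd_ln = 0.4,
                           zone_offsets = c(0, 2, 4), n_per_cell = 8,
                           poisson_n = FALSE)
  mm0 <- mmi_average(enumerate_models(g0$records))
  imp0 <- setNames(mm0$coefficients$importance, mm0$coefficients$term)
  expect_gt(imp0[["zonePermanent_control"]], imp0[["time"]])

  # a decline rate whose CI reaches zero yields an infinite upper half-life
  hl <- ecological_half_life(mm0$decline_rate$estimate,
                             mm0$decline_rate$se)
  expect_true(is.infinite(hl$upper))
})

test_that("the chernobyl reader validates and reweights summary tables", {
  g <- generate_chernobyl(seed = 31)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(Zone = g$records$zone, Time = g$records$time,
                       N = g$records$n_animals,
                       LnMeanCs = g$records$ln_mean_cs,
                       LnMinCs = g$records$ln_min_cs,
                       LnMaxCs = g$records$ln_max_cs,
                       LnMeanCs_c = g$records$ln_mean_cs_c),
            f, row.names = FALSE)
  rec <- read_chernobyl(f)
  expect_equal(rec$weight, g$records$weight, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(Zone = "Nowhere", Time = 1), bad, row.names = FALSE)
  expect_error(read_chernobyl(bad), "missing column")
})
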