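#' @name synthetic_data
#' @title Synthetic record generators with known ground truth
#' @description
#' [generate_fukushima()] emulates the structure of post-accident monitoring
#' records: log-normal burdens spanning orders of magnitude, district and
#' municipality random effects, per-district noise variances, sinusoidal
#' seasonality, two-isotope physical decay with measurement-delay offsets,
#' below-detection censoring and a configurable fraction of gross outliers.
#' [generate_chernobyl()] emulates zone/year summary tables (animal counts,
#' mean/min/max burdens) with a known decline slope and zone offsets.
#' Both return the realised ground truth alongside the records and are
#' bit-reproducible from the configured seed.
NULL

DISTRICTS <- c("Soso", "Kenpoku", "Kenchu", "Kennan", "Iwaki", "Aizu",
               "Minamiaizu")

#' Configuration for the Fukushima-style generator
#'
#' Defaults describe the study conditions for wild boar: 1404 samples over
#' 0.20-7.03 years, truth `Q = -4.851`, `mu = 0.173`, `A = 0.641`,
#' `P = 0.405` (`nu = 1`), ln-scale noise SD 1.0 in every district, seven
#' districts with three municipalities each, no location random effects and
#' no outliers unless requested.  The environment term uses equal isotope
#' intercepts `ln(1e6)` (a heavily contaminated area, Bq/m2 scale) and an
#' at-release 134:137 activity ratio of 1.
#'
#' @param truth a [model_parameters()] object.
#' @param env an [environment_spec()].
#' @param n_samples number of records.
#' @param t_range sampling window in years (within `[0, 10]`).
#' @param n_districts number of districts (up to 7 named ones).
#' @param municipalities_per_district municipalities nested per district.
#' @param district_sd named numeric: random-effect SDs for `q`, `mu`,
#'   `amp`, `phase` by district.
#' @param municipality_sd same for municipality within district (intercept
#'   `q` only unless other entries are set).
#' @param noise_sd_by_district residual ln-scale SD, length 1 or
#'   `n_districts`.
#' @param outlier_fraction fraction of records replaced by gross outliers.
#' @param outlier_shift_sd SD of the symmetric ln-scale outlier shift.
#' @param below_detection_threshold reporting limit (Bq/kg) applied to the
#'   reported total.
#' @param measurement_delay_range delay between collection and measurement
#'   (years).
#' @param species `"boar"` or `"black_bear"`.
#' @param seed integer seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    truth = model_parameters(q = -4.851, mu = 0.173, nu = 1,
                             amp = 0.641, phase = 0.405),
    env = environment_spec(log(1e6), log(1e6)),
    n_samples = 1404,
    t_range = c(0.20, 7.03),
    n_districts = 7,
    municipalities_per_district = 3,
    district_sd = c(q = 0, mu = 0, amp = 0, phase = 0),
    municipality_sd = c(q = 0, mu = 0, amp = 0, phase = 0),
    noise_sd_by_district = 1.0,
    outlier_fraction = 0,
    outlier_shift_sd = 8,
    below_detection_threshold = 10,
    measurement_delay_range = c(0.01, 0.15),
    species = "boar",
    seed = 1) {
  fill <- function(x) {
    out <- c(q = 0, mu = 0, amp = 0, phase = 0)
    out[names(x)] <- x
    out
  }
  cfg <- list(truth = truth, env = env, n_samples = as.integer(n_samples),
              t_range = t_range, n_districts = as.integer(n_districts),
              municipalities_per_district =
                as.integer(municipalities_per_district),
              district_sd = fill(district_sd),
              municipality_sd = fill(municipality_sd),
              noise_sd_by_district = noise_sd_by_district,
              outlier_fraction = outlier_fraction,
              outlier_shift_sd = outlier_shift_sd,
              below_detection_threshold = below_detection_threshold,
              measurement_delay_range = measurement_delay_range,
              species = species, seed = as.integer(seed))
  stopifnot(cfg$n_samples > 0,
            cfg$outlier_fraction >= 0, cfg$outlier_fraction < 1,
            cfg$t_range[1] >= 0, cfg$t_range[2] <= 10,
            cfg$t_range[1] < cfg$t_range[2],
            cfg$n_districts >= 1,
            all(cfg$district_sd >= 0), all(cfg$municipality_sd >= 0),
            all(cfg$noise_sd_by_district >= 0),
            cfg$measurement_delay_range[1] >= 0,
            diff(cfg$measurement_delay_range) >= 0)
  if (!length(cfg$noise_sd_by_district) %in% c(1L, cfg$n_districts))
    stop("noise_sd_by_district must have length 1 or n_districts")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate Fukushima-style animal records with known truth
#'
#' @param config a [simulation_config()].
#' @return List with `records` (the analysis-ready layout of
#'   [read_samples()], including per-isotope activities at the measurement
#'   date, the reported total and a below-detection flag) and `truth`
#'   (config echo, realised district/municipality effects, noiseless means
#'   and outlier indices).
#' @export
generate_fukushima <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$env$constants
  tr <- config$truth
  nd <- config$n_districts
  districts <- if (nd <= length(DISTRICTS)) DISTRICTS[seq_len(nd)]
  else c(DISTRICTS, sprintf("District%02d", seq_len(nd - length(DISTRICTS))))
  noise_sd <- rep(config$noise_sd_by_district, length.out = nd)

  with_seed(config$seed, {
    # realised location random effects
    deff <- data.frame(
      district = districts,
      q = rnorm(nd, 0, config$district_sd[["q"]]),
      mu = rnorm(nd, 0, config$district_sd[["mu"]]),
      amp = rnorm(nd, 0, config$district_sd[["amp"]]),
      phase = rnorm(nd, 0, config$district_sd[["phase"]]),
      noise_sd = noise_sd, stringsAsFactors = FALSE)
    muni <- expand.grid(district = districts,
                        idx = seq_len(config$municipalities_per_district),
                        stringsAsFactors = FALSE)
    muni$municipality <- paste0(muni$district, "-M", muni$idx)
    for (p in c("q", "mu", "amp", "phase"))
      muni[[p]] <- rnorm(nrow(muni), 0, config$municipality_sd[[p]])

    n <- config$n_samples
    di <- sample.int(nd, n, replace = TRUE)
    mi <- sample.int(config$municipalities_per_district, n, replace = TRUE)
    mrow <- match(paste0(districts[di], "-M", mi), muni$municipality)

    # sampling days on the calendar grid so T = days/365.25 exactly
    day <- round(runif(n, config$t_range[1] * DAYS_PER_YEAR,
                       config$t_range[2] * DAYS_PER_YEAR))
    t_years <- day / DAYS_PER_YEAR
    collection_date <- k$accident_date + day

    q_i <- tr$q + deff$q[di] + muni$q[mrow]
    mu_i <- tr$mu + deff$mu[di] + muni$mu[mrow]
    amp_i <- tr$amp + deff$amp[di] + muni$amp[mrow]
    ph_i <- tr$phase + deff$phase[di] + muni$phase[mrow]
    mean_i <- environment_term(t_years, config$env) + q_i -
      mu_i * t_years^tr$nu + amp_i * sin(2 * pi * (t_years + ph_i))

    lncs_c <- mean_i + rnorm(n, 0, deff$noise_sd[di])
    n_out <- round(config$outlier_fraction * n)
    out_idx <- if (n_out > 0) sample.int(n, n_out) else integer(0)
    if (n_out > 0)
      lncs_c[out_idx] <- lncs_c[out_idx] +
        rnorm(n_out, 0, config$outlier_shift_sd)

    # isotope split at collection from the environment composition
    l134 <- config$env$lncs134_t0r - t_years * log(2) / k$th_cs134
    l137 <- config$env$lncs137_t0r - t_years * log(2) / k$th_cs137
    f134 <- 1 / (1 + exp(l137 - l134))
    total_coll <- exp(lncs_c)
    delay_days <- round(runif(n, config$measurement_delay_range[1] *
                                DAYS_PER_YEAR,
                              config$measurement_delay_range[2] *
                                DAYS_PER_YEAR))
    delta <- delay_days / DAYS_PER_YEAR
    cs134 <- total_coll * f134 * 2^(-delta / k$th_cs134)
    cs137 <- total_coll * (1 - f134) * 2^(-delta / k$th_cs137)
    cs_total_reported <- cs134 + cs137

    records <- data.frame(
      species = config$species,
      collection_date = collection_date,
      measurement_date = collection_date + delay_days,
      t_years = t_years,
      district = districts[di],
      municipality = muni$municipality[mrow],
      cs134 = cs134, cs137 = cs137,
      cs_total_reported = cs_total_reported,
      below_detection = cs_total_reported <
        config$below_detection_threshold,
      lncs_c = lncs_c, stringsAsFactors = FALSE)

    list(records = records,
         truth = list(config = config, district_effects = deff,
                      municipality_effects = muni,
                      mean_noiseless = mean_i,
                      outlier_indices = sort(out_idx)))
  })
}

#' Write generated records in a layout readable by read_samples()
#'
#' @param records generated records.
#' @param path output CSV path.
#' @param dialect `"supplement"` or `"raw"`.
#' @export
write_fukushima_csv <- function(records, path,
                                dialect = c("supplement", "raw")) {
  dialect <- match.arg(dialect)
  out <- if (dialect == "supplement")
    data.frame(Species = records$species, T = records$t_years,
               District = records$district,
               Municipality = records$municipality,
               LnCs_c = records$lncs_c,
               BelowDetection = records$below_detection)
  else
    data.frame(Species = records$species,
               CollectionDate = format(records$collection_date, "%Y-%m-%d"),
               MeasurementDate = format(records$measurement_date,
                                        "%Y-%m-%d"),
               District = records$district,
               Municipality = records$municipality,
               Cs134 = records$cs134, Cs137 = records$cs137,
               CsTotal = records$cs_total_reported,
               BelowDetection = records$below_detection)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Generate Chernobyl-style zone/year summary records with known truth
#'
#' Per zone and year, `n` individual ln burdens are drawn as
#' `ln X_zone(t) + q + offset_zone - rate * t + N(0, sd)`, where
#' `ln X_zone(t)` is the zone's land contamination decayed with the 137Cs
#' half-life, and summarised into the mean/min/max layout of the summary
#' tables; weights follow [compute_weights()].
#'
#' @param n_zones number of zones (2 or 3; labels follow the study zones).
#' @param times sampling years (since the accident).
#' @param q base ln tissue:land ratio (Alienation zone).
#' @param zone_offsets additive offsets of the other zones relative to the
#'   first.
#' @param rate true ecological decline rate (1/years).
#' @param ln_land_t0 ln land contamination at `t = 0` per zone.
#' @param sd_ln within-cell ln-scale SD.
#' @param n_per_cell animals per cell: fixed number, or mean of a shifted
#'   Poisson when `poisson_n = TRUE`.
#' @param poisson_n draw cell sizes as `2 + rpois(mean - 2)`.
#' @param constants an [isotope_constants()] (137Cs half-life is used).
#' @param seed integer seed.
#' @return List with `records` (weighted summary data frame) and `truth`.
#' @export
generate_chernobyl <- function(n_zones = 3, times = 5:22, q = -5.5,
                               zone_offsets = c(0, 0.955, 1.438),
                               rate = 0.033,
                               ln_land_t0 = c(14.5, 13.0, 11.8),
                               sd_ln = 1.0, n_per_cell = 6,
                               poisson_n = TRUE,
                               constants = isotope_constants(
                                 accident_date = as.Date("1986-04-26")),
                               seed = 1) {
  if (n_zones < 2) stop("need at least 2 zones")
  stopifnot(n_zones <= length(ZONE_LEVELS), length(times) >= 3)
  zones <- ZONE_LEVELS[seq_len(n_zones)]
  zone_offsets <- rep(zone_offsets, length.out = n_zones)
  ln_land_t0 <- rep(ln_land_t0, length.out = n_zones)
  with_seed(seed, {
    cells <- expand.grid(zone = zones, time = times,
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      zi <- match(cells$zone[i], zones)
      tt <- cells$time[i]
      n <- if (poisson_n) 2 + rpois(1, max(n_per_cell - 2, 0))
      else n_per_cell
      if (n < 2) stop("fewer than 2 animals in a cell")
      ln_land <- ln_land_t0[zi] - tt * log(2) / constants$th_cs137
      m <- ln_land + q + zone_offsets[zi] - rate * tt
      draws <- rnorm(n, m, sd_ln)
      data.frame(zone = cells$zone[i], time = tt, n_animals = n,
                 ln_mean_cs = log(mean(exp(draws))),
                 ln_min_cs = min(draws), ln_max_cs = max(draws),
                 ln_mean_cs_c = log(mean(exp(draws))) - ln_land,
                 stringsAsFactors = FALSE)
    })
    records <- compute_weights(do.call(rbind, rows))
    list(records = records,
         truth = list(q = q, zone_offsets = setNames(zone_offsets, zones),
                      rate = rate, slope = -rate, sd_ln = sd_ln,
                      ln_land_t0 = setNames(ln_land_t0, zones),
                      seed = seed))
  })
}
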