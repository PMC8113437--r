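#' @name io_ingest
#' @title Reading, filtering and decay-correcting radioactivity records
#' @description
#' Animal radioactivity monitoring records arrive either as an
#' analysis-ready table (species, `T`, district, municipality, decay-corrected
#' `LnCs_c`) or as raw exports carrying per-isotope activities (Bq/kg), a
#' collection date and a measurement date.  [read_samples()] parses both
#' layouts into one analysis-ready data frame, removing (and counting) rows
#' with missing data or levels below detection.  The column schema is
#' documented in `system.file("extdata", "schema_columns.tsv", package =
#' "radcesium")`.
NULL

SPECIES_LEVELS <- c("boar", "black_bear")

.normalize_species <- function(x) {
  key <- gsub("[ _-]+", " ", trimws(tolower(as.character(x))))
  map <- c("boar" = "boar", "wild boar" = "boar", "sus scrofa" = "boar",
           "black bear" = "black_bear", "bear" = "black_bear",
           "asian black bear" = "black_bear",
           "ursus thibetanus" = "black_bear")
  unname(map[key])
}

# Strict date parser: ISO-8601 or slashed year-first form only; anything
# else (including ambiguous day/month orders) is an error naming the rows.
.parse_dates <- function(x, what = "date") {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  sla <- grepl("^\\d{4}/\\d{1,2}/\\d{1,2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[sla] <- as.Date(x[sla], format = "%Y/%m/%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop("unparseable ", what, " at row(s): ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  out
}

#' Filter report for an ingested sample table
#'
#' @param n_input rows in the input file.
#' @param n_removed_missing rows dropped for missing/invalid fields.
#' @param n_removed_below_detection rows dropped as below detection.
#' @param n_removed_invalid_species rows dropped for unknown species labels.
#' @return Object of class `filter_report`.
#' @export
filter_report <- function(n_input, n_removed_missing = 0L,
                          n_removed_below_detection = 0L,
                          n_removed_invalid_species = 0L) {
  stopifnot(n_input >= 0, n_removed_missing >= 0,
            n_removed_below_detection >= 0, n_removed_invalid_species >= 0)
  removed <- n_removed_missing + n_removed_below_detection +
    n_removed_invalid_species
  structure(list(n_input = as.integer(n_input),
                 n_removed_missing = as.integer(n_removed_missing),
                 n_removed_below_detection =
                   as.integer(n_removed_below_detection),
                 n_removed_invalid_species =
                   as.integer(n_removed_invalid_species),
                 n_removed = as.integer(removed),
                 n_analysis = as.integer(n_input - removed),
                 fraction_removed =
                   if (n_input > 0) removed / n_input else 0),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Filter report: %d rows in; removed %d (%.1f%%): %d missing, %d below detection, %d unknown species; %d in analysis set\n",
    x$n_input, x$n_removed, 100 * x$fraction_removed, x$n_removed_missing,
    x$n_removed_below_detection, x$n_removed_invalid_species, x$n_analysis))
  invisible(x)
}

#' Correct reported total radiocesium for physical decay since collection
#'
#' Between collection and measurement each isotope decays physically; the
#' reported total at measurement is back-corrected to the collection date by
#' multiplying each isotope component by `2^(+delta/Th)` where `delta` is the
#' elapsed time in years (365.25 days/year).  When per-isotope activities are
#' not available the 134:137 split at measurement is inferred from the
#' at-release activity ratio decayed from the accident date.
#'
#' @param cs_total_reported total activity at the measurement date (Bq/kg,
#'   positive).
#' @param collection_date,measurement_date `Date` vectors;
#'   `measurement_date >= collection_date`.
#' @param constants an [isotope_constants()] object.
#' @param cs134,cs137 optional per-isotope activities at the measurement
#'   date; when both are given they take precedence over the ratio path.
#' @return `LnCs_c`: ln of the total activity at collection time.
#' @examples
#' k <- isotope_constants()
#' d <- as.Date("2015-06-01")
#' correct_decay(1000, d, d, k)  # log(1000): no elapsed time
#' @export
correct_decay <- function(cs_total_reported, collection_date,
                          measurement_date,
                          constants = isotope_constants(),
                          cs134 = NULL, cs137 = NULL) {
  delta <- as.numeric(measurement_date - collection_date) / DAYS_PER_YEAR
  if (any(delta < 0)) stop("measurement_date earlier than collection_date")
  if (any(!is.finite(cs_total_reported) | cs_total_reported <= 0))
    stop("cs_total_reported must be positive")
  g134 <- 2^(+delta / constants$th_cs134)
  g137 <- 2^(+delta / constants$th_cs137)
  if (!is.null(cs134) && !is.null(cs137)) {
    if (any(cs134 < 0 | cs137 < 0)) stop("negative isotope activity")
    corrected <- cs134 * g134 + cs137 * g137
  } else {
    # isotope split at the measurement date implied by the release ratio
    t_meas <- years_since_accident(measurement_date, constants)
    if (any(t_meas < 0)) stop("measurement before the accident date")
    r134 <- constants$release_activity_ratio_134_137 *
      2^(-t_meas / constants$th_cs134)
    r137 <- 2^(-t_meas / constants$th_cs137)
    f134 <- r134 / (r134 + r137)
    corrected <- cs_total_reported * (f134 * g134 + (1 - f134) * g137)
  }
  log(corrected)
}

#' Read animal radioactivity records
#'
#' Two delimited-text layouts are supported.  `"supplement"`: analysis-ready
#' columns `Species, T, District, Municipality, LnCs_c` (optionally
#' `BelowDetection`).  `"raw"`: columns `Species, CollectionDate,
#' MeasurementDate, District, Municipality` plus either `Cs134` and `Cs137`
#' or `CsTotal` (Bq/kg at the measurement date), optionally
#' `BelowDetection`; `T` is computed from the collection date at 365.25
#' days/year and `LnCs_c` via [correct_decay()].
#'
#' Rows with missing required fields or below-detection flags are excluded
#' from the analysis set and counted in the filter report; unknown species
#' labels are rejected with a warning; unparseable dates and empty files are
#' errors.
#'
#' @param path path to a CSV file.
#' @param dialect `"supplement"` or `"raw"`.
#' @param constants an [isotope_constants()] object (raw dialect).
#' @param composition `"isotopes"` to use per-isotope activities when
#'   present, `"release_ratio"` to always infer the split from the release
#'   ratio.
#' @return List with `records` (analysis-ready data frame with columns
#'   `species, collection_date, measurement_date, t_years, district,
#'   municipality, cs134, cs137, cs_total_reported, below_detection,
#'   lncs_c`) and `report` (a [filter_report()]).
#' @export
read_samples <- function(path, dialect = c("supplement", "raw"),
                         constants = isotope_constants(),
                         composition = c("isotopes", "release_ratio")) {
  dialect <- match.arg(dialect)
  composition <- match.arg(composition)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty input file: ", path)
  need <- if (dialect == "supplement")
    c("Species", "T", "District", "Municipality", "LnCs_c")
  else c("Species", "CollectionDate", "MeasurementDate", "District",
         "Municipality")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))

  species <- .normalize_species(raw$Species)
  bad_sp <- is.na(species) & !is.na(raw$Species) & nzchar(trimws(raw$Species))
  if (any(bad_sp))
    warning(sum(bad_sp), " row(s) with unknown species label rejected")

  below <- if ("BelowDetection" %in% names(raw))
    as.logical(raw$BelowDetection) & !is.na(raw$BelowDetection)
  else rep(FALSE, nrow(raw))
  below[is.na(below)] <- FALSE

  if (dialect == "supplement") {
    rec <- data.frame(
      species = species,
      collection_date = constants$accident_date +
        round(as.numeric(raw$T) * DAYS_PER_YEAR),
      measurement_date = constants$accident_date +
        round(as.numeric(raw$T) * DAYS_PER_YEAR),
      t_years = as.numeric(raw$T),
      district = as.character(raw$District),
      municipality = as.character(raw$Municipality),
      cs134 = NA_real_, cs137 = NA_real_, cs_total_reported = NA_real_,
      below_detection = below,
      lncs_c = as.numeric(raw$LnCs_c),
      stringsAsFactors = FALSE)
    missing_row <- is.na(rec$t_years) | rec$t_years < 0 |
      (is.na(rec$lncs_c) & !below) | is.na(rec$district) |
      !nzchar(rec$district)
  } else {
    cdate <- .parse_dates(raw$CollectionDate, "collection date")
    mdate <- .parse_dates(raw$MeasurementDate, "measurement date")
    has_iso <- all(c("Cs134", "Cs137") %in% names(raw))
    cs134 <- if (has_iso) as.numeric(raw$Cs134) else NA_real_
    cs137 <- if (has_iso) as.numeric(raw$Cs137) else NA_real_
    cstot <- if ("CsTotal" %in% names(raw)) as.numeric(raw$CsTotal)
    else cs134 + cs137
    rec <- data.frame(
      species = species, collection_date = cdate, measurement_date = mdate,
      t_years = years_since_accident(cdate, constants),
      district = as.character(raw$District),
      municipality = as.character(raw$Municipality),
      cs134 = cs134, cs137 = cs137, cs_total_reported = cstot,
      below_detection = below, lncs_c = NA_real_,
      stringsAsFactors = FALSE)
    missing_row <- is.na(rec$collection_date) | is.na(rec$measurement_date) |
      is.na(rec$t_years) | rec$t_years < 0 |
      (is.na(rec$cs_total_reported) & !below) |
      (!is.na(rec$cs_total_reported) & rec$cs_total_reported <= 0 & !below) |
      is.na(rec$district) | !nzchar(rec$district)
    ok <- !missing_row & !below & !bad_sp
    if (any(ok)) {
      use_iso <- has_iso && composition == "isotopes"
      rec$lncs_c[ok] <- correct_decay(
        rec$cs_total_reported[ok], rec$collection_date[ok],
        rec$measurement_date[ok], constants,
        cs134 = if (use_iso) rec$cs134[ok] else NULL,
        cs137 = if (use_iso) rec$cs137[ok] else NULL)
    }
  }

  missing_row <- missing_row & !bad_sp        # count each row once
  below_cnt <- below & !bad_sp & !missing_row
  keep <- !bad_sp & !missing_row & !below_cnt
  rep_out <- filter_report(
    n_input = nrow(raw),
    n_removed_missing = sum(missing_row),
    n_removed_below_detection = sum(below_cnt),
    n_removed_invalid_species = sum(bad_sp))
  list(records = rec[keep, , drop = FALSE], report = rep_out)
}

#' Write an analysis-ready table in the supplement layout
#'
#' @param records analysis-ready data frame as returned by [read_samples()].
#' @param path output CSV path.
#' @export
write_analysis_table <- function(records, path) {
  out <- data.frame(Species = records$species, T = records$t_years,
                    District = records$district,
                    Municipality = records$municipality,
                    LnCs_c = records$lncs_c)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Robust ln-linear intercepts for each isotope
#'
#' Fits a robust linear regression (`MASS::rlm`, Huber M-estimation) of
#' `ln(activity)` on `T` separately for each isotope, returning the
#' intercepts at `T = 0` with standard errors.  These intercepts parameterise
#' the environment term.
#'
#' @param records data frame with columns `t_years`, `cs134`, `cs137`
#'   (activities, Bq/kg).
#' @return List with elements `cs134` and `cs137`, each
#'   `list(intercept, se, slope)`.
#' @export
estimate_isotope_intercepts <- function(records) {
  one <- function(act, label) {
    ok <- is.finite(act) & act > 0 & is.finite(records$t_years)
    if (sum(ok) < 10)
      stop("insufficient data for isotope ", label,
           " (need >= 10 positive records, have ", sum(ok), ")")
    la <- log(act[ok]); tt <- records$t_years[ok]
    ls <- lm(la ~ tt)
    if (max(abs(resid(ls))) < 1e-10 * max(1, sd(la))) {
      # exact line: robust regression coincides with least squares, and
      # M-estimation has no scale to iterate on; the SE is legitimately ~0
      sm <- suppressWarnings(summary(ls))
      return(list(intercept = unname(coef(ls)[1L]),
                  se = unname(sm$coefficients[1L, "Std. Error"]),
                  slope = unname(coef(ls)[2L])))
    }
    fit <- MASS::rlm(la ~ tt, maxit = 100)
    sm <- summary(fit)
    list(intercept = unname(coef(fit)[1L]),
         se = unname(sm$coefficients[1L, "Std. Error"]),
         slope = unname(coef(fit)[2L]))
  }
  list(cs134 = one(records$cs134, "134Cs"),
       cs137 = one(records$cs137, "137Cs"))
}

#' Subset records by the study's analysis rules
#'
#' `"full"` keeps everything; `"high_districts"` keeps the two districts with
#' the highest mean burdens and sufficient samples (boar: Soso and Kenpoku;
#' black bear: Kenpoku and Kenchu); `"sensitivity"` drops the Aizu and
#' Minamiaizu districts (separated by mountains from the plant) and all
#' samples collected within 6 months of the accident.
#'
#' @param records analysis-ready data frame.
#' @param rule one of `"full"`, `"high_districts"`, `"sensitivity"`.
#' @param species `"boar"` or `"black_bear"` (needed for
#'   `"high_districts"`).
#' @return The subsetted data frame.
#' @export
subset_records <- function(records, rule = c("full", "high_districts",
                                             "sensitivity"),
                           species = c("boar", "black_bear")) {
  rule <- match.arg(rule)
  species <- match.arg(species)
  switch(rule,
    full = records,
    high_districts = {
      keep <- if (species == "boar") c("Soso", "Kenpoku")
      else c("Kenpoku", "Kenchu")
      records[records$district %in% keep, , drop = FALSE]
    },
    sensitivity = records[!(records$district %in%
                              c("Aizu", "Minamiaizu")) &
                            records$t_years > 0.5, , drop = FALSE])
}
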