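#' Physical constants for the two cesium isotopes
#'
#' Bundles the physical half-lives of 134Cs and 137Cs, the accident date and
#' the 134Cs:137Cs activity ratio of the release at the accident date.  The
#' defaults use standard nuclide data (134Cs: 2.0652 y; 137Cs: 30.08 y), the
#' 2011-03-11 Fukushima accident date, and an at-release activity ratio of 1,
#' as widely reported for the Fukushima source term.  All values are
#' configurable, e.g. for the 1986 Chernobyl source term.
#'
#' @param th_cs134 physical half-life of 134Cs in years.
#' @param th_cs137 physical half-life of 137Cs in years.
#' @param accident_date `Date`, start of the release; time zero for `T`.
#' @param release_activity_ratio_134_137 134Cs:137Cs activity ratio at
#'   `accident_date` (dimensionless, > 0).
#' @return An object of class `isotope_constants`.
#' @examples
#' isotope_constants()
#' @export
isotope_constants <- function(th_cs134 = 2.0652,
                              th_cs137 = 30.08,
                              accident_date = as.Date("2011-03-11"),
                              release_activity_ratio_134_137 = 1) {
  stopifnot(is.numeric(th_cs134), th_cs134 > 0,
            is.numeric(th_cs137), th_cs137 > 0,
            inherits(accident_date, "Date"),
            is.numeric(release_activity_ratio_134_137),
            release_activity_ratio_134_137 > 0)
  structure(list(th_cs134 = th_cs134, th_cs137 = th_cs137,
                 accident_date = accident_date,
                 release_activity_ratio_134_137 =
                   release_activity_ratio_134_137),
            class = "isotope_constants")
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("Isotope constants: Th(134Cs) =", x$th_cs134, "y, Th(137Cs) =",
      x$th_cs137, "y\n  accident date:", format(x$accident_date),
      " 134:137 release activity ratio:", x$release_activity_ratio_134_137,
      "\n")
  invisible(x)
}

# days per year used for every calendar -> T conversion
DAYS_PER_YEAR <- 365.25

#' Convert calendar dates to years since the accident
#'
#' Uses exactly 365.25 days per year.
#'
#' @param date `Date` vector.
#' @param constants an [isotope_constants()] object carrying the accident
#'   date.
#' @return Numeric vector of years since the accident.
#' @export
years_since_accident <- function(date, constants = isotope_constants()) {
  as.numeric(date - constants$accident_date) / DAYS_PER_YEAR
}
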