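#' Model parameters of the burden model
#'
#' The mean model for ln total radiocesium in tissue is
#' `X(T) + Q - mu * T^nu + A * sin(2*pi*(T + P))`.
#'
#' @param q offset linking tissue burden (Bq/kg) to environmental deposition
#'   (Bq/m2), on the natural-log scale.
#' @param mu net ecological loss rate, 1/years.  Positive values mean burdens
#'   decline faster than physical decay alone.
#' @param nu power of the time dependence of ecological loss (>= 0.1);
#'   `nu = 1` is exponential kinetics.
#' @param amp seasonal amplitude `A` on the ln scale (canonical form >= 0).
#' @param phase seasonal phase shift `P` in years (canonical range `[0, 1)`).
#' @return An object of class `model_parameters` (a named list).
#' @seealso [model_mean()], [canonicalize_seasonal()]
#' @export
model_parameters <- function(q, mu, nu = 1, amp, phase) {
  stopifnot(is.numeric(q), is.numeric(mu), is.numeric(nu),
            is.numeric(amp), is.numeric(phase), length(nu) == 1)
  if (nu < 0.1) stop("'nu' must be >= 0.1")
  structure(list(q = q, mu = mu, nu = nu, amp = amp, phase = phase),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("Burden model parameters: Q = %.4g, mu = %.4g, nu = %.4g, A = %.4g, P = %.4g\n",
              x$q, x$mu, x$nu, x$amp, x$phase))
  invisible(x)
}

#' Environment-term specification
#'
#' Holds the ln-scale intercepts (at `T = 0`) of the two isotope components
#' of the environmental contamination and the physical constants governing
#' their decay.
#'
#' @param lncs134_t0r ln-scale 134Cs intercept at `T = 0`.
#' @param lncs137_t0r ln-scale 137Cs intercept at `T = 0`.
#' @param constants an [isotope_constants()] object.
#' @return An object of class `environment_spec`.
#' @export
environment_spec <- function(lncs134_t0r, lncs137_t0r,
                             constants = isotope_constants()) {
  stopifnot(is.finite(lncs134_t0r), is.finite(lncs137_t0r),
            inherits(constants, "isotope_constants"))
  structure(list(lncs134_t0r = lncs134_t0r, lncs137_t0r = lncs137_t0r,
                 constants = constants),
            class = "environment_spec")
}

#' Environment term X(T): physical decay of the two-isotope mixture
#'
#' `X(T) = ln[exp(LnCs134_t0r) * 2^(-T/Th134) + exp(LnCs137_t0r) *
#' 2^(-T/Th137)]`.  Computed with a log-sum-exp to stay finite for large `T`.
#'
#' @param t_years time since the accident in years (>= 0), vectorised.
#' @param env an [environment_spec()].
#' @return `X` on the natural-log activity scale.
#' @export
environment_term <- function(t_years, env) {
  stopifnot(inherits(env, "environment_spec"), all(t_years >= 0))
  k <- env$constants
  l1 <- env$lncs134_t0r - t_years * (log(2) / k$th_cs134)
  l2 <- env$lncs137_t0r - t_years * (log(2) / k$th_cs137)
  m <- pmax(l1, l2)
  m + log(exp(l1 - m) + exp(l2 - m))
}

#' Mean of the burden model
#'
#' Evaluates `X(T) + Q - mu * T^nu + A * sin(2*pi*(T + P))`.
#'
#' @inheritParams environment_term
#' @param params a [model_parameters()] object.
#' @return Predicted ln total radiocesium (Bq/kg), decay-corrected to the
#'   collection date.
#' @export
model_mean <- function(t_years, params, env) {
  stopifnot(inherits(params, "model_parameters"))
  if (params$nu < 0.1) stop("'nu' must be >= 0.1")
  environment_term(t_years, env) + params$q - params$mu * t_years^params$nu +
    params$amp * sin(2 * pi * (t_years + params$phase))
}

#' Canonical form of the seasonal amplitude and phase
#'
#' `A * sin(2*pi*(T + P))` is unchanged by `(A, P) -> (-A, P + 1/2)` and by
#' integer shifts of `P`; the canonical representative has `A >= 0` and
#' `P` in `[0, 1)`.
#'
#' @param amp seasonal amplitude, any sign.
#' @param phase phase shift in years, any value.
#' @return Named numeric vector `c(amp = , phase = )`.
#' @export
canonicalize_seasonal <- function(amp, phase) {
  if (amp < 0) {
    amp <- -amp
    phase <- phase + 0.5
  }
  c(amp = amp, phase = phase %% 1)
}

# (a, b) harmonic coefficients <-> canonical (A, P):
#   A*sin(2pi(T+P)) = a*sin(2piT) + b*cos(2piT),
#   a = A*cos(2piP), b = A*sin(2piP).
amp_phase_to_ab <- function(amp, phase) {
  c(a = amp * cos(2 * pi * phase), b = amp * sin(2 * pi * phase))
}

ab_to_amp_phase <- function(a, b) {
  amp <- sqrt(a^2 + b^2)
  phase <- (atan2(b, a) / (2 * pi)) %% 1
  c(amp = amp, phase = phase)
}

# Delta-method jacobian of (A, P) wrt (a, b); NA-guarded near A = 0.
ab_jacobian <- function(a, b) {
  amp <- sqrt(a^2 + b^2)
  if (amp < 1e-10) return(matrix(NA_real_, 2, 2))
  matrix(c(a / amp, b / amp,
           -b / (2 * pi * amp^2), a / (2 * pi * amp^2)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("A", "P"), c("a", "b")))
}

#' Ecological half-life with a Wald confidence interval
#'
#' The ecological half-life is `ln(2)/mu`: the time for tissue burdens to
#' halve through all processes other than physical decay.  The interval is
#' the image of the Wald interval for `mu`; when `mu - z*se <= 0` the upper
#' bound is `Inf`, and when `mu <= 0` the point estimate itself is `Inf`.
#'
#' @param mu ecological loss rate (1/years).
#' @param se_mu standard error of `mu` (>= 0).
#' @param conf confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper` (years).
#' @examples
#' ecological_half_life(log(2), 0)        # exactly 1 year
#' ecological_half_life(0.033, 0.020)     # upper bound infinite
#' @export
ecological_half_life <- function(mu, se_mu = 0, conf = 0.95) {
  stopifnot(se_mu >= 0)
  z <- qnorm(1 - (1 - conf) / 2)
  hl <- function(m) if (m <= 0) Inf else log(2) / m
  list(estimate = hl(mu),
       lower = hl(mu + z * se_mu),
       upper = hl(mu - z * se_mu))
}

#' Seasonal summary metrics
#'
#' Converts the canonical seasonal parameters into the reporting scale:
#' `amplitude_metric = exp(A)` (the factor by which the oscillation moves the
#' burden above its mean at peak), `phase_months = 12 * P`, the peak timing
#' `peak_fraction_of_year = (0.25 - P) mod 1`, and the peak-to-trough fold
#' change `exp(2A)`.  Confidence intervals are delta-method on `A` and `P`.
#'
#' @param amp seasonal amplitude (ln scale).
#' @param phase phase shift (years).
#' @param se_amp,se_phase standard errors (optional).
#' @param conf confidence level.
#' @return List with `amplitude_metric`, `phase_months`,
#'   `peak_fraction_of_year`, `fold_change_peak_trough`, each with
#'   `lower`/`upper` where a standard error was given.
#' @export
seasonal_summaries <- function(amp, phase, se_amp = NA_real_,
                               se_phase = NA_real_, conf = 0.95) {
  cp <- canonicalize_seasonal(amp, phase)
  amp <- cp[["amp"]]; phase <- cp[["phase"]]
  z <- qnorm(1 - (1 - conf) / 2)
  ci <- function(x, se) {
    if (is.na(se)) c(NA_real_, NA_real_) else c(x - z * se, x + z * se)
  }
  amp_ci <- ci(amp, se_amp)
  ph_ci <- ci(phase, se_phase)
  list(
    amplitude_metric = exp(amp),
    amplitude_ci = exp(amp_ci),
    phase_months = 12 * phase,
    phase_months_ci = 12 * ph_ci,
    peak_fraction_of_year = (0.25 - phase) %% 1,
    fold_change_peak_trough = exp(2 * amp),
    fold_change_ci = exp(2 * amp_ci)
  )
}
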