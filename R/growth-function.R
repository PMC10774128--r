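#' Reference-curve parameters for the asymptotic growth function
#'
#' Bundle the triple defining one region's growth curve: the asymptote
#' (plateau volume, mm3), the intercept (volume at birth, mm3) and the
#' log rate constant (the per-day approach rate is `exp(log_rate)`).
#'
#' @param asymptote Plateau volume in mm3.
#' @param intercept Volume at age 0 in mm3.
#' @param log_rate Dimensionless log of the per-day rate constant.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(asymptote, intercept, log_rate) {
  stopifnot(is.numeric(asymptote), is.numeric(intercept), is.numeric(log_rate),
            length(asymptote) == 1L, length(intercept) == 1L, length(log_rate) == 1L)
  if (!is.finite(asymptote) || !is.finite(intercept) || !is.finite(log_rate))
    stop("growth_params components must be finite")
  if (asymptote == intercept)
    stop("asymptote and intercept must differ (flat curve is degenerate)")
  structure(list(asymptote = asymptote, intercept = intercept, log_rate = log_rate),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth curve: asymptote %.2f mm3, intercept %.2f mm3, log-rate %.3f (rate %.3g/day)\n",
              x$asymptote, x$intercept, x$log_rate, exp(x$log_rate)))
  invisible(x)
}

#' Asymptotic growth function
#'
#' Expected regional volume at a given postnatal age under the asymptotic
#' model `f(x) = theta1 + (theta2 - theta1) * exp(-exp(theta3) * x)`, where
#' `theta1` is the asymptote, `theta2` the intercept (volume at birth) and
#' `exp(theta3)` the per-day rate constant. The curve equals the intercept
#' at age 0 and approaches the asymptote as age grows.
#'
#' @param age_days Non-negative age(s) in postnatal days.
#' @param params A [growth_params()] object.
#' @return Volume(s) in mm3, same length as `age_days`.
#' @export
growth_function <- function(age_days, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(age_days < 0)) stop("age_days must be non-negative")
  params$asymptote + (params$intercept - params$asymptote) *
    exp(-exp(params$log_rate) * age_days)
}

#' Maturation age of a growth curve
#'
#' The age at which the curve reaches a given fraction (by default 99%)
#' of its asymptotic volume. Closed form:
#' `x = -log((1 - fraction) * theta1 / (theta1 - theta2)) / exp(theta3)`.
#'
#' @param params A [growth_params()] object with `asymptote > intercept > 0`.
#' @param fraction Fraction of the asymptote defining maturity; default 0.99.
#' @return Age in days. If the curve already starts at or above
#'   `fraction * asymptote`, returns 0 with a warning.
#' @export
maturation_age <- function(params, fraction = 0.99) {
  stopifnot(inherits(params, "growth_params"),
            is.numeric(fraction), length(fraction) == 1L, fraction > 0, fraction < 1)
  t1 <- params$asymptote; t2 <- params$intercept
  if (t1 <= t2) stop("maturation age requires an increasing curve (asymptote > intercept)")
  if (t2 <= 0) stop("intercept must be positive")
  if (fraction * t1 <= t2) {
    warning("curve starts at or above the maturity threshold; returning 0 days")
    return(0)
  }
  -log((1 - fraction) * t1 / (t1 - t2)) / exp(params$log_rate)
}

#' Convert an age in days to years
#'
#' Uses 365.25 days per year, the convention used throughout the package
#' when reporting maturation ages.
#'
#' @param age_days Age(s) in days.
#' @param digits Decimal places to round to; `NULL` for no rounding.
#' @return Age(s) in years.
#' @export
days_to_years <- function(age_days, digits = NULL) {
  y <- age_days / 365.25
  if (!is.null(digits)) y <- round(y, digits)
  y
}

#' Effect size as a percentage of the reference value
#'
#' Expresses an additive covariate effect (mm3) relative to the reference
#' curve value it modifies, as `100 * effect / reference`, rounded to two
#' decimals as conventionally tabulated.
#'
#' @param effect Additive effect in the units of the reference.
#' @param reference_value Reference-level value; must be nonzero.
#' @return Percentage, rounded to 2 decimal places.
#' @export
percent_effect <- function(effect, reference_value) {
  if (any(reference_value == 0)) stop("reference_value must be nonzero")
  round(100 * effect / reference_value, 2)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of tests in the family (>= 1).
#' @param alpha Family-wise error rate; default 0.05.
#' @return The per-test p-value threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1 ||
      n_tests != round(n_tests))
    stop("n_tests must be a positive integer")
  stopifnot(alpha > 0, alpha < 1)
  alpha / n_tests
}
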