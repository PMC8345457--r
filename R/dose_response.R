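#' Clamped linear dose-response function
#'
#' A straight line `slope * dose + intercept` whose output is clamped to the
#' unit interval, so that it can be read directly as a mortality or
#' reproductive-effect rate. Negative raw values are corrected to 0 and values
#' above 1 to 1.
#'
#' @param slope change in effect rate per unit exposure (per mg/kg bw/day).
#' @param intercept effect rate at zero exposure (usually 0 or negative).
#' @return an object of class `lagopop_dr`.
#' @seealso [derive_acute_dr()], [derive_chronic_dr()], [evaluate_dr()]
#' @export
dose_response <- function(slope, intercept = 0) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept), class = "lagopop_dr")
}

#' @export
print.lagopop_dr <- function(x, digits = 6, ...) {
  cat(sprintf("Clamped linear dose-response: effect = %s * dose %s %s  (clamped to [0, 1])\n",
              format(round_half_up(x$slope, digits)),
              if (x$intercept < 0) "-" else "+",
              format(abs(round_half_up(x$intercept, digits)))))
  invisible(x)
}

#' Toxicity endpoints used to derive dose-response lines
#'
#' Bundle of regulatory reference points for one pesticide: acute lethality
#' anchors (LD0, LD50), repeated-dose anchors (NOAEL, LOAEL) and the
#' interspecies extrapolation factors applied as divisors to each. The default
#' level of effect allocated to the LOAEL is 25%, and linearity through the
#' origin is accepted provided the implied effect at the NOAEL falls in the
#' 5--10% band.
#'
#' @param ld0 highest acute dose with no mortality (mg/kg bw); `NA` or absent
#'   is treated as 0 (line through the origin).
#' @param ld50 acute median lethal dose (mg/kg bw).
#' @param noael no-observed-adverse-effect level (mg/kg bw/day).
#' @param loael lowest-observed-adverse-effect level (mg/kg bw/day).
#' @param f_acute_ld50,f_acute_ld0 interspecies factors (divisors, >= 1)
#'   applied to the acute anchors.
#' @param f_chronic interspecies factor applied to NOAEL/LOAEL (default 5 for
#'   chronic extrapolation between mammal species).
#' @param loael_effect effect rate assumed at the adjusted LOAEL (default 0.25).
#' @param noael_effect_band acceptable effect range at the adjusted NOAEL for
#'   the linear model to be considered adequate (default `c(0.05, 0.10)`).
#' @return an object of class `lagopop_endpoints` (a validated list).
#' @export
endpoint_inputs <- function(ld0 = NA, ld50 = NA, noael = NA, loael = NA,
                            f_acute_ld50 = 1, f_acute_ld0 = 1, f_chronic = 5,
                            loael_effect = 0.25,
                            noael_effect_band = c(0.05, 0.10)) {
  if (!is.na(ld0) && !is.na(ld50) && ld0 >= ld50)
    stop_config("LD0 (%g) must be below LD50 (%g)", ld0, ld50)
  if (!is.na(noael) && !is.na(loael) && noael >= loael)
    stop_config("NOAEL (%g) must be below LOAEL (%g)", noael, loael)
  if (any(c(f_acute_ld50, f_acute_ld0, f_chronic) < 1))
    stop_config("interspecies factors are divisors and must be >= 1")
  structure(list(ld0 = ld0, ld50 = ld50, noael = noael, loael = loael,
                 f_acute_ld50 = f_acute_ld50, f_acute_ld0 = f_acute_ld0,
                 f_chronic = f_chronic, loael_effect = loael_effect,
                 noael_effect_band = noael_effect_band),
            class = "lagopop_endpoints")
}

#' Derive the acute mortality dose-response line
#'
#' Fits the straight line through the two acute anchor points
#' `(LD0 / f_acute_ld0, 0)` and `(LD50 / f_acute_ld50, 0.5)`, i.e. zero
#' mortality at the adjusted LD0 and 50% mortality at the adjusted LD50. An
#' absent LD0 anchors the line at the origin.
#'
#' @param inputs a [endpoint_inputs()] object with `ld50` (and usually `ld0`).
#' @return a [dose_response()] object (input: same-day dietary exposure in
#'   mg/kg bw/day).
#' @export
#' @examples
#' # LD0 > 200, LD50 > 2000 mg/kg bw, no interspecies correction:
#' derive_acute_dr(endpoint_inputs(ld0 = 200, ld50 = 2000))
derive_acute_dr <- function(inputs) {
  stopifnot(inherits(inputs, "lagopop_endpoints"))
  if (is.na(inputs$ld50)) stop_config("acute derivation requires an LD50")
  x0 <- if (is.na(inputs$ld0)) 0 else inputs$ld0 / inputs$f_acute_ld0
  x1 <- inputs$ld50 / inputs$f_acute_ld50
  if (x1 <= x0)
    stop_config("degenerate acute anchors: adjusted LD0 (%g) >= adjusted LD50 (%g)",
                x0, x1)
  slope <- 0.5 / (x1 - x0)
  dose_response(slope, intercept = -slope * x0)
}

#' Derive a chronic or reproductive dose-response line
#'
#' Fits the straight line through the origin and
#' `(LOAEL / f_chronic, loael_effect)`: the interspecies-adjusted LOAEL is
#' allocated the default 25% level of effect. When a NOAEL is supplied, the
#' implied effect at the adjusted NOAEL is checked against the 5--10%
#' linearity band and the verdict attached to the result.
#'
#' @param inputs a [endpoint_inputs()] object with `loael` (and usually
#'   `noael`).
#' @param loael overriding LOAEL (mg/kg bw/day); defaults to `inputs$loael`.
#'   Chronic-mortality and reproduction lines often come from different
#'   endpoints of the same pesticide.
#' @param noael overriding NOAEL; defaults to `inputs$noael`.
#' @return a [dose_response()] object (input: time-weighted-average exposure
#'   in mg/kg bw/day) with attributes `noael_effect` (effect rate at the
#'   adjusted NOAEL, or `NA`) and `noael_in_band` (logical verdict).
#' @export
derive_chronic_dr <- function(inputs, loael = inputs$loael, noael = inputs$noael) {
  stopifnot(inherits(inputs, "lagopop_endpoints"))
  if (is.na(loael)) stop_config("chronic derivation requires a LOAEL")
  x1 <- loael / inputs$f_chronic
  if (x1 <= 0) stop_config("adjusted LOAEL must be positive, got %g", x1)
  dr <- dose_response(inputs$loael_effect / x1, intercept = 0)
  if (!is.na(noael)) {
    e <- evaluate_dr(dr, noael / inputs$f_chronic)
    attr(dr, "noael_effect") <- e
    attr(dr, "noael_in_band") <- e >= inputs$noael_effect_band[1] &&
      e <= inputs$noael_effect_band[2]
  } else {
    attr(dr, "noael_effect") <- NA_real_
    attr(dr, "noael_in_band") <- NA
  }
  dr
}

#' Evaluate a dose-response line at a given exposure
#'
#' @param dr a [dose_response()] object.
#' @param exposure non-negative exposure (mg/kg bw/day); vectorised.
#' @return effect rate(s) in `[0, 1]`.
#' @export
evaluate_dr <- function(dr, exposure) {
  stopifnot(inherits(dr, "lagopop_dr"))
  if (any(exposure < 0)) stop_config("exposure must be non-negative")
  pmin(1, pmax(0, dr$slope * exposure + dr$intercept))
}

#' Combine background and pesticide mortality rates
#'
#' Independent-survival combination: the accumulated mortality rate is one
#' minus the product of the individual survival probabilities,
#' `1 - (1 - background) * prod(1 - rates)`. For acute mortality the
#' background is 0 (no background acute mortality is assumed).
#'
#' @param background background mortality rate in `[0, 1]`.
#' @param pesticide_rates numeric vector of per-pesticide mortality rates in
#'   `[0, 1]` (may be empty).
#' @return accumulated mortality rate in `[0, 1]`.
#' @export
#' @examples
#' combine_mortality(0.11, 0.25) # 1 - 0.89 * 0.75 = 0.3325
combine_mortality <- function(background, pesticide_rates = numeric(0)) {
  check_fraction(background, "background mortality")
  check_fraction(pesticide_rates, "pesticide mortality rates")
  1 - (1 - background) * prod(1 - pesticide_rates)
}

#' Combine background reproduction with pesticide reproductive effects
#'
#' Final monthly reproduction rate: the background rate (offspring per
#' reproductive female per month) multiplied by `1 - effect` for each
#' pesticide acting independently.
#'
#' @param background background monthly reproduction rate (>= 0).
#' @param pesticide_effects per-pesticide reproductive effect rates in
#'   `[0, 1]` (may be empty).
#' @return reduced monthly reproduction rate.
#' @export
#' @examples
#' combine_reproduction(4, 0.25) # 3
combine_reproduction <- function(background, pesticide_effects = numeric(0)) {
  if (any(background < 0)) stop_config("background reproduction must be >= 0")
  check_fraction(pesticide_effects, "pesticide reproductive effects")
  background * prod(1 - pesticide_effects)
}

#' Toxicity profile of one pesticide
#'
#' Collects the three effect pathways of a pesticide -- acute mortality
#' (driven by the same-day exposure), chronic mortality and reproductive
#' effects (driven by time-weighted-average exposure over pesticide-specific
#' windows) -- together with the month-lag rules that connect exposure months
#' to effect months.
#'
#' @param pesticide name.
#' @param acute [dose_response()] for acute mortality, or `NULL` for none.
#' @param chronic [dose_response()] for chronic mortality, or `NULL`.
#' @param reproduction [dose_response()] for reproductive effects, or `NULL`.
#' @param chronic_window,reproduction_window TWA window lengths in days.
#' @param mortality_lag_months months of lag between the exposure month whose
#'   maximum TWA is used and the month whose mortality it modifies (default 1:
#'   previous month).
#' @param reproduction_lag_months vector of month lags contributing to a
#'   month's reproductive effect (default `c(1, 2)`: the two previous months;
#'   use `1` for a 30-day pregnancy reading).
#' @return an object of class `lagopop_profile`.
#' @export
toxicity_profile <- function(pesticide, acute = NULL, chronic = NULL,
                             reproduction = NULL, chronic_window = 1,
                             reproduction_window = chronic_window,
                             mortality_lag_months = 1,
                             reproduction_lag_months = c(1, 2)) {
  for (dr in list(acute, chronic, reproduction))
    if (!is.null(dr) && !inherits(dr, "lagopop_dr"))
      stop_config("dose-response components must be dose_response() objects")
  if (chronic_window < 1 || reproduction_window < 1)
    stop_config("TWA windows must be >= 1 day")
  if (any(c(mortality_lag_months, reproduction_lag_months) < 0))
    stop_config("month lags must be >= 0")
  structure(list(pesticide = pesticide, acute = acute, chronic = chronic,
                 reproduction = reproduction,
                 chronic_window = as.integer(chronic_window),
                 reproduction_window = as.integer(reproduction_window),
                 mortality_lag_months = as.integer(mortality_lag_months),
                 reproduction_lag_months = as.integer(reproduction_lag_months)),
            class = "lagopop_profile")
}

#' @export
print.lagopop_profile <- function(x, ...) {
  cat("Pesticide toxicity profile:", x$pesticide, "\n")
  if (!is.null(x$acute)) {
    cat("  acute (daily exposure):        "); print(x$acute)
  }
  if (!is.null(x$chronic)) {
    cat(sprintf("  chronic (%d-day TWA):           ", x$chronic_window))
    print(x$chronic)
  }
  if (!is.null(x$reproduction)) {
    cat(sprintf("  reproduction (%d-day TWA):      ", x$reproduction_window))
    print(x$reproduction)
  }
  cat(sprintf("  lags: mortality %d month(s); reproduction month(s) {%s}\n",
              x$mortality_lag_months,
              paste(x$reproduction_lag_months, collapse = ", ")))
  invisible(x)
}
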