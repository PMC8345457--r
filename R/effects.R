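#' Effective monthly rates under pesticide exposure
#'
#' Applies the month-lag schedule: for month `m`, the chronic mortality effect
#' of each pesticide is its chronic dose-response evaluated at the maximum TWA
#' exposure of month `m - mortality_lag_months`; the reproductive effect is
#' the reproduction dose-response evaluated at the largest of the monthly
#' maximum TWAs over the reproduction lag months (default: the two previous
#' months). Months before the simulation start contribute zero exposure.
#' Effects are folded into the background rates by [combine_mortality()] and
#' [combine_reproduction()].
#'
#' @param month 0-based month block index.
#' @param profiles list of [toxicity_profile()] objects.
#' @param series named list of [exposure_series()], one per pesticide in
#'   `profiles`.
#' @param background list with numeric vectors `mortality` and `reproduction`
#'   (one entry per age group).
#' @param days_per_month days per month block.
#' @param intake_multipliers per-group multipliers on exposure (default 1).
#' @return list with per-group vectors `mortality` and `reproduction`, plus
#'   matrices `chronic_effect` and `reproduction_effect`
#'   (pesticide x age group) for auditing.
#' @export
effective_rates_for_month <- function(month, profiles, series, background,
                                      days_per_month = 30,
                                      intake_multipliers =
                                        rep(1, length(background$mortality))) {
  ng <- length(background$mortality)
  stopifnot(length(background$reproduction) == ng)
  np <- length(profiles)
  chronic_eff <- matrix(0, np, ng)
  repro_eff <- matrix(0, np, ng)
  pest_names <- character(np)
  for (i in seq_len(np)) {
    pr <- profiles[[i]]
    pest_names[i] <- pr$pesticide
    s <- series[[pr$pesticide]]
    if (is.null(s))
      stop_config("no exposure series for pesticide '%s'", pr$pesticide)
    if (!is.null(pr$chronic)) {
      m_src <- month - pr$mortality_lag_months
      x <- if (m_src < 0) 0 else
        max_monthly_twa(s, pr$chronic_window, m_src, days_per_month)
      chronic_eff[i, ] <- evaluate_dr(pr$chronic, x * intake_multipliers)
    }
    if (!is.null(pr$reproduction)) {
      xs <- vapply(pr$reproduction_lag_months, function(lag) {
        m_src <- month - lag
        if (m_src < 0) 0 else
          max_monthly_twa(s, pr$reproduction_window, m_src, days_per_month)
      }, numeric(1))
      repro_eff[i, ] <- evaluate_dr(pr$reproduction, max(xs) * intake_multipliers)
    }
  }
  dimnames(chronic_eff) <- dimnames(repro_eff) <- list(pest_names, NULL)
  mortality <- vapply(seq_len(ng), function(g)
    combine_mortality(background$mortality[g], chronic_eff[, g]), numeric(1))
  reproduction <- vapply(seq_len(ng), function(g)
    combine_reproduction(background$reproduction[g], repro_eff[, g]), numeric(1))
  list(mortality = mortality, reproduction = reproduction,
       chronic_effect = chronic_eff, reproduction_effect = repro_eff)
}

# Per-group acute mortality rate for one day: each pesticide's acute line at
# the day's exposure, combined with zero background acute mortality.
acute_rates_for_day <- function(day, profiles, series, ng, intake_multipliers) {
  rates <- numeric(ng)
  acute <- matrix(0, length(profiles), ng)
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    if (is.null(pr$acute)) next
    x <- series[[pr$pesticide]]$ete[day + 1L]
    acute[i, ] <- evaluate_dr(pr$acute, x * intake_multipliers)
  }
  vapply(seq_len(ng), function(g) combine_mortality(0, acute[, g]), numeric(1))
}
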