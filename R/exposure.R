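#' Pesticide application event
#'
#' One application of one pesticide to one field: day, rate, and the
#' deposition fraction reaching each zone category. The treated core and inner
#' band receive the full rate by default; the outer band receives edge-of-field
#' drift, and the background none, unless overridden.
#'
#' @param pesticide name.
#' @param field_id treated field.
#' @param day simulation day of application (>= 0).
#' @param rate application rate (kg/ha, > 0).
#' @param drift_fractions named fractions per zone category; defaults
#'   `c(core = 1, inner = 1, outer = 0, background = 0)`, merged with any
#'   user-supplied entries.
#' @return an object of class `lagopop_application`.
#' @export
application_event <- function(pesticide, field_id, day, rate,
                              drift_fractions = NULL) {
  if (rate <= 0) stop_config("application rate must be positive")
  if (day < 0) stop_config("application day must be >= 0")
  drift <- c(core = 1, inner = 1, outer = 0, background = 0)
  if (!is.null(drift_fractions)) {
    bad <- setdiff(names(drift_fractions), names(drift))
    if (length(bad)) stop_config("unknown drift zones: %s", paste(bad, collapse = ", "))
    check_fraction(unlist(drift_fractions), "drift fractions")
    drift[names(drift_fractions)] <- unlist(drift_fractions)
  }
  structure(list(pesticide = pesticide, field_id = field_id,
                 day = as.integer(day), rate = rate, drift = drift),
            class = "lagopop_application")
}

#' Residue behaviour of a pesticide on a food item
#'
#' Initial residue is `RUD * application rate` (residue per unit dose), and
#' residues dissipate first-order with half-life `DT50`.
#'
#' @param pesticide name.
#' @param food_item food item the parameters apply to.
#' @param rud residue per unit dose (mg/kg fresh weight per 1 kg/ha applied).
#' @param dt50 dissipation half-life on the item (days, > 0).
#' @return an object of class `lagopop_residue_params`.
#' @export
residue_parameters <- function(pesticide, food_item, rud, dt50) {
  if (rud < 0) stop_config("RUD must be >= 0")
  if (dt50 <= 0) stop_config("DT50 must be positive")
  structure(list(pesticide = pesticide, food_item = food_item,
                 rud = rud, dt50 = dt50), class = "lagopop_residue_params")
}

#' Food intake scaling of a species
#'
#' @param species name.
#' @param fir_over_bw daily food intake rate divided by body weight
#'   (kg food / kg bw / day, > 0).
#' @return an object of class `lagopop_intake`.
#' @export
intake_parameters <- function(species, fir_over_bw) {
  if (fir_over_bw <= 0) stop_config("FIR/bw must be positive")
  structure(list(species = species, fir_over_bw = fir_over_bw),
            class = "lagopop_intake")
}

#' Residue on a food item at a given day
#'
#' Sums, over all applications at or before `day` that treat the relevant
#' field, `RUD * rate * drift(zone) * 2^(-(day - application day)/DT50)`.
#' Vectorised over `day`.
#'
#' @param day integer day(s) (>= 0).
#' @param applications list of [application_event()] (assumed already filtered
#'   to the relevant field and pesticide).
#' @param params a [residue_parameters()] object.
#' @param zone zone category: `"core"`, `"inner"`, `"outer"` or
#'   `"background"`.
#' @return residue concentration(s), mg/kg.
#' @export
residue_at <- function(day, applications, params, zone = "core") {
  stopifnot(inherits(params, "lagopop_residue_params"))
  if (!zone %in% c("core", "inner", "outer", "background"))
    stop_config("unknown zone category '%s'", zone)
  res <- numeric(length(day))
  for (app in applications) {
    if (app$pesticide != params$pesticide) next
    active <- day >= app$day
    res[active] <- res[active] +
      params$rud * app$rate * app$drift[[zone]] *
      2^(-(day[active] - app$day) / params$dt50)
  }
  res
}

#' Daily dietary exposure from residues
#'
#' Estimated theoretical exposure: the intake rate per body weight times the
#' diet-fraction-weighted sum of the residues on each (zone, food item).
#'
#' @param diet data frame from [diet_fractions()].
#' @param residues numeric vector of residues (mg/kg), one per diet row.
#' @param intake an [intake_parameters()] object.
#' @return exposure in mg/kg bw/day.
#' @export
daily_ete <- function(diet, residues, intake) {
  stopifnot(inherits(intake, "lagopop_intake"),
            length(residues) == nrow(diet))
  intake$fir_over_bw * sum(diet$fraction * residues)
}

#' Daily exposure series of a nest for one pesticide
#'
#' @param nest_id nest.
#' @param pesticide pesticide.
#' @param ete numeric vector of daily exposures (mg/kg bw/day), element `t+1`
#'   holding day `t` (days are 0-based).
#' @return an object of class `lagopop_exposure`.
#' @export
exposure_series <- function(nest_id, pesticide, ete) {
  if (any(ete < 0)) stop_config("exposure must be non-negative")
  structure(list(nest_id = nest_id, pesticide = pesticide,
                 ete = as.numeric(ete)), class = "lagopop_exposure")
}

#' Time-weighted average exposure
#'
#' Arithmetic mean of the daily exposure over the `window` days ending at day
#' `t` (window truncated at simulation start).
#'
#' @param series a [exposure_series()].
#' @param window window length in days (>= 1).
#' @param t 0-based day (vectorised).
#' @return TWA exposure(s), mg/kg bw/day.
#' @export
twa <- function(series, window, t) {
  stopifnot(inherits(series, "lagopop_exposure"))
  if (window < 1) stop_config("TWA window must be >= 1 day")
  if (any(t < 0) || any(t >= length(series$ete)))
    stop_config("day outside the simulated horizon")
  vapply(t, function(tt) {
    from <- max(0L, tt - window + 1L)
    mean(series$ete[(from + 1L):(tt + 1L)])
  }, numeric(1))
}

#' Maximum TWA exposure within a 30-day month block
#'
#' @param series a [exposure_series()].
#' @param window TWA window (days).
#' @param month_index 0-based month block; months before the simulation start
#'   are an error in direct calls (the effects scheduler treats them as zero
#'   exposure).
#' @param days_per_month days per month block.
#' @return the maximum of [twa()] over the days of the month that fall within
#'   the simulated horizon.
#' @export
max_monthly_twa <- function(series, window, month_index, days_per_month = 30) {
  if (month_index < 0) stop_config("month before simulation start")
  d0 <- month_index * days_per_month
  d1 <- min((month_index + 1) * days_per_month - 1, length(series$ete) - 1)
  if (d0 > d1) stop_config("month %d not simulated", month_index)
  max(twa(series, window, d0:d1))
}

# Cumulative-sum TWA of a bare ete vector for every day; used by the engine.
twa_series <- function(ete, window) {
  cs <- cumsum(ete)
  n <- length(ete)
  t <- seq_len(n)
  from <- pmax(0L, t - window)
  (cs[t] - c(0, cs)[from + 1L]) / (t - from)
}

#' Build per-pesticide exposure series for a nest
#'
#' Connects a nest's feeding area to the landscape and application schedule.
#' In `"landscape"` mode, zone overlap fractions are combined with food
#' weights into diet fractions, per-zone residues are computed for every day,
#' and the exposure is the intake-scaled diet-weighted residue sum. In
#' `"worst_case"` mode the whole diet is assumed to come from the treated zone
#' (core) of each treated field.
#'
#' @param nest a [nest_config()].
#' @param land a [landscape()].
#' @param applications list of [application_event()].
#' @param residue_params list of [residue_parameters()].
#' @param intake an [intake_parameters()].
#' @param horizon_days number of simulated days.
#' @param food_weights data frame (`zone`, `food_item`, `weight`); in
#'   landscape mode, zones are the labels produced by
#'   [feeding_zone_overlap()]. Defaults to weight 1 on the treated crop in
#'   each field's core and inner band and on untreated vegetation in the
#'   background.
#' @param mode `"worst_case"` (default) or `"landscape"`.
#' @param resolution raster resolution for the overlap computation.
#' @return named list of [exposure_series()], one per pesticide appearing in
#'   `applications` (empty list if no applications).
#' @export
build_exposure <- function(nest, land, applications, residue_params, intake,
                           horizon_days, food_weights = NULL,
                           mode = c("worst_case", "landscape"),
                           resolution = NULL) {
  mode <- match.arg(mode)
  pesticides <- unique(vapply(applications, `[[`, character(1), "pesticide"))
  if (!length(pesticides)) return(list())
  days <- 0:(horizon_days - 1)
  find_rp <- function(pest, item) {
    for (rp in residue_params)
      if (rp$pesticide == pest && rp$food_item == item) return(rp)
    stop_config("no residue parameters for pesticide '%s' on food item '%s'",
                pest, item)
  }
  out <- list()
  if (mode == "worst_case") {
    for (pest in pesticides) {
      ete <- numeric(horizon_days)
      apps <- Filter(function(a) a$pesticide == pest, applications)
      items <- unique(vapply(apps, function(a) treated_item(land, a), character(1)))
      for (it in items) {
        rp <- find_rp(pest, it)
        apps_it <- Filter(function(a) treated_item(land, a) == it, apps)
        ete <- ete + intake$fir_over_bw * residue_at(days, apps_it, rp, "core")
      }
      out[[pest]] <- exposure_series(nest$nest_id, pest, ete)
    }
    return(out)
  }
  area <- feeding_area(nest$nest_id, nest$location, nest$feeding_radius)
  af <- feeding_zone_overlap(area, land,
                             resolution %||% (nest$feeding_radius / 100))
  if (is.null(food_weights)) food_weights <- default_food_weights(land)
  diet <- diet_fractions(af, food_weights)
  for (pest in pesticides) {
    apps <- Filter(function(a) a$pesticide == pest, applications)
    resmat <- matrix(0, nrow = horizon_days, ncol = nrow(diet))
    for (j in seq_len(nrow(diet))) {
      z <- strsplit(diet$zone[j], ":", fixed = TRUE)[[1]]
      if (z[1] == "background") next
      apps_f <- Filter(function(a) a$field_id == z[1], apps)
      if (!length(apps_f)) next
      # untreated food items (no residue parameters) carry no residue
      rp <- tryCatch(find_rp(pest, diet$food_item[j]), error = function(e) NULL)
      if (is.null(rp)) next
      resmat[, j] <- residue_at(days, apps_f, rp, z[2])
    }
    ete <- intake$fir_over_bw * as.numeric(resmat %*% diet$fraction)
    out[[pest]] <- exposure_series(nest$nest_id, pest, ete)
  }
  out
}

# crop grown on the field treated by an application (at the application day)
treated_item <- function(land, app) {
  for (fld in land$fields) {
    if (fld$field_id != app$field_id) next
    cs <- fld$crop_schedule
    if (is.null(cs)) return("crop")
    hit <- cs$start_day <= app$day & app$day <= cs$end_day
    return(if (any(hit)) cs$crop[which(hit)[1]] else "crop")
  }
  stop_config("application targets unknown field '%s'", app$field_id)
}

# Default dietary weights: treated crop in core and inner band, in-field grass
# in the inner band, untreated vegetation in the background.
default_food_weights <- function(land) {
  rows <- list(data.frame(zone = "background", food_item = "vegetation",
                          weight = 1))
  for (fld in land$fields) {
    crop <- if (!is.null(fld$crop_schedule) && nrow(fld$crop_schedule))
      fld$crop_schedule$crop[1] else "crop"
    rows[[length(rows) + 1]] <- data.frame(
      zone = paste0(fld$field_id, c(":core", ":inner", ":inner", ":outer")),
      food_item = c(crop, crop, "grass", "vegetation"),
      weight = c(1, 0.5, 0.5, 1))
  }
  do.call(rbind, rows)
}
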