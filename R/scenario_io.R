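#' Read a scenario from a YAML or JSON file
#'
#' The file is a hierarchical key-value document with top-level keys matching
#' the [scenario_config()] arguments. Species demographic blocks are defined
#' once under `species:` and referenced by name from each nest. Toxicity
#' profiles may be given either as raw endpoints (`ld0`, `ld50`, `loael`,
#' `noael`, factors), from which the dose-response lines are derived at load
#' time, or as pre-derived `slope`/`intercept` pairs. See the bundled example
#' files under `inst/extdata/`.
#'
#' @param path file path (`.yml`, `.yaml` or `.json`).
#' @return a [scenario_config()] object.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  scenario_from_list(raw)
}

#' Build a scenario from a nested list (parsed YAML/JSON)
#'
#' @param raw nested list with the schema described in [read_scenario()].
#' @return a [scenario_config()] object.
#' @export
scenario_from_list <- function(raw) {
  species <- lapply(raw$species %||% list(), function(sp)
    make_age_groups(unlist(sp$thresholds), unlist(sp$mortality),
                    unlist(sp$reproduction)))
  seasons <- lapply(raw$species %||% list(), function(sp) unlist(sp$season))
  nests <- lapply(raw$nests %||% list(), function(n) {
    spn <- n$species %||% "rabbit"
    ag <- species[[spn]]
    if (is.null(ag)) stop_config("nest '%s': unknown species '%s'", n$nest_id, spn)
    nest_config(nest_id = n$nest_id,
                location = unlist(n$location) %||% c(0, 0),
                species = spn, age_groups = ag,
                initial_counts = unlist(n$initial_counts),
                sex_ratio_male = n$sex_ratio_male %||% 0.5,
                reproductive_season = unlist(n$season) %||% seasons[[spn]],
                feeding_radius = n$feeding_radius %||% 100)
  })
  fields <- lapply(raw$landscape$fields %||% list(), function(f) {
    cs <- if (!is.null(f$crop_schedule)) as.data.frame(do.call(rbind, lapply(
      f$crop_schedule, as.data.frame)))
    if (!is.null(f$rect))
      rect_field(f$field_id, f$rect[[1]], f$rect[[2]], f$rect[[3]], f$rect[[4]],
                 crop_schedule = cs,
                 inner_band_width = f$inner_band_width %||% 0,
                 outer_band_width = f$outer_band_width %||% 0)
    else
      field(f$field_id, do.call(rbind, lapply(f$polygon, unlist)),
            crop_schedule = cs,
            inner_band_width = f$inner_band_width %||% 0,
            outer_band_width = f$outer_band_width %||% 0)
  })
  apps <- lapply(raw$applications %||% list(), function(a)
    application_event(a$pesticide, a$field_id, a$day, a$rate,
                      drift_fractions = a$drift_fractions))
  rps <- lapply(raw$residue_parameters %||% list(), function(r)
    residue_parameters(r$pesticide, r$food_item %||% "crop", r$rud, r$dt50))
  intake <- if (!is.null(raw$intake))
    intake_parameters(raw$intake$species %||% "rabbit", raw$intake$fir_over_bw)
  profiles <- lapply(raw$toxicity_profiles %||% list(), profile_from_list)
  scenario_config(
    horizon_days = raw$horizon_days, nests = nests,
    land = landscape(fields), applications = apps, residue_params = rps,
    intake = intake, profiles = profiles,
    iterations = raw$iterations %||% 1, base_seed = raw$base_seed %||% 1,
    summary_mode = raw$summary_mode %||% "mean_ci95",
    days_per_month = raw$days_per_month %||% 30,
    start_month = raw$start_month %||% 12,
    rate_conversion = raw$rate_conversion %||% "uniform",
    exposure_mode = raw$exposure_mode %||% "worst_case")
}

# one toxicity profile from its list form (raw endpoints or slope/intercept)
profile_from_list <- function(p) {
  dr_from <- function(block, derive) {
    if (is.null(block)) return(NULL)
    if (!is.null(block$slope))
      return(dose_response(block$slope, block$intercept %||% 0))
    derive(block)
  }
  acute <- dr_from(p$acute, function(b)
    derive_acute_dr(endpoint_inputs(ld0 = b$ld0 %||% NA, ld50 = b$ld50,
                                    f_acute_ld50 = b$f_acute_ld50 %||% 1,
                                    f_acute_ld0 = b$f_acute_ld0 %||% 1)))
  mk_chronic <- function(b)
    derive_chronic_dr(endpoint_inputs(loael = b$loael, noael = b$noael %||% NA,
                                      f_chronic = b$f_chronic %||% 5,
                                      loael_effect = b$loael_effect %||% 0.25))
  chronic <- dr_from(p$chronic, mk_chronic)
  repro <- dr_from(p$reproduction, mk_chronic)
  toxicity_profile(p$pesticide, acute = acute, chronic = chronic,
                   reproduction = repro,
                   chronic_window = p$chronic$window %||% 1,
                   reproduction_window = p$reproduction$window %||%
                     (p$chronic$window %||% 1),
                   mortality_lag_months = p$mortality_lag_months %||% 1,
                   reproduction_lag_months =
                     unlist(p$reproduction_lag_months) %||% c(1, 2))
}

#' Write a scenario to a YAML file
#'
#' Inverse of [read_scenario()] for the subset of scenarios expressible in the
#' file schema (rectangular or polygon fields, derived or explicit
#' dose-response lines are written as explicit `slope`/`intercept`).
#'
#' @param cfg a [scenario_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(cfg, path) {
  sp_key <- function(n) n$species
  species <- list()
  nests <- lapply(cfg$nests, function(n) {
    species[[sp_key(n)]] <<- list(
      thresholds = as.integer(group_thresholds(n$age_groups)),
      mortality = vapply(n$age_groups, `[[`, numeric(1), "monthly_mortality"),
      reproduction = vapply(n$age_groups, `[[`, numeric(1),
                            "monthly_reproduction"),
      season = as.integer(n$reproductive_season))
    list(nest_id = n$nest_id, species = n$species,
         location = as.numeric(n$location),
         initial_counts = as.integer(n$initial_counts),
         sex_ratio_male = n$sex_ratio_male,
         feeding_radius = n$feeding_radius)
  })
  fields <- lapply(cfg$landscape$fields, function(f) {
    out <- list(field_id = f$field_id,
                inner_band_width = f$inner_band_width,
                outer_band_width = f$outer_band_width)
    if (f$is_rect)
      out$rect <- c(min(f$polygon[, 1]), min(f$polygon[, 2]),
                    max(f$polygon[, 1]), max(f$polygon[, 2]))
    else out$polygon <- apply(f$polygon, 1, as.numeric, simplify = FALSE)
    if (!is.null(f$crop_schedule))
      out$crop_schedule <- lapply(seq_len(nrow(f$crop_schedule)), function(i)
        as.list(f$crop_schedule[i, ]))
    out
  })
  dr_list <- function(dr) if (is.null(dr)) NULL else
    list(slope = dr$slope, intercept = dr$intercept)
  profiles <- lapply(cfg$profiles, function(p) {
    out <- list(pesticide = p$pesticide)
    if (!is.null(p$acute)) out$acute <- dr_list(p$acute)
    if (!is.null(p$chronic)) out$chronic <- c(dr_list(p$chronic),
                                              list(window = p$chronic_window))
    if (!is.null(p$reproduction))
      out$reproduction <- c(dr_list(p$reproduction),
                            list(window = p$reproduction_window))
    out$mortality_lag_months <- p$mortality_lag_months
    out$reproduction_lag_months <- as.integer(p$reproduction_lag_months)
    out
  })
  doc <- list(horizon_days = cfg$horizon_days,
              days_per_month = cfg$days_per_month,
              start_month = cfg$start_month,
              iterations = cfg$iterations, base_seed = cfg$base_seed,
              summary_mode = cfg$summary_mode,
              rate_conversion = cfg$rate_conversion,
              exposure_mode = cfg$exposure_mode,
              species = species, nests = nests,
              landscape = list(fields = fields),
              applications = lapply(cfg$applications, function(a)
                list(pesticide = a$pesticide, field_id = a$field_id,
                     day = a$day, rate = a$rate,
                     drift_fractions = as.list(a$drift))),
              residue_parameters = lapply(cfg$residue_params, function(r)
                list(pesticide = r$pesticide, food_item = r$food_item,
                     rud = r$rud, dt50 = r$dt50)),
              intake = if (!is.null(cfg$intake))
                list(species = cfg$intake$species,
                     fir_over_bw = cfg$intake$fir_over_bw),
              toxicity_profiles = profiles)
  yaml::write_yaml(doc, path)
  invisible(path)
}
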