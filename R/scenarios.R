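#' Bundled case-study fixtures
#'
#' Ready-to-run scenarios for the lagomorph case study: species demographic
#' defaults, glyphosate and bromoxynil toxicity profiles derived from EFSA
#' endpoints, and landscape/treatment experiments. Every numeric default
#' carries a provenance note; exposure-side values that regulatory guidance
#' supplies per crop and species (RUD, DT50, FIR/bw, feeding radius, drift)
#' are clearly labelled non-normative placeholders and are user-overridable.
#'
#' @name fixtures
NULL

new_fixture <- function(name, scenario, description, provenance) {
  structure(list(name = name, scenario = scenario, description = description,
                 provenance = provenance), class = "lagopop_fixture")
}

#' @export
print.lagopop_fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s': %s\n", x$name, x$description))
  print(x$scenario)
  invisible(x)
}

prov <- function(parameter, value, source) {
  data.frame(parameter = parameter, value = as.character(value),
             source = source)
}

SRC_ECO <- "species defaults from lagomorph ecology reviews"
SRC_EFSA <- "EFSA assessment endpoint"
SRC_PLACEHOLDER <- "non-normative placeholder (regulatory guidance supplies crop/species-specific values)"

#' Rabbit demographic defaults
#'
#' Four age groups (infant, juvenile, subadult, adult) with background monthly
#' mortalities 0.77/0.38/0.11/0.11, reproduction 0/0/0/4 offspring per
#' reproductive female per month, breeding December to May (Mediterranean
#' conditions). Age thresholds 0/30/120/270 days are modelling defaults (the
#' ecology reviews report maturation between four and nine months).
#'
#' @return list of four [age_group()] objects.
#' @export
rabbit_age_groups <- function() {
  make_age_groups(c(0L, 30L, 120L, 270L),
                  c(0.77, 0.38, 0.11, 0.11),
                  c(0, 0, 0, 4))
}

#' @rdname rabbit_age_groups
#' @export
rabbit_season <- function() c(12L, 1L, 2L, 3L, 4L, 5L)

#' Hare demographic defaults
#'
#' Background monthly mortalities 0.87/0.30/0.08/0.08, reproduction
#' 0/0/0.6/1.75 (young and adult reproductive females), breeding January to
#' August (central Europe). Age thresholds 0/30/180/365 days.
#'
#' @return list of four [age_group()] objects.
#' @export
hare_age_groups <- function() {
  make_age_groups(c(0L, 30L, 180L, 365L),
                  c(0.87, 0.30, 0.08, 0.08),
                  c(0, 0, 0.6, 1.75))
}

#' @rdname hare_age_groups
#' @export
hare_season <- function() 1:8

#' Default rabbit nest
#'
#' 140 individuals split 0/0/60/80 over the age groups: the December
#' (season-start) stationary age structure implied by the default rates, under
#' which no infants or juveniles remain from the previous season.
#'
#' @param nest_id identifier.
#' @param initial_counts per-group counts (default `c(0, 0, 60, 80)`).
#' @param location,feeding_radius see [nest_config()].
#' @return a [nest_config()].
#' @export
rabbit_nest <- function(nest_id = "nest1", initial_counts = c(0, 0, 60, 80),
                        location = c(0, 0), feeding_radius = 150) {
  nest_config(nest_id, location = location, species = "rabbit",
              age_groups = rabbit_age_groups(),
              initial_counts = initial_counts,
              reproductive_season = rabbit_season(),
              feeding_radius = feeding_radius)
}

#' Default hare nest
#'
#' @param nest_id identifier.
#' @param initial_counts per-group counts (default `c(0, 10, 30, 60)`).
#' @param location,feeding_radius see [nest_config()].
#' @return a [nest_config()].
#' @export
hare_nest <- function(nest_id = "nest1", initial_counts = c(0, 10, 30, 60),
                      location = c(0, 0), feeding_radius = 300) {
  nest_config(nest_id, location = location, species = "hare",
              age_groups = hare_age_groups(),
              initial_counts = initial_counts,
              reproductive_season = hare_season(),
              feeding_radius = feeding_radius)
}

species_provenance <- function(species) {
  if (species == "rabbit")
    rbind(prov("monthly mortality (groups 0-3)", "0.77/0.38/0.11/0.11", SRC_ECO),
          prov("monthly reproduction (groups 0-3)", "0/0/0/4", SRC_ECO),
          prov("reproductive season", "December-May", SRC_ECO),
          prov("initial individuals per nest", 140, SRC_ECO),
          prov("sex ratio", "1:1", SRC_ECO),
          prov("age thresholds (days)", "0/30/120/270", "modelling default"),
          prov("initial split per group", "0/0/60/80",
               "stationary December age structure (modelling default)"),
          prov("feeding radius (m)", 150, SRC_PLACEHOLDER))
  else
    rbind(prov("monthly mortality (groups 0-3)", "0.87/0.30/0.08/0.08", SRC_ECO),
          prov("monthly reproduction (groups 0-3)", "0/0/0.6/1.75", SRC_ECO),
          prov("reproductive season", "January-August", SRC_ECO),
          prov("initial individuals per nest", 100, SRC_ECO),
          prov("sex ratio", "1:1", SRC_ECO),
          prov("age thresholds (days)", "0/30/180/365", "modelling default"),
          prov("feeding radius (m)", 300, SRC_PLACEHOLDER))
}

#' Rabbit default scenario (pesticide-free)
#'
#' One nest of 140 rabbits simulated for 1000 days over 50 replicates,
#' starting in December at the onset of the reproductive season.
#'
#' @param horizon_days,iterations,base_seed overridable run settings.
#' @return a fixture (name, scenario, description, provenance).
#' @export
rabbit_default <- function(horizon_days = 1000, iterations = 50, base_seed = 1) {
  cfg <- scenario_config(horizon_days = horizon_days,
                         nests = list(rabbit_nest()),
                         iterations = iterations, base_seed = base_seed,
                         start_month = 12)
  new_fixture("rabbit_default", cfg,
              "wild rabbit, Mediterranean defaults, no pesticide",
              species_provenance("rabbit"))
}

#' Hare default scenario (pesticide-free)
#'
#' One nest of 100 brown hares simulated for 1000 days over 50 replicates,
#' starting in January at the onset of the reproductive season.
#'
#' @inheritParams rabbit_default
#' @return a fixture.
#' @export
hare_default <- function(horizon_days = 1000, iterations = 50, base_seed = 1) {
  cfg <- scenario_config(horizon_days = horizon_days,
                         nests = list(hare_nest()),
                         iterations = iterations, base_seed = base_seed,
                         start_month = 1)
  new_fixture("hare_default", cfg,
              "brown hare, central-European defaults, no pesticide",
              species_provenance("hare"))
}

#' Glyphosate toxicity endpoints and profile
#'
#' Acute: LD50 > 2000 and LD0 > 200 mg/kg bw ("greater than" values, so no
#' interspecies correction). Chronic: LOAEL 175 mg/kg bw/day (maternal
#' toxicity, rabbit developmental study), NOAEL 50, interspecies factor 5,
#' 12-day TWA window; the reproduction line reuses the chronic line (maternal
#' toxicity was more sensitive than developmental toxicity).
#'
#' @return `glyphosate_endpoints()`: a list with elements `acute` and
#'   `chronic` ([endpoint_inputs()] objects); `glyphosate_profile()`: the
#'   derived [toxicity_profile()].
#' @export
glyphosate_endpoints <- function() {
  list(acute = endpoint_inputs(ld0 = 200, ld50 = 2000,
                               f_acute_ld50 = 1, f_acute_ld0 = 1),
       chronic = endpoint_inputs(noael = 50, loael = 175, f_chronic = 5))
}

#' @rdname glyphosate_endpoints
#' @export
glyphosate_profile <- function() {
  ep <- glyphosate_endpoints()
  chronic <- derive_chronic_dr(ep$chronic)
  toxicity_profile("glyphosate",
                   acute = derive_acute_dr(ep$acute),
                   chronic = chronic, reproduction = chronic,
                   chronic_window = 12, reproduction_window = 12)
}

#' Bromoxynil toxicity endpoints and profile
#'
#' Acute: rat LD50 130 mg/kg bw with an interspecies factor of 5 (adjusted
#' anchor 26) and LD0 10 without correction (absence of mortality confirmed in
#' rabbits). Chronic: LOAEL 17.1 mg/kg bw/day (subacute, mouse), factor 5,
#' 5-day TWA window. Reproduction: LOAEL 12.5 mg/kg bw/day (post-implantation
#' loss and malformation), factor 5, 5-day window.
#'
#' @return `bromoxynil_endpoints()`: list with `acute`, `chronic`,
#'   `reproduction` [endpoint_inputs()]; `bromoxynil_profile()`: the derived
#'   [toxicity_profile()].
#' @export
bromoxynil_endpoints <- function() {
  list(acute = endpoint_inputs(ld0 = 10, ld50 = 130,
                               f_acute_ld50 = 5, f_acute_ld0 = 1),
       chronic = endpoint_inputs(loael = 17.1, f_chronic = 5),
       reproduction = endpoint_inputs(loael = 12.5, f_chronic = 5))
}

#' @rdname bromoxynil_endpoints
#' @export
bromoxynil_profile <- function() {
  ep <- bromoxynil_endpoints()
  toxicity_profile("bromoxynil",
                   acute = derive_acute_dr(ep$acute),
                   chronic = derive_chronic_dr(ep$chronic),
                   reproduction = derive_chronic_dr(ep$reproduction),
                   chronic_window = 5, reproduction_window = 5)
}

#' Endpoint provenance for the two case-study pesticides
#'
#' @return data frame with one row per numeric endpoint.
#' @export
pesticide_provenance <- function() {
  rbind(prov("glyphosate LD0 / LD50 (mg/kg bw)", "200 / 2000", SRC_EFSA),
        prov("glyphosate NOAEL / LOAEL (mg/kg bw/day)", "50 / 175", SRC_EFSA),
        prov("glyphosate chronic TWA window (days)", 12, SRC_EFSA),
        prov("bromoxynil LD0 / LD50 (mg/kg bw)", "10 / 130 (factor 5 on LD50 only)", SRC_EFSA),
        prov("bromoxynil chronic LOAEL (mg/kg bw/day)", 17.1, SRC_EFSA),
        prov("bromoxynil reproduction LOAEL (mg/kg bw/day)", 12.5, SRC_EFSA),
        prov("bromoxynil TWA windows (days)", 5, SRC_EFSA),
        prov("interspecies factor, chronic", 5, SRC_EFSA),
        prov("LOAEL default effect level", 0.25, SRC_EFSA),
        prov("NOAEL linearity band", "0.05-0.10", SRC_EFSA),
        prov("RUD cereals/grass (mg/kg per kg/ha)", 85, SRC_PLACEHOLDER),
        prov("DT50 glyphosate / bromoxynil (days)", "10 / 3", SRC_PLACEHOLDER),
        prov("FIR/bw (kg food / kg bw / day)", 0.45, SRC_PLACEHOLDER))
}

# placeholder exposure parameterization shared by the treatment fixtures
case_residue_params <- function() {
  list(residue_parameters("glyphosate", "cereal", rud = 85, dt50 = 10),
       residue_parameters("bromoxynil", "cereal", rud = 85, dt50 = 3))
}

case_intake <- function() intake_parameters("rabbit", fir_over_bw = 0.45)

cereal_field <- function(field_id = "f1", xmin = 0, ymin = 0, size = 400,
                         inner = 0, outer = 0) {
  rect_field(field_id, xmin, ymin, xmin + size, ymin + size,
             crop_schedule = data.frame(crop = "cereal", start_day = 0,
                                        end_day = 100000),
             inner_band_width = inner, outer_band_width = outer)
}

#' Treatment and design experiments mirroring the case study
#'
#' A set of ready-to-run fixtures:
#' \describe{
#'   \item{replicability}{4 identical rabbit nests, 1000 days, 50 replicates
#'     (run twice with different seeds to assess replicability).}
#'   \item{density_sweep}{initial nest sizes 30, 70, 100, 140, 200.}
#'   \item{longrun}{one nest over 10000 days.}
#'   \item{rate_combinations}{five nests with different mortality/reproduction
#'     combinations and season lengths.}
#'   \item{glyphosate_2x4}{two applications of glyphosate on cereals at
#'     4.0 kg/ha during the rabbit reproductive period (worst-case diet).}
#'   \item{bromoxynil_1x1}{one application of bromoxynil at 1.0 kg/ha.}
#'   \item{dose_timing_<d>}{four nests on separate fields -- control plus
#'     bromoxynil at 0.05, 0.1 and 0.2 kg/ha -- treated `d` days after the
#'     start of the breeding season (`d` in 15, 30, 90, 120).}
#'   \item{splitting_total01}{one, two or three applications summing
#'     0.1 kg/ha.}
#'   \item{splitting_interval}{three 0.05 kg/ha applications at 15-day or
#'     monthly intervals versus a single application.}
#' }
#'
#' @param iterations,base_seed run settings applied to every fixture.
#' @return named list of fixtures.
#' @export
figure_experiments <- function(iterations = 50, base_seed = 1) {
  fx <- list()
  pp <- pesticide_provenance()

  fx$replicability <- new_fixture(
    "replicability",
    scenario_config(1000, nests = lapply(1:4, function(i)
      rabbit_nest(paste0("nest", i))),
      iterations = iterations, base_seed = base_seed, start_month = 12),
    "identical rabbit nests, no pesticide; compare independent runs",
    species_provenance("rabbit"))

  dens <- c(30, 70, 100, 140, 200)
  fx$density_sweep <- new_fixture(
    "density_sweep",
    scenario_config(1000, nests = lapply(dens, function(n0) {
      counts <- round(n0 * c(0, 0, 60, 80) / 140)
      rabbit_nest(paste0("init", n0), initial_counts = counts)
    }), iterations = iterations, base_seed = base_seed, start_month = 12),
    "initial nest sizes 30-200, no pesticide",
    rbind(species_provenance("rabbit"),
          prov("initial sizes", "30-200", SRC_ECO)))

  fx$longrun <- new_fixture(
    "longrun",
    scenario_config(10000, nests = list(rabbit_nest()),
                    iterations = iterations, base_seed = base_seed,
                    start_month = 12),
    "long-horizon stability check (10000 days)",
    species_provenance("rabbit"))

  combos <- list(  # mortality of groups 2-3, reproduction, season length
    list(m = 0.11, r = 4.0, len = 6), list(m = 0.22, r = 8.0, len = 6),
    list(m = 0.22, r = 4.0, len = 12), list(m = 0.22, r = 4.0, len = 6),
    list(m = 0.16, r = 6.0, len = 6))
  fx$rate_combinations <- new_fixture(
    "rate_combinations",
    scenario_config(1000, nests = lapply(seq_along(combos), function(i) {
      cb <- combos[[i]]
      ag <- make_age_groups(c(0L, 30L, 120L, 270L),
                            c(0.77, 0.38, cb$m, cb$m), c(0, 0, 0, cb$r))
      months <- month_of_year(seq_len(cb$len) - 1, 12)
      nest_config(paste0("nest", i), species = "rabbit", age_groups = ag,
                  initial_counts = c(0, 0, 60, 80),
                  reproductive_season = months, feeding_radius = 150)
    }), iterations = iterations, base_seed = base_seed, start_month = 12),
    "mortality/reproduction/season-length combinations",
    rbind(species_provenance("rabbit"),
          prov("rate combinations", "0.11-0.22 / 4-8 / 6-12 months", SRC_ECO)))

  worst_case <- function(name, apps, description, horizon = 540) {
    applied <- unique(vapply(apps, `[[`, character(1), "pesticide"))
    profs <- Filter(function(p) p$pesticide %in% applied,
                    list(glyphosate_profile(), bromoxynil_profile()))
    cfg <- scenario_config(horizon, nests = list(rabbit_nest()),
                           land = landscape(list(cereal_field())),
                           applications = apps,
                           residue_params = case_residue_params(),
                           intake = case_intake(),
                           profiles = profs,
                           iterations = iterations, base_seed = base_seed,
                           start_month = 12, exposure_mode = "worst_case")
    new_fixture(name, cfg, description, rbind(species_provenance("rabbit"), pp))
  }
  fx$glyphosate_2x4 <- worst_case(
    "glyphosate_2x4",
    list(application_event("glyphosate", "f1", 30, 4.0),
         application_event("glyphosate", "f1", 75, 4.0)),
    "two glyphosate applications on cereals at 4.0 kg/ha in the breeding season")
  fx$bromoxynil_1x1 <- worst_case(
    "bromoxynil_1x1",
    list(application_event("bromoxynil", "f1", 30, 1.0)),
    "one bromoxynil application on cereals at 1.0 kg/ha in the breeding season")

  # dose x timing grid: 4 nests on separate fields, nest 1 untreated control
  for (d in c(15L, 30L, 90L, 120L)) {
    rates <- c(0, 0.05, 0.1, 0.2)
    fields <- lapply(1:4, function(i)
      cereal_field(paste0("f", i), xmin = (i - 1) * 2000, ymin = 0))
    nests <- lapply(1:4, function(i)
      rabbit_nest(paste0("nest", i),
                  location = c((i - 1) * 2000 + 200, 200),
                  feeding_radius = 100))
    apps <- lapply(which(rates > 0), function(i)
      application_event("bromoxynil", paste0("f", i), d, rates[i]))
    fx[[paste0("dose_timing_", d)]] <- new_fixture(
      paste0("dose_timing_", d),
      scenario_config(540, nests = nests, land = landscape(fields),
                      applications = apps,
                      residue_params = case_residue_params(),
                      intake = case_intake(),
                      profiles = list(bromoxynil_profile()),
                      iterations = iterations, base_seed = base_seed,
                      start_month = 12, exposure_mode = "landscape"),
      sprintf("bromoxynil 0/0.05/0.1/0.2 kg/ha applied %d days after season start", d),
      rbind(species_provenance("rabbit"), pp))
  }

  split_fixture <- function(name, app_sets, description) {
    fields <- lapply(seq_along(app_sets), function(i)
      cereal_field(paste0("f", i), xmin = (i - 1) * 2000, ymin = 0))
    nests <- lapply(seq_along(app_sets), function(i)
      rabbit_nest(paste0("nest", i),
                  location = c((i - 1) * 2000 + 200, 200),
                  feeding_radius = 100))
    apps <- unlist(lapply(seq_along(app_sets), function(i)
      lapply(app_sets[[i]], function(a)
        application_event("bromoxynil", paste0("f", i), a[1], a[2]))),
      recursive = FALSE)
    new_fixture(name,
                scenario_config(540, nests = nests, land = landscape(fields),
                                applications = apps,
                                residue_params = case_residue_params(),
                                intake = case_intake(),
                                profiles = list(bromoxynil_profile()),
                                iterations = iterations, base_seed = base_seed,
                                start_month = 12,
                                exposure_mode = "landscape"),
                description, rbind(species_provenance("rabbit"), pp))
  }
  fx$splitting_total01 <- split_fixture(
    "splitting_total01",
    list(list(),                                    # control
         list(c(15, 0.1)),                          # one application
         list(c(15, 0.05), c(45, 0.05)),            # two applications
         list(c(15, 0.033), c(45, 0.033), c(75, 0.033))),
    "one/two/three bromoxynil applications summing ~0.1 kg/ha")
  fx$splitting_interval <- split_fixture(
    "splitting_interval",
    list(list(),
         list(c(15, 0.05)),
         list(c(15, 0.05), c(30, 0.05), c(45, 0.05)),
         list(c(15, 0.05), c(45, 0.05), c(75, 0.05))),
    "single vs repeated 0.05 kg/ha applications at 15-day or monthly intervals")
  fx
}

#' List the bundled fixtures
#'
#' @return data frame with fixture names and descriptions.
#' @export
list_fixtures <- function() {
  fx <- c(list(rabbit_default(), hare_default()),
          figure_experiments(iterations = 2))
  data.frame(name = vapply(fx, `[[`, character(1), "name"),
             description = vapply(fx, `[[`, character(1), "description"),
             row.names = NULL)
}
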