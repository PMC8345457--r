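#' Scenario configuration
#'
#' Full specification of a simulation run: horizon, nests, landscape,
#' application schedule, exposure and toxicity parameters, and replication
#' settings. Months are fixed blocks of `days_per_month` days counted from
#' day 0; the block starting at day 0 carries the calendar month
#' `start_month`, against which each nest's reproductive season is evaluated.
#'
#' @param horizon_days simulated days (>= 1).
#' @param nests list of [nest_config()] objects.
#' @param land a [landscape()] (may be empty for pesticide-free runs).
#' @param applications list of [application_event()].
#' @param residue_params list of [residue_parameters()].
#' @param intake an [intake_parameters()] or `NULL` when no applications.
#' @param profiles list of [toxicity_profile()].
#' @param iterations replicate count (>= 1).
#' @param base_seed integer; replicate `i` uses seed `base_seed + i`, from
#'   which each nest derives an independent sub-stream.
#' @param summary_mode `"mean_ci95"`, `"min_max"` or `"percentile"`.
#' @param days_per_month days per month block (default 30).
#' @param start_month calendar month (1..12) of the first month block.
#' @param rate_conversion monthly-to-daily conversion, see
#'   [daily_rate_from_monthly()].
#' @param exposure_mode `"worst_case"` or `"landscape"`, see
#'   [build_exposure()].
#' @param food_weights optional food-availability table for landscape mode.
#' @param resolution optional raster resolution for zone overlap.
#' @return an object of class `lagopop_scenario`.
#' @export
scenario_config <- function(horizon_days, nests, land = landscape(),
                            applications = list(), residue_params = list(),
                            intake = NULL, profiles = list(), iterations = 1,
                            base_seed = 1,
                            summary_mode = c("mean_ci95", "min_max", "percentile"),
                            days_per_month = 30, start_month = 12,
                            rate_conversion = c("uniform", "compound"),
                            exposure_mode = c("worst_case", "landscape"),
                            food_weights = NULL, resolution = NULL) {
  cfg <- structure(list(
    horizon_days = as.integer(horizon_days), nests = nests, landscape = land,
    applications = applications, residue_params = residue_params,
    intake = intake, profiles = profiles, iterations = as.integer(iterations),
    base_seed = as.integer(base_seed),
    summary_mode = match.arg(summary_mode),
    days_per_month = as.integer(days_per_month),
    start_month = as.integer(start_month),
    rate_conversion = match.arg(rate_conversion),
    exposure_mode = match.arg(exposure_mode),
    food_weights = food_weights, resolution = resolution),
    class = "lagopop_scenario")
  problems <- validate_scenario(cfg)
  if (length(problems))
    stop_config("invalid scenario:\n  - %s", paste(problems, collapse = "\n  - "))
  cfg
}

#' Validate a scenario configuration
#'
#' @param cfg a `lagopop_scenario` (or a plain list with the same fields).
#' @return character vector of violations (empty when valid).
#' @export
validate_scenario <- function(cfg) {
  p <- character(0)
  add <- function(...) p <<- c(p, sprintf(...))
  if (is.null(cfg$horizon_days) || cfg$horizon_days < 1) add("horizon_days must be >= 1")
  if (is.null(cfg$days_per_month) || cfg$days_per_month < 1) add("days_per_month must be >= 1")
  if (!length(cfg$nests)) add("at least one nest required")
  for (n in cfg$nests) if (!inherits(n, "lagopop_nest"))
    add("nests must be nest_config() objects")
  ids <- vapply(cfg$nests, function(n) as.character(n$nest_id), character(1))
  if (anyDuplicated(ids)) add("duplicated nest ids")
  if (cfg$iterations < 1) add("iterations must be >= 1")
  if (cfg$iterations < 2 && identical(cfg$summary_mode, "mean_ci95"))
    add("mean_ci95 summaries need at least 2 iterations")
  if (is.null(cfg$start_month) || cfg$start_month < 1 || cfg$start_month > 12)
    add("start_month must be in 1..12")
  if (length(cfg$applications)) {
    if (is.null(cfg$intake)) add("applications present but no intake parameters")
    if (!length(cfg$profiles)) add("applications present but no toxicity profiles")
    fids <- vapply(cfg$landscape$fields, `[[`, character(1), "field_id")
    for (a in cfg$applications) {
      if (!a$field_id %in% fids)
        add("application targets unknown field '%s'", a$field_id)
      if (a$day >= cfg$horizon_days)
        add("application on day %d is beyond the horizon", a$day)
    }
    pests <- unique(vapply(cfg$applications, `[[`, character(1), "pesticide"))
    prof_pests <- vapply(cfg$profiles, `[[`, character(1), "pesticide")
    for (pe in setdiff(pests, prof_pests))
      add("no toxicity profile for applied pesticide '%s'", pe)
  }
  p
}

# simulate one nest for one iteration; returns per-day per-group abundance,
# deaths, births and the monthly effective rates used.
simulate_nest <- function(nest, cfg, series, seed) {
  thr <- group_thresholds(nest$age_groups)
  ng <- length(thr)
  bg <- list(
    mortality = vapply(nest$age_groups, `[[`, numeric(1), "monthly_mortality"),
    reproduction = vapply(nest$age_groups, `[[`, numeric(1), "monthly_reproduction"))
  horizon <- cfg$horizon_days
  dpm <- cfg$days_per_month
  state <- initialize_nest(nest, seed)  # also seeds the nest's RNG sub-stream
  age <- state$age; sex <- state$sex
  abundance <- matrix(0L, horizon + 1L, ng)
  abundance[1L, ] <- tabulate(findInterval(age, thr), ng)
  deaths <- births <- integer(horizon)
  n_months <- (horizon - 1L) %/% dpm + 1L
  rates_log <- vector("list", n_months)
  eff <- NULL
  has_pest <- length(cfg$profiles) > 0 && length(series) > 0
  for (d in 0:(horizon - 1L)) {
    mo <- d %/% dpm
    if (d %% dpm == 0L) {
      eff <- if (has_pest)
        effective_rates_for_month(mo, cfg$profiles, series, bg, dpm,
                                  nest$intake_multipliers)
      else list(mortality = bg$mortality, reproduction = bg$reproduction)
      eff$daily_mortality <- daily_rate_from_monthly(eff$mortality, dpm,
                                                     cfg$rate_conversion)
      rates_log[[mo + 1L]] <- data.frame(
        nest_id = nest$nest_id, month = mo,
        month_of_year = month_of_year(mo, cfg$start_month),
        group = seq_len(ng) - 1L,
        monthly_mortality = eff$mortality,
        monthly_reproduction = eff$reproduction)
    }
    # (1) acute mortality at the day's exposure (no background acute mortality)
    if (has_pest) {
      ar <- acute_rates_for_day(d, cfg$profiles, series, ng,
                                nest$intake_multipliers)
      if (any(ar > 0)) {
        k <- kernel_mortality(age, thr, ar)
        deaths[d + 1L] <- deaths[d + 1L] + sum(k$deaths)
        age <- age[k$keep]; sex <- sex[k$keep]
      }
    }
    # (2) background + chronic mortality
    k <- kernel_mortality(age, thr, eff$daily_mortality)
    deaths[d + 1L] <- deaths[d + 1L] + sum(k$deaths)
    age <- age[k$keep]; sex <- sex[k$keep]
    # (3) reproduction within the season
    if (month_of_year(mo, cfg$start_month) %in% nest$reproductive_season) {
      nb <- kernel_births(age, sex, thr, eff$reproduction, dpm)
      if (nb > 0L) {
        births[d + 1L] <- nb
        age <- c(age, rep(0L, nb))
        sex <- c(sex, ifelse(stats::runif(nb) < nest$sex_ratio_male, "M", "F"))
      }
    }
    # (4) ageing and promotion
    age <- age + 1L
    abundance[d + 2L, ] <- tabulate(findInterval(age, thr), ng)
  }
  list(nest_id = nest$nest_id, abundance = abundance,
       total = as.integer(rowSums(abundance)), deaths = deaths,
       births = births, monthly_rates = do.call(rbind, rates_log))
}

#' Run one simulation iteration
#'
#' Executes the daily loop for every nest: at each month boundary the
#' effective monthly rates are recomputed from the lagged maximum TWA
#' exposures; each day acute mortality (same-day exposure), background plus
#' chronic mortality, seasonal reproduction and ageing are applied in that
#' fixed order. Each nest consumes an independent RNG sub-stream derived from
#' `(base_seed + iteration, nest_id)`, so results are deterministic and
#' per-nest reproducible.
#'
#' @param cfg a [scenario_config()].
#' @param iteration iteration index (>= 1; replicate `i` uses seed
#'   `base_seed + i`).
#' @param exposure optional list of precomputed per-nest exposure series (as
#'   produced by [scenario_exposure()]); the exposure model is deterministic,
#'   so replicated runs can share it.
#' @return an object of class `lagopop_result` with per-nest abundance
#'   matrices (rows: day 0..horizon; columns: age groups), totals, deaths,
#'   births, the monthly rates applied, and the exposure series used.
#' @export
simulate_scenario <- function(cfg, iteration = 1, exposure = NULL) {
  stopifnot(inherits(cfg, "lagopop_scenario"))
  problems <- validate_scenario(cfg)
  if (length(problems))
    stop_config("invalid scenario:\n  - %s", paste(problems, collapse = "\n  - "))
  exposures <- exposure %||% scenario_exposure(cfg)
  nests_out <- vector("list", length(cfg$nests))
  for (i in seq_along(cfg$nests)) {
    nest <- cfg$nests[[i]]
    seed <- nest_seed(cfg$base_seed + iteration, nest$nest_id)
    nests_out[[i]] <- simulate_nest(nest, cfg, exposures[[i]], seed)
  }
  names(nests_out) <-
    vapply(cfg$nests, function(n) as.character(n$nest_id), character(1))
  structure(list(scenario = cfg, iteration = iteration, nests = nests_out,
                 exposure = exposures),
            class = "lagopop_result")
}

#' Deterministic exposure series of every nest in a scenario
#'
#' @param cfg a [scenario_config()].
#' @return named list (per nest) of named lists (per pesticide) of
#'   [exposure_series()] objects.
#' @export
scenario_exposure <- function(cfg) {
  out <- lapply(cfg$nests, function(nest) {
    if (!length(cfg$applications)) return(list())
    build_exposure(nest, cfg$landscape, cfg$applications, cfg$residue_params,
                   cfg$intake, cfg$horizon_days, cfg$food_weights,
                   cfg$exposure_mode, cfg$resolution)
  })
  names(out) <- vapply(cfg$nests, function(n) as.character(n$nest_id),
                       character(1))
  out
}

#' Run replicated simulations and summarize abundance
#'
#' Runs `cfg$iterations` independent replicates (seeds `base_seed + i`) and
#' summarizes, per nest and per day, the total abundance across replicates:
#' mean with a normal-approximation 95% confidence interval
#' (`mean +/- 1.96 sd / sqrt(n)`), a min/max envelope, or percentile 2.5/97.5%
#' bounds, according to `summary_mode`.
#'
#' @param cfg a [scenario_config()].
#' @param keep_replicates keep the per-replicate total-abundance matrices
#'   (day x iteration per nest) in the result (default `TRUE`).
#' @return an object of class `lagopop_summary`: a list with `table` (data
#'   frame: nest_id, day, mean, low, high), `pooled` (the same for the sum
#'   over nests) and run metadata.
#' @export
replicate_scenario <- function(cfg, keep_replicates = TRUE) {
  stopifnot(inherits(cfg, "lagopop_scenario"))
  n_it <- cfg$iterations
  nn <- length(cfg$nests)
  ids <- vapply(cfg$nests, function(n) as.character(n$nest_id), character(1))
  totals <- lapply(seq_len(nn), function(i)
    matrix(0L, cfg$horizon_days + 1L, n_it))
  expo <- scenario_exposure(cfg)  # deterministic, shared across replicates
  for (it in seq_len(n_it)) {
    res <- simulate_scenario(cfg, it, exposure = expo)
    for (i in seq_len(nn)) totals[[i]][, it] <- res$nests[[i]]$total
  }
  names(totals) <- ids
  summarize <- function(m) {
    mu <- rowMeans(m)
    switch(cfg$summary_mode,
           mean_ci95 = {
             se <- apply(m, 1, stats::sd) / sqrt(ncol(m))
             list(mean = mu, low = mu - 1.96 * se, high = mu + 1.96 * se)
           },
           min_max = list(mean = mu, low = apply(m, 1, min),
                          high = apply(m, 1, max)),
           percentile = list(mean = mu,
                             low = apply(m, 1, stats::quantile, 0.025),
                             high = apply(m, 1, stats::quantile, 0.975)))
  }
  days <- 0:cfg$horizon_days
  tab <- do.call(rbind, lapply(seq_len(nn), function(i) {
    s <- summarize(totals[[i]])
    data.frame(nest_id = ids[i], day = days, mean = s$mean, low = s$low,
               high = s$high)
  }))
  pooled_m <- Reduce(`+`, totals)
  sp <- summarize(pooled_m)
  pooled <- data.frame(day = days, mean = sp$mean, low = sp$low, high = sp$high)
  structure(list(table = tab, pooled = pooled, iterations = n_it,
                 summary_mode = cfg$summary_mode, base_seed = cfg$base_seed,
                 replicates = if (keep_replicates) totals else NULL,
                 scenario = cfg),
            class = "lagopop_summary")
}

#' @export
print.lagopop_scenario <- function(x, ...) {
  cat(sprintf("lagopop scenario: %d day(s), %d nest(s), %d field(s), %d application(s)\n",
              x$horizon_days, length(x$nests), length(x$landscape$fields),
              length(x$applications)))
  cat(sprintf("  iterations %d, base seed %d, summary %s, %s rate conversion, start month %d\n",
              x$iterations, x$base_seed, x$summary_mode, x$rate_conversion,
              x$start_month))
  invisible(x)
}

#' @export
print.lagopop_result <- function(x, ...) {
  cat(sprintf("lagopop result (iteration %d): %d nest(s), %d day(s)\n",
              x$iteration, length(x$nests), x$scenario$horizon_days))
  for (n in x$nests)
    cat(sprintf("  %s: initial %d -> final %d (deaths %d, births %d)\n",
                n$nest_id, n$total[1], n$total[length(n$total)],
                sum(n$deaths), sum(n$births)))
  invisible(x)
}

#' @export
summary.lagopop_result <- function(object, ...) {
  do.call(rbind, lapply(object$nests, function(n) {
    data.frame(nest_id = n$nest_id, initial = n$total[1],
               final = n$total[length(n$total)], peak = max(n$total),
               deaths = sum(n$deaths), births = sum(n$births))
  }))
}

#' @export
print.lagopop_summary <- function(x, ...) {
  cat(sprintf("lagopop replication summary: %d iteration(s), %s\n",
              x$iterations, x$summary_mode))
  cat(sprintf("  pooled abundance: initial %.1f, peak %.1f (day %d), final %.1f\n",
              x$pooled$mean[1], max(x$pooled$mean),
              x$pooled$day[which.max(x$pooled$mean)],
              x$pooled$mean[nrow(x$pooled)]))
  invisible(x)
}

#' Plot abundance trajectories
#'
#' @param x a `lagopop_result` or `lagopop_summary`.
#' @param ... passed to [graphics::matplot()] / [graphics::plot()].
#' @return the input, invisibly.
#' @export
plot.lagopop_result <- function(x, ...) {
  m <- do.call(cbind, lapply(x$nests, `[[`, "total"))
  graphics::matplot(0:(nrow(m) - 1), m, type = "l", lty = 1,
                    xlab = "day", ylab = "total abundance", ...)
  graphics::legend("topleft", legend = names(x$nests), bty = "n",
                   col = seq_along(x$nests), lty = 1, cex = 0.8)
  invisible(x)
}

#' @rdname plot.lagopop_result
#' @export
plot.lagopop_summary <- function(x, ...) {
  p <- x$pooled
  graphics::plot(p$day, p$mean, type = "n", xlab = "day",
                 ylab = "total abundance", ylim = range(p$low, p$high), ...)
  graphics::polygon(c(p$day, rev(p$day)), c(p$low, rev(p$high)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(p$day, p$mean, col = "steelblue4")
  invisible(x)
}

#' Export simulation outputs as CSV plus run metadata
#'
#' Writes, into `dir`: `abundance.csv` (nest_id, day, one column per age
#' group, total; one row per nest and simulated day), `rates.csv` (the
#' effective monthly rates applied), `exposure.csv` (nest_id, pesticide, day,
#' ete, twa over the chronic window) and `metadata.json` (seed, iteration
#' count, horizon and settings).
#'
#' @param x a `lagopop_result` or `lagopop_summary`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- list(package = "lagopop",
               base_seed = x$scenario$base_seed,
               iterations = x$scenario$iterations,
               horizon_days = x$scenario$horizon_days,
               days_per_month = x$scenario$days_per_month,
               start_month = x$scenario$start_month,
               rate_conversion = x$scenario$rate_conversion,
               summary_mode = x$scenario$summary_mode,
               nests = vapply(x$scenario$nests,
                              function(n) as.character(n$nest_id), character(1)))
  if (inherits(x, "lagopop_result")) {
    meta$iteration <- x$iteration
    ab <- do.call(rbind, lapply(x$nests, function(n) {
      ng <- ncol(n$abundance)
      d <- data.frame(nest_id = n$nest_id, day = seq_len(nrow(n$abundance) - 1L))
      grp <- as.data.frame(n$abundance[-1L, , drop = FALSE])
      names(grp) <- paste0("group_", seq_len(ng) - 1L)
      cbind(d, grp, total = n$total[-1L])
    }))
    f <- file.path(dir, "abundance.csv")
    utils::write.csv(ab, f, row.names = FALSE); paths <- c(paths, f)
    rates <- do.call(rbind, lapply(x$nests, `[[`, "monthly_rates"))
    f <- file.path(dir, "rates.csv")
    utils::write.csv(rates, f, row.names = FALSE); paths <- c(paths, f)
    expo <- do.call(rbind, lapply(names(x$exposure), function(nid) {
      do.call(rbind, lapply(x$exposure[[nid]], function(s) {
        w <- chronic_window_of(x$scenario$profiles, s$pesticide)
        data.frame(nest_id = nid, pesticide = s$pesticide,
                   day = seq_along(s$ete) - 1L, ete = s$ete,
                   twa = twa_series(s$ete, w))
      }))
    }))
    if (!is.null(expo) && nrow(expo)) {
      f <- file.path(dir, "exposure.csv")
      utils::write.csv(expo, f, row.names = FALSE); paths <- c(paths, f)
    }
  } else if (inherits(x, "lagopop_summary")) {
    f <- file.path(dir, "summary.csv")
    utils::write.csv(x$table, f, row.names = FALSE); paths <- c(paths, f)
    f <- file.path(dir, "summary_pooled.csv")
    utils::write.csv(x$pooled, f, row.names = FALSE); paths <- c(paths, f)
  } else stop_config("cannot export object of class %s", class(x)[1])
  f <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, f)
  invisible(paths)
}

chronic_window_of <- function(profiles, pesticide) {
  for (p in profiles) if (p$pesticide == pesticide) return(p$chronic_window)
  1L
}
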