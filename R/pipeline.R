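# End-to-end pipeline: generate -> tabulate -> estimate -> calibrate ->
# scenarios, with a reproducibility manifest. Stage outputs are plain
# CSV/JSON so any stage can be fed external data of the same shape.

#' Annual calibration series observed in an episode-structured cohort
#'
#' The empirical counterpart of [annual_summaries()]: year-end stocks (alive,
#' on OAT by setting, proportion currently or recently incarcerated) and
#' within-year death flows computed directly from the episode tables.
#'
#' @param tables an `episode_tables` object.
#' @param years integer vector of calendar years.
#' @param recent_release_days window after prison release during which a
#'   person still counts as "recently incarcerated" (default 28 days).
#' @return a `calibration_series` data.frame, one row per year.
#' @export
cohort_calibration_series <- function(tables, years, recent_release_days = 28) {
  stopifnot(inherits(tables, "episode_tables"))
  persons <- data.table::as.data.table(tables$persons)
  oat <- data.table::as.data.table(tables$oat_episodes)
  inc <- data.table::as.data.table(tables$incarceration_episodes)
  deaths <- data.table::as.data.table(tables$deaths)
  persons[, entry := as_day(entry_date)]
  oat[, `:=`(s = as_day(start_date), e = as_day(end_date))]
  inc[, `:=`(s = as_day(start_date), e = as_day(end_date))]
  dday <- if (nrow(deaths)) {
    deaths[, dd := as_day(death_date)]
    deaths[, dyear := as.integer(format(death_date, "%Y"))]
    stats::setNames(deaths$dd, deaths$person_id)
  } else {
    integer(0)
  }

  active_ids <- function(ep, day) {
    unique(ep[s <= day & e > day, person_id])
  }
  rows <- lapply(years, function(y) {
    ye <- as_day(as.Date(sprintf("%d-12-31", y)))
    dd <- dday[as.character(persons$person_id)]
    alive <- persons$entry <= ye & (is.na(dd) | dd > ye)
    alive_ids <- persons$person_id[alive]
    on_ids <- intersect(active_ids(oat, ye), alive_ids)
    pr_ids <- intersect(active_ids(inc, ye), alive_ids)
    recent_ids <- intersect(
      unique(inc[e > ye - recent_release_days & e <= ye, person_id]),
      alive_ids
    )
    n_alive <- length(alive_ids)
    if (nrow(deaths)) {
      dy <- deaths[dyear == y]
      n_d <- nrow(dy)
      n_od <- if (n_d) {
        sum(classify_codes_vec(dy$underlying_icd10, dy$additional_icd10) == "overdose")
      } else 0L
    } else {
      n_d <- 0L
      n_od <- 0L
    }
    data.frame(
      year = y,
      alive = n_alive,
      on_oat_community = length(setdiff(on_ids, pr_ids)),
      on_oat_prison = length(intersect(on_ids, pr_ids)),
      prop_incarcerated = if (n_alive > 0) {
        length(union(pr_ids, recent_ids)) / n_alive
      } else 0,
      deaths_total = n_d,
      prop_overdose = if (n_d > 0) n_od / n_d else 0
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_series", "data.frame")
  out
}

# Annual first-time OAT initiates observed in the cohort, extended to the
# model horizon by carrying the mean of the last `carry` observed years.
cohort_entry_series <- function(tables, through_year, carry = 3) {
  ey <- as.integer(format(tables$persons$entry_date, "%Y"))
  tab <- table(ey)
  years_obs <- as.integer(names(tab))
  series <- stats::setNames(as.numeric(tab), years_obs)
  all_years <- seq(min(years_obs), through_year)
  out <- stats::setNames(numeric(length(all_years)), all_years)
  out[names(series)] <- series
  beyond <- all_years[all_years > max(years_obs)]
  if (length(beyond)) {
    out[as.character(beyond)] <- mean(utils::tail(series, carry))
  }
  out
}

#' Default desk-scale pipeline configuration
#'
#' A complete [run_pipeline()] configuration at a size suited to interactive
#' use: a reduced cohort, three calibrated parameters, and a short ABC run.
#' Every element can be overridden before passing it on.
#'
#' @param seed master seed for the whole pipeline.
#' @param n_entrants cohort size for the synthetic generator.
#' @param n_particles,n_generations ABC-SMC run size.
#' @return a nested configuration list.
#' @export
demo_config <- function(seed = 1L, n_entrants = 8000, n_particles = 100,
                        n_generations = 3) {
  list(
    seed = seed,
    generator = list(n_entrants = n_entrants),
    tabulation = list(study_start = "2001-08-01", study_end = "2017-12-31",
                      alpha = 0.05),
    model = list(dt = 1 / 52, scenario_through_year = 2020),
    priors = list(
      name = c("oat_cessation_rate_community", "oat_reentry_rate",
               "overdose_rate.community_off"),
      dist = c("uniform", "uniform", "loguniform"),
      lower = c(0.3, 0.3, 0.001),
      upper = c(1.0, 1.5, 0.02)
    ),
    abc = list(n_particles = n_particles, n_generations = n_generations,
               quantile_schedule = 0.5),
    scenarios = list(median_age_suicide = 39, median_age_other = 47,
                     freeze_uncertainty = FALSE)
  )
}

validate_run_config <- function(config) {
  required <- c("seed", "generator", "tabulation", "priors", "abc", "scenarios")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop_domain(sprintf("pipeline configuration is missing field(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    stop_domain("pipeline configuration field 'seed' must be a single integer")
  }
  for (f in c("study_start", "study_end")) {
    if (is.null(config$tabulation[[f]])) {
      stop_domain(sprintf("pipeline configuration is missing field(s): tabulation.%s", f))
    }
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes generate -> tabulate -> estimate-parameters -> calibrate ->
#' scenarios on a configuration (a nested list as from [demo_config()], or a
#' path to a YAML file of the same shape), writing every stage output and a
#' manifest (seeds, file hashes, package version) to `out_dir`. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config nested configuration list or path to a YAML file.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the key in-memory results (`tables`,
#'   `counts`, `estimates`, `particles`, `scenario`, `validation`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)

  ## stage 1: synthetic cohort
  gen_args <- config$generator %||% list()
  gen_args$seed <- seeds[1L]
  cfg <- do.call(generator_config, gen_args)
  tables <- generate_cohort(cfg)
  cohort_dir <- file.path(out_dir, "cohort")
  table_paths <- write_cohort_tables(tables, cohort_dir)

  ## stage 2: person-time tabulation
  tb <- config$tabulation
  counts <- allocate_person_time(tables, tb$study_start, tb$study_end)
  counts_path <- file.path(out_dir, "stratum_counts.csv")
  utils::write.csv(counts, counts_path, row.names = FALSE, quote = FALSE)

  ## stage 3: parameter estimation
  alpha <- tb$alpha %||% 0.05
  estimates <- estimate_all_parameters(counts, alpha = alpha)
  params_path <- file.path(out_dir, "params.json")
  jsonlite::write_json(
    list(
      irr = list(
        community = estimates$irr_community[c("irr", "ci_low", "ci_high")],
        prison = estimates$irr_prison[c("irr", "ci_low", "ci_high")]
      ),
      fractions = estimates$fractions
    ),
    params_path, auto_unbox = TRUE, digits = NA
  )

  ## stage 4: ABC-SMC calibration against the cohort's own annual series
  study_years <- seq(as.integer(format(as.Date(tb$study_start), "%Y")),
                     as.integer(format(as.Date(tb$study_end), "%Y")))
  observed <- cohort_calibration_series(tables, study_years)
  observed_path <- file.path(out_dir, "observed_series.csv")
  utils::write.csv(observed, observed_path, row.names = FALSE, quote = FALSE)

  through_year <- config$model$scenario_through_year %||% max(study_years)
  dt <- config$model$dt %||% (1 / 52)
  entry_series <- cohort_entry_series(tables, through_year)
  model_args <- config$model$params %||% list()
  model_args$entry_series <- entry_series
  base_params <- do.call(model_params, model_args)

  priors <- prior_spec(config$priors$name, config$priors$dist,
                       config$priors$lower, config$priors$upper)
  n_cal_years <- length(study_years)
  sim_fn <- function(theta) {
    annual_summaries(simulate_cohort(apply_param_vector(base_params, theta),
                                     horizon = n_cal_years, dt = dt))
  }
  particles <- run_abc_smc(
    priors, observed, sim_fn,
    n_particles = config$abc$n_particles,
    n_generations = config$abc$n_generations,
    quantile_schedule = config$abc$quantile_schedule %||% 0.5,
    seed = seeds[2L]
  )
  particles_path <- file.path(out_dir, "particles.csv")
  utils::write.csv(as.data.frame(particles), particles_path,
                   row.names = FALSE, quote = FALSE)

  ## stage 5: scenarios
  sc <- config$scenarios
  scen <- run_scenarios(
    particles, base_params, estimates,
    years = seq(min(study_years), through_year),
    median_age_suicide = sc$median_age_suicide %||% 39,
    median_age_other = sc$median_age_other %||% 47,
    dt = dt,
    validation_years = study_years,
    freeze_uncertainty = isTRUE(sc$freeze_uncertainty),
    seed = seeds[3L]
  )
  results_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    list(summary = scen$summary,
         years = range(scen$years),
         validation_years = range(scen$validation_years)),
    results_path, auto_unbox = TRUE, digits = NA
  )
  observed_suicides <- observed_suicide_totals(counts)
  validation <- validate_against_observed(scen, observed_suicides)
  validation_path <- file.path(out_dir, "validation.csv")
  utils::write.csv(validation, validation_path, row.names = FALSE, quote = FALSE)

  outputs <- c(table_paths, counts = counts_path, params = params_path,
               observed_series = observed_path, particles = particles_path,
               results = results_path, validation = validation_path)
  rel <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
             normalizePath(unname(outputs)))
  md5 <- tools::md5sum(unname(outputs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("oatimpact")),
    master_seed = config$seed,
    stage_seeds = as.list(stats::setNames(seeds, c("generate", "calibrate",
                                                   "scenarios", "reserve"))),
    outputs = as.list(stats::setNames(rel, names(outputs))),
    md5 = as.list(stats::setNames(unname(md5), rel))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(tables = tables, counts = counts, estimates = estimates,
                 observed_series = observed, particles = particles,
                 scenario = scen, validation = validation, manifest = manifest))
}

# Observed suicide counts by setting from a stratum-count table.
observed_suicide_totals <- function(counts) {
  s <- stats::setNames(counts$suicides, counts$stratum)
  c(community = unname(s[["community_on"]] + s[["community_off"]]),
    prison = unname(s[["prison_on"]] + s[["prison_off"]]))
}

#' Run the packaged end-to-end demo
#'
#' [run_pipeline()] on [demo_config()]: synthetic cohort, tabulation,
#' estimation, a short ABC-SMC calibration, and the scenario comparison.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... overrides forwarded to [demo_config()].
#' @return the [run_pipeline()] result list, invisibly.
#' @export
demo_pipeline <- function(out_dir = tempfile("oatimpact-demo-"), seed = 1L, ...) {
  run_pipeline(demo_config(seed = seed, ...), out_dir)
}
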