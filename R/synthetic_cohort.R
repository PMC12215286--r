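# Synthetic episode-structured cohort generator.
#
# Emulates a linked administrative cohort of people entering opioid agonist
# treatment (OAT): episodic treatment engagement with gaps, incarceration
# spells, and cause-coded deaths drawn from piecewise-constant competing
# hazards (suicide / overdose / other) that depend on the stratum occupied
# (on/off OAT x prison/community). The on-OAT suicide hazard equals the
# off-OAT hazard multiplied by a configurable incidence rate ratio per
# setting, so downstream rate estimators have a known truth to recover.

#' Generator configuration for the synthetic OAT cohort
#'
#' Defaults describe a cohort of the size and composition of a large
#' state-wide OAT program observed 2001--2017: ~47k entrants, median entry age
#' 32 (IQR 26--39), episodic treatment with mean episode ~600 days and mean
#' gap ~1 year, modest incarceration exposure, and stratum-specific death
#' hazards chosen so that the on/off-OAT suicide IRR is 0.32 in the community
#' and 0.34 in prison, and suicides make up 10/13/21/36% of non-overdose
#' deaths in the community-on/community-off/prison-on/prison-off strata.
#'
#' @param n_entrants number of persons entering the cohort.
#' @param entry_start,entry_end calendar window of cohort entry (first OAT
#'   episode start).
#' @param study_end administrative censoring date.
#' @param oat_episode_duration_mean,oat_gap_duration_mean mean OAT episode and
#'   between-episode gap lengths, days (exponential).
#' @param prob_return_to_oat probability that a treatment gap ends in a new
#'   OAT episode rather than permanent discontinuation.
#' @param incarceration_rate incarceration events per person-year.
#' @param incarceration_duration_mean mean spell length, days (exponential).
#' @param hazard_suicide_off_community,hazard_suicide_off_prison off-OAT
#'   suicide hazards, events per person-year.
#' @param irr_suicide_on_oat_community,irr_suicide_on_oat_prison ratio of the
#'   on-OAT to off-OAT suicide hazard in each setting.
#' @param hazard_overdose_by_stratum,hazard_other_nonsuicide_by_stratum named
#'   length-4 vectors (community_on, community_off, prison_on, prison_off) of
#'   overdose and other-cause (non-suicide, non-overdose) death hazards per
#'   person-year.
#' @param age_entry_median,age_entry_iqr median and IQR (length-2) of age at
#'   entry, years; ages are drawn log-normal matched to these quantiles.
#' @param allow_suicide_overdose if `TRUE`, a fraction of suicides carry an
#'   opioid poisoning T-code (and are therefore classified overdose
#'   downstream); off by default, matching an analysis that counts suicides
#'   within non-overdose deaths only.
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(
    n_entrants = 46845,
    entry_start = as.Date("2001-08-01"),
    entry_end = as.Date("2017-12-31"),
    study_end = as.Date("2017-12-31"),
    oat_episode_duration_mean = 600,
    oat_gap_duration_mean = 365,
    prob_return_to_oat = 0.8,
    incarceration_rate = 0.1,
    incarceration_duration_mean = 120,
    hazard_suicide_off_community = 0.0011,
    irr_suicide_on_oat_community = 0.32,
    hazard_suicide_off_prison = 0.0025,
    irr_suicide_on_oat_prison = 0.34,
    hazard_overdose_by_stratum = c(
      community_on = 0.002, community_off = 0.006,
      prison_on = 0.0005, prison_off = 0.001
    ),
    hazard_other_nonsuicide_by_stratum = c(
      community_on = 0.003168, community_off = 0.0073615,
      prison_on = 0.0031976, prison_off = 0.0044444
    ),
    age_entry_median = 32,
    age_entry_iqr = c(26, 39),
    allow_suicide_overdose = FALSE,
    seed = NULL) {
  cfg <- list(
    n_entrants = n_entrants,
    entry_start = entry_start, entry_end = entry_end, study_end = study_end,
    oat_episode_duration_mean = oat_episode_duration_mean,
    oat_gap_duration_mean = oat_gap_duration_mean,
    prob_return_to_oat = prob_return_to_oat,
    incarceration_rate = incarceration_rate,
    incarceration_duration_mean = incarceration_duration_mean,
    hazard_suicide_off_community = hazard_suicide_off_community,
    irr_suicide_on_oat_community = irr_suicide_on_oat_community,
    hazard_suicide_off_prison = hazard_suicide_off_prison,
    irr_suicide_on_oat_prison = irr_suicide_on_oat_prison,
    hazard_overdose_by_stratum = hazard_overdose_by_stratum,
    hazard_other_nonsuicide_by_stratum = hazard_other_nonsuicide_by_stratum,
    age_entry_median = age_entry_median,
    age_entry_iqr = age_entry_iqr,
    allow_suicide_overdose = isTRUE(allow_suicide_overdose),
    seed = seed
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  assert_scalar_number(cfg$n_entrants, "n_entrants", min = 1)
  assert_scalar_number(cfg$oat_episode_duration_mean, "oat_episode_duration_mean",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(cfg$oat_gap_duration_mean, "oat_gap_duration_mean",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(cfg$incarceration_duration_mean, "incarceration_duration_mean",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(cfg$prob_return_to_oat, "prob_return_to_oat", min = 0, max = 1)
  assert_scalar_number(cfg$incarceration_rate, "incarceration_rate", min = 0)
  for (f in c("hazard_suicide_off_community", "hazard_suicide_off_prison")) {
    assert_scalar_number(cfg[[f]], f, min = 0)
  }
  for (f in c("irr_suicide_on_oat_community", "irr_suicide_on_oat_prison")) {
    assert_scalar_number(cfg[[f]], f, min = 0)
  }
  for (f in c("hazard_overdose_by_stratum", "hazard_other_nonsuicide_by_stratum")) {
    v <- cfg[[f]]
    if (length(v) != 4L || !all(STRATA %in% names(v))) {
      stop_domain(sprintf("'%s' must be a named length-4 vector over the strata", f))
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_domain(sprintf("'%s' must be non-negative and finite", f))
    }
    cfg[[f]] <- v[STRATA]
  }
  e0 <- as_day(cfg$entry_start, "entry_start")
  e1 <- as_day(cfg$entry_end, "entry_end")
  s1 <- as_day(cfg$study_end, "study_end")
  if (e0 > e1) stop_domain("'entry_end' must not precede 'entry_start'")
  if (s1 < e1) stop_domain("'study_end' must not precede 'entry_end'")
  if (length(cfg$age_entry_iqr) != 2L || cfg$age_entry_iqr[1] >= cfg$age_entry_iqr[2]) {
    stop_domain("'age_entry_iqr' must be an increasing length-2 vector")
  }
  assert_scalar_number(cfg$age_entry_median, "age_entry_median",
                       min = cfg$age_entry_iqr[1], max = cfg$age_entry_iqr[2])
  if (!is.null(cfg$seed)) assert_scalar_number(cfg$seed, "seed")
  structure(cfg, class = "generator_config")
}

# Stratum-specific suicide hazards implied by a config (per person-year).
suicide_hazards <- function(cfg) {
  c(
    community_on = cfg$hazard_suicide_off_community * cfg$irr_suicide_on_oat_community,
    community_off = cfg$hazard_suicide_off_community,
    prison_on = cfg$hazard_suicide_off_prison * cfg$irr_suicide_on_oat_prison,
    prison_off = cfg$hazard_suicide_off_prison
  )
}

# ICD-10 code pools the generator draws from.
SUICIDE_UNDERLYING_POOL <- c(sprintf("X%02d", c(70, 80, 81, 82, 64, 67, 78)), "Y870")
OVERDOSE_UNDERLYING_POOL <- c("X42", "X41", "X44", "Y12")
OVERDOSE_T_POOL <- c("T401", "T402", "T403", "T404", "T406", "T424", "T426", "T427", "T436")
OTHER_UNDERLYING_POOL <- c("I219", "I250", "C349", "J449", "K746", "X959", "V499", "W190", "G309")

#' Generate a synthetic episode-structured OAT cohort
#'
#' Simulates per-person OAT treatment episodes (alternating exponential
#' episode/gap lengths, geometric return), independent incarceration spells
#' (Poisson process with exponential durations), and a single competing-risks
#' death event drawn from piecewise-constant stratum hazards over each
#' person's timeline. Episodes are truncated at death; deaths carry ICD-10
#' cause codes from the configured code pools.
#'
#' @param config a [generator_config()] object.
#' @return an `episode_tables` object: list of data.frames `persons`
#'   (person_id, date_of_birth, entry_date), `oat_episodes` and
#'   `incarceration_episodes` (person_id, start_date, end_date), and `deaths`
#'   (person_id, death_date, underlying_icd10, additional_icd10 as a
#'   ";"-separated string).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_generator_config(config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- as.integer(cfg$n_entrants)
  e0 <- as_day(cfg$entry_start)
  e1 <- as_day(cfg$entry_end)
  s_end <- as_day(cfg$study_end)

  entry <- if (e1 > e0) e0 + sample.int(e1 - e0 + 1L, n, replace = TRUE) - 1L else rep(e0, n)
  # log-normal age matched to the configured median and IQR
  sdlog <- log(cfg$age_entry_iqr[2] / cfg$age_entry_iqr[1]) / (2 * stats::qnorm(0.75))
  age <- stats::rlnorm(n, meanlog = log(cfg$age_entry_median), sdlog = sdlog)
  dob <- entry - as.integer(round(age * DAYS_PER_YEAR))

  persons <- data.table::data.table(person_id = seq_len(n), dob = dob, entry = entry)

  ## --- OAT episodes: alternate episode/gap until censoring or non-return ---
  ep_list <- list()
  cur_id <- persons$person_id
  cur_start <- entry
  k <- 0L
  while (length(cur_id) > 0L && k < 500L) {
    k <- k + 1L
    dur <- pmax(1L, as.integer(round(stats::rexp(length(cur_id),
                                                 1 / cfg$oat_episode_duration_mean))))
    ep_end <- pmin(cur_start + dur, s_end)
    keep <- ep_end > cur_start
    ep_list[[k]] <- data.table::data.table(
      person_id = cur_id[keep], start = cur_start[keep], end = ep_end[keep]
    )
    open <- ep_end < s_end
    ret <- stats::runif(length(cur_id)) < cfg$prob_return_to_oat
    cont <- open & ret
    if (!any(cont)) break
    gap <- pmax(1L, as.integer(round(stats::rexp(sum(cont),
                                                 1 / cfg$oat_gap_duration_mean))))
    cur_start <- ep_end[cont] + gap
    cur_id <- cur_id[cont]
    alive_window <- cur_start < s_end
    cur_id <- cur_id[alive_window]
    cur_start <- cur_start[alive_window]
  }
  oat <- data.table::rbindlist(ep_list)
  data.table::setorder(oat, person_id, start)

  ## --- incarceration spells: Poisson count, uniform starts, merged overlaps ---
  fu_years <- (s_end - entry) / DAYS_PER_YEAR
  n_spells <- stats::rpois(n, cfg$incarceration_rate * fu_years)
  idx <- rep.int(seq_len(n), n_spells)
  if (length(idx)) {
    sp_start <- entry[idx] +
      as.integer(floor(stats::runif(length(idx)) * pmax(1, s_end - entry[idx])))
    sp_dur <- pmax(1L, as.integer(round(stats::rexp(length(idx),
                                                    1 / cfg$incarceration_duration_mean))))
    inc <- data.table::data.table(person_id = idx, start = sp_start,
                                  end = pmin(sp_start + sp_dur, s_end))
    inc <- inc[start < end]
    data.table::setorder(inc, person_id, start)
    # merge overlapping spells within person
    inc[, grp := cumsum(c(TRUE, start[-1L] > cummax(end)[-.N])), by = person_id]
    inc <- inc[, .(start = min(start), end = max(end)), by = .(person_id, grp)]
    inc[, grp := NULL]
  } else {
    inc <- data.table::data.table(person_id = integer(), start = integer(), end = integer())
  }

  ## --- death simulation: competing exponential clocks per stratum interval ---
  follow <- data.table::data.table(person_id = persons$person_id,
                                   fstart = entry, fend = s_end)
  follow <- follow[fstart < fend]
  ivl <- stratum_intervals_dt(oat, inc, follow)
  h_sui <- suicide_hazards(cfg) / DAYS_PER_YEAR
  h_od <- cfg$hazard_overdose_by_stratum / DAYS_PER_YEAR
  h_ot <- cfg$hazard_other_nonsuicide_by_stratum / DAYS_PER_YEAR
  ivl[, `:=`(hs = h_sui[stratum], ho = h_od[stratum], hx = h_ot[stratum])]
  ivl[, htot := hs + ho + hx]
  ivl[, t_ev := data.table::fifelse(htot > 0, stats::rexp(.N) / htot, Inf)]
  ivl[, hit := t_ev < (end - start)]
  ev <- ivl[hit == TRUE]
  ev <- ev[ev[, .I[which.min(start)], by = person_id]$V1]
  deaths <- data.table::data.table(person_id = integer(), death_day = integer(),
                                   cause = character())
  if (nrow(ev)) {
    u <- stats::runif(nrow(ev)) * ev$htot
    cause <- ifelse(u < ev$hs, "suicide", ifelse(u < ev$hs + ev$ho, "overdose", "other"))
    deaths <- data.table::data.table(
      person_id = ev$person_id,
      death_day = ev$start + as.integer(floor(ev$t_ev)),
      cause = cause
    )
  }

  ## --- ICD-10 coding of deaths ---
  if (nrow(deaths)) {
    nm <- nrow(deaths)
    und <- character(nm)
    add <- character(nm)
    is_sui <- deaths$cause == "suicide"
    is_od <- deaths$cause == "overdose"
    is_ot <- deaths$cause == "other"
    und[is_sui] <- sample(SUICIDE_UNDERLYING_POOL, sum(is_sui), replace = TRUE)
    und[is_od] <- sample(OVERDOSE_UNDERLYING_POOL, sum(is_od), replace = TRUE)
    add[is_od] <- sample(OVERDOSE_T_POOL, sum(is_od), replace = TRUE)
    und[is_ot] <- sample(OTHER_UNDERLYING_POOL, sum(is_ot), replace = TRUE)
    if (cfg$allow_suicide_overdose && any(is_sui)) {
      # robustness option: a fifth of suicides are opioid-overdose suicides
      tag <- is_sui & stats::runif(nm) < 0.2
      add[tag] <- sample(OVERDOSE_T_POOL, sum(tag), replace = TRUE)
    }
    deaths[, `:=`(underlying_icd10 = und, additional_icd10 = add)]
    deaths[, cause := NULL]
    # truncate episodes at death
    oat <- merge(oat, deaths[, .(person_id, death_day)], by = "person_id", all.x = TRUE)
    oat[!is.na(death_day), end := pmin(end, death_day)]
    oat <- oat[end > start][, death_day := NULL]
    inc <- merge(inc, deaths[, .(person_id, death_day)], by = "person_id", all.x = TRUE)
    inc[!is.na(death_day), end := pmin(end, death_day)]
    inc <- inc[end > start][, death_day := NULL]
  } else {
    deaths[, `:=`(underlying_icd10 = character(), additional_icd10 = character())]
    deaths[, cause := NULL]
  }

  # a person whose death day equals their entry day keeps a sentinel 1-day
  # episode so the "every person has >= 1 OAT episode" invariant holds; the
  # tabulator contributes no exposure past death regardless.
  missing_ep <- setdiff(persons$person_id, unique(oat$person_id))
  if (length(missing_ep)) {
    oat <- rbind(oat, data.table::data.table(
      person_id = missing_ep,
      start = persons$entry[match(missing_ep, persons$person_id)],
      end = persons$entry[match(missing_ep, persons$person_id)] + 1L
    ))
    data.table::setorder(oat, person_id, start)
  }

  new_episode_tables(
    persons = data.frame(person_id = persons$person_id,
                         date_of_birth = day_to_date(persons$dob),
                         entry_date = day_to_date(persons$entry)),
    oat_episodes = data.frame(person_id = oat$person_id,
                              start_date = day_to_date(oat$start),
                              end_date = day_to_date(oat$end)),
    incarceration_episodes = data.frame(person_id = inc$person_id,
                                        start_date = day_to_date(inc$start),
                                        end_date = day_to_date(inc$end)),
    deaths = data.frame(person_id = deaths$person_id,
                        death_date = day_to_date(deaths$death_day),
                        underlying_icd10 = deaths$underlying_icd10,
                        additional_icd10 = deaths$additional_icd10)
  )
}

new_episode_tables <- function(persons, oat_episodes, incarceration_episodes, deaths) {
  structure(
    list(persons = persons, oat_episodes = oat_episodes,
         incarceration_episodes = incarceration_episodes, deaths = deaths),
    class = "episode_tables"
  )
}

#' @export
print.episode_tables <- function(x, ...) {
  cat(sprintf(
    "Episode tables: %d persons, %d OAT episodes, %d incarceration episodes, %d deaths\n",
    nrow(x$persons), nrow(x$oat_episodes),
    nrow(x$incarceration_episodes), nrow(x$deaths)
  ))
  invisible(x)
}

TABLE_COLUMNS <- list(
  persons = c("person_id", "date_of_birth", "entry_date"),
  oat_episodes = c("person_id", "start_date", "end_date"),
  incarceration_episodes = c("person_id", "start_date", "end_date"),
  deaths = c("person_id", "death_date", "underlying_icd10", "additional_icd10")
)

#' Write episode tables to a directory of CSV files
#'
#' Writes `persons.csv`, `oat_episodes.csv`, `incarceration_episodes.csv` and
#' `deaths.csv` (RFC-4180, ISO-8601 dates, UTF-8). [read_cohort_tables()] is
#' the inverse.
#'
#' @param tables an `episode_tables` object.
#' @param directory output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort_tables <- function(tables, directory) {
  stopifnot(inherits(tables, "episode_tables"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(TABLE_COLUMNS)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]][, TABLE_COLUMNS[[nm]], drop = FALSE], path,
                     row.names = FALSE, quote = FALSE, na = "")
    paths[nm] <- path
  }
  invisible(paths)
}

#' Read episode tables from a directory of CSV files
#'
#' @param directory directory holding the four CSV tables written by
#'   [write_cohort_tables()].
#' @return an `episode_tables` object.
#' @export
read_cohort_tables <- function(directory) {
  read_one <- function(nm, date_cols) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) stop_domain(sprintf("missing table file '%s'", path))
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing <- setdiff(TABLE_COLUMNS[[nm]], names(df))
    if (length(missing)) {
      stop_domain(sprintf("table '%s' is missing column(s): %s",
                          nm, paste(missing, collapse = ", ")))
    }
    df <- df[, TABLE_COLUMNS[[nm]], drop = FALSE]
    df$person_id <- as.integer(df$person_id)
    for (dc in date_cols) {
      parsed <- as.Date(df[[dc]], format = "%Y-%m-%d")
      bad <- which(is.na(parsed) & nzchar(df[[dc]]))
      if (nrow(df) && (anyNA(parsed) || length(bad))) {
        bad <- which(is.na(parsed))
        stop_domain(sprintf("table '%s', row %d: unparseable date in '%s'",
                            nm, bad[1L], dc))
      }
      df[[dc]] <- parsed
    }
    df
  }
  persons <- read_one("persons", c("date_of_birth", "entry_date"))
  oat <- read_one("oat_episodes", c("start_date", "end_date"))
  inc <- read_one("incarceration_episodes", c("start_date", "end_date"))
  deaths <- read_one("deaths", "death_date")
  for (tab in list(oat = oat, inc = inc)) {
    bad <- which(tab$end_date <= tab$start_date)
    if (length(bad)) {
      stop_domain(sprintf("episode row %d has end_date <= start_date", bad[1L]))
    }
  }
  deaths$underlying_icd10 <- as.character(deaths$underlying_icd10)
  deaths$additional_icd10 <- ifelse(is.na(deaths$additional_icd10), "",
                                    as.character(deaths$additional_icd10))
  new_episode_tables(persons, oat, inc, deaths)
}
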