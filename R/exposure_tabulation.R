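# Person-time allocation to the four exposure strata and ICD-10 cause-of-death
# classification.
#
# Strata cross OAT status (on/off an active treatment episode) with setting
# (prison/community). All intervals are half-open [start, end) on a whole-day
# grid: the death day itself contributes no exposure but fixes the stratum the
# death is attributed to.

# ICD-10 stems defining opioid/psychotropic overdose-related causes.
OVERDOSE_T_STEMS <- c(paste0("T40", 0:6), "T424", "T426", "T427", "T436")
SUICIDE_X_STEMS <- sprintf("X%02d", 60:84)
SUICIDE_SEQUELAE_STEM <- "Y870"

normalize_icd <- function(codes) {
  out <- toupper(gsub("[. ]", "", codes))
  bad <- !grepl("^[A-Z][0-9]{2,4}$", out) & nzchar(out)
  if (any(bad)) {
    stop_domain(sprintf("unparseable ICD-10 code: '%s'", codes[bad][1L]))
  }
  out
}

is_overdose_code <- function(stems) substr(stems, 1L, 4L) %in% OVERDOSE_T_STEMS

is_suicide_underlying <- function(stem) {
  substr(stem, 1L, 3L) %in% SUICIDE_X_STEMS ||
    substr(stem, 1L, 4L) == SUICIDE_SEQUELAE_STEM
}

#' Classify a death record by ICD-10 cause codes
#'
#' A death is overdose-related if any listed code (underlying or additional)
#' has an opioid/psychotropic poisoning stem in T400-T406, T424, T426, T427 or
#' T436. A non-overdose death is a suicide when the underlying cause is in
#' X60-X84 or is Y87.0 (sequelae of intentional self-harm); all remaining
#' deaths are other non-overdose deaths. Codes are normalized by stripping
#' dots and upper-casing before stem comparison, so "T40.1" and "t401" match.
#'
#' @param underlying_icd10 single underlying-cause ICD-10 code.
#' @param additional_icd10 character vector of additional cause codes
#'   (possibly empty).
#' @return an object of class `death_class`: a list with `category` (one of
#'   `"suicide_nonoverdose"`, `"overdose"`, `"other_nonoverdose"`),
#'   `is_suicide` and `is_overdose` flags.
#' @examples
#' classify_death("X70")                 # suicide_nonoverdose
#' classify_death("X44", c("T40.1"))     # overdose
#' classify_death("I21")                 # other_nonoverdose
#' @export
classify_death <- function(underlying_icd10, additional_icd10 = character()) {
  if (length(underlying_icd10) != 1L || is.na(underlying_icd10) ||
      !nzchar(underlying_icd10)) {
    stop_domain("a death record must carry exactly one underlying ICD-10 code")
  }
  und <- normalize_icd(underlying_icd10)
  add <- normalize_icd(additional_icd10[nzchar(additional_icd10)])
  overdose <- any(is_overdose_code(c(und, add)))
  suicide <- !overdose && is_suicide_underlying(und)
  category <- if (overdose) {
    "overdose"
  } else if (suicide) {
    "suicide_nonoverdose"
  } else {
    "other_nonoverdose"
  }
  structure(
    list(category = category, is_suicide = suicide, is_overdose = overdose),
    class = "death_class"
  )
}

# Vectorized classification for tables: `additional` is a ";"-separated string
# per death (the CSV on-disk encoding). Returns a character vector of
# categories.
classify_codes_vec <- function(underlying, additional) {
  und <- normalize_icd(underlying)
  add_list <- strsplit(ifelse(is.na(additional), "", additional), ";", fixed = TRUE)
  add_od <- vapply(add_list, function(a) {
    a <- a[nzchar(a)]
    length(a) > 0L && any(is_overdose_code(normalize_icd(a)))
  }, logical(1))
  od <- is_overdose_code(und) | add_od
  sui <- !od & (substr(und, 1L, 3L) %in% SUICIDE_X_STEMS |
                  substr(und, 1L, 4L) == SUICIDE_SEQUELAE_STEM)
  ifelse(od, "overdose", ifelse(sui, "suicide_nonoverdose", "other_nonoverdose"))
}

# Core interval-overlay engine. `follow` is a data.table
# (person_id, fstart, fend) in integer days with fstart < fend; `oat` and
# `inc` are (person_id, start, end) integer-day episode tables (already
# normalized and clipped by the caller or not -- clipping happens here).
# Returns data.table(person_id, start, end, stratum) partitioning each
# person's [fstart, fend).
stratum_intervals_dt <- function(oat, inc, follow) {
  if (nrow(follow) == 0L) {
    return(data.table::data.table(person_id = integer(), start = integer(),
                                  end = integer(), stratum = character()))
  }
  clip <- function(ep) {
    if (nrow(ep) == 0L) return(data.table::data.table(person_id = integer(), s = integer(), e = integer()))
    x <- ep[follow, on = "person_id", nomatch = NULL]
    x[, `:=`(s = pmax(start, fstart), e = pmin(end, fend))]
    x <- x[s < e, .(person_id, s, e)]
    x
  }
  oat_c <- clip(oat)
  inc_c <- clip(inc)
  bounds <- rbind(
    follow[, .(person_id, day = fstart)],
    follow[, .(person_id, day = fend)],
    oat_c[, .(person_id, day = s)],
    oat_c[, .(person_id, day = e)],
    inc_c[, .(person_id, day = s)],
    inc_c[, .(person_id, day = e)]
  )
  bounds <- unique(bounds)
  data.table::setorder(bounds, person_id, day)
  ivl <- bounds[, .(start = day[-.N], end = day[-1L]), by = person_id]
  ivl <- ivl[start < end]
  ivl[, `:=`(on_oat = FALSE, in_prison = FALSE)]
  if (nrow(oat_c)) ivl[oat_c, on = .(person_id, start >= s, start < e), on_oat := TRUE]
  if (nrow(inc_c)) ivl[inc_c, on = .(person_id, start >= s, start < e), in_prison := TRUE]
  ivl[, stratum := ifelse(in_prison,
                          ifelse(on_oat, "prison_on", "prison_off"),
                          ifelse(on_oat, "community_on", "community_off"))]
  # merge runs of identical stratum so each person's timeline is minimal
  ivl[, run := data.table::rleid(stratum), by = person_id]
  out <- ivl[, .(start = min(start), end = max(end)), by = .(person_id, run, stratum)]
  out[, run := NULL]
  data.table::setorder(out, person_id, start)
  out[]
}

#' Partition one person's follow-up into stratum intervals
#'
#' Overlays a person's OAT episodes and incarceration spells onto the
#' follow-up window `[entry, exit)` and returns the resulting timeline of
#' half-open intervals, each labeled with one of the four strata. The
#' intervals are contiguous, non-overlapping, and cover the window exactly.
#'
#' @param oat_episodes data.frame with `start_date`, `end_date` (Date) for one
#'   person; may have zero rows.
#' @param incarceration_episodes same shape, for incarceration spells.
#' @param entry,exit follow-up window bounds (Date); `entry < exit`.
#' @return data.frame with `start`, `end` (Date), `stratum`, and `days`
#'   (integer interval length).
#' @export
build_timeline <- function(oat_episodes, incarceration_episodes, entry, exit) {
  e0 <- as_day(entry, "entry")
  e1 <- as_day(exit, "exit")
  if (e0 >= e1) stop_domain("'entry' must precede 'exit'")
  ep_dt <- function(ep, what) {
    if (is.null(ep) || nrow(ep) == 0L) {
      return(data.table::data.table(person_id = integer(), start = integer(), end = integer()))
    }
    s <- as_day(ep$start_date, paste0(what, " start_date"))
    e <- as_day(ep$end_date, paste0(what, " end_date"))
    if (any(s >= e)) stop_domain(sprintf("%s episode with start_date >= end_date", what))
    if (any(e <= e0 | s >= e1)) {
      stop_domain(sprintf("%s episode lies entirely outside [entry, exit)", what))
    }
    data.table::data.table(person_id = 1L, start = s, end = e)
  }
  follow <- data.table::data.table(person_id = 1L, fstart = e0, fend = e1)
  ivl <- stratum_intervals_dt(ep_dt(oat_episodes, "OAT"),
                              ep_dt(incarceration_episodes, "incarceration"),
                              follow)
  data.frame(
    start = day_to_date(ivl$start),
    end = day_to_date(ivl$end),
    stratum = ivl$stratum,
    days = ivl$end - ivl$start
  )
}

# OAT / incarceration state evaluated on the death day, for attributing a
# death to a stratum. Episodes are half-open, and episode records are
# truncated at death, so three cases count as active on day d: an episode
# spanning d, an episode starting on d (death on the day of entry into the
# state), and an episode ending exactly on d (the person held the state up to
# the moment of death).
state_on_day <- function(episodes, deaths_dt) {
  if (nrow(episodes) == 0L || nrow(deaths_dt) == 0L) {
    return(rep(FALSE, nrow(deaths_dt)))
  }
  hit <- rep(FALSE, nrow(deaths_dt))
  dd <- data.table::data.table(person_id = deaths_dt$person_id,
                               day = deaths_dt$death_day,
                               row = seq_len(nrow(deaths_dt)))
  m <- episodes[dd, on = .(person_id, start <= day, end >= day), nomatch = NULL, .(row = row)]
  hit[unique(m$row)] <- TRUE
  hit
}

#' Allocate cohort person-time and deaths to the four exposure strata
#'
#' Follow-up for each person runs from the later of `study_start` and their
#' first OAT episode start, to the earlier of `study_end` and their death
#' date (half-open, whole days). Person-years are days/365.25 summed per
#' stratum; each death is classified by [classify_death()] rules and
#' attributed to the stratum occupied on the death date.
#'
#' @param tables an `episode_tables` object (see [generate_cohort()] /
#'   [read_cohort_tables()]).
#' @param study_start,study_end analysis window bounds (Date or ISO string).
#' @return a `stratum_counts` data.frame with one row per stratum and columns
#'   `person_years`, `suicides`, `overdose_deaths`,
#'   `other_nonoverdose_deaths`.
#' @export
allocate_person_time <- function(tables, study_start, study_end) {
  stopifnot(inherits(tables, "episode_tables"))
  s0 <- as_day(study_start, "study_start")
  s1 <- as_day(study_end, "study_end")
  if (s0 >= s1) stop_domain("'study_start' must precede 'study_end'")

  oat <- data.table::as.data.table(tables$oat_episodes)
  inc <- data.table::as.data.table(tables$incarceration_episodes)
  oat[, `:=`(start = as_day(start_date), end = as_day(end_date))]
  inc[, `:=`(start = as_day(start_date), end = as_day(end_date))]

  first_oat <- oat[, .(first_start = min(start)), by = person_id]
  persons <- data.table::as.data.table(tables$persons)
  if (!all(persons$person_id %in% first_oat$person_id)) {
    stop_domain("every person must have at least one OAT episode")
  }
  fu <- first_oat[, .(person_id, fstart = pmax(s0, first_start))]

  deaths <- data.table::as.data.table(tables$deaths)
  if (nrow(deaths)) {
    deaths[, death_day := as_day(death_date)]
    fu <- merge(fu, deaths[, .(person_id, death_day)], by = "person_id", all.x = TRUE)
    if (any(!is.na(fu$death_day) & fu$death_day < fu$fstart)) {
      stop_domain("death recorded before a person's follow-up entry")
    }
    fu[, fend := pmin(s1, data.table::fifelse(is.na(death_day), s1, death_day))]
  } else {
    fu[, `:=`(death_day = NA_integer_, fend = s1)]
  }

  ivl <- stratum_intervals_dt(oat[, .(person_id, start, end)],
                              inc[, .(person_id, start, end)],
                              fu[fend > fstart, .(person_id, fstart, fend)])
  py <- ivl[, .(days = sum(as.numeric(end - start))), by = stratum]

  counts <- data.table::data.table(
    stratum = STRATA, person_years = 0, suicides = 0L,
    overdose_deaths = 0L, other_nonoverdose_deaths = 0L
  )
  counts[py, on = "stratum", person_years := days / DAYS_PER_YEAR]

  in_window <- if (nrow(deaths)) deaths[death_day >= s0 & death_day <= s1] else deaths
  if (nrow(in_window)) {
    in_window[, category := classify_codes_vec(underlying_icd10, additional_icd10)]
    in_window[, on_oat := state_on_day(oat[, .(person_id, start, end)], .SD)]
    in_window[, in_prison := state_on_day(inc[, .(person_id, start, end)], .SD)]
    in_window[, stratum := ifelse(in_prison,
                                  ifelse(on_oat, "prison_on", "prison_off"),
                                  ifelse(on_oat, "community_on", "community_off"))]
    tab <- in_window[, .N, by = .(stratum, category)]
    counts[tab[category == "suicide_nonoverdose"], on = "stratum", suicides := N]
    counts[tab[category == "overdose"], on = "stratum", overdose_deaths := N]
    counts[tab[category == "other_nonoverdose"], on = "stratum",
           other_nonoverdose_deaths := N]
  }
  out <- as.data.frame(counts)
  class(out) <- c("stratum_counts", "data.frame")
  out
}

#' @export
print.stratum_counts <- function(x, ...) {
  cat("Person-years and deaths by exposure stratum\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
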