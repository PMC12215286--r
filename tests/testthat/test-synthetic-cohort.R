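test_that("config validation names the offending field", {
  expect_error(generator_config(n_entrants = 0), "n_entrants")
  expect_error(generator_config(prob_return_to_oat = 1.5), "prob_return_to_oat")
  expect_error(generator_config(oat_gap_duration_mean = 0), "oat_gap_duration_mean")
  expect_error(generator_config(hazard_suicide_off_community = -1),
               "hazard_suicide_off_community")
  expect_error(generator_config(hazard_overdose_by_stratum = c(a = 1)),
               "hazard_overdose_by_stratum")
  expect_error(generator_config(entry_end = as.Date("2000-01-01")), "entry")
  expect_error(generator_config(study_end = as.Date("2001-01-01")), "study_end")
})

test_that("zero hazards produce an empty deaths table and full-count persons", {
  cfg <- small_config(
    n = 100,
    hazard_suicide_off_community = 0, hazard_suicide_off_prison = 0,
    hazard_overdose_by_stratum = zero_stratum_vec(),
    hazard_other_nonsuicide_by_stratum = zero_stratum_vec()
  )
  tabs <- generate_cohort(cfg)
  expect_equal(nrow(tabs$deaths), 0L)
  expect_equal(nrow(tabs$persons), 100L)
  expect_true(all(tabs$persons$person_id %in% tabs$oat_episodes$person_id))
})

test_that("generated tables satisfy the episode invariants", {
  tabs <- generate_cohort(small_config(n = 800, seed = 11))
  for (ep in list(tabs$oat_episodes, tabs$incarceration_episodes)) {
    expect_true(all(ep$end_date > ep$start_date))
    # non-overlapping within person after sorting
    dt <- data.table::as.data.table(ep)
    data.table::setorder(dt, person_id, start_date)
    gaps <- dt[, if (.N > 1L) all(start_date[-1L] >= end_date[-.N]) else TRUE,
               by = person_id]$V1
    expect_true(all(gaps))
  }
  expect_false(anyDuplicated(tabs$deaths$person_id) > 0)
  # no OAT episode extends past the death date (entry-day deaths keep a one-day
  # sentinel episode so the at-least-one-episode invariant holds)
  m <- merge(tabs$oat_episodes, tabs$deaths[, c("person_id", "death_date")],
             by = "person_id")
  entry_d <- tabs$persons$entry_date[match(m$person_id, tabs$persons$person_id)]
  expect_true(all(m$end_date <= m$death_date | m$death_date == entry_d))
  # entry date equals first OAT start
  first <- aggregate(start_date ~ person_id, tabs$oat_episodes, min)
  expect_equal(first$start_date[match(tabs$persons$person_id, first$person_id)],
               tabs$persons$entry_date)
})

test_that("identical config and seed reproduce byte-identical tables", {
  t1 <- generate_cohort(small_config(n = 300, seed = 99))
  t2 <- generate_cohort(small_config(n = 300, seed = 99))
  expect_identical(t1, t2)
})

test_that("event counts match configured hazards within Poisson concentration", {
  # one cause, one stratum: expected count h*T with 4*sqrt(hT) slack
  cfg <- small_config(
    n = 4000, seed = 5,
    incarceration_rate = 0,
    hazard_suicide_off_community = 0, hazard_suicide_off_prison = 0,
    hazard_overdose_by_stratum = zero_stratum_vec(),
    hazard_other_nonsuicide_by_stratum = stats::setNames(
      c(0.004, 0.004, 0, 0), STRATA4
    )
  )
  tabs <- generate_cohort(cfg)
  counts <- allocate_person_time(tabs, cfg$entry_start, cfg$study_end)
  total_py <- sum(counts$person_years)
  expected <- 0.004 * total_py
  observed <- sum(counts$other_nonoverdose_deaths)
  expect_gt(expected, 25)
  expect_lt(abs(observed - expected), 4 * sqrt(expected))
})

test_that("suicide-overdose deaths appear only when the config flag is on", {
  base <- list(
    n = 1500, seed = 21,
    hazard_suicide_off_community = 0.05,
    hazard_overdose_by_stratum = zero_stratum_vec(),
    hazard_other_nonsuicide_by_stratum = zero_stratum_vec()
  )
  t_off <- generate_cohort(do.call(small_config, base))
  expect_true(all(t_off$deaths$additional_icd10 == ""))
  t_on <- generate_cohort(do.call(small_config, c(base, allow_suicide_overdose = TRUE)))
  expect_gt(sum(t_on$deaths$additional_icd10 != ""), 0)
})

test_that("tables round-trip through CSV unchanged", {
  tabs <- generate_cohort(small_config(n = 200, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort_tables(tabs, dir)
  back <- read_cohort_tables(dir)
  expect_equal(back, tabs)

  # empty deaths table round-trips as a header-only file
  cfg0 <- small_config(
    n = 50,
    hazard_suicide_off_community = 0, hazard_suicide_off_prison = 0,
    hazard_overdose_by_stratum = zero_stratum_vec(),
    hazard_other_nonsuicide_by_stratum = zero_stratum_vec()
  )
  t0 <- generate_cohort(cfg0)
  d2 <- withr::local_tempdir()
  write_cohort_tables(t0, d2)
  expect_equal(length(readLines(file.path(d2, "deaths.csv"))), 1L)
  expect_equal(nrow(read_cohort_tables(d2)$deaths), 0L)
})

test_that("malformed CSV tables are rejected with the offending location", {
  tabs <- generate_cohort(small_config(n = 50, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort_tables(tabs, dir)

  # reversed episode
  ep <- utils::read.csv(file.path(dir, "oat_episodes.csv"))
  ep$end_date[3] <- as.character(as.Date(ep$start_date[3]) - 5)
  utils::write.csv(ep, file.path(dir, "oat_episodes.csv"), row.names = FALSE)
  expect_error(read_cohort_tables(dir), "row 3")

  write_cohort_tables(tabs, dir)
  ep <- utils::read.csv(file.path(dir, "persons.csv"))
  ep$entry_date[2] <- "not-a-date"
  utils::write.csv(ep, file.path(dir, "persons.csv"), row.names = FALSE)
  expect_error(read_cohort_tables(dir), "row 2.*entry_date")

  write_cohort_tables(tabs, dir)
  ep <- utils::read.csv(file.path(dir, "deaths.csv"))
  ep$death_date <- NULL
  utils::write.csv(ep, file.path(dir, "deaths.csv"), row.names = FALSE)
  expect_error(read_cohort_tables(dir), "death_date")
})

test_that("a unit IRR yields equal on/off community suicide rates at scale", {
  cfg <- generator_config(
    n_entrants = 42000,
    entry_start = as.Date("2001-08-01"), entry_end = as.Date("2003-12-31"),
    study_end = as.Date("2017-12-31"),
    irr_suicide_on_oat_community = 1.0,
    hazard_suicide_off_community = 0.002,
    incarceration_rate = 0,
    hazard_overdose_by_stratum = zero_stratum_vec(),
    hazard_other_nonsuicide_by_stratum = zero_stratum_vec(),
    seed = 17
  )
  tabs <- generate_cohort(cfg)
  counts <- allocate_person_time(tabs, cfg$entry_start, cfg$study_end)
  on <- counts[counts$stratum == "community_on", ]
  off <- counts[counts$stratum == "community_off", ]
  expect_gt(on$person_years, 2e5)
  expect_gt(off$person_years, 2e5)
  r_on <- on$suicides / on$person_years
  r_off <- off$suicides / off$person_years
  # 3 Monte-Carlo standard errors of the rate difference
  se <- sqrt(on$suicides / on$person_years^2 + off$suicides / off$person_years^2)
  expect_lt(abs(r_on - r_off), 3 * se)
})
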