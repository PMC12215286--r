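test_that("ICD-10 classification follows the suicide/overdose code sets", {
  expect_equal(classify_death("X70")$category, "suicide_nonoverdose")
  expect_equal(classify_death("X44", "T401")$category, "overdose")
  expect_equal(classify_death("I21")$category, "other_nonoverdose")
  # dots and case are normalized before stem comparison
  expect_equal(classify_death("x44", "T40.1")$category, "overdose")
  expect_equal(classify_death("Y87.0")$category, "suicide_nonoverdose")
  # a suicide-coded death with an opioid T-code counts as overdose
  cl <- classify_death("X64", c("T509", "T402"))
  expect_equal(cl$category, "overdose")
  expect_false(cl$is_suicide)
  # boundary stems of the suicide range
  expect_equal(classify_death("X60")$category, "suicide_nonoverdose")
  expect_equal(classify_death("X84")$category, "suicide_nonoverdose")
  expect_equal(classify_death("X85")$category, "other_nonoverdose")
  expect_equal(classify_death("X599")$category, "other_nonoverdose")
  # T-codes outside the overdose set do not trigger overdose
  expect_equal(classify_death("X70", "T425")$category, "suicide_nonoverdose")
})

test_that("classification rejects empty or malformed codes", {
  expect_error(classify_death(character(0)), "underlying")
  expect_error(classify_death(""), "underlying")
  expect_error(classify_death("9X1"), "9X1")
  expect_error(classify_death("X70", "bad!"), "bad!")
})

test_that("build_timeline partitions follow-up exactly", {
  d0 <- as.Date("2005-01-01")
  # full-coverage OAT episode, no incarceration
  tl <- build_timeline(
    data.frame(start_date = d0, end_date = d0 + 200),
    NULL, d0, d0 + 200
  )
  expect_equal(nrow(tl), 1L)
  expect_equal(tl$stratum, "community_on")
  expect_equal(tl$days, 200)

  # no episodes at all
  tl <- build_timeline(NULL, NULL, d0, d0 + 50)
  expect_equal(tl$stratum, "community_off")
  expect_equal(tl$days, 50)

  # overlapping OAT and incarceration split the axis into four strata
  tl <- build_timeline(
    data.frame(start_date = d0, end_date = d0 + 100),
    data.frame(start_date = d0 + 50, end_date = d0 + 150),
    d0, d0 + 200
  )
  expect_equal(tl$stratum,
               c("community_on", "prison_on", "prison_off", "community_off"))
  expect_equal(tl$days, c(50, 50, 50, 50))
  expect_equal(sum(tl$days), 200)
  expect_equal(tl$start[-1], tl$end[-nrow(tl)])

  # episodes fully outside the window are a consistency error
  expect_error(
    build_timeline(data.frame(start_date = d0 + 300, end_date = d0 + 400),
                   NULL, d0, d0 + 200),
    "outside"
  )
})

test_that("trivial person-time allocations follow the day-count conventions", {
  mk_tables <- function(persons, oat, inc, deaths) {
    structure(list(persons = persons, oat_episodes = oat,
                   incarceration_episodes = inc, deaths = deaths),
              class = "episode_tables")
  }
  d0 <- as.Date("2002-01-01")
  no_deaths <- data.frame(person_id = integer(), death_date = as.Date(character()),
                          underlying_icd10 = character(),
                          additional_icd10 = character())
  # 1461 whole days fully on OAT in the community = 1461/365.25 = 4.0 person-years
  t1 <- mk_tables(
    data.frame(person_id = 1L, date_of_birth = d0 - 30 * 365, entry_date = d0),
    data.frame(person_id = 1L, start_date = d0, end_date = d0 + 1461),
    data.frame(person_id = integer(), start_date = as.Date(character()),
               end_date = as.Date(character())),
    no_deaths
  )
  c1 <- allocate_person_time(t1, d0, d0 + 1461)
  expect_equal(c1$person_years[c1$stratum == "community_on"], 4.0, tolerance = 1e-9)
  expect_equal(sum(c1$person_years), 4.0, tolerance = 1e-9)
  expect_equal(sum(c1[, c("suicides", "overdose_deaths", "other_nonoverdose_deaths")]), 0)

  # death on the entry day: zero person-years, community-on suicide counted
  t2 <- mk_tables(
    data.frame(person_id = 1L, date_of_birth = d0 - 30 * 365, entry_date = d0),
    data.frame(person_id = 1L, start_date = d0, end_date = d0 + 1),
    data.frame(person_id = integer(), start_date = as.Date(character()),
               end_date = as.Date(character())),
    data.frame(person_id = 1L, death_date = d0, underlying_icd10 = "X70",
               additional_icd10 = "")
  )
  c2 <- allocate_person_time(t2, d0, d0 + 100)
  expect_equal(sum(c2$person_years), 0)
  expect_equal(c2$suicides[c2$stratum == "community_on"], 1L)

  # death before follow-up entry is a consistency error
  t3 <- t2
  t3$deaths$death_date <- d0 - 10
  expect_error(allocate_person_time(t3, d0, d0 + 100), "before")
})

test_that("interval engine agrees with day-by-day brute force on random cohorts", {
  set.seed(404)
  for (rep in 1:25) {
    cfg <- generator_config(
      n_entrants = 6,
      entry_start = as.Date("2001-08-01"), entry_end = as.Date("2002-06-30"),
      study_end = as.Date("2004-12-31"),
      oat_episode_duration_mean = 120, oat_gap_duration_mean = 90,
      incarceration_rate = 1.5, incarceration_duration_mean = 60,
      hazard_suicide_off_community = 0.2, hazard_suicide_off_prison = 0.3,
      hazard_overdose_by_stratum = zero_stratum_vec(0.3),
      hazard_other_nonsuicide_by_stratum = zero_stratum_vec(0.3),
      seed = 1000 + rep
    )
    tabs <- generate_cohort(cfg)
    fast <- allocate_person_time(tabs, cfg$entry_start, cfg$study_end)
    slow <- brute_force_tabulate(tabs, cfg$entry_start, cfg$study_end)
    expect_equal(fast$person_years * 365.25, slow$person_days, tolerance = 1e-9)
    expect_equal(fast$suicides, slow$suicides)
    expect_equal(fast$overdose_deaths, slow$overdose_deaths)
    expect_equal(fast$other_nonoverdose_deaths, slow$other_nonoverdose_deaths)
    # death conservation: every in-window death is classified exactly once
    expect_equal(
      sum(fast[, c("suicides", "overdose_deaths", "other_nonoverdose_deaths")]),
      nrow(tabs$deaths)
    )
  }
})

test_that("per-person timelines sum exactly to follow-up length", {
  tabs <- generate_cohort(small_config(n = 120, seed = 33,
                                       incarceration_rate = 0.6))
  s0 <- as.Date("2001-08-01")
  s1 <- as.Date("2010-12-31")
  for (pid in sample(tabs$persons$person_id, 20)) {
    oat <- tabs$oat_episodes[tabs$oat_episodes$person_id == pid, ]
    inc <- tabs$incarceration_episodes[tabs$incarceration_episodes$person_id == pid, ]
    drow <- tabs$deaths[tabs$deaths$person_id == pid, ]
    fstart <- max(s0, min(oat$start_date))
    fend <- if (nrow(drow)) min(s1, drow$death_date) else s1
    if (fend <= fstart) next
    keep <- function(ep) ep[ep$end_date > fstart & ep$start_date < fend, ]
    tl <- build_timeline(keep(oat), keep(inc), fstart, fend)
    expect_equal(sum(tl$days), as.integer(fend - fstart))
    expect_true(all(tl$start[-1] == tl$end[-nrow(tl)]))
  }
})
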