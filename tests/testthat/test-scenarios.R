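test_that("suicides follow from other-cause deaths by the stratum fractions", {
  od <- c(community_on = 1530, community_off = 100, prison_on = 10, prison_off = 20)
  fr <- c(community_on = 0.10, community_off = 0.13, prison_on = 0.21, prison_off = 0.36)
  s <- suicides_from_other_deaths(od, fr)
  expect_equal(s[["community_on"]], 153)
  expect_equal(unname(suicide_totals(s)["total"]), 153 + 13 + 2.1 + 7.2)
  expect_true(all(suicides_from_other_deaths(od, zero_stratum_vec()) == 0))
  expect_equal(as.numeric(suicides_from_other_deaths(od, zero_stratum_vec(1))),
               as.numeric(od[STRATA4]))
  expect_error(suicides_from_other_deaths(od[-1], fr), "strata")
  expect_error(suicides_from_other_deaths(od, zero_stratum_vec(2)), "0, 1")
})

test_that("the no-OAT counterfactual scales on-OAT suicides by the inverse IRR", {
  b <- suicide_counts(153, 446, 5, 22)
  cf <- counterfactual_no_oat(b, 0.32, 0.34)
  expect_equal(unname(suicide_totals(cf)["community"]), 446 + 153 / 0.32)
  expect_equal(round(unname(suicide_totals(cf)["community"])), 924)
  expect_equal(unname(suicide_totals(cf)["prison"]), 22 + 5 / 0.34)
  expect_equal(round(unname(suicide_totals(cf)["prison"]), 2), 36.71)
  # off-OAT components are copied unchanged
  expect_identical(cf[["community_off"]], b[["community_off"]])
  expect_identical(cf[["prison_off"]], b[["prison_off"]])
  # unit IRRs are the identity
  expect_equal(as.numeric(counterfactual_no_oat(b, 1, 1)), as.numeric(b))
  expect_error(counterfactual_no_oat(b, 0, 1), "irr_community")
})

test_that("averted counts, percentages and life-years reproduce the printed chain", {
  b <- suicide_counts(153, 446, 5, 22)
  cf_community_total <- round(446 + 153 / 0.32)
  av_comm <- cf_community_total - 599
  expect_equal(av_comm, 325)
  expect_equal(round(100 * av_comm / cf_community_total), 35)
  overall <- averted_summary(
    suicide_counts(153, 446, 5, 22),
    suicide_counts(153 / 0.32, 446, 5 / 0.34, 22)
  )
  expect_equal(unname(overall$averted["total"]),
               (153 / 0.32 - 153) + (5 / 0.34 - 5))
  expect_equal(unname(overall$percent["total"]),
               unname(overall$averted["total"] /
                        (446 + 153 / 0.32 + 22 + 5 / 0.34)))
  # (963 - 626) / 963 on the printed rounded totals
  expect_equal(round(100 * (963 - 626) / 963), 35)
  # identity case
  eq <- averted_summary(b, b)
  expect_true(all(eq$averted == 0) && all(eq$percent == 0))

  expect_equal(life_years_gained(338, 39, 47), 2704)
  expect_equal(life_years_gained(0, 39, 47), 0)
  expect_equal(life_years_gained(10, 40, 50), 100)
  expect_error(life_years_gained(-1, 39, 47), "averted")
  expect_error(life_years_gained(10, 50, 40), "median_age_other")
})

make_estimates <- function(irr_c = 0.32, irr_p = 0.34) {
  counts <- data.frame(
    stratum = STRATA4,
    person_years = c(312756, 300000, 8000, 9000),
    suicides = c(96L, round(96 / 312756 / irr_c * 300000), 5L, 8L),
    overdose_deaths = c(300L, 800L, 5L, 10L),
    other_nonoverdose_deaths = c(860L, 1900L, 19L, 14L)
  )
  class(counts) <- c("stratum_counts", "data.frame")
  estimate_all_parameters(counts)
}

test_that("scenario runs propagate per-draw uncertainty coherently", {
  est <- make_estimates()
  base <- model_params(entry_series = stats::setNames(rep(400, 8), 2001:2008))
  res <- run_scenarios(NULL, base, est, seed = 5)
  # a single frozen draw equals its own summary
  res1 <- run_scenarios(NULL, base, est, freeze_uncertainty = TRUE, seed = 5)
  expect_equal(res1$summary$median[res1$summary$quantity == "averted_total"],
               res1$draws$averted_total)
  expect_equal(res1$summary$lower, res1$summary$median)

  # per-draw invariants: off-OAT bit-identical, consistency of sums
  expect_identical(res$draws$cf_community_off, res$draws$baseline_community_off)
  expect_identical(res$draws$cf_prison_off, res$draws$baseline_prison_off)
  expect_equal(res$draws$averted_total,
               res$draws$averted_community + res$draws$averted_prison)
  expect_equal(res$draws$percent_total,
               res$draws$averted_total / res$draws$cf_total)

  # determinism under a fixed seed
  res2 <- run_scenarios(NULL, base, est, seed = 5)
  expect_equal(res, res2)
})

test_that("direction: protective IRRs in both settings yield positive aversion", {
  est <- make_estimates()
  base <- model_params(entry_series = stats::setNames(rep(400, 8), 2001:2008))
  res <- run_scenarios(NULL, base, est, freeze_uncertainty = TRUE, seed = 9)
  expect_true(all(res$draws$averted_community > 0))
  expect_true(all(res$draws$averted_prison > 0))
  expect_true(all(res$draws$averted_total > 0))
})

test_that("validation tables flag observed counts against the credible interval", {
  est <- make_estimates()
  base <- model_params(entry_series = stats::setNames(rep(400, 8), 2001:2008))
  res <- run_scenarios(NULL, base, est, validation_years = 2001:2006,
                       freeze_uncertainty = TRUE, seed = 2)
  med <- res$draws$valid_community
  # observed equal to the median is inside; far outside is flagged
  v1 <- validate_against_observed(res, c(community = med, prison = res$draws$valid_prison))
  expect_true(all(v1$within_cri))
  v2 <- validate_against_observed(res, c(community = med * 10, prison = 0))
  expect_false(v2$within_cri[v2$setting == "community"])
  expect_error(validate_against_observed(res, c(community = 1)), "prison")
  res_noval <- run_scenarios(NULL, base, est, freeze_uncertainty = TRUE, seed = 2)
  expect_error(validate_against_observed(res_noval, c(community = 1, prison = 1)),
               "validation")
})
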