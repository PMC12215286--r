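# Baseline vs no-OAT counterfactual scenario analysis.
#
# The chain: the compartmental model's other-cause (non-overdose) death flow
# per stratum is converted to suicides with the per-stratum suicide fractions;
# the no-OAT counterfactual divides on-OAT suicides by the on/off-OAT suicide
# IRR of the corresponding setting while off-OAT suicides are unchanged;
# averted counts, percent reductions and life-years gained follow.

#' Construct a per-stratum suicide-count vector
#'
#' @param community_on,community_off,prison_on,prison_off non-negative counts.
#' @return a `suicide_counts` named numeric vector over the four strata.
#' @export
suicide_counts <- function(community_on, community_off, prison_on, prison_off) {
  new_suicide_counts(c(community_on = community_on, community_off = community_off,
                       prison_on = prison_on, prison_off = prison_off))
}

new_suicide_counts <- function(x) {
  stopifnot(all(STRATA %in% names(x)))
  if (any(x[STRATA] < 0)) stop_domain("suicide counts must be non-negative")
  structure(as.numeric(x[STRATA]), names = STRATA, class = "suicide_counts")
}

#' Totals of a suicide-count vector by setting and overall
#'
#' @param counts a `suicide_counts` vector over the four strata.
#' @return named numeric: `community`, `prison`, `total`.
#' @export
suicide_totals <- function(counts) {
  c(
    community = unname(counts[["community_on"]] + counts[["community_off"]]),
    prison = unname(counts[["prison_on"]] + counts[["prison_off"]]),
    total = unname(sum(counts))
  )
}

#' @export
print.suicide_counts <- function(x, ...) {
  cat("Suicides by stratum:\n")
  print(stats::setNames(as.numeric(x), names(x)))
  tt <- suicide_totals(x)
  cat(sprintf("community %.1f, prison %.1f, total %.1f\n",
              tt["community"], tt["prison"], tt["total"]))
  invisible(x)
}

#' Convert other-cause deaths to suicides via per-stratum fractions
#'
#' @param other_deaths named length-4 vector of non-overdose deaths per
#'   stratum.
#' @param fractions named length-4 vector of the proportions of non-overdose
#'   deaths attributable to suicide, in \[0, 1\].
#' @return a `suicide_counts` vector.
#' @export
suicides_from_other_deaths <- function(other_deaths, fractions) {
  for (v in list(other_deaths, fractions)) {
    if (!all(STRATA %in% names(v))) {
      stop_domain("inputs must be named vectors covering all four strata")
    }
  }
  if (any(other_deaths[STRATA] < 0)) stop_domain("death counts must be non-negative")
  if (any(fractions[STRATA] < 0 | fractions[STRATA] > 1)) {
    stop_domain("fractions must lie in [0, 1]")
  }
  new_suicide_counts(other_deaths[STRATA] * fractions[STRATA])
}

#' No-OAT counterfactual suicide counts by inverse-IRR scaling
#'
#' On-OAT suicides in each setting are divided by that setting's on/off-OAT
#' suicide IRR (equivalently multiplied by its inverse); off-OAT suicides are
#' copied unchanged, since those individuals did not benefit from treatment.
#'
#' @param baseline a `suicide_counts` vector (baseline, with-OAT scenario).
#' @param irr_community,irr_prison on/off-OAT suicide incidence rate ratios;
#'   must be positive.
#' @return a `suicide_counts` vector for the no-OAT scenario.
#' @examples
#' b <- suicide_counts(153, 446, 5, 22)
#' cf <- counterfactual_no_oat(b, 0.32, 0.34)
#' round(suicide_totals(cf)[["community"]]) # 924
#' @export
counterfactual_no_oat <- function(baseline, irr_community, irr_prison) {
  assert_scalar_number(irr_community, "irr_community", min = 0, strict_min = TRUE)
  assert_scalar_number(irr_prison, "irr_prison", min = 0, strict_min = TRUE)
  if (!all(STRATA %in% names(baseline))) {
    stop_domain("'baseline' must cover all four strata")
  }
  out <- as.numeric(baseline[STRATA])
  names(out) <- STRATA
  out["community_on"] <- out["community_on"] / irr_community
  out["prison_on"] <- out["prison_on"] / irr_prison
  new_suicide_counts(out)
}

#' Averted suicides and percent reduction by setting and overall
#'
#' @param baseline,counterfactual `suicide_counts` vectors for the with-OAT
#'   and no-OAT scenarios.
#' @return list with `averted` and `percent` (averted / counterfactual),
#'   each a named vector over `community`, `prison`, `total`.
#' @export
averted_summary <- function(baseline, counterfactual) {
  tb <- suicide_totals(new_suicide_counts(baseline))
  tc <- suicide_totals(new_suicide_counts(counterfactual))
  if (any(tc < 0)) stop_domain("counterfactual totals must be non-negative")
  averted <- tc - tb
  percent <- ifelse(tc > 0, averted / tc, 0)
  list(averted = averted, percent = percent)
}

#' Life-years gained from averted suicides
#'
#' Averted suicides multiplied by the difference between the median age at
#' death from other causes and the median age at death by suicide.
#'
#' @param averted number of averted suicides (non-negative).
#' @param median_age_suicide,median_age_other median ages at death, years;
#'   `median_age_other >= median_age_suicide >= 0`.
#' @return life-years gained.
#' @examples
#' life_years_gained(338, 39, 47) # 2704
#' @export
life_years_gained <- function(averted, median_age_suicide, median_age_other) {
  assert_scalar_number(averted, "averted", min = 0)
  assert_scalar_number(median_age_suicide, "median_age_suicide", min = 0)
  assert_scalar_number(median_age_other, "median_age_other",
                       min = median_age_suicide)
  averted * (median_age_other - median_age_suicide)
}

# Per-draw sampling of IRRs (log-normal matched to the estimate's CI) and
# fractions (Jeffreys beta from the underlying counts).
draw_irr <- function(est, n) {
  if (est$ci_high <= est$ci_low) return(rep(est$irr, n))
  z <- stats::qnorm(1 - est$alpha / 2)
  sdlog <- (log(est$ci_high) - log(est$ci_low)) / (2 * z)
  stats::rlnorm(n, meanlog = log(est$irr), sdlog = sdlog)
}

draw_fractions <- function(fractions, n) {
  # fractions: data.frame(stratum, suicides, nonoverdose_deaths, p, ...)
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, STRATA))
  for (s in STRATA) {
    r <- fractions[fractions$stratum == s, ]
    out[, s] <- stats::rbeta(n, r$suicides + 0.5,
                             r$nonoverdose_deaths - r$suicides + 0.5)
  }
  out
}

#' Run the baseline vs no-OAT scenario comparison over a posterior particle set
#'
#' For each calibrated particle the compartmental model is simulated, the
#' other-cause death flow per stratum over the analysis years is extracted,
#' suicides are formed via per-stratum fractions, and the no-OAT
#' counterfactual is constructed by inverse-IRR scaling. Estimation
#' uncertainty in the IRRs (log-normal matched to their CIs) and fractions
#' (beta, matched to their counts) is propagated per draw unless
#' `freeze_uncertainty = TRUE`. Summaries are weighted medians with weighted
#' 2.5/97.5 percentile credible intervals.
#'
#' @param particles a `particle_set` from [run_abc_smc()] (parameter columns
#'   are dotted paths into [model_params()]), or `NULL` to run a single draw
#'   at `base_params`.
#' @param base_params an [model_params()] object the particles override.
#' @param estimates an `oat_parameter_estimates` object from
#'   [estimate_all_parameters()] (supplies IRRs and fractions with their
#'   uncertainty).
#' @param years calendar years to accumulate deaths over (default: the full
#'   entry-series span).
#' @param median_age_suicide,median_age_other median ages at death used for
#'   life-years gained.
#' @param dt simulation step, years.
#' @param validation_years optional year span for the validation extract of
#'   baseline suicides (e.g. `2001:2017`); stored per draw when given.
#' @param freeze_uncertainty if `TRUE`, IRRs and fractions are held at their
#'   point estimates in every draw.
#' @param seed seed for the per-draw IRR/fraction sampling.
#' @return a `scenario_result`: list with `draws` (per-particle data.frame),
#'   `summary` (quantity, median, lower, upper), `weights`, and inputs.
#' @export
run_scenarios <- function(particles, base_params, estimates,
                          years = NULL,
                          median_age_suicide = 39, median_age_other = 47,
                          dt = 1 / 52, validation_years = NULL,
                          freeze_uncertainty = FALSE, seed = 1L) {
  stopifnot(inherits(base_params, "oat_model_params"),
            inherits(estimates, "oat_parameter_estimates"))
  if (is.null(years)) {
    yrs <- as.integer(names(base_params$entry_series))
    years <- seq(min(yrs), max(yrs))
  }
  horizon <- max(years) - as.integer(names(base_params$entry_series))[1L] + 1L

  if (is.null(particles)) {
    pmat <- matrix(numeric(0), nrow = 1L)
    w <- 1
  } else {
    stopifnot(nrow(particles) >= 1L)
    par_cols <- setdiff(names(particles), c("weight", "distance"))
    pmat <- as.matrix(particles[, par_cols, drop = FALSE])
    w <- particles$weight
  }
  n <- nrow(pmat)

  set.seed(seed)
  if (freeze_uncertainty) {
    irr_c <- rep(estimates$irr_community$irr, n)
    irr_p <- rep(estimates$irr_prison$irr, n)
    fr <- matrix(rep(estimates$fractions$p[match(STRATA, estimates$fractions$stratum)],
                     each = n), n, 4, dimnames = list(NULL, STRATA))
  } else {
    irr_c <- draw_irr(estimates$irr_community, n)
    irr_p <- draw_irr(estimates$irr_prison, n)
    fr <- draw_fractions(estimates$fractions, n)
  }

  draws <- vector("list", n)
  for (i in seq_len(n)) {
    params_i <- if (ncol(pmat) > 0L) {
      apply_param_vector(base_params, stats::setNames(pmat[i, ], colnames(pmat)))
    } else {
      base_params
    }
    traj <- simulate_cohort(params_i, horizon = horizon, dt = dt)
    od <- other_cause_deaths_by_stratum(traj, years = years)
    base_s <- suicides_from_other_deaths(od, fr[i, ])
    cf_s <- counterfactual_no_oat(base_s, irr_c[i], irr_p[i])
    av <- averted_summary(base_s, cf_s)
    tb <- suicide_totals(base_s)
    tc <- suicide_totals(cf_s)
    lyg <- life_years_gained(max(av$averted[["total"]], 0),
                             median_age_suicide, median_age_other)
    row <- data.frame(
      draw = i,
      baseline_community_on = base_s[["community_on"]],
      baseline_community_off = base_s[["community_off"]],
      baseline_prison_on = base_s[["prison_on"]],
      baseline_prison_off = base_s[["prison_off"]],
      baseline_community = tb[["community"]],
      baseline_prison = tb[["prison"]],
      baseline_total = tb[["total"]],
      cf_community_on = cf_s[["community_on"]],
      cf_community_off = cf_s[["community_off"]],
      cf_prison_on = cf_s[["prison_on"]],
      cf_prison_off = cf_s[["prison_off"]],
      cf_community = tc[["community"]],
      cf_prison = tc[["prison"]],
      cf_total = tc[["total"]],
      averted_community = av$averted[["community"]],
      averted_prison = av$averted[["prison"]],
      averted_total = av$averted[["total"]],
      percent_community = av$percent[["community"]],
      percent_prison = av$percent[["prison"]],
      percent_total = av$percent[["total"]],
      life_years_gained = lyg,
      irr_community = irr_c[i], irr_prison = irr_p[i]
    )
    if (!is.null(validation_years)) {
      odv <- other_cause_deaths_by_stratum(traj, years = validation_years)
      vs <- suicides_from_other_deaths(odv, fr[i, ])
      vt <- suicide_totals(vs)
      row$valid_community <- vt[["community"]]
      row$valid_prison <- vt[["prison"]]
      row$valid_total <- vt[["total"]]
    }
    draws[[i]] <- row
  }
  draws <- do.call(rbind, draws)

  qty <- setdiff(names(draws), "draw")
  summary <- do.call(rbind, lapply(qty, function(nm) {
    q <- weighted_quantile(draws[[nm]], w, probs = c(0.025, 0.5, 0.975))
    data.frame(quantity = nm, median = q[2], lower = q[1], upper = q[3])
  }))

  structure(
    list(draws = draws, summary = summary, weights = w, years = years,
         validation_years = validation_years,
         median_age_suicide = median_age_suicide,
         median_age_other = median_age_other),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  get_q <- function(nm) x$summary[x$summary$quantity == nm, ]
  fmt <- function(nm, scale = 1, digits = 0) {
    q <- get_q(nm)
    sprintf("%s (95%% CrI %s-%s)",
            format(round(q$median * scale, digits), nsmall = 0),
            format(round(q$lower * scale, digits), nsmall = 0),
            format(round(q$upper * scale, digits), nsmall = 0))
  }
  cat(sprintf("Scenario analysis over %d-%d (%d draws)\n",
              min(x$years), max(x$years), nrow(x$draws)))
  cat("  Baseline suicides:       community ", fmt("baseline_community"),
      ", prison ", fmt("baseline_prison"),
      ", total ", fmt("baseline_total"), "\n", sep = "")
  cat("  No-OAT counterfactual:   community ", fmt("cf_community"),
      ", prison ", fmt("cf_prison"),
      ", total ", fmt("cf_total"), "\n", sep = "")
  cat("  Averted by the program:  community ", fmt("averted_community"),
      ", prison ", fmt("averted_prison"),
      ", total ", fmt("averted_total"), "\n", sep = "")
  cat("  Percent averted:         community ", fmt("percent_community", 100),
      "%, prison ", fmt("percent_prison", 100),
      "%, total ", fmt("percent_total", 100), "%\n", sep = "")
  cat("  Life-years gained:       ", fmt("life_years_gained"), "\n", sep = "")
  invisible(x)
}

#' Compare modeled baseline suicides against observed counts
#'
#' Builds the validation table for a cutoff span: the model's weighted median
#' and 95% credible interval for baseline suicides per setting, the observed
#' count, and a within-interval flag.
#'
#' @param result a `scenario_result` run with `validation_years` set.
#' @param observed named numeric with elements `community`, `prison` (and
#'   optionally `total`, otherwise their sum) of observed suicides over the
#'   validation span.
#' @return data.frame (setting, model_median, cri_low, cri_high, observed,
#'   within_cri).
#' @export
validate_against_observed <- function(result, observed) {
  stopifnot(inherits(result, "scenario_result"))
  if (!all(c("valid_community", "valid_prison") %in% names(result$draws))) {
    stop_domain("scenario result was run without 'validation_years'")
  }
  if (!all(c("community", "prison") %in% names(observed))) {
    stop_domain("'observed' must name community and prison counts")
  }
  obs <- c(community = unname(observed[["community"]]),
           prison = unname(observed[["prison"]]),
           total = if ("total" %in% names(observed)) {
             unname(observed[["total"]])
           } else {
             unname(observed[["community"]] + observed[["prison"]])
           })
  rows <- lapply(c("community", "prison", "total"), function(s) {
    q <- weighted_quantile(result$draws[[paste0("valid_", s)]], result$weights,
                           probs = c(0.025, 0.5, 0.975))
    data.frame(setting = s, model_median = q[2], cri_low = q[1], cri_high = q[3],
               observed = obs[[s]],
               within_cri = obs[[s]] >= q[1] && obs[[s]] <= q[3])
  })
  do.call(rbind, rows)
}

#' Bar chart of baseline vs no-OAT suicide estimates
#'
#' Side-by-side bars by setting with credible-interval whiskers; requires
#' ggplot2.
#'
#' @param result a `scenario_result`.
#' @return a ggplot object.
#' @export
plot_scenario_result <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_domain("plot_scenario_result() requires the ggplot2 package")
  }
  pick <- function(nm) result$summary[result$summary$quantity == nm, ]
  df <- do.call(rbind, lapply(c("community", "prison", "total"), function(s) {
    rbind(
      cbind(setting = s, scenario = "With OAT", pick(paste0("baseline_", s))),
      cbind(setting = s, scenario = "No OAT", pick(paste0("cf_", s)))
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = setting, y = median, fill = scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = lower, ymax = upper),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Suicides, 2001-2020", fill = NULL) +
    ggplot2::theme_minimal()
}
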