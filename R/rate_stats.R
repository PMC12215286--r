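# Incidence rates, rate ratios, and suicide fractions of non-overdose deaths.

#' Incidence rate ratio with Wald confidence interval on the log scale
#'
#' IRR = (events_on / py_on) / (events_off / py_off), with
#' CI = exp(log IRR +/- z * sqrt(1/events_on + 1/events_off)). If either
#' event count is zero, 0.5 is added to both counts (continuity correction)
#' and the estimate is flagged `corrected`.
#'
#' @param events_on,events_off event counts in the exposed (on-OAT) and
#'   unexposed (off-OAT) groups.
#' @param py_on,py_off person-years at risk in each group; must be positive.
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @param setting optional label (`"community"` or `"prison"`).
#' @return an `irr_estimate` list: `irr`, `ci_low`, `ci_high`, `alpha`,
#'   `events_on`, `events_off`, `py_on`, `py_off`, `corrected`, `setting`.
#' @examples
#' irr_with_ci(5, 1000, 10, 640)  # irr = 0.32
#' @export
irr_with_ci <- function(events_on, py_on, events_off, py_off,
                        alpha = 0.05, setting = NA_character_) {
  for (v in list(events_on = events_on, events_off = events_off)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop_domain("event counts must be single non-negative numbers")
    }
  }
  assert_scalar_number(py_on, "py_on", min = 0, strict_min = TRUE)
  assert_scalar_number(py_off, "py_off", min = 0, strict_min = TRUE)
  assert_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)

  corrected <- events_on == 0 || events_off == 0
  a <- if (corrected) events_on + 0.5 else events_on
  b <- if (corrected) events_off + 0.5 else events_off
  irr <- (a / py_on) / (b / py_off)
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(1 / a + 1 / b)
  structure(
    list(
      setting = setting, irr = irr,
      ci_low = exp(log(irr) - z * se), ci_high = exp(log(irr) + z * se),
      alpha = alpha, events_on = events_on, events_off = events_off,
      py_on = py_on, py_off = py_off, corrected = corrected
    ),
    class = "irr_estimate"
  )
}

#' @export
print.irr_estimate <- function(x, ...) {
  cat(sprintf(
    "IRR%s = %.3f (%.0f%% CI %.3f-%.3f)%s [%g/%.1f PY vs %g/%.1f PY]\n",
    if (is.na(x$setting)) "" else paste0(" (", x$setting, ")"),
    x$irr, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
    if (x$corrected) " [continuity-corrected]" else "",
    x$events_on, x$py_on, x$events_off, x$py_off
  ))
  invisible(x)
}

#' Proportion of non-overdose deaths that are suicides, with Wilson CI
#'
#' @param suicides suicide count.
#' @param nonoverdose_deaths total non-overdose deaths (suicides plus other
#'   non-overdose causes); must be positive and at least `suicides`.
#' @param alpha two-sided significance level.
#' @return list with `p`, `ci_low`, `ci_high`, `suicides`,
#'   `nonoverdose_deaths`, `alpha`.
#' @export
suicide_fraction <- function(suicides, nonoverdose_deaths, alpha = 0.05) {
  assert_scalar_number(suicides, "suicides", min = 0)
  assert_scalar_number(nonoverdose_deaths, "nonoverdose_deaths", min = 0,
                       strict_min = TRUE)
  if (suicides > nonoverdose_deaths) {
    stop_domain("'suicides' cannot exceed 'nonoverdose_deaths'")
  }
  assert_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  n <- nonoverdose_deaths
  p <- suicides / n
  z <- stats::qnorm(1 - alpha / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  list(
    p = p, ci_low = max(0, center - half), ci_high = min(1, center + half),
    suicides = suicides, nonoverdose_deaths = nonoverdose_deaths, alpha = alpha
  )
}

#' Estimate the full model-input parameter set from stratum counts
#'
#' Computes the community and prison on/off-OAT suicide IRRs and the four
#' per-stratum proportions of non-overdose deaths attributable to suicide
#' (non-overdose deaths = suicides + other non-overdose deaths).
#'
#' @param counts a `stratum_counts` table from [allocate_person_time()].
#' @param alpha two-sided significance level for all intervals.
#' @return an `oat_parameter_estimates` list with elements `irr_community`,
#'   `irr_prison` (class `irr_estimate`) and `fractions`, a data.frame with
#'   one row per stratum (`stratum`, `suicides`, `nonoverdose_deaths`, `p`,
#'   `ci_low`, `ci_high`).
#' @export
estimate_all_parameters <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "stratum_counts") || is.data.frame(counts))
  need <- c("stratum", "person_years", "suicides", "other_nonoverdose_deaths")
  if (!all(need %in% names(counts)) || !setequal(counts$stratum, STRATA)) {
    stop_domain("'counts' must hold all four strata with person-years and death counts")
  }
  row <- function(s) counts[counts$stratum == s, , drop = FALSE]
  irr_comm <- irr_with_ci(
    row("community_on")$suicides, row("community_on")$person_years,
    row("community_off")$suicides, row("community_off")$person_years,
    alpha = alpha, setting = "community"
  )
  irr_pris <- irr_with_ci(
    row("prison_on")$suicides, row("prison_on")$person_years,
    row("prison_off")$suicides, row("prison_off")$person_years,
    alpha = alpha, setting = "prison"
  )
  fr <- do.call(rbind, lapply(STRATA, function(s) {
    r <- row(s)
    nod <- r$suicides + r$other_nonoverdose_deaths
    f <- suicide_fraction(r$suicides, max(nod, 1), alpha = alpha)
    data.frame(stratum = s, suicides = r$suicides, nonoverdose_deaths = nod,
               p = if (nod > 0) f$p else NA_real_,
               ci_low = f$ci_low, ci_high = f$ci_high)
  }))
  structure(
    list(irr_community = irr_comm, irr_prison = irr_pris, fractions = fr,
         alpha = alpha),
    class = "oat_parameter_estimates"
  )
}

#' @export
print.oat_parameter_estimates <- function(x, ...) {
  print(x$irr_community)
  print(x$irr_prison)
  cat("Suicide fractions of non-overdose deaths:\n")
  print.data.frame(x$fractions, row.names = FALSE, digits = 3)
  invisible(x)
}
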