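# Shared fixtures: small configurations and independent brute-force oracles.

STRATA4 <- c("community_on", "community_off", "prison_on", "prison_off")

zero_stratum_vec <- function(value = 0) {
  stats::setNames(rep(value, 4), STRATA4)
}

small_config <- function(n = 500, seed = 1, ...) {
  generator_config(
    n_entrants = n,
    entry_start = as.Date("2001-08-01"), entry_end = as.Date("2005-12-31"),
    study_end = as.Date("2010-12-31"),
    seed = seed, ...
  )
}

# Independent day-by-day oracle: enumerate every follow-up day of every
# person, look up OAT and incarceration state, and accumulate person-days and
# deaths per stratum. Deliberately naive; used to cross-check the interval
# engine.
brute_force_tabulate <- function(tables, study_start, study_end) {
  s0 <- as.integer(as.Date(study_start))
  s1 <- as.integer(as.Date(study_end))
  res <- data.frame(
    stratum = STRATA4, person_days = 0,
    suicides = 0L, overdose_deaths = 0L, other_nonoverdose_deaths = 0L
  )
  oat <- tables$oat_episodes
  inc <- tables$incarceration_episodes
  deaths <- tables$deaths
  covered <- function(ep, pid, day) {
    rows <- ep[ep$person_id == pid, , drop = FALSE]
    any(as.integer(rows$start_date) <= day & as.integer(rows$end_date) > day)
  }
  stratum_of <- function(on, pris) {
    if (pris) (if (on) "prison_on" else "prison_off")
    else (if (on) "community_on" else "community_off")
  }
  for (pid in tables$persons$person_id) {
    first_oat <- min(as.integer(oat$start_date[oat$person_id == pid]))
    fstart <- max(s0, first_oat)
    drow <- deaths[deaths$person_id == pid, , drop = FALSE]
    dday <- if (nrow(drow)) as.integer(drow$death_date) else NA_integer_
    fend <- min(s1, if (is.na(dday)) s1 else dday)
    if (fend > fstart) {
      for (day in fstart:(fend - 1L)) {
        st <- stratum_of(covered(oat, pid, day), covered(inc, pid, day))
        res$person_days[res$stratum == st] <- res$person_days[res$stratum == st] + 1
      }
    }
    if (!is.na(dday) && dday >= s0 && dday <= s1) {
      on_day <- function(ep) {
        rows <- ep[ep$person_id == pid, , drop = FALSE]
        s <- as.integer(rows$start_date)
        e <- as.integer(rows$end_date)
        any(s <= dday & e >= dday)
      }
      st <- stratum_of(on_day(oat), on_day(inc))
      cl <- classify_death(drow$underlying_icd10,
                           strsplit(drow$additional_icd10, ";")[[1]])
      col <- switch(cl$category,
                    suicide_nonoverdose = "suicides",
                    overdose = "overdose_deaths",
                    other_nonoverdose = "other_nonoverdose_deaths")
      res[[col]][res$stratum == st] <- res[[col]][res$stratum == st] + 1L
    }
  }
  res
}

# Naive step-by-step ledger simulation of the compartmental model, coded
# independently of simulate_cohort(): explicit per-flow bookkeeping with no
# matrix algebra.
ledger_simulate <- function(params, horizon, dt) {
  comps <- c("c_on", "c_off_rec", "c_off", "c_pr_on", "c_pr_off", "p_on", "p_off")
  X <- stats::setNames(rep(0, 7), comps)
  spy <- round(1 / dt)
  wpy <- 365.25 / 7
  p <- params
  od_mult <- c(c_on = 1, c_off_rec = p$overdose_multiplier_post_cessation,
               c_off = 1, c_pr_on = p$overdose_multiplier_post_release,
               c_pr_off = p$overdose_multiplier_post_release, p_on = 1, p_off = 1)
  strat <- c(c_on = "community_on", c_off_rec = "community_off",
             c_off = "community_off", c_pr_on = "community_on",
             c_pr_off = "community_off", p_on = "prison_on", p_off = "prison_off")
  years <- as.integer(names(p$entry_series))
  d_od <- matrix(0, horizon, 4, dimnames = list(NULL, STRATA4))
  d_ot <- d_od
  for (step in seq_len(horizon * spy)) {
    yr <- (step - 1) %/% spy + 1
    entry_y <- years[1] + yr - 1
    e_step <- if (as.character(entry_y) %in% names(p$entry_series)) {
      p$entry_series[[as.character(entry_y)]] / spy
    } else 0
    move <- stats::setNames(rep(0, 7), comps)
    take <- function(from, rate) X[[from]] * rate * dt
    flows <- list(
      c("c_on", "c_off_rec", p$oat_cessation_rate_community),
      c("c_off_rec", "c_off", wpy / p$post_cessation_window_weeks),
      c("c_off_rec", "c_on", p$oat_reentry_rate),
      c("c_off", "c_on", p$oat_reentry_rate),
      c("c_pr_on", "c_on", wpy / p$post_release_window_weeks),
      c("c_pr_on", "c_pr_off", p$oat_cessation_rate_community),
      c("c_pr_off", "c_off", wpy / p$post_release_window_weeks),
      c("c_pr_off", "c_on", p$oat_reentry_rate),
      c("c_on", "p_on", p$incarceration_rate_on),
      c("c_pr_on", "p_on", p$incarceration_rate_on),
      c("c_off_rec", "p_off", p$incarceration_rate_off),
      c("c_off", "p_off", p$incarceration_rate_off),
      c("c_pr_off", "p_off", p$incarceration_rate_off),
      c("p_on", "p_off", p$oat_cessation_rate_prison),
      c("p_off", "p_on", p$oat_reentry_rate),
      c("p_on", "c_pr_on", p$release_rate),
      c("p_off", "c_pr_off", p$release_rate)
    )
    for (f in flows) {
      amt <- take(f[1], as.numeric(f[3]))
      move[[f[1]]] <- move[[f[1]]] - amt
      move[[f[2]]] <- move[[f[2]]] + amt
    }
    for (cc in comps) {
      od_amt <- X[[cc]] * p$overdose_rate[[strat[[cc]]]] * od_mult[[cc]] * dt
      ot_amt <- X[[cc]] * p$other_cause_rate[[strat[[cc]]]] * dt
      move[[cc]] <- move[[cc]] - od_amt - ot_amt
      d_od[yr, strat[[cc]]] <- d_od[yr, strat[[cc]]] + od_amt
      d_ot[yr, strat[[cc]]] <- d_ot[yr, strat[[cc]]] + ot_amt
    }
    X <- X + move
    X[["c_on"]] <- X[["c_on"]] + e_step
  }
  list(X = X, deaths_overdose = d_od, deaths_other = d_ot)
}
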