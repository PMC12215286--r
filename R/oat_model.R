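# Deterministic compartmental model of mortality in an OAT-ever cohort.
#
# Seven compartments realize OAT initiation/ongoing treatment/discontinuation,
# incarceration stratification, and the two elevated-overdose-risk windows
# (after treatment cessation and after prison release):
#
#   c_on        on OAT, community
#   c_off_rec   off OAT, community, within the post-cessation window
#   c_off       off OAT, community
#   c_pr_on     on OAT, community, within the post-release window
#   c_pr_off    off OAT, community, within the post-release window
#   p_on        on OAT, prison
#   p_off       off OAT, prison
#
# Reporting aggregates the post-release and recent-cessation substrata onto
# the four on/off x prison/community strata. People enter on first OAT
# initiation (into c_on) and leave only through overdose or other-cause death.

COMPARTMENTS <- c("c_on", "c_off_rec", "c_off", "c_pr_on", "c_pr_off", "p_on", "p_off")

# compartment -> reporting stratum
COMPARTMENT_STRATUM <- c(
  c_on = "community_on", c_off_rec = "community_off", c_off = "community_off",
  c_pr_on = "community_on", c_pr_off = "community_off",
  p_on = "prison_on", p_off = "prison_off"
)

WEEKS_PER_YEAR <- DAYS_PER_YEAR / 7

#' Parameters of the compartmental OAT cohort model
#'
#' All rates are per person-year. Elevated-risk multipliers scale the
#' overdose rate of the corresponding community stratum inside the
#' post-cessation and post-release windows.
#'
#' @param entry_series named numeric vector of new first-time OAT initiates
#'   per calendar year; names are the years.
#' @param oat_cessation_rate_community,oat_cessation_rate_prison rate of
#'   leaving treatment.
#' @param oat_reentry_rate rate of returning to (or starting) treatment while
#'   off OAT.
#' @param incarceration_rate_on,incarceration_rate_off incarceration rates by
#'   OAT status.
#' @param release_rate rate of release from prison.
#' @param post_release_window_weeks,post_cessation_window_weeks mean duration
#'   of the elevated-overdose-risk windows, weeks.
#' @param overdose_rate,other_cause_rate named length-4 vectors of death rates
#'   per stratum (community_on, community_off, prison_on, prison_off).
#'   `other_cause_rate` is all non-overdose mortality, including suicide.
#' @param overdose_multiplier_post_cessation,overdose_multiplier_post_release
#'   overdose-rate multipliers inside each window.
#' @return a validated `oat_model_params` list.
#' @export
model_params <- function(
    entry_series = stats::setNames(rep(2450, 20), 2001:2020),
    oat_cessation_rate_community = 0.61,
    oat_cessation_rate_prison = 0.61,
    oat_reentry_rate = 0.80,
    incarceration_rate_on = 0.08,
    incarceration_rate_off = 0.12,
    release_rate = 3.0,
    post_release_window_weeks = 4,
    post_cessation_window_weeks = 4,
    overdose_rate = c(community_on = 0.002, community_off = 0.006,
                      prison_on = 0.0005, prison_off = 0.001),
    other_cause_rate = c(community_on = 0.00352, community_off = 0.0084615,
                         prison_on = 0.0040476, prison_off = 0.0069444),
    overdose_multiplier_post_cessation = 4,
    overdose_multiplier_post_release = 8) {
  p <- list(
    entry_series = entry_series,
    oat_cessation_rate_community = oat_cessation_rate_community,
    oat_cessation_rate_prison = oat_cessation_rate_prison,
    oat_reentry_rate = oat_reentry_rate,
    incarceration_rate_on = incarceration_rate_on,
    incarceration_rate_off = incarceration_rate_off,
    release_rate = release_rate,
    post_release_window_weeks = post_release_window_weeks,
    post_cessation_window_weeks = post_cessation_window_weeks,
    overdose_rate = overdose_rate,
    other_cause_rate = other_cause_rate,
    overdose_multiplier_post_cessation = overdose_multiplier_post_cessation,
    overdose_multiplier_post_release = overdose_multiplier_post_release
  )
  validate_model_params(p)
}

validate_model_params <- function(p) {
  if (length(p$entry_series) < 1L || any(!is.finite(p$entry_series)) ||
      any(p$entry_series < 0) || is.null(names(p$entry_series))) {
    stop_domain("'entry_series' must be a named, non-negative numeric vector")
  }
  scalar_rates <- c(
    "oat_cessation_rate_community", "oat_cessation_rate_prison",
    "oat_reentry_rate", "incarceration_rate_on", "incarceration_rate_off",
    "release_rate", "overdose_multiplier_post_cessation",
    "overdose_multiplier_post_release"
  )
  for (f in scalar_rates) assert_scalar_number(p[[f]], f, min = 0)
  for (f in c("post_release_window_weeks", "post_cessation_window_weeks")) {
    assert_scalar_number(p[[f]], f, min = 0, strict_min = TRUE)
  }
  for (f in c("overdose_rate", "other_cause_rate")) {
    v <- p[[f]]
    if (length(v) != 4L || !all(STRATA %in% names(v)) || any(!is.finite(v)) ||
        any(v < 0)) {
      stop_domain(sprintf("'%s' must be a named non-negative length-4 vector", f))
    }
    p[[f]] <- v[STRATA]
  }
  structure(p, class = "oat_model_params")
}

# Override (possibly nested) parameter fields from a named numeric vector,
# e.g. c(oat_reentry_rate = 0.9, `overdose_rate.community_off` = 0.01). Used
# to wire ABC-SMC particles into the simulator.
apply_param_vector <- function(params, values) {
  stopifnot(inherits(params, "oat_model_params"), !is.null(names(values)))
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) {
      if (!parts %in% names(params)) stop_domain(sprintf("unknown parameter '%s'", nm))
      params[[parts]] <- unname(values[[nm]])
    } else if (length(parts) == 2L) {
      if (!parts[1L] %in% names(params) ||
          !parts[2L] %in% names(params[[parts[1L]]])) {
        stop_domain(sprintf("unknown parameter '%s'", nm))
      }
      params[[parts[1L]]][[parts[2L]]] <- unname(values[[nm]])
    } else {
      stop_domain(sprintf("unknown parameter '%s'", nm))
    }
  }
  validate_model_params(params)
}

# Per-compartment transition matrix A (A[i, j] = rate i -> j, per year) and
# per-compartment death-rate vectors.
model_rate_structure <- function(p) {
  nC <- length(COMPARTMENTS)
  A <- matrix(0, nC, nC, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  w_cess <- WEEKS_PER_YEAR / p$post_cessation_window_weeks
  w_rel <- WEEKS_PER_YEAR / p$post_release_window_weeks

  A["c_on", "c_off_rec"] <- p$oat_cessation_rate_community
  A["c_off_rec", "c_off"] <- w_cess
  A["c_off_rec", "c_on"] <- p$oat_reentry_rate
  A["c_off", "c_on"] <- p$oat_reentry_rate
  A["c_pr_on", "c_on"] <- w_rel
  A["c_pr_on", "c_pr_off"] <- p$oat_cessation_rate_community
  A["c_pr_off", "c_off"] <- w_rel
  A["c_pr_off", "c_on"] <- p$oat_reentry_rate
  A["c_on", "p_on"] <- p$incarceration_rate_on
  A["c_pr_on", "p_on"] <- p$incarceration_rate_on
  A["c_off_rec", "p_off"] <- p$incarceration_rate_off
  A["c_off", "p_off"] <- p$incarceration_rate_off
  A["c_pr_off", "p_off"] <- p$incarceration_rate_off
  A["p_on", "p_off"] <- p$oat_cessation_rate_prison
  A["p_off", "p_on"] <- p$oat_reentry_rate
  A["p_on", "c_pr_on"] <- p$release_rate
  A["p_off", "c_pr_off"] <- p$release_rate

  od <- p$overdose_rate[COMPARTMENT_STRATUM]
  ot <- p$other_cause_rate[COMPARTMENT_STRATUM]
  names(od) <- names(ot) <- COMPARTMENTS
  od["c_off_rec"] <- od["c_off_rec"] * p$overdose_multiplier_post_cessation
  od[c("c_pr_on", "c_pr_off")] <- od[c("c_pr_on", "c_pr_off")] *
    p$overdose_multiplier_post_release
  list(A = A, od = od, ot = ot)
}

#' Simulate the compartmental OAT cohort model
#'
#' Fixed-step forward-Euler integration of the compartment difference
#' equations over `horizon` whole years starting from an empty cohort at the
#' first year of the entry series. Entries are spread uniformly over the
#' steps within each calendar year.
#'
#' @param params an [model_params()] object.
#' @param horizon number of whole years to simulate (defaults to the length
#'   of the entry series).
#' @param dt step size in years; must not exceed one week (1/52 year, the
#'   default).
#' @param init optional named initial occupancy vector over the seven
#'   compartments (default: empty cohort); useful for pulse/decay analyses.
#' @return an `oat_trajectory`: list with `times` (year offsets),
#'   `occupancy` (steps x 7 matrix), `deaths_overdose` and `deaths_other`
#'   (years x 4 strata matrices of within-year death flows), `entries_total`,
#'   `params`, `dt`, `start_year`.
#' @export
simulate_cohort <- function(params, horizon = length(params$entry_series),
                            dt = 1 / 52, init = NULL) {
  p <- validate_model_params(params)
  assert_scalar_number(horizon, "horizon", min = 1)
  if (abs(horizon - round(horizon)) > 1e-9) {
    stop_domain("'horizon' must be a whole number of years")
  }
  horizon <- as.integer(round(horizon))
  assert_scalar_number(dt, "dt", min = 0, strict_min = TRUE)
  if (dt > 1 / 52 + 1e-12) stop_domain("'dt' must not exceed one week (1/52 year)")
  steps_per_year <- round(1 / dt)
  if (abs(steps_per_year * dt - 1) > 1e-9) {
    stop_domain("'dt' must divide one year into a whole number of steps")
  }

  rs <- model_rate_structure(p)
  out_rate <- rowSums(rs$A) + rs$od + rs$ot
  if (any(out_rate * dt > 1)) {
    stop_domain(
      "total outflow rate exceeds 1 per step; use a smaller 'dt' for stability"
    )
  }
  M <- diag(1 - out_rate * dt) + t(rs$A) * dt

  years <- as.integer(names(p$entry_series))
  start_year <- years[1L]
  entry_by_year <- rep(0, horizon)
  idx <- match(start_year + seq_len(horizon) - 1L, years)
  entry_by_year[!is.na(idx)] <- p$entry_series[idx[!is.na(idx)]]

  nC <- length(COMPARTMENTS)
  n_steps <- horizon * steps_per_year
  occupancy <- matrix(0, n_steps + 1L, nC, dimnames = list(NULL, COMPARTMENTS))
  smap <- outer(STRATA, COMPARTMENT_STRATUM, "==") * 1 # 4 x 7 aggregation
  dimnames(smap) <- list(STRATA, COMPARTMENTS)
  deaths_od <- matrix(0, horizon, 4, dimnames = list(start_year + seq_len(horizon) - 1L, STRATA))
  deaths_ot <- deaths_od

  X <- numeric(nC)
  names(X) <- COMPARTMENTS
  entries_total <- 0
  if (!is.null(init)) {
    if (is.null(names(init)) || !all(names(init) %in% COMPARTMENTS) ||
        any(init < 0)) {
      stop_domain("'init' must be a non-negative vector named by compartment")
    }
    X[names(init)] <- init
    entries_total <- sum(init)
    occupancy[1L, ] <- X
  }
  for (s in seq_len(n_steps)) {
    yr <- ((s - 1L) %/% steps_per_year) + 1L
    e_step <- entry_by_year[yr] / steps_per_year
    d_od <- X * rs$od * dt
    d_ot <- X * rs$ot * dt
    X <- drop(M %*% X)
    X[1L] <- X[1L] + e_step
    entries_total <- entries_total + e_step
    if (any(X < -1e-9)) {
      stop_domain("negative compartment occupancy; use a smaller 'dt'")
    }
    if (any(!is.finite(X))) stop_domain("non-finite compartment occupancy")
    deaths_od[yr, ] <- deaths_od[yr, ] + drop(smap %*% d_od)
    deaths_ot[yr, ] <- deaths_ot[yr, ] + drop(smap %*% d_ot)
    occupancy[s + 1L, ] <- X
  }

  structure(
    list(
      times = seq(0, horizon, by = dt), occupancy = occupancy,
      deaths_overdose = deaths_od, deaths_other = deaths_ot,
      entries_total = entries_total, params = p, dt = dt,
      start_year = start_year, steps_per_year = steps_per_year
    ),
    class = "oat_trajectory"
  )
}

#' @export
print.oat_trajectory <- function(x, ...) {
  cat(sprintf(
    "Cohort trajectory: %d years from %d, dt = %.4g yr; final population %.1f; deaths %.1f overdose / %.1f other\n",
    nrow(x$deaths_overdose), x$start_year, x$dt,
    sum(x$occupancy[nrow(x$occupancy), ]),
    sum(x$deaths_overdose), sum(x$deaths_other)
  ))
  invisible(x)
}

#' Annual calibration summaries of a model trajectory
#'
#' Year-end snapshots for stocks and within-year sums for death flows, in the
#' shape the calibration targets use: total cohort alive, on OAT in the
#' community and in prison, proportion currently or recently incarcerated
#' (prison plus post-release-window occupants), total deaths, and the
#' proportion of deaths that are overdose-related.
#'
#' @param trajectory an `oat_trajectory` from [simulate_cohort()].
#' @return a `calibration_series` data.frame with one row per year.
#' @export
annual_summaries <- function(trajectory) {
  stopifnot(inherits(trajectory, "oat_trajectory"))
  spy <- trajectory$steps_per_year
  n_years <- nrow(trajectory$deaths_overdose)
  ye <- trajectory$occupancy[1L + spy * seq_len(n_years), , drop = FALSE]
  alive <- rowSums(ye)
  inc_now_or_recent <- rowSums(ye[, c("p_on", "p_off", "c_pr_on", "c_pr_off"), drop = FALSE])
  d_od <- rowSums(trajectory$deaths_overdose)
  d_ot <- rowSums(trajectory$deaths_other)
  d_tot <- d_od + d_ot
  out <- data.frame(
    year = trajectory$start_year + seq_len(n_years) - 1L,
    alive = alive,
    on_oat_community = ye[, "c_on"] + ye[, "c_pr_on"],
    on_oat_prison = ye[, "p_on"],
    prop_incarcerated = ifelse(alive > 0, inc_now_or_recent / alive, 0),
    deaths_total = d_tot,
    prop_overdose = ifelse(d_tot > 0, d_od / d_tot, 0)
  )
  class(out) <- c("calibration_series", "data.frame")
  out
}

# Cumulative other-cause (non-overdose) deaths per reporting stratum over a
# span of years; the input the scenario analysis consumes.
other_cause_deaths_by_stratum <- function(trajectory, years = NULL) {
  stopifnot(inherits(trajectory, "oat_trajectory"))
  d <- trajectory$deaths_other
  if (!is.null(years)) {
    keep <- rownames(d) %in% as.character(years)
    d <- d[keep, , drop = FALSE]
  }
  colSums(d)
}
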