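# Approximate Bayesian computation with sequential Monte Carlo.
#
# Generic over a simulator closure so the sampler can be exercised on cheap
# toy models as well as the compartmental cohort model. Particles are
# parameter vectors; each generation resamples by weight, perturbs with a
# component-wise uniform kernel on the (log-)transformed scale, reflects at
# the prior bounds, and accepts at an adaptively shrinking tolerance.

#' Prior specification for ABC-SMC
#'
#' @param names character vector of parameter names. Nested model fields use
#'   a dotted path (e.g. `"overdose_rate.community_off"`).
#' @param dist distribution family per parameter: `"uniform"` or
#'   `"loguniform"`.
#' @param lower,upper finite bounds per parameter; `lower < upper`, and
#'   `lower > 0` for log-uniform components.
#' @return a `prior_spec` data.frame.
#' @export
prior_spec <- function(names, dist, lower, upper) {
  n <- length(names)
  stopifnot(length(dist) == n, length(lower) == n, length(upper) == n)
  if (!all(dist %in% c("uniform", "loguniform"))) {
    stop_domain("'dist' entries must be 'uniform' or 'loguniform'")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop_domain("prior bounds must be finite with lower < upper")
  }
  if (any(dist == "loguniform" & lower <= 0)) {
    stop_domain("log-uniform priors require strictly positive lower bounds")
  }
  out <- data.frame(name = names, dist = dist, lower = lower, upper = upper,
                    stringsAsFactors = FALSE)
  class(out) <- c("prior_spec", "data.frame")
  out
}

# transform to the scale the kernel operates on
prior_transform <- function(x, priors) {
  t(vapply(seq_len(nrow(priors)), function(k) {
    if (priors$dist[k] == "loguniform") log(x[, k]) else x[, k]
  }, numeric(nrow(x))))
}

sample_priors <- function(priors, n) {
  m <- vapply(seq_len(nrow(priors)), function(k) {
    if (priors$dist[k] == "loguniform") {
      exp(stats::runif(n, log(priors$lower[k]), log(priors$upper[k])))
    } else {
      stats::runif(n, priors$lower[k], priors$upper[k])
    }
  }, numeric(n))
  m <- matrix(m, nrow = n, dimnames = list(NULL, priors$name))
  m
}

prior_density <- function(x, priors) {
  # x: matrix n x p on the natural scale; returns vector of joint densities
  d <- rep(1, nrow(x))
  for (k in seq_len(nrow(priors))) {
    lo <- priors$lower[k]
    up <- priors$upper[k]
    v <- x[, k]
    inside <- v >= lo & v <= up
    dk <- if (priors$dist[k] == "loguniform") {
      ifelse(inside, 1 / (v * log(up / lo)), 0)
    } else {
      ifelse(inside, 1 / (up - lo), 0)
    }
    d <- d * dk
  }
  d
}

#' Calibration distance between simulated and observed annual series
#'
#' Weighted sum over metrics of the mean squared relative error across years
#' (relative to the observed value; observed-zero cells fall back to absolute
#' error on `zero_scale`).
#'
#' @param simulated,observed `calibration_series` data.frames covering
#'   identical years and metrics (a `year` column plus metric columns).
#' @param weights optional named metric weights (default 1 for every metric).
#' @param zero_scale absolute-error scale used where the observed value is 0.
#' @return a single finite non-negative number.
#' @export
calibration_distance <- function(simulated, observed, weights = NULL,
                                 zero_scale = 1) {
  if (!identical(sort(names(simulated)), sort(names(observed)))) {
    stop_domain("simulated and observed series carry different metrics")
  }
  if (!identical(as.integer(simulated$year), as.integer(observed$year))) {
    stop_domain("simulated and observed series cover different years")
  }
  metrics <- setdiff(names(observed), "year")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(metrics)), metrics)
  if (!all(metrics %in% names(weights))) {
    stop_domain("'weights' must name every metric in the series")
  }
  total <- 0
  for (m in metrics) {
    obs <- observed[[m]]
    sim <- simulated[[m]]
    rel <- ifelse(obs != 0, (sim - obs) / obs, (sim - obs) / zero_scale)
    total <- total + weights[[m]] * mean(rel^2)
  }
  if (!is.finite(total)) stop_domain("non-finite calibration distance")
  total
}

#' Calibrate parameters by ABC sequential Monte Carlo
#'
#' Generation 0 draws from the prior and keeps the `n_particles` draws below
#' the `quantile_schedule` quantile of the prior-predictive distances. Each
#' later generation resamples particles by weight, perturbs on the
#' transformed scale with a component-wise uniform kernel of half-width
#' `kernel_scale` times the weighted standard deviation, reflects proposals
#' at the prior bounds, accepts at the shrunk tolerance (the
#' `quantile_schedule` quantile of the previous generation's accepted
#' distances), and reweights with the standard SMC importance correction.
#'
#' @param priors a [prior_spec()].
#' @param observed observed `calibration_series` (or any object the
#'   `sim_fn`'s output can be compared against via [calibration_distance()]).
#' @param sim_fn function taking a named parameter vector and returning a
#'   simulated series comparable to `observed`.
#' @param n_particles number of particles per generation (>= 50).
#' @param n_generations number of SMC generations (>= 1).
#' @param quantile_schedule tolerance quantile in (0, 1); default 0.5.
#' @param kernel_scale perturbation half-width as a fraction of the weighted
#'   per-parameter standard deviation; default 0.68.
#' @param distance_weights optional metric weights for
#'   [calibration_distance()].
#' @param tolerance_schedule optional explicit tolerance per generation,
#'   overriding the adaptive schedule (e.g. `rep(Inf, 3)` to sample the
#'   prior).
#' @param min_acceptance_rate floor below which a generation aborts with a
#'   warning, returning the last completed generation.
#' @param seed master seed; per-generation child seeds are derived from it.
#' @return a `particle_set`: data.frame of parameter columns plus `weight`
#'   and `distance`, with attributes `tolerances`, `ess`, `acceptance_rates`,
#'   `generation`.
#' @export
run_abc_smc <- function(priors, observed, sim_fn, n_particles = 200,
                        n_generations = 5, quantile_schedule = 0.5,
                        kernel_scale = 0.68, distance_weights = NULL,
                        tolerance_schedule = NULL,
                        min_acceptance_rate = 0.002, seed = 1L) {
  stopifnot(inherits(priors, "prior_spec"))
  assert_scalar_number(n_particles, "n_particles", min = 50)
  assert_scalar_number(n_generations, "n_generations", min = 1)
  assert_scalar_number(quantile_schedule, "quantile_schedule",
                       min = 0, max = 1, strict_min = TRUE)
  if (quantile_schedule >= 1) stop_domain("'quantile_schedule' must be in (0, 1)")
  n_particles <- as.integer(n_particles)
  n_generations <- as.integer(n_generations)
  p_dim <- nrow(priors)
  seeds <- derive_seeds(seed, n_generations)

  dist_fn <- function(theta) {
    calibration_distance(sim_fn(stats::setNames(as.numeric(theta), priors$name)),
                         observed, weights = distance_weights)
  }
  explicit_tol <- !is.null(tolerance_schedule)
  if (explicit_tol && length(tolerance_schedule) != n_generations) {
    stop_domain("'tolerance_schedule' must supply one tolerance per generation")
  }

  ## generation 0: prior rejection at the initial tolerance
  set.seed(seeds[1L])
  n_pilot <- ceiling(n_particles / quantile_schedule)
  pilot <- sample_priors(priors, n_pilot)
  pilot_d <- apply(pilot, 1L, dist_fn)
  eps <- if (explicit_tol) tolerance_schedule[1L] else {
    unname(stats::quantile(pilot_d, quantile_schedule, type = 1))
  }
  keep <- which(pilot_d <= eps)
  if (length(keep) < n_particles) keep <- order(pilot_d)[seq_len(n_particles)]
  keep <- keep[seq_len(n_particles)]
  theta <- pilot[keep, , drop = FALSE]
  d <- pilot_d[keep]
  w <- rep(1 / n_particles, n_particles)
  tolerances <- eps
  ess <- 1 / sum(w^2)
  acc_rates <- length(keep) / n_pilot

  gen_done <- 1L
  for (g in seq_len(n_generations - 1L)) {
    set.seed(seeds[g + 1L])
    eps_new <- if (explicit_tol) tolerance_schedule[g + 1L] else {
      unname(weighted_quantile(d, w, quantile_schedule))
    }
    if (is.finite(eps_new) && is.finite(eps)) {
      eps_new <- min(eps_new, eps * (1 - 1e-12))
    }
    tr <- prior_transform(theta, priors)      # p x n on kernel scale
    lo_t <- ifelse(priors$dist == "loguniform", log(priors$lower), priors$lower)
    up_t <- ifelse(priors$dist == "loguniform", log(priors$upper), priors$upper)
    h <- vapply(seq_len(p_dim), function(k) {
      s <- kernel_scale * weighted_sd(tr[k, ], w)
      min(max(s, 1e-12), up_t[k] - lo_t[k])
    }, numeric(1))

    new_theta <- matrix(NA_real_, n_particles, p_dim,
                        dimnames = list(NULL, priors$name))
    new_d <- numeric(n_particles)
    accepted <- 0L
    attempts <- 0L
    max_attempts <- max(5000L, ceiling(n_particles / min_acceptance_rate / 10))
    aborted <- FALSE
    while (accepted < n_particles) {
      batch <- min(4L * (n_particles - accepted), 2000L)
      attempts <- attempts + batch
      pick <- sample.int(n_particles, batch, replace = TRUE, prob = w)
      prop_t <- tr[, pick, drop = FALSE] +
        matrix(stats::runif(batch * p_dim, -h, h), p_dim, batch)
      # reflect at transformed prior bounds
      for (k in seq_len(p_dim)) {
        v <- prop_t[k, ]
        span <- up_t[k] - lo_t[k]
        v <- abs((v - lo_t[k]) %% (2 * span))
        v <- ifelse(v > span, 2 * span - v, v) + lo_t[k]
        prop_t[k, ] <- v
      }
      prop <- t(prop_t)
      for (k in which(priors$dist == "loguniform")) prop[, k] <- exp(prop[, k])
      for (b in seq_len(batch)) {
        if (accepted >= n_particles) break
        db <- dist_fn(prop[b, ])
        if (db <= eps_new) {
          accepted <- accepted + 1L
          new_theta[accepted, ] <- prop[b, ]
          new_d[accepted] <- db
        }
      }
      if (attempts >= max_attempts && accepted < n_particles) {
        warning(sprintf(
          "ABC-SMC generation %d acceptance rate below floor (%d/%d); returning generation %d",
          g + 1L, accepted, attempts, gen_done
        ), call. = FALSE)
        aborted <- TRUE
        break
      }
    }
    if (aborted) break

    # importance weights: prior density over kernel mixture density
    new_tr <- prior_transform(new_theta, priors)  # p x n
    kern <- matrix(0, n_particles, n_particles)
    for (k in seq_len(p_dim)) {
      # reflected uniform kernel: direct image plus the two boundary mirror
      # images, so the proposal density is exact under bound reflection
      direct <- abs(outer(new_tr[k, ], tr[k, ], "-")) <= h[k]
      mlo <- abs(outer(new_tr[k, ], tr[k, ], "+") - 2 * lo_t[k]) <= h[k]
      mup <- abs(outer(new_tr[k, ], tr[k, ], "+") - 2 * up_t[k]) <= h[k]
      kern_k <- (direct + mlo + mup) / (2 * h[k])
      kern <- if (k == 1L) kern_k else kern * kern_k
    }
    denom <- drop(kern %*% w)
    # transformed-scale kernel density corresponds to a density in log-space
    # for log-uniform components; the prior density must be on the same scale
    pri <- prior_density(new_theta, priors)
    for (k in which(priors$dist == "loguniform")) {
      pri <- pri * new_theta[, k] # Jacobian: uniform-in-log prior is flat in log space
    }
    w_new <- pri / pmax(denom, .Machine$double.xmin)
    if (all(w_new == 0) || any(!is.finite(w_new))) {
      stop_domain("degenerate importance weights in ABC-SMC")
    }
    w <- w_new / sum(w_new)
    theta <- new_theta
    d <- new_d
    eps <- eps_new
    tolerances <- c(tolerances, eps_new)
    ess_g <- 1 / sum(w^2)
    if (!is.finite(ess_g)) stop_domain("non-finite effective sample size")
    ess <- c(ess, ess_g)
    acc_rates <- c(acc_rates, accepted / attempts)
    gen_done <- g + 1L
    if (ess_g < n_particles / 20) {
      warning(sprintf("ABC-SMC generation %d has low effective sample size (%.1f)",
                      gen_done, ess_g), call. = FALSE)
    }
  }

  out <- as.data.frame(theta)
  out$weight <- w
  out$distance <- d
  class(out) <- c("particle_set", "data.frame")
  attr(out, "tolerances") <- tolerances
  attr(out, "ess") <- ess
  attr(out, "acceptance_rates") <- acc_rates
  attr(out, "generation") <- gen_done
  attr(out, "priors") <- priors
  out
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf(
    "ABC-SMC particle set: %d particles, generation %d, tolerance %.4g, ESS %.1f\n",
    nrow(x), attr(x, "generation"),
    utils::tail(attr(x, "tolerances"), 1), utils::tail(attr(x, "ess"), 1)
  ))
  invisible(x)
}

#' Weighted posterior interval per calibrated parameter
#'
#' @param particles a `particle_set`.
#' @param probs interval probabilities (default central 95%).
#' @return data.frame with one row per parameter: weighted median and bounds.
#' @export
particle_intervals <- function(particles, probs = c(0.025, 0.975)) {
  par_cols <- setdiff(names(particles), c("weight", "distance"))
  do.call(rbind, lapply(par_cols, function(nm) {
    q <- weighted_quantile(particles[[nm]], particles$weight,
                           probs = c(probs[1], 0.5, probs[2]))
    data.frame(parameter = nm, lower = q[1], median = q[2], upper = q[3])
  }))
}
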