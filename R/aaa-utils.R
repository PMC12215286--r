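# Internal helpers shared across modules.

# Canonical stratum order used everywhere: person-time tables, model output,
# fraction vectors. prison/community x on/off OAT.
STRATA <- c("community_on", "community_off", "prison_on", "prison_off")

DAYS_PER_YEAR <- 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("'%s' must be a single finite number", name))
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    stop_domain(sprintf("'%s' = %g is outside its valid range", name, x))
  }
  invisible(x)
}

as_day <- function(x, name = "date") {
  if (inherits(x, "Date")) return(as.integer(x))
  if (is.character(x)) {
    d <- as.Date(x, format = "%Y-%m-%d")
    if (anyNA(d)) stop_domain(sprintf("'%s' contains unparseable dates", name))
    return(as.integer(d))
  }
  if (is.numeric(x)) return(as.integer(x))
  stop_domain(sprintf("'%s' must be a Date, ISO-8601 string, or day number", name))
}

day_to_date <- function(x) as.Date(x, origin = "1970-01-01")

#' Weighted quantiles of a numeric vector
#'
#' Type-1 (left-continuous inverse CDF) weighted quantiles, the convention
#' used for all credible-interval summaries in this package.
#'
#' @param x numeric vector.
#' @param w non-negative weights, same length as `x`; need not sum to 1.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

# Derive reproducible child seeds from a master seed without disturbing the
# caller's RNG stream more than once.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# Weighted standard deviation (population form) used by the ABC kernel.
weighted_sd <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sqrt(max(sum(w * (x - m)^2), 0))
}
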