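#' Sample true stroke-onset ages at wake
#'
#' Draws the time from stroke onset to waking. The onset distribution is
#' defined on the *fraction of sleep remaining* at onset, so small fractions
#' mean onset close to wake time; the returned onset age at wake is
#' `sleep_minutes` times that fraction. The base case is uniform over the
#' whole sleep period; beta alternatives model onsets clustered toward (or
#' away from) wake time, e.g. Beta(3, 5) puts its mean at 3/8 of the sleep
#' period before waking.
#'
#' @param dist list with `family` ("uniform" or "beta") and, for beta,
#'   positive shapes `alpha`, `beta`.
#' @param sleep_minutes sleep duration in minutes (> 0).
#' @param n number of draws.
#' @return Numeric vector of onset ages at wake, in minutes, in
#'   \[0, sleep_minutes\].
#' @examples
#' set.seed(1)
#' mean(sample_onset_age(list(family = "uniform"), 480, 1e4)) # ~240
#' @export
sample_onset_age <- function(dist, sleep_minutes, n = 1) {
  stopifnot(sleep_minutes > 0, n >= 1)
  frac <- switch(dist$family,
    uniform = stats::runif(n),
    beta    = stats::rbeta(n, dist$alpha, dist$beta),
    stop("unknown onset distribution family: ", dist$family, call. = FALSE)
  )
  sleep_minutes * frac
}

# CDF of the fraction-of-sleep-remaining distribution
onset_fraction_cdf <- function(dist, q) {
  q <- pmin(pmax(q, 0), 1)
  switch(dist$family,
    uniform = q,
    beta    = stats::pbeta(q, dist$alpha, dist$beta),
    stop("unknown onset distribution family: ", dist$family, call. = FALSE)
  )
}

# fit a gamma by anchoring the mean at `mean` and root-finding the shape so
# that the ratio of the two central quantiles matches `upper/lower`
fit_gamma_mean_interval <- function(mean, lower, upper, probs = c(0.025, 0.975)) {
  stopifnot(mean > 0, lower > 0, upper > lower)
  target <- upper / lower
  f <- function(log_shape) {
    q <- stats::qgamma(probs, shape = exp(log_shape), rate = 1)
    q[2] / q[1] - target
  }
  root <- tryCatch(
    stats::uniroot(f, lower = log(0.05), upper = log(1e7), tol = 1e-10),
    error = function(e) stop("gamma fit failed (mean ", mean, ", interval ",
                             lower, "-", upper, "): ", conditionMessage(e),
                             call. = FALSE)
  )
  shape <- exp(root$root)
  if (shape <= 0) stop("non-positive fitted gamma shape", call. = FALSE)
  list(shape = shape, rate = shape / mean)
}

#' Sample the delay chain from waking to treatment start
#'
#' In fixed mode (the base case) every patient gets the expected-value
#' delays. In stochastic mode the wake-to-hospital and door-to-needle delays
#' are drawn from gamma distributions anchored at the base-case mean with
#' the shape chosen so the ratio of the 25th/75th percentiles matches the
#' reported interquartile range; the additional MRI time is gamma with mean
#' 30 and its 20-40 min range treated as a central 95% interval.
#'
#' @param timing a `timing` section of [default_parameters()].
#' @param n number of patients.
#' @return A tibble with columns `wake_to_hospital`, `door_to_needle`,
#'   `mri_time` (minutes).
#' @export
sample_delays <- function(timing, n = 1) {
  if (!isTRUE(timing$stochastic_delays)) {
    return(tibble::tibble(
      wake_to_hospital = rep(timing$wake_to_hospital_minutes, n),
      door_to_needle   = rep(timing$door_to_needle_minutes, n),
      mri_time         = rep(timing$mri_additional_minutes, n)
    ))
  }
  draw <- function(mean, lower, upper, probs) {
    if (mean == 0) return(rep(0, n))
    g <- fit_gamma_mean_interval(mean, lower, upper, probs)
    stats::rgamma(n, shape = g$shape, rate = g$rate)
  }
  tibble::tibble(
    wake_to_hospital = draw(timing$wake_to_hospital_minutes, 36, 72,
                            c(0.25, 0.75)),
    door_to_needle   = draw(timing$door_to_needle_minutes, 60, 98,
                            c(0.25, 0.75)),
    mri_time         = draw(timing$mri_additional_minutes, 20, 40,
                            c(0.025, 0.975))
  )
}

#' Onset age at treatment start
#'
#' Under the MRI-based strategy treatment starts after the full delay chain
#' (wake-to-hospital + door-to-needle + additional MRI time). Under no
#' treatment the value is bookkeeping only and runs to hospital arrival.
#'
#' @param onset_age_at_wake minutes from stroke onset to waking (>= 0).
#' @param delays tibble as returned by [sample_delays()].
#' @param strategy `"mri_based"` or `"no_treatment"`.
#' @return Numeric vector of minutes since stroke onset.
#' @export
onset_age_at_treatment <- function(onset_age_at_wake, delays,
                                   strategy = c("mri_based", "no_treatment")) {
  strategy <- match.arg(strategy)
  if (strategy == "mri_based")
    onset_age_at_wake + delays$wake_to_hospital + delays$door_to_needle +
      delays$mri_time
  else
    onset_age_at_wake + delays$wake_to_hospital
}

#' Closed-form probability that onset age at treatment is below a threshold
#'
#' Deterministic oracle for the simulated eligibility fraction: with a fixed
#' total delay D, P(onset age at wake + D < threshold) equals the CDF of the
#' fraction-of-sleep-remaining distribution at (threshold - D)/sleep,
#' clamped to \[0, 1\]. For the base case (uniform onset over 480 min, delay
#' 158 min, threshold 270 min) this is 112/480 = 0.2333.
#'
#' @param dist onset distribution (see [sample_onset_age()]).
#' @param sleep_minutes sleep duration (min).
#' @param total_delay fixed delay from wake to treatment start (min).
#' @param threshold eligibility threshold (min since onset).
#' @return A probability.
#' @export
prob_onset_age_below <- function(dist, sleep_minutes, total_delay, threshold) {
  stopifnot(threshold >= 0, sleep_minutes > 0, total_delay >= 0)
  onset_fraction_cdf(dist, (threshold - total_delay) / sleep_minutes)
}

#' Closed-form probabilities of treatment-start time falling in OR bands
#'
#' Returns the probability of the onset age at treatment landing in each
#' band `(previous edge, edge]` plus the open tail beyond the last edge;
#' the vector sums to one.
#'
#' @inheritParams prob_onset_age_below
#' @param edges strictly increasing band upper edges (min since onset).
#' @return Numeric vector of length `length(edges) + 1`.
#' @export
band_probabilities <- function(dist, sleep_minutes, total_delay, edges) {
  stopifnot(!is.unsorted(edges, strictly = TRUE))
  cdf <- vapply(edges, function(e)
    prob_onset_age_below(dist, sleep_minutes, total_delay, e), numeric(1))
  diff(c(0, cdf, 1))
}
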