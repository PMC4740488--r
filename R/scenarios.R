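#' Named scenario presets
#'
#' The scenario library used throughout the analyses: uniform onset with 8,
#' 6 and 4 hours of sleep, and the beta onset alternatives over an 8-hour
#' sleep. Beta shapes are on the fraction-of-sleep-remaining axis, so
#' Beta(3,5) is skewed toward wake time. The `beta26` and `beta17` presets
#' are additional illustrative skewed-toward-wake shapes (provenance
#' `"illustrative"`), not reference scenarios.
#'
#' @return A tibble with columns `name`, `sleep_minutes`, `onset_family`,
#'   `alpha`, `beta`, `delay_mode`, `provenance`, `description`.
#' @export
scenario_library <- function() {
  tibble::tribble(
    ~name,      ~sleep_minutes, ~onset_family, ~alpha, ~beta, ~delay_mode, ~provenance,    ~description,
    "base8h",   480,            "uniform",     NA,     NA,    "fixed",     "reference",    "8 h sleep, uniform onset (base case)",
    "sleep6h",  360,            "uniform",     NA,     NA,    "fixed",     "reference",    "6 h sleep, uniform onset",
    "sleep4h",  240,            "uniform",     NA,     NA,    "fixed",     "reference",    "4 h sleep, uniform onset",
    "beta44",   480,            "beta",        4,      4,     "fixed",     "reference",    "8 h sleep, symmetric Beta(4,4) onset",
    "beta35",   480,            "beta",        3,      5,     "fixed",     "reference",    "8 h sleep, Beta(3,5) onset skewed toward wake",
    "beta26",   480,            "beta",        2,      6,     "fixed",     "illustrative", "8 h sleep, Beta(2,6) onset strongly skewed toward wake",
    "beta17",   480,            "beta",        1,      7,     "fixed",     "illustrative", "8 h sleep, Beta(1,7) onset very strongly skewed toward wake"
  )
}

#' Parameters for a named scenario
#'
#' Applies a scenario preset's sleep duration, onset distribution and delay
#' mode on top of a base parameter set.
#'
#' @param name a scenario name from [scenario_library()].
#' @param params base parameters to override (defaults to
#'   [default_parameters()]).
#' @return A validated `wus_parameters` object.
#' @examples
#' scenario_parameters("sleep6h")$timing$sleep_minutes # 360
#' @export
scenario_parameters <- function(name, params = default_parameters()) {
  lib <- scenario_library()
  row <- lib[lib$name == name, ]
  if (nrow(row) != 1)
    stop("unknown scenario: ", name, " (known: ",
         paste(lib$name, collapse = ", "), ")", call. = FALSE)
  params$timing$sleep_minutes <- row$sleep_minutes
  params$onset$family <- row$onset_family
  if (row$onset_family == "beta") {
    params$onset$alpha <- row$alpha
    params$onset$beta <- row$beta
  }
  params$timing$stochastic_delays <- !identical(row$delay_mode, "fixed")
  validate_parameters(params)
}

#' Synthetic placeholder mRS outcome distribution
#'
#' Builds a 7-category mRS distribution whose untreated favorable
#' (mRS 0-1) mass equals `p_favorable_untreated` exactly. The favorable
#' mass is split 60:40 between mRS 0 and mRS 1 and the remaining mass is
#' spread over mRS 2..6 with fixed declining weights 5:4:3:2:1. This is a
#' declared synthetic stand-in for trial-arm outcome vectors that are not
#' packaged; only its favorable aggregate is calibrated. The treated arm
#' equals the untreated arm (the treatment effect enters through the
#' time-banded odds ratios, which use the treated arm only for the
#' conditional splits within the favorable and unfavorable blocks).
#'
#' @param p_favorable_untreated untreated P(mRS 0-1), strictly in (0, 1);
#'   default 0.451.
#' @return A `wus_mrs_distribution` with provenance `"synthetic"`.
#' @export
placeholder_mrs_distribution <- function(p_favorable_untreated = 0.451) {
  stopifnot(p_favorable_untreated > 0, p_favorable_untreated < 1)
  p <- p_favorable_untreated
  fav <- p * c(0.6, 0.4)
  unfav <- (1 - p) * c(5, 4, 3, 2, 1) / 15
  v <- c(fav, unfav)
  as_mrs_distribution(
    tibble::tibble(mrs = 0:6, untreated = v, treated = v),
    provenance = "synthetic"
  )
}

#' Provenance of a packaged fixture
#'
#' @param x an object carrying a `provenance` attribute (life tables, mRS
#'   distributions).
#' @return The provenance label (`"synthetic"`, `"user"`, ...), or
#'   `NA_character_` if none is recorded.
#' @export
provenance <- function(x) {
  p <- attr(x, "provenance")
  if (is.null(p)) NA_character_ else p
}
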