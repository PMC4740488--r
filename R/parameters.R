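#' Base-case model parameters
#'
#' Returns the complete parameter set for the wake-up stroke
#' cost-effectiveness model at its base-case values: an average 65-year-old,
#' 60% male cohort sleeping 8 hours, a fixed delay chain of 51 min
#' (wake to hospital) + 77 min (door to needle) + 30 min (additional MRI),
#' a DWI-FLAIR mismatch test with sensitivity 0.62 and specificity 0.78
#' against true onset age < 270 min at treatment start, time-banded tPA
#' odds ratios 1.75 / 1.26 / 1.00 (0-180 / 181-270 / 271-360 min), and the
#' lifetime Markov inputs (mRS-specific hazard ratios, recurrence, costs in
#' 2013 USD, utilities, 3% annual discounting).
#'
#' The modified Rankin Scale (mRS) outcome distribution attached by default
#' is a synthetic placeholder constrained to an untreated favorable
#' (mRS 0-1) probability of 0.451; see [placeholder_mrs_distribution()].
#' The default life table is likewise synthetic (Gompertz-Makeham); see
#' [synthesize_life_table()].
#'
#' @return An object of class `wus_parameters`: a named list with components
#'   `timing`, `onset`, `diagnostic`, `treatment_effect`, `progression`,
#'   `costs`, `utilities`, `demographics`, `population_impact`, `mrs_dist`,
#'   `life_table` and `simulation`.
#' @examples
#' p <- default_parameters()
#' p$treatment_effect$odds_ratios[1] # 1.75
#' @export
default_parameters <- function() {
  p <- list(
    timing = list(
      sleep_minutes            = 480,
      wake_to_hospital_minutes = 51,
      door_to_needle_minutes   = 77,
      mri_additional_minutes   = 30,
      stochastic_delays        = FALSE,
      delay_distribution_family = "fixed"
    ),
    onset = list(family = "uniform", alpha = 1, beta = 1),
    diagnostic = list(
      sensitivity = 0.62,
      specificity = 0.78,
      eligibility_threshold_minutes = 270
    ),
    treatment_effect = list(
      band_edges_minutes  = c(180, 270, 360),
      odds_ratios         = c(1.75, 1.26, 1.00),
      beyond_last_band_or = 1.00
    ),
    progression = list(
      nonstroke_death_hr_by_mrs    = c(1, 1, 1.11, 1.27, 1.71, 2.37),
      annual_recurrent_stroke_prob = 0.051,
      recurrent_stroke_case_fatality = 0.190
    ),
    costs = list(
      mri                      = 488,
      acute_hosp_no_treatment  = 11462,
      acute_hosp_with_treatment = 18182,
      annual_mrs0_3            = 5293,
      annual_mrs4_5            = 13557,
      recurrent_stroke_hosp    = 20079
    ),
    utilities = list(by_mrs = c(0.8, 0.8, 0.65, 0.5, 0.35, 0.2)),
    demographics = list(
      start_age            = 65,
      male_fraction        = 0.60,
      annual_discount_rate = 0.03,
      willingness_to_pay   = 100000,
      max_age              = 110
    ),
    population_impact = list(
      wakeup_share_of_ischemic_strokes = 0.20,
      sich_rate_among_treated          = 0.055
    ),
    mrs_dist = placeholder_mrs_distribution(),
    # life table as a recipe so the configuration file stays small and the
    # round trip is lossless; resolved by resolve_life_table()
    life_table = list(
      source = "makeham", a = 2e-4, b = 3e-5, c = 1.1,
      male_multiplier = 1, female_multiplier = 1
    ),
    simulation = list(n = 100000, seed = 1, cycle_accrual = "full")
  )
  structure(p, class = "wus_parameters")
}

#' @export
print.wus_parameters <- function(x, ...) {
  cat("<wus_parameters>\n")
  cat("  sleep:", x$timing$sleep_minutes, "min; onset:", x$onset$family)
  if (x$onset$family == "beta")
    cat(sprintf("(%g,%g)", x$onset$alpha, x$onset$beta))
  cat("\n  delays (wake->hospital, door->needle, MRI):",
      x$timing$wake_to_hospital_minutes, "+",
      x$timing$door_to_needle_minutes, "+",
      x$timing$mri_additional_minutes, "min",
      if (x$timing$stochastic_delays) "(stochastic)" else "(fixed)", "\n")
  cat("  test: Se", x$diagnostic$sensitivity, "/ Sp", x$diagnostic$specificity,
      "at", x$diagnostic$eligibility_threshold_minutes, "min\n")
  cat("  tPA odds ratios:",
      paste(x$treatment_effect$odds_ratios, collapse = " / "),
      "by band <=", paste(x$treatment_effect$band_edges_minutes, collapse = "/"),
      "min\n")
  cat("  cohort: age", x$demographics$start_age, ",",
      100 * x$demographics$male_fraction, "% male, discount",
      100 * x$demographics$annual_discount_rate, "%/yr\n")
  invisible(x)
}

# -- validation ---------------------------------------------------------------

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) < 1 || anyNA(x) || any(x < 0) || any(x > 1))
    stop_invalid(field, "must be a probability in [0, 1]")
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop_invalid(field, "must be >= 0")
}

#' Validate a parameter set
#'
#' Checks every typed bound (probabilities in \[0,1\], non-negative durations
#' and costs, positive beta shapes, increasing odds-ratio band edges,
#' mRS distributions summing to one). Violations raise an error naming the
#' offending field; values are never silently clamped.
#'
#' @param params a `wus_parameters` object.
#' @return `params`, invisibly classed, if valid.
#' @export
validate_parameters <- function(params) {
  t <- params$timing
  check_nonneg(t$wake_to_hospital_minutes, "timing.wake_to_hospital_minutes")
  check_nonneg(t$door_to_needle_minutes, "timing.door_to_needle_minutes")
  check_nonneg(t$mri_additional_minutes, "timing.mri_additional_minutes")
  if (!is.numeric(t$sleep_minutes) || t$sleep_minutes <= 0)
    stop_invalid("timing.sleep_minutes", "must be > 0")
  if (!t$delay_distribution_family %in% c("fixed", "gamma"))
    stop_invalid("timing.delay_distribution_family", "must be 'fixed' or 'gamma'")

  o <- params$onset
  if (!o$family %in% c("uniform", "beta"))
    stop_invalid("onset.family", "must be 'uniform' or 'beta'")
  if (o$family == "beta" && (!is.numeric(o$alpha) || !is.numeric(o$beta) ||
                             o$alpha <= 0 || o$beta <= 0))
    stop_invalid("onset.alpha/beta", "beta shapes must be > 0")

  d <- params$diagnostic
  check_prob(d$sensitivity, "diagnostic.sensitivity")
  check_prob(d$specificity, "diagnostic.specificity")
  check_nonneg(d$eligibility_threshold_minutes,
               "diagnostic.eligibility_threshold_minutes")

  te <- params$treatment_effect
  if (is.unsorted(te$band_edges_minutes, strictly = TRUE))
    stop_invalid("treatment_effect.band_edges_minutes", "must be strictly increasing")
  if (length(te$odds_ratios) != length(te$band_edges_minutes))
    stop_invalid("treatment_effect.odds_ratios",
                 "must have one odds ratio per band edge")
  if (any(te$odds_ratios <= 0) || te$beyond_last_band_or <= 0)
    stop_invalid("treatment_effect.odds_ratios", "odds ratios must be > 0")

  pr <- params$progression
  if (length(pr$nonstroke_death_hr_by_mrs) != 6 ||
      any(pr$nonstroke_death_hr_by_mrs <= 0))
    stop_invalid("progression.nonstroke_death_hr_by_mrs",
                 "must be 6 positive hazard ratios (mRS 0..5)")
  check_prob(pr$annual_recurrent_stroke_prob,
             "progression.annual_recurrent_stroke_prob")
  check_prob(pr$recurrent_stroke_case_fatality,
             "progression.recurrent_stroke_case_fatality")

  for (nm in names(params$costs))
    check_nonneg(params$costs[[nm]], paste0("costs.", nm))

  u <- params$utilities$by_mrs
  if (length(u) != 6) stop_invalid("utilities.by_mrs", "must have 6 entries (mRS 0..5)")
  check_prob(u, "utilities.by_mrs")

  dm <- params$demographics
  check_prob(dm$male_fraction, "demographics.male_fraction")
  check_nonneg(dm$annual_discount_rate, "demographics.annual_discount_rate")
  check_nonneg(dm$willingness_to_pay, "demographics.willingness_to_pay")
  if (dm$max_age <= dm$start_age)
    stop_invalid("demographics.max_age", "must exceed start_age")

  pi_ <- params$population_impact
  check_prob(pi_$wakeup_share_of_ischemic_strokes,
             "population_impact.wakeup_share_of_ischemic_strokes")
  check_prob(pi_$sich_rate_among_treated, "population_impact.sich_rate_among_treated")

  validate_mrs_distribution(params$mrs_dist)

  s <- params$simulation
  if (!is.numeric(s$n) || s$n < 1) stop_invalid("simulation.n", "must be >= 1")
  if (!s$cycle_accrual %in% c("full", "none"))
    stop_invalid("simulation.cycle_accrual", "must be 'full' or 'none'")

  invisible(structure(params, class = "wus_parameters"))
}

# -- serialization ------------------------------------------------------------

# nested-list merge that rejects keys absent from the reference structure
merge_checked <- function(base, override, path = character()) {
  for (nm in names(override)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base))
      stop(sprintf("unknown configuration key `%s`", here), call. = FALSE)
    if (is.list(base[[nm]]) && !is.data.frame(base[[nm]])) {
      if (!is.list(override[[nm]]))
        stop(sprintf("configuration key `%s` must be a section", here), call. = FALSE)
      base[[nm]] <- merge_checked(base[[nm]], override[[nm]], c(path, nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load model parameters from a YAML configuration file
#'
#' Missing keys fall back to the base-case defaults of
#' [default_parameters()]; unknown keys are rejected with an error naming the
#' key; the merged parameter set is fully validated. The mRS outcome
#' distribution may be given inline (section `mrs_dist` with `mrs`,
#' `untreated`, `treated` columns) or left at the packaged default.
#'
#' @param path path to a YAML file, or a YAML string.
#' @return A validated `wus_parameters` object.
#' @seealso [save_parameters()]
#' @export
load_parameters <- function(path) {
  raw <- tryCatch(
    if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path),
    error = function(e) stop("malformed configuration: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(raw)) raw <- list()
  defaults <- default_parameters()
  if (!is.null(raw$mrs_dist)) {
    raw$mrs_dist <- as_mrs_distribution(
      tibble::as_tibble(lapply(raw$mrs_dist, unlist)),
      provenance = "user"
    )
    defaults$mrs_dist <- raw$mrs_dist
    raw$mrs_dist <- NULL
  }
  merged <- merge_checked(unclass(defaults), raw)
  validate_parameters(structure(merged, class = "wus_parameters"))
}

#' Save model parameters to a YAML configuration file
#'
#' Writes every section of the parameter set, including the mRS outcome
#' distribution, at full floating precision so that
#' `load_parameters(save_parameters(p, f))` reproduces `p` exactly.
#'
#' @param params a `wus_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  x <- unclass(validate_parameters(params))
  x$mrs_dist <- list(
    mrs = x$mrs_dist$mrs,
    untreated = x$mrs_dist$untreated,
    treated = x$mrs_dist$treated
  )
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

# resolve a parameter path like "costs.mri" or "utilities.by_mrs.3"
# (numeric trailing components index into vectors)
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- params
  for (p in parts) {
    x <- if (grepl("^[0-9]+$", p)) x[[as.integer(p)]] else x[[p]]
    if (is.null(x)) stop("unknown parameter path: ", path, call. = FALSE)
  }
  x
}

param_set <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, parts) {
    p <- parts[1]
    key <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    if ((is.character(key) && !key %in% names(x)) ||
        (is.integer(key) && key > length(x)))
      stop("unknown parameter path component: ", p, call. = FALSE)
    if (length(parts) == 1L) x[[key]] <- value
    else x[[key]] <- rec(x[[key]], parts[-1])
    x
  }
  rec(params, parts)
}
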