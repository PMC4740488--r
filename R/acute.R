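#' mRS outcome distributions
#'
#' A `wus_mrs_distribution` is a 7-row tibble (`mrs` 0..6, `untreated`,
#' `treated`) giving the probability of each modified Rankin Scale category
#' at the end of the acute phase for the two arms; each column sums to one.
#' The `provenance` attribute records whether the vector comes from data
#' supplied by the user or from the packaged synthetic placeholder.
#'
#' @param x a data frame with columns `mrs` (0..6), `untreated`, `treated`.
#' @param provenance provenance label stored on the object.
#' @return A validated `wus_mrs_distribution` tibble.
#' @export
as_mrs_distribution <- function(x, provenance = "user") {
  x <- tibble::as_tibble(x)[c("mrs", "untreated", "treated")]
  x$mrs <- as.integer(x$mrs)
  out <- structure(x, class = c("wus_mrs_distribution", class(x)),
                   provenance = provenance)
  validate_mrs_distribution(out)
  out
}

validate_mrs_distribution <- function(x) {
  if (!all(c("mrs", "untreated", "treated") %in% names(x)))
    stop_invalid("mrs_dist", "needs columns mrs, untreated, treated")
  if (!identical(as.integer(x$mrs), 0:6))
    stop_invalid("mrs_dist.mrs", "must be exactly 0..6")
  for (arm in c("untreated", "treated")) {
    p <- x[[arm]]
    check_prob(p, paste0("mrs_dist.", arm))
    if (abs(sum(p) - 1) > 1e-12)
      stop_invalid(paste0("mrs_dist.", arm), "must sum to 1 (within 1e-12)")
  }
  invisible(x)
}

#' Read an mRS outcome distribution from a tabular text file
#'
#' Expects a whitespace- or comma-separated file with a header row and
#' columns `mrs`, `untreated`, `treated` (probabilities). Both arms must sum
#' to one within 1e-12.
#'
#' @param path file path.
#' @return A `wus_mrs_distribution`.
#' @export
read_mrs_distribution <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "",
                         comment.char = "#", strip.white = TRUE)
  if (ncol(x) == 1) # comma-separated fallback
    x <- utils::read.csv(path, comment.char = "#")
  as_mrs_distribution(x, provenance = "user")
}

#' Classify DWI-FLAIR mismatch test results
#'
#' Applies the imperfect diagnostic rule: truly eligible patients (onset age
#' at treatment below the threshold) test positive with probability equal to
#' the sensitivity; ineligible patients test positive with probability
#' 1 - specificity.
#'
#' @param truly_eligible logical vector.
#' @param perf list with `sensitivity` and `specificity`.
#' @param u optional uniform(0,1) draws of the same length (for common
#'   random numbers); drawn internally if omitted.
#' @return Logical vector of test-positive flags.
#' @export
classify_mismatch <- function(truly_eligible, perf, u = NULL) {
  if (is.null(u)) u <- stats::runif(length(truly_eligible))
  ifelse(truly_eligible, u < perf$sensitivity, u < 1 - perf$specificity)
}

#' Time-banded treatment odds ratio
#'
#' Looks up the tPA odds ratio for a favorable outcome (mRS 0-1) in the band
#' containing the onset age at treatment: by default 1.75 for 0-180 min,
#' 1.26 for 181-270, 1.00 for 271-360, and the boundary value 1.00 extended
#' indefinitely beyond the last band.
#'
#' @param onset_age minutes since stroke onset at treatment start (vector).
#' @param schedule a `treatment_effect` section of [default_parameters()].
#' @return Numeric vector of odds ratios.
#' @export
or_for_onset_time <- function(onset_age, schedule) {
  stopifnot(all(onset_age >= 0))
  band <- findInterval(onset_age, schedule$band_edges_minutes,
                       left.open = TRUE) + 1L
  c(schedule$odds_ratios, schedule$beyond_last_band_or)[band]
}

#' Odds-ratio adjustment of a favorable-outcome probability
#'
#' Converts the untreated favorable probability to odds, multiplies by the
#' treatment odds ratio, and converts back:
#' p' = OR * o / (1 + OR * o) with o = p / (1 - p).
#'
#' @param p untreated favorable probability, strictly inside (0, 1).
#' @param or_value odds ratio (> 0), vectorized.
#' @return Adjusted probability vector.
#' @examples
#' adjusted_favorable_probability(0.451, 1.75) # 0.5898
#' @export
adjusted_favorable_probability <- function(p, or_value) {
  if (any(p <= 0) || any(p >= 1))
    stop("degenerate favorable probability: p must lie strictly in (0, 1)",
         call. = FALSE)
  if (any(or_value <= 0)) stop("odds ratio must be > 0", call. = FALSE)
  o <- or_value * p / (1 - p)
  o / (1 + o)
}

# per-arm mRS category probabilities for each patient; treated patients get
# the favorable mass replaced by the OR-adjusted value, redistributed within
# {0,1} and {2..6} by the treated arm's internal conditional splits
mrs_category_probs <- function(treated, or_value, dist) {
  p0 <- sum(dist$untreated[dist$mrs <= 1])
  tr <- dist$treated
  fav_split <- tr[1:2] / sum(tr[1:2])
  unfav_split <- tr[3:7] / sum(tr[3:7])
  n <- length(treated)
  probs <- matrix(rep(dist$untreated, each = n), nrow = n)
  if (any(treated)) {
    pfav <- adjusted_favorable_probability(p0, or_value[treated])
    probs[treated, ] <- cbind(outer(pfav, fav_split),
                              outer(1 - pfav, unfav_split))
  }
  probs
}

#' Assign acute-phase mRS scores
#'
#' Untreated patients draw from the untreated-arm outcome distribution.
#' Treated patients have their favorable (mRS 0-1) mass set to the
#' OR-adjusted untreated favorable probability for their time band; within
#' the favorable and unfavorable blocks the treated arm's internal splits
#' apply.
#'
#' @param treated logical vector.
#' @param onset_age onset age at treatment start (min), same length.
#' @param dist a `wus_mrs_distribution`.
#' @param schedule a `treatment_effect` section.
#' @param u optional uniform(0,1) draws (common random numbers).
#' @return Integer vector of mRS scores 0..6.
#' @export
assign_acute_mrs <- function(treated, onset_age, dist, schedule, u = NULL) {
  n <- length(treated)
  if (is.null(u)) u <- stats::runif(n)
  or_value <- or_for_onset_time(onset_age, schedule)
  probs <- mrs_category_probs(treated, or_value, dist)
  cum <- probs %*% (upper.tri(diag(7), diag = TRUE) * 1) # row-wise cumsum
  as.integer(rowSums(u > cum[, 1:6, drop = FALSE]))
}

#' Acute-phase hospitalization cost
#'
#' No-treatment strategy: untreated hospitalization cost only. MRI-based
#' strategy: every patient incurs the MRI cost; treated patients incur the
#' (higher) with-treatment hospitalization cost.
#'
#' @param strategy `"mri_based"` or `"no_treatment"`.
#' @param treated logical vector (all `FALSE` under no treatment).
#' @param costs a `costs` section of [default_parameters()].
#' @return Numeric vector of 2013 USD costs.
#' @export
acute_phase_cost <- function(strategy = c("mri_based", "no_treatment"),
                             treated, costs) {
  strategy <- match.arg(strategy)
  hosp <- ifelse(treated, costs$acute_hosp_with_treatment,
                 costs$acute_hosp_no_treatment)
  if (strategy == "mri_based") hosp + costs$mri else hosp
}

#' Population-level increase in symptomatic intracranial hemorrhage
#'
#' Side calculation outside the patient-level model: the absolute increase
#' in sICH among all ischemic strokes is the product of the wake-up share of
#' ischemic strokes, the fraction of wake-up strokes treated under the
#' MRI-based strategy, and the sICH rate among tPA-treated patients,
#' expressed in percentage points.
#'
#' @param impact a `population_impact` section of [default_parameters()].
#' @param treated_fraction_of_wakeup proportion of wake-up strokes treated.
#' @return Percentage points.
#' @examples
#' population_sich_increase(
#'   list(wakeup_share_of_ischemic_strokes = 0.2,
#'        sich_rate_among_treated = 0.055), 0.31) # 0.341
#' @export
population_sich_increase <- function(impact, treated_fraction_of_wakeup) {
  stopifnot(treated_fraction_of_wakeup >= 0, treated_fraction_of_wakeup <= 1)
  100 * impact$wakeup_share_of_ischemic_strokes *
    treated_fraction_of_wakeup * impact$sich_rate_among_treated
}
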