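# derive a reproducible sub-stream seed (< 2^31) from a master seed and a
# stream name, so each model stage draws from its own named stream
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.numeric(seed) * 48271 + h * 7919) %% 2147483647
}

#' Simulate a shared patient cohort (onset, delays, latent uniforms)
#'
#' Draws everything that is common to both strategies: the onset age at
#' wake, the delay chain, and the latent uniform variates later consumed by
#' the diagnostic test and the acute mRS assignment. Sharing this table
#' between strategies implements common random numbers, so strategy deltas
#' are not inflated by independent sampling noise.
#'
#' @param params a `wus_parameters` object.
#' @param n number of patients.
#' @return A tibble with one row per patient: `onset_age_at_wake`,
#'   `wake_to_hospital`, `door_to_needle`, `mri_time`, `u_test`, `u_mrs`.
#' @export
simulate_cohort <- function(params, n) {
  delays <- sample_delays(params$timing, n)
  tibble::tibble(
    onset_age_at_wake = sample_onset_age(params$onset,
                                         params$timing$sleep_minutes, n),
    wake_to_hospital = delays$wake_to_hospital,
    door_to_needle = delays$door_to_needle,
    mri_time = delays$mri_time,
    u_test = stats::runif(n),
    u_mrs = stats::runif(n)
  )
}

# acute-phase outcomes for one strategy on a shared cohort table
apply_strategy <- function(cohort, strategy, params) {
  thr <- params$diagnostic$eligibility_threshold_minutes
  t_treat <- onset_age_at_treatment(cohort$onset_age_at_wake, cohort,
                                    strategy = "mri_based")
  truly_eligible <- t_treat < thr
  if (strategy == "mri_based") {
    test_positive <- classify_mismatch(truly_eligible, params$diagnostic,
                                       u = cohort$u_test)
    treated <- test_positive
  } else {
    test_positive <- rep(FALSE, nrow(cohort))
    treated <- test_positive
    t_treat <- onset_age_at_treatment(cohort$onset_age_at_wake, cohort,
                                      strategy = "no_treatment")
  }
  acute_mrs <- assign_acute_mrs(
    treated,
    onset_age_at_treatment(cohort$onset_age_at_wake, cohort, "mri_based"),
    params$mrs_dist, params$treatment_effect, u = cohort$u_mrs
  )
  cost <- acute_phase_cost(strategy, treated, params$costs)
  dplyr::mutate(cohort,
    strategy = strategy,
    onset_age_at_treatment = t_treat,
    truly_eligible = truly_eligible,
    test_positive = test_positive,
    treated = treated,
    acute_mrs = acute_mrs,
    acute_cost = cost
  )
}

summarize_strategy <- function(patients, lifetime = NULL) {
  eligible_at_mri <- patients$truly_eligible
  out <- tibble::tibble(
    strategy = patients$strategy[1],
    n_patients = nrow(patients),
    pct_mrs01 = 100 * mean(patients$acute_mrs <= 1),
    pct_onset_lt_270 = 100 * mean(eligible_at_mri),
    pct_onset_ge_270 = 100 * mean(!eligible_at_mri),
    pct_treated = 100 * mean(patients$treated),
    pct_inappropriately_treated =
      100 * mean(patients$treated & !eligible_at_mri),
    life_years = NA_real_, qalys = NA_real_, cost = NA_real_
  )
  if (!is.null(lifetime)) {
    out$life_years <- mean(lifetime$life_years)
    out$qalys <- mean(lifetime$qalys)
    out$cost <- mean(lifetime$cost + patients$acute_cost)
  }
  class(out) <- c("wus_strategy_result", class(out))
  out
}

#' Run one treatment strategy end to end
#'
#' Simulates `n` patients through onset timing, the MRI decision rule (for
#' the MRI-based strategy), acute mRS assignment, acute costing and the
#' lifetime Markov model, and aggregates them into a one-row strategy
#' summary. Deterministic given `seed`. The eligibility percentages
#' (`pct_onset_lt_270` / `_ge_270`) are always evaluated at the MRI-based
#' treatment-start time, matching how "onset < 4.5 h" is tabulated for
#' both strategies.
#'
#' @param strategy `"mri_based"` or `"no_treatment"`.
#' @param params a `wus_parameters` object.
#' @param n number of simulated patients.
#' @param seed integer master seed.
#' @param lifetime if `FALSE`, skip the lifetime Markov model (acute
#'   percentages only; life years, QALYs and cost are `NA`).
#' @param keep_patients if `TRUE`, attach the per-patient tibble as the
#'   `"patients"` attribute.
#' @return A one-row `wus_strategy_result` tibble.
#' @examples
#' run_strategy("no_treatment", default_parameters(), n = 1000, seed = 1,
#'              lifetime = FALSE)
#' @export
run_strategy <- function(strategy = c("mri_based", "no_treatment"), params,
                         n = params$simulation$n,
                         seed = params$simulation$seed,
                         lifetime = TRUE, keep_patients = FALSE) {
  strategy <- match.arg(strategy)
  set.seed(substream_seed(seed, "cohort"))
  cohort <- simulate_cohort(params, n)
  patients <- apply_strategy(cohort, strategy, params)
  lt <- NULL
  if (lifetime) {
    # the lifetime stream is keyed by the master seed only, so both strategy
    # arms of a common-random-numbers comparison share it
    set.seed(substream_seed(seed, "lifetime"))
    lt <- simulate_lifetimes(patients$acute_mrs, params)
  }
  out <- summarize_strategy(patients, lt)
  if (keep_patients) attr(out, "patients") <- patients
  out
}

#' Compare two strategies: deltas, ICER and optimal strategy
#'
#' Computes alternative-minus-reference differences in QALYs and cost, the
#' incremental cost-effectiveness ratio when both deltas are positive, and
#' dominance markers otherwise (`"dominant"`: more QALYs for less cost;
#' `"dominated"`: fewer QALYs for more cost; `"unstable"`: QALY delta below
#' the numerical floor). The optimal strategy at the willingness-to-pay
#' threshold is the one with the higher net monetary benefit.
#'
#' @param reference,alternative one-row `wus_strategy_result` tibbles from
#'   runs with identical `n` and parameters.
#' @param wtp willingness to pay per QALY.
#' @param qaly_floor smallest |delta QALY| treated as a stable denominator.
#' @return A `wus_cea` object (list with `strategies`, `delta_qalys`,
#'   `delta_cost`, `icer`, `icer_label`, `optimal_at_wtp`, `wtp`).
#' @examples
#' # arithmetic on externally reported per-strategy aggregates
#' ref <- tibble::tibble(strategy = "no_treatment", n_patients = 1e5,
#'                       qalys = 5.312, cost = 88247)
#' alt <- tibble::tibble(strategy = "mri_based", n_patients = 1e5,
#'                       qalys = 5.355, cost = 91082)
#' compare(ref, alt)$icer # ~65,930 $/QALY
#' @export
compare <- function(reference, alternative, wtp = 100000,
                    qaly_floor = 1e-9) {
  if (!is.null(reference$n_patients) && !is.null(alternative$n_patients) &&
      reference$n_patients != alternative$n_patients)
    stop("strategies were run with different n", call. = FALSE)
  dq <- alternative$qalys - reference$qalys
  dc <- alternative$cost - reference$cost
  if (is.na(dq) || is.na(dc)) { # acute-only runs carry no lifetime values
    out <- list(strategies = dplyr::bind_rows(tibble::as_tibble(reference),
                                              tibble::as_tibble(alternative)),
                delta_qalys = NA_real_, delta_cost = NA_real_,
                icer = NA_real_, icer_label = "no_lifetime",
                optimal_at_wtp = NA_character_, wtp = wtp)
    class(out) <- "wus_cea"
    return(out)
  }
  if (abs(dq) < qaly_floor) {
    icer <- NA_real_; label <- "unstable"
  } else if (dq > 0 && dc > 0) {
    icer <- dc / dq; label <- "icer"
  } else if (dq > 0 && dc <= 0) {
    icer <- NA_real_; label <- "dominant"
  } else if (dq < 0 && dc >= 0) {
    icer <- NA_real_; label <- "dominated"
  } else { # fewer QALYs, lower cost: ICER in the south-west quadrant
    icer <- dc / dq; label <- "icer_sw"
  }
  nmb_ref <- net_monetary_benefit(reference, wtp)
  nmb_alt <- net_monetary_benefit(alternative, wtp)
  out <- list(
    strategies = dplyr::bind_rows(tibble::as_tibble(reference),
                                  tibble::as_tibble(alternative)),
    delta_qalys = dq, delta_cost = dc,
    icer = icer, icer_label = label,
    optimal_at_wtp = if (nmb_alt > nmb_ref) alternative$strategy
                     else reference$strategy,
    wtp = wtp
  )
  class(out) <- "wus_cea"
  out
}

#' Net monetary benefit
#'
#' NMB = wtp x QALYs - cost; the strategy with the higher NMB at a
#' willingness-to-pay threshold is the one an ICER-vs-threshold rule
#' selects.
#'
#' @param result a strategy result (anything with `qalys` and `cost`).
#' @param wtp willingness to pay per QALY (>= 0).
#' @return Currency value (vectorized over rows of `result`).
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$qalys - result$cost
}

#' Run and compare both strategies on a common cohort
#'
#' Runs the no-treatment and MRI-based strategies and compares them. With
#' `crn = TRUE` (default) both strategies share the same onset, delay and
#' latent-uniform draws (common random numbers), which leaves each
#' strategy's marginal distribution unchanged but sharply reduces the
#' variance of the estimated differences; `crn = FALSE` reproduces fully
#' independent arms.
#'
#' @inheritParams run_strategy
#' @param crn share random draws across strategies.
#' @param wtp willingness to pay per QALY for the optimal-strategy call.
#' @return A `wus_cea` object.
#' @export
compare_strategies <- function(params, n = params$simulation$n,
                               seed = params$simulation$seed,
                               crn = TRUE, wtp = params$demographics$willingness_to_pay,
                               lifetime = TRUE) {
  seeds <- if (crn) c(seed, seed) else c(seed, substream_seed(seed, "arm2"))
  ref <- run_strategy("no_treatment", params, n, seeds[1], lifetime = lifetime)
  alt <- run_strategy("mri_based", params, n, seeds[2], lifetime = lifetime)
  compare(ref, alt, wtp = wtp)
}

#' @export
print.wus_cea <- function(x, ...) {
  cat("<wus_cea>  (alternative vs reference)\n")
  print(x$strategies)
  cat(sprintf("\n  delta QALYs: %.4f   delta cost: %.0f\n",
              x$delta_qalys, x$delta_cost))
  if (x$icer_label == "icer")
    cat(sprintf("  ICER: %.0f $/QALY\n", x$icer))
  else cat("  ICER:", x$icer_label, "\n")
  cat(sprintf("  optimal at $%s/QALY: %s\n",
              format(x$wtp, big.mark = ","), x$optimal_at_wtp))
  invisible(x)
}

#' Tidy per-strategy results of a comparison
#'
#' @param x a `wus_cea` object.
#' @param ... unused.
#' @return The per-strategy tibble (one row per strategy).
#' @export
tidy.wus_cea <- function(x, ...) x$strategies

#' One-row summary of a strategy comparison
#'
#' @param x a `wus_cea` object.
#' @param ... unused.
#' @return A one-row tibble with deltas, ICER (NA under dominance), the
#'   dominance label and the NMB-optimal strategy.
#' @export
glance.wus_cea <- function(x, ...) {
  tibble::tibble(delta_qalys = x$delta_qalys, delta_cost = x$delta_cost,
                 icer = x$icer, icer_label = x$icer_label,
                 optimal_at_wtp = x$optimal_at_wtp, wtp = x$wtp)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
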