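#' Synthesize a Gompertz-Makeham life table
#'
#' Builds a synthetic annual life table for use when no empirical table is
#' supplied: the annual all-cause death probability at age x is
#' 1 - exp(-(a + b c^x)) (times an optional per-sex hazard multiplier),
#' capped at 1, with the final-age probability forced to 1 so every cohort
#' terminates. This is a labelled synthetic stand-in, not any national
#' life table.
#'
#' @param a Makeham age-independent hazard component (per year).
#' @param b Gompertz baseline hazard (per year).
#' @param c Gompertz growth factor per year of age.
#' @param max_age last age in the table.
#' @param male_multiplier,female_multiplier hazard multipliers per sex.
#' @return A `wus_life_table` tibble with columns `age`, `qx_male`,
#'   `qx_female` and a `"synthetic"` provenance attribute.
#' @export
synthesize_life_table <- function(a = 2e-4, b = 3e-5, c = 1.1, max_age = 110,
                                  male_multiplier = 1, female_multiplier = 1) {
  stopifnot(a >= 0, b >= 0, c > 0, max_age > 0)
  age <- 0:max_age
  hazard <- a + b * c^age
  qx <- function(mult) {
    p <- pmin(1 - exp(-hazard * mult), 1)
    p[length(p)] <- 1
    p
  }
  out <- tibble::tibble(age = age, qx_male = qx(male_multiplier),
                        qx_female = qx(female_multiplier))
  structure(out, class = c("wus_life_table", class(out)),
            provenance = "synthetic")
}

#' Read a life table from a tabular text file
#'
#' Whitespace- or comma-separated text with header columns `age`, `qx_male`,
#' `qx_female`; ages must be contiguous 1-year steps and probabilities in
#' \[0, 1\].
#'
#' @param path file path.
#' @return A `wus_life_table` tibble (provenance `"user"`).
#' @export
read_life_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "",
                         comment.char = "#", strip.white = TRUE)
  if (ncol(x) == 1) x <- utils::read.csv(path, comment.char = "#")
  validate_life_table(x)
  out <- tibble::as_tibble(x[c("age", "qx_male", "qx_female")])
  structure(out, class = c("wus_life_table", class(out)), provenance = "user")
}

validate_life_table <- function(x) {
  if (!all(c("age", "qx_male", "qx_female") %in% names(x)))
    stop("life table needs columns age, qx_male, qx_female", call. = FALSE)
  if (any(diff(x$age) != 1))
    stop("life table ages must be contiguous 1-year steps", call. = FALSE)
  check_prob(x$qx_male, "life_table.qx_male")
  check_prob(x$qx_female, "life_table.qx_female")
  invisible(x)
}

# materialize the life table referenced by a parameter set
resolve_life_table <- function(params) {
  lt <- params$life_table
  if (inherits(lt, "wus_life_table")) return(lt)
  if (is.data.frame(lt)) {
    validate_life_table(lt)
    return(structure(tibble::as_tibble(lt),
                     class = c("wus_life_table", "tbl_df", "tbl", "data.frame"),
                     provenance = "user"))
  }
  switch(lt$source,
    makeham = synthesize_life_table(
      a = lt$a, b = lt$b, c = lt$c, max_age = params$demographics$max_age,
      male_multiplier = lt$male_multiplier,
      female_multiplier = lt$female_multiplier),
    file = read_life_table(lt$path),
    stop("unknown life_table source: ", lt$source, call. = FALSE)
  )
}

#' Annual non-stroke death probability with an mRS hazard ratio
#'
#' Blends the male and female life-table probabilities by the cohort male
#' fraction, then applies the disability-state hazard ratio on the hazard
#' scale: q' = 1 - (1 - q)^hr. The hazard-scale application keeps the result
#' a probability even for large hazard ratios at high ages. Ages beyond the
#' table return probability 1.
#'
#' @param age age in years (vector).
#' @param demographics a `demographics` section (uses `male_fraction`).
#' @param table a `wus_life_table`.
#' @param hr hazard ratio (vector, recycled against `age`).
#' @return Death probability vector.
#' @examples
#' # hazard-scale closed form: q = 0.10, hr = 2.37 -> 0.2211
#' 1 - (1 - 0.10)^2.37
#' @export
annual_nonstroke_death_prob <- function(age, demographics, table, hr = 1) {
  idx <- match(age, table$age)
  q <- demographics$male_fraction * table$qx_male[idx] +
    (1 - demographics$male_fraction) * table$qx_female[idx]
  q[is.na(idx)] <- 1
  1 - (1 - q)^hr
}

#' Destination state after a non-fatal recurrent stroke
#'
#' Survivors of a recurrent stroke move to a strictly worse living mRS state
#' with equal probability over all higher non-death states; from mRS 5 there
#' is no worse living state, so the patient remains in mRS 5.
#'
#' @param current_mrs integer vector of current states (0..5).
#' @param u optional uniform(0,1) draws.
#' @return Integer vector of destination states.
#' @export
recurrent_stroke_destination <- function(current_mrs, u = NULL) {
  stopifnot(all(current_mrs >= 0), all(current_mrs <= 5))
  if (is.null(u)) u <- stats::runif(length(current_mrs))
  n_up <- 5L - as.integer(current_mrs)
  dest <- as.integer(current_mrs) + 1L + as.integer(floor(u * n_up))
  dest[n_up == 0L] <- 5L
  pmin(dest, 5L)
}

annual_state_cost <- function(mrs, costs) {
  ifelse(mrs <= 3, costs$annual_mrs0_3, costs$annual_mrs4_5)
}

# Vectorized one-cycle update for a cohort of living patients.
# Event order within a cycle: (1) recurrent stroke (fatal cases die at cycle
# end, survivors move to a worse state, recurrence hospitalization cost
# added); (2) otherwise background non-stroke death at the state's hazard
# ratio. Utilities and annual costs accrue on the state occupied at cycle
# start; under `cycle_accrual = "full"` patients dying this cycle still
# accrue that cycle's utility and cost, under `"none"` they accrue nothing.
cycle_update <- function(mrs, age, params, table,
                         u_recur, u_fatal, u_dest, u_death) {
  pr <- params$progression
  recur <- u_recur < pr$annual_recurrent_stroke_prob
  fatal <- recur & (u_fatal < pr$recurrent_stroke_case_fatality)
  hr <- pr$nonstroke_death_hr_by_mrs[mrs + 1L]
  q <- annual_nonstroke_death_prob(rep(age, length(mrs)),
                                   params$demographics, table, hr)
  dies_ns <- !recur & (u_death < q)
  next_mrs <- mrs
  move <- recur & !fatal
  if (any(move))
    next_mrs[move] <- recurrent_stroke_destination(mrs[move], u_dest[move])
  next_mrs[fatal | dies_ns] <- 6L
  dies <- fatal | dies_ns
  alive_weight <- if (params$simulation$cycle_accrual == "full") 1 else !dies
  list(
    next_mrs = next_mrs,
    utility  = alive_weight * params$utilities$by_mrs[mrs + 1L],
    cost     = alive_weight * (annual_state_cost(mrs, params$costs) +
                                 recur * params$costs$recurrent_stroke_hosp),
    ly       = alive_weight * 1
  )
}

#' Advance one annual Markov cycle for a single patient
#'
#' One yearly cycle of the post-stroke model: recurrent stroke (annual
#' probability 0.051, case fatality 0.190, hospitalization cost 20,079),
#' otherwise non-stroke death from the blended life table at the state's
#' hazard ratio; survivors and (by default) patients dying this cycle accrue
#' the state's utility and annual cost. Deaths take effect at cycle end.
#'
#' @param state list with `mrs` (0..5) and `age` (years).
#' @param params a `wus_parameters` object.
#' @param u optional named list of uniforms (`recur`, `fatal`, `dest`,
#'   `death`) to force events deterministically.
#' @return A list with `state` (next `mrs`/`age`), `utility` and `cost`
#'   accrued this cycle (undiscounted).
#' @export
step_one_cycle <- function(state, params, u = NULL) {
  if (state$mrs >= 6L)
    stop("step_one_cycle() called on a dead state", call. = FALSE)
  if (is.null(u)) u <- list(recur = stats::runif(1), fatal = stats::runif(1),
                            dest = stats::runif(1), death = stats::runif(1))
  table <- resolve_life_table(params)
  res <- cycle_update(state$mrs, state$age, params, table,
                      u$recur, u$fatal, u$dest, u$death)
  list(state = list(mrs = res$next_mrs, age = state$age + 1),
       utility = res$utility, cost = res$cost)
}

#' Simulate discounted lifetimes for a cohort of acute survivors
#'
#' Monte-Carlo engine: iterates annual cycles from the cohort start age to
#' death or the maximum age, discounting cycle t at (1 + r)^-t. Acute-phase
#' costs are *not* included (they are added undiscounted at t = 0 by the
#' strategy runner). Patients entering dead (mRS 6) get zeros.
#'
#' @param initial_mrs integer vector of acute-phase mRS scores (0..6).
#' @param params a `wus_parameters` object.
#' @return A tibble with per-patient `life_years`, `qalys`, `cost`
#'   (all discounted).
#' @export
simulate_lifetimes <- function(initial_mrs, params) {
  n <- length(initial_mrs)
  table <- resolve_life_table(params)
  r <- params$demographics$annual_discount_rate
  ly <- qa <- co <- numeric(n)
  mrs <- as.integer(initial_mrs)
  alive <- which(mrs < 6L)
  horizon <- params$demographics$max_age - params$demographics$start_age
  for (t in seq_len(horizon)) {
    if (length(alive) == 0L) break
    age <- params$demographics$start_age + t - 1
    # uniforms drawn for the full cohort each cycle, so that two strategy
    # arms sharing a seed keep per-patient draws aligned (common random
    # numbers) even when survival differs between arms
    u1 <- stats::runif(n); u2 <- stats::runif(n)
    u3 <- stats::runif(n); u4 <- stats::runif(n)
    res <- cycle_update(mrs[alive], age, params, table,
                        u1[alive], u2[alive], u3[alive], u4[alive])
    df <- (1 + r)^(-t)
    ly[alive] <- ly[alive] + df * res$ly
    qa[alive] <- qa[alive] + df * res$utility
    co[alive] <- co[alive] + df * res$cost
    mrs[alive] <- res$next_mrs
    alive <- alive[res$next_mrs < 6L]
  }
  tibble::tibble(life_years = ly, qalys = qa, cost = co)
}

#' Simulate one patient's discounted lifetime
#'
#' Scalar convenience wrapper around [simulate_lifetimes()].
#'
#' @inheritParams simulate_lifetimes
#' @return A list with `life_years`, `qalys`, `cost`.
#' @export
simulate_lifetime <- function(initial_mrs, params) {
  as.list(simulate_lifetimes(initial_mrs, params))
}

#' Deterministic cohort-expectation lifetime engine
#'
#' Evaluates the same annual-cycle model as [simulate_lifetimes()] by
#' transition-matrix products instead of Monte Carlo: tracks the expected
#' occupancy of each living mRS state, accrues expected utility, cost and
#' life years on start-of-cycle occupancy (matching the full-accrual
#' convention), and discounts cycle t at (1 + r)^-t. Serves as the
#' independent oracle for the Monte-Carlo engine.
#'
#' @param initial_probs probability vector over mRS 0..6 at model entry.
#' @param params a `wus_parameters` object.
#' @return A list with expected discounted `life_years`, `qalys`, `cost`.
#' @export
cohort_expectation <- function(initial_probs, params) {
  stopifnot(length(initial_probs) == 7, abs(sum(initial_probs) - 1) < 1e-9)
  table <- resolve_life_table(params)
  pr <- params$progression
  r <- params$demographics$annual_discount_rate
  occ <- initial_probs[1:6] # living states mRS 0..5
  p_rec <- pr$annual_recurrent_stroke_prob
  cf <- pr$recurrent_stroke_case_fatality
  utility <- params$utilities$by_mrs
  cost_state <- annual_state_cost(0:5, params$costs) +
    p_rec * params$costs$recurrent_stroke_hosp
  ly <- qa <- co <- 0
  horizon <- params$demographics$max_age - params$demographics$start_age
  for (t in seq_len(horizon)) {
    if (sum(occ) < 1e-15) break
    age <- params$demographics$start_age + t - 1
    df <- (1 + r)^(-t)
    ly <- ly + df * sum(occ)
    qa <- qa + df * sum(occ * utility)
    co <- co + df * sum(occ * cost_state)
    q <- annual_nonstroke_death_prob(rep(age, 6), params$demographics, table,
                                     pr$nonstroke_death_hr_by_mrs)
    # transition matrix over living states
    M <- matrix(0, 6, 6)
    for (i in 0:5) {
      stay <- (1 - p_rec) * (1 - q[i + 1])
      if (i < 5) {
        up <- p_rec * (1 - cf) / (5 - i)
        M[i + 1, (i + 2):6] <- up
      } else {
        stay <- stay + p_rec * (1 - cf) # mRS5 survivors of recurrence stay
      }
      M[i + 1, i + 1] <- M[i + 1, i + 1] + stay
    }
    occ <- as.numeric(occ %*% M)
  }
  list(life_years = ly, qalys = qa, cost = co)
}
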