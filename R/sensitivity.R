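#' Default probabilistic-sensitivity-analysis specification
#'
#' One row per uncertain parameter: the parameter path inside the parameter
#' list, the distribution family, the base value and the reported range,
#' and how the range is interpreted (central 95% interval, or interquartile
#' range for the two timing variables reported as IQRs). Probabilities get
#' beta distributions, positive quantities gamma, ratios lognormal, and the
#' untreated mRS outcome vector a Dirichlet with effective sample size
#' `dirichlet_ess`.
#'
#' @param params a `wus_parameters` object (supplies base values).
#' @param dirichlet_ess Dirichlet concentration = base probabilities times
#'   this effective sample size.
#' @return A `wus_psa_spec` tibble with columns `path`, `family`, `base`,
#'   `low`, `high`, `interpretation`.
#' @export
psa_default_spec <- function(params = default_parameters(),
                             dirichlet_ess = 100) {
  spec <- tibble::tribble(
    ~path,                                      ~family,     ~low,  ~high, ~interpretation,
    "timing.wake_to_hospital_minutes",          "gamma",     36,    72,    "iqr",
    "timing.door_to_needle_minutes",            "gamma",     60,    98,    "iqr",
    "timing.mri_additional_minutes",            "gamma",     20,    40,    "ci95",
    "diagnostic.sensitivity",                   "beta",      0.57,  0.67,  "ci95",
    "diagnostic.specificity",                   "beta",      0.72,  0.84,  "ci95",
    "treatment_effect.odds_ratios.1",           "lognormal", 1.35,  2.27,  "ci95",
    "treatment_effect.odds_ratios.2",           "lognormal", 1.05,  1.51,  "ci95",
    "treatment_effect.odds_ratios.3",           "lognormal", 0.95,  1.40,  "ci95",
    "progression.nonstroke_death_hr_by_mrs.3",  "lognormal", 1.0,   1.3,   "ci95",
    "progression.nonstroke_death_hr_by_mrs.4",  "lognormal", 1.2,   1.4,   "ci95",
    "progression.nonstroke_death_hr_by_mrs.5",  "lognormal", 1.3,   2.0,   "ci95",
    "progression.nonstroke_death_hr_by_mrs.6",  "lognormal", 1.5,   4.0,   "ci95",
    "progression.annual_recurrent_stroke_prob", "beta",      0.02,  0.065, "ci95",
    "progression.recurrent_stroke_case_fatality", "beta",    0.10,  0.30,  "ci95",
    "costs.mri",                                "gamma",     390,   586,   "ci95",
    "costs.acute_hosp_no_treatment",            "gamma",     10421, 12503, "ci95",
    "costs.acute_hosp_with_treatment",          "gamma",     16798, 19565, "ci95",
    "costs.annual_mrs0_3",                      "gamma",     4234,  6351,  "ci95",
    "costs.annual_mrs4_5",                      "gamma",     10846, 16268, "ci95",
    "costs.recurrent_stroke_hosp",              "gamma",     16063, 24095, "ci95",
    "utilities.by_mrs.1",                       "beta",      0.80,  1.00,  "ci95",
    "utilities.by_mrs.2",                       "beta",      0.80,  0.95,  "ci95",
    "utilities.by_mrs.3",                       "beta",      0.68,  0.90,  "ci95",
    "utilities.by_mrs.4",                       "beta",      0.45,  0.65,  "ci95",
    "utilities.by_mrs.5",                       "beta",      0.10,  0.40,  "ci95",
    "utilities.by_mrs.6",                       "beta",      0.00,  0.32,  "ci95",
    "mrs_dist.untreated",                       "dirichlet", NA,    NA,    "ess"
  )
  spec$base <- lapply(spec$path, function(p)
    if (p == "mrs_dist.untreated") params$mrs_dist$untreated
    else param_get(params, p))
  spec$ess <- ifelse(spec$family == "dirichlet", dirichlet_ess, NA)
  structure(spec[c("path", "family", "base", "low", "high",
                   "interpretation", "ess")],
            class = c("wus_psa_spec", class(spec)))
}

# draws from a Dirichlet(alpha) via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Fit a sampling distribution for one uncertain parameter
#'
#' Beta and gamma families are anchored at the base value as the mean, with
#' the dispersion chosen by 1-D root finding so the stated range matches
#' the central interval implied by `interpretation` (95% interval, or IQR):
#' gamma matches the interval's quantile ratio; beta matches its width. If
#' a mean-anchored beta fit is infeasible (base value on or outside the
#' range, as happens for some utility rows), the fit falls back to pure
#' two-quantile matching and flags it. Lognormal is fitted by quantile
#' matching: the log-scale midpoint of the interval is the log-median.
#' `fixed` returns a degenerate sampler at the base value; `dirichlet`
#' draws a probability vector with concentration base x ess.
#'
#' @param entry one row of a [psa_default_spec()] tibble (as a list or
#'   one-row tibble).
#' @return A list with `sampler` (function of `n`), `quantile` (where
#'   defined), `family`, `pars` and `anchored_mean` (FALSE when the
#'   quantile-only fallback was used).
#' @export
fit_psa_distribution <- function(entry) {
  entry <- as.list(entry)
  if (is.list(entry$base) && length(entry$base) == 1)
    entry$base <- entry$base[[1]]
  base <- entry$base
  fam <- entry$family
  probs <- if (identical(entry$interpretation, "iqr")) c(0.25, 0.75)
           else c(0.025, 0.975)
  infeasible <- function(msg)
    stop("PSA fit infeasible for `", entry$path, "`: ", msg, call. = FALSE)

  if (fam == "fixed") {
    return(list(sampler = function(n) rep(base, n), quantile = function(p) rep(base, length(p)),
                family = fam, pars = list(value = base), anchored_mean = TRUE))
  }
  if (fam == "dirichlet") {
    alpha <- base * entry$ess
    return(list(sampler = function(n) t(replicate(n, rdirichlet1(alpha))),
                quantile = NULL, family = fam, pars = list(alpha = alpha),
                anchored_mean = TRUE))
  }
  if (is.na(entry$low) || is.na(entry$high) || entry$low >= entry$high)
    infeasible("range low must be < high")
  low <- entry$low; high <- entry$high

  if (fam == "gamma") {
    g <- fit_gamma_mean_interval(base, low, high, probs)
    return(list(sampler = function(n) stats::rgamma(n, g$shape, g$rate),
                quantile = function(p) stats::qgamma(p, g$shape, g$rate),
                family = fam, pars = g, anchored_mean = TRUE))
  }
  if (fam == "lognormal") {
    z <- stats::qnorm(probs[2])
    sdlog <- (log(high) - log(low)) / (2 * z)
    meanlog <- (log(low) + log(high)) / 2
    return(list(sampler = function(n) stats::rlnorm(n, meanlog, sdlog),
                quantile = function(p) stats::qlnorm(p, meanlog, sdlog),
                family = fam, pars = list(meanlog = meanlog, sdlog = sdlog),
                anchored_mean = FALSE))
  }
  if (fam == "beta") {
    width <- high - low
    make <- function(a, b) list(
      sampler = function(n) stats::rbeta(n, a, b),
      quantile = function(p) stats::qbeta(p, a, b),
      family = "beta", pars = list(shape1 = a, shape2 = b))
    if (base > low && base < high) {
      f <- function(log_nu) {
        nu <- exp(log_nu)
        # probe points at tiny nu can trigger harmless qbeta accuracy
        # warnings; the root lies well inside the accurate region
        q <- suppressWarnings(stats::qbeta(probs, base * nu, (1 - base) * nu))
        (q[2] - q[1]) - width
      }
      root <- tryCatch(
        stats::uniroot(f, lower = log(1e-2), upper = log(1e7), tol = 1e-10),
        error = function(e) NULL)
      if (!is.null(root)) {
        nu <- exp(root$root)
        return(c(make(base * nu, (1 - base) * nu), anchored_mean = TRUE))
      }
    }
    # fallback: match the two quantiles directly, ignoring the mean anchor
    lo <- max(low, 1e-6); hi <- min(high, 1 - 1e-6)
    obj <- function(par) {
      q <- stats::qbeta(probs, exp(par[1]), exp(par[2]))
      (q[1] - lo)^2 + (q[2] - hi)^2
    }
    m0 <- (lo + hi) / 2
    opt <- stats::optim(c(log(5 * m0 + 0.1), log(5 * (1 - m0) + 0.1)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    return(c(make(exp(opt$par[1]), exp(opt$par[2])), anchored_mean = FALSE))
  }
  infeasible(paste("unknown family", fam))
}

draw_psa_parameters <- function(params, spec, fits) {
  for (i in seq_len(nrow(spec))) {
    path <- spec$path[i]
    value <- fits[[i]]$sampler(1)
    if (spec$family[i] == "dirichlet") {
      v <- as.numeric(value)
      params$mrs_dist$untreated <- v
      params$mrs_dist$treated <- v
    } else {
      params <- param_set(params, path, as.numeric(value))
    }
  }
  params
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full two-strategy comparison with each parameter set to its
#' low and high endpoint in turn (all others at base, same seed and common
#' random numbers throughout), records the ICER at each endpoint, and sorts
#' by descending ICER spread. Dominance cases carry `NA` ICERs with their
#' labels; their spread is `NA` and they sort after finite spreads.
#'
#' @param params base `wus_parameters`.
#' @param spec tibble with columns `path`, `low`, `high` (e.g. a subset of
#'   [psa_default_spec()]).
#' @param n patients per strategy run.
#' @param seed master seed (shared by every evaluation).
#' @param wtp willingness to pay.
#' @return A `wus_tornado` tibble: `path`, `low`, `high`, `icer_low`,
#'   `icer_high`, `label_low`, `label_high`, `spread`, plus the base-case
#'   ICER as attribute `"icer_base"`.
#' @export
one_way_analysis <- function(params, spec, n = 2000,
                             seed = params$simulation$seed,
                             wtp = params$demographics$willingness_to_pay) {
  eval_icer <- function(p) {
    cea <- compare_strategies(p, n = n, seed = seed, crn = TRUE, wtp = wtp)
    list(icer = cea$icer, label = cea$icer_label)
  }
  base_icer <- eval_icer(params)
  rows <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    at <- function(v) eval_icer(param_set(params, spec$path[i], v))
    lo <- at(spec$low[i]); hi <- at(spec$high[i])
    tibble::tibble(path = spec$path[i], low = spec$low[i], high = spec$high[i],
                   icer_low = lo$icer, icer_high = hi$icer,
                   label_low = lo$label, label_high = hi$label,
                   spread = abs(hi$icer - lo$icer))
  })
  rows <- dplyr::arrange(rows, dplyr::desc(!is.na(spread)), dplyr::desc(spread))
  structure(rows, class = c("wus_tornado", class(rows)),
            icer_base = base_icer$icer)
}

#' Two-way sensitivity analysis over MRI sensitivity and specificity
#'
#' Labels the NMB-optimal strategy at the willingness-to-pay threshold for
#' every (sensitivity, specificity) grid cell, and estimates the
#' specificity frontier (the specificity at which the optimal strategy
#' flips) at the base-case sensitivity by linear interpolation of the NMB
#' difference along the grid.
#'
#' @param params base `wus_parameters`.
#' @param se_grid,sp_grid probability grids.
#' @param wtp willingness to pay.
#' @param n patients per cell (per strategy).
#' @param seed master seed (common random numbers across cells).
#' @return A `wus_twoway` tibble (`sensitivity`, `specificity`,
#'   `nmb_difference`, `optimal`) with attribute `"sp_frontier_at_base_se"`.
#' @export
two_way_sensitivity_specificity <- function(params, se_grid, sp_grid,
                                            wtp = params$demographics$willingness_to_pay,
                                            n = 2000,
                                            seed = params$simulation$seed) {
  stopifnot(all(se_grid >= 0 & se_grid <= 1), all(sp_grid >= 0 & sp_grid <= 1))
  grid <- expand.grid(sensitivity = se_grid, specificity = sp_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    p <- params
    p$diagnostic$sensitivity <- grid$sensitivity[i]
    p$diagnostic$specificity <- grid$specificity[i]
    cea <- compare_strategies(p, n = n, seed = seed, crn = TRUE, wtp = wtp)
    nmb <- net_monetary_benefit(cea$strategies, wtp)
    tibble::tibble(sensitivity = grid$sensitivity[i],
                   specificity = grid$specificity[i],
                   nmb_difference = nmb[2] - nmb[1],
                   optimal = cea$optimal_at_wtp)
  })
  base_se <- params$diagnostic$sensitivity
  frontier <- NA_real_
  row_se <- se_grid[which.min(abs(se_grid - base_se))]
  slice <- res[res$sensitivity == row_se, ]
  slice <- slice[order(slice$specificity), ]
  sgn <- sign(slice$nmb_difference)
  flip <- which(diff(sgn) != 0)
  if (length(flip) > 0) {
    i <- flip[1]
    x0 <- slice$specificity[i]; x1 <- slice$specificity[i + 1]
    y0 <- slice$nmb_difference[i]; y1 <- slice$nmb_difference[i + 1]
    frontier <- x0 - y0 * (x1 - x0) / (y1 - y0)
  }
  structure(res, class = c("wus_twoway", class(res)),
            sp_frontier_at_base_se = frontier)
}

#' Threshold analysis on a single parameter
#'
#' Bisection on the sign of NMB(MRI-based) - NMB(no treatment), evaluated
#' with common random numbers and a fixed seed so each evaluation is
#' deterministic, until the bracket is narrower than `tol` in the
#' parameter's own units. If the NMB difference has the same sign at both
#' bounds, returns a no-threshold result rather than an error.
#'
#' @param params base `wus_parameters`.
#' @param path parameter path (see [psa_default_spec()]).
#' @param bounds length-2 numeric search interval.
#' @param wtp willingness to pay.
#' @param n patients per evaluation (per strategy).
#' @param seed master seed.
#' @param tol bracket width at which bisection stops.
#' @return A list: `found`, `value` (NA if no sign change), `bounds`,
#'   `nmb_low`, `nmb_high`, `n_evaluations`.
#' @export
threshold_search <- function(params, path, bounds,
                             wtp = params$demographics$willingness_to_pay,
                             n = 2000, seed = params$simulation$seed,
                             tol = 0.5) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  evals <- 0
  g <- function(x) {
    evals <<- evals + 1
    cea <- compare_strategies(param_set(params, path, x), n = n, seed = seed,
                              crn = TRUE, wtp = wtp)
    nmb <- net_monetary_benefit(cea$strategies, wtp)
    nmb[2] - nmb[1]
  }
  lo <- bounds[1]; hi <- bounds[2]
  glo <- g(lo); ghi <- g(hi)
  if (sign(glo) == sign(ghi))
    return(list(found = FALSE, value = NA_real_, bounds = bounds,
                nmb_low = glo, nmb_high = ghi, n_evaluations = evals))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0) { lo <- hi <- mid; break }
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else { hi <- mid }
  }
  list(found = TRUE, value = (lo + hi) / 2, bounds = bounds,
       nmb_low = glo, nmb_high = ghi, n_evaluations = evals)
}

#' Probabilistic sensitivity analysis with CEAC
#'
#' Draws every uncertain parameter jointly from its fitted distribution,
#' re-runs both strategies per draw (common random numbers within a draw,
#' an independent patient stream per draw), and records the QALY and cost
#' differences. The cost-effectiveness acceptability curve gives, at each
#' willingness-to-pay value, the fraction of draws in which each strategy
#' has the higher net monetary benefit; the two curves sum to one
#' everywhere.
#'
#' @param params base `wus_parameters`.
#' @param spec a `wus_psa_spec` (default [psa_default_spec()]).
#' @param draws number of joint parameter draws.
#' @param n_per_draw patients per strategy within each draw.
#' @param seed master seed.
#' @param wtp_grid willingness-to-pay grid for the CEAC.
#' @return A `wus_psa` object: list with `draws` (tibble of per-draw
#'   `delta_qalys`, `delta_cost`) and `ceac` (tibble of `wtp`, `strategy`,
#'   `probability`).
#' @export
run_psa <- function(params, spec = psa_default_spec(params), draws = 10000,
                    n_per_draw = 10000, seed = params$simulation$seed,
                    wtp_grid = seq(0, 200000, by = 10000)) {
  fits <- lapply(seq_len(nrow(spec)), function(i) fit_psa_distribution(spec[i, ]))
  # one patient stream shared by all draws: only the parameters vary across
  # draws, so an all-fixed spec yields identical rows
  run_seed <- substream_seed(seed, "psa_run")
  out <- purrr::map_dfr(seq_len(draws), function(d) {
    set.seed(substream_seed(seed, paste0("psa_param_", d)))
    p <- draw_psa_parameters(params, spec, fits)
    cea <- compare_strategies(p, n = n_per_draw, seed = run_seed, crn = TRUE)
    tibble::tibble(draw = d, delta_qalys = cea$delta_qalys,
                   delta_cost = cea$delta_cost)
  })
  ceac <- purrr::map_dfr(wtp_grid, function(w) {
    p_mri <- mean(w * out$delta_qalys - out$delta_cost > 0)
    tibble::tibble(wtp = w,
                   strategy = c("mri_based", "no_treatment"),
                   probability = c(p_mri, 1 - p_mri))
  })
  structure(list(draws = out, ceac = ceac, wtp_grid = wtp_grid),
            class = "wus_psa")
}

#' @export
print.wus_psa <- function(x, ...) {
  cat("<wus_psa> ", nrow(x$draws), "draws\n")
  cat("  mean delta QALYs:", signif(mean(x$draws$delta_qalys), 4),
      "  mean delta cost:", signif(mean(x$draws$delta_cost), 6), "\n")
  invisible(x)
}
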