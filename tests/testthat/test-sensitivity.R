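spec_row <- function(spec, path) spec[spec$path == path, ]

test_that("PSA samplers recover their target moments and intervals", {
  spec <- psa_default_spec()
  set.seed(111)
  # beta for MRI sensitivity: mean anchored, 95% interval ~ (0.57, 0.67)
  fit_se <- fit_psa_distribution(spec_row(spec, "diagnostic.sensitivity"))
  x <- fit_se$sampler(1e5)
  expect_equal(mean(x), 0.62, tolerance = 0.01)
  expect_equal(unname(quantile(x, c(0.025, 0.975))), c(0.57, 0.67),
               tolerance = 0.01 / 0.6)
  expect_true(fit_se$anchored_mean)
  # gamma for MRI cost: mean anchored
  fit_mri <- fit_psa_distribution(spec_row(spec, "costs.mri"))
  expect_equal(mean(fit_mri$sampler(1e5)), 488, tolerance = 0.01)
  # lognormal for the early OR: log-scale midpoint of the interval
  fit_or <- fit_psa_distribution(spec_row(spec, "treatment_effect.odds_ratios.1"))
  expect_equal(unname(fit_or$quantile(0.5)), sqrt(1.35 * 2.27),
               tolerance = 1e-9)
  expect_equal(log(sqrt(1.35 * 2.27)), log(1.75), tolerance = 0.001)
  expect_equal(unname(fit_or$quantile(c(0.025, 0.975))), c(1.35, 2.27),
               tolerance = 1e-9)
})

test_that("degenerate, Dirichlet and infeasible fits behave as declared", {
  fit_fix <- fit_psa_distribution(list(path = "costs.mri", family = "fixed",
                                       base = 488))
  expect_equal(fit_fix$sampler(5), rep(488, 5))
  spec <- psa_default_spec()
  fit_dir <- fit_psa_distribution(spec_row(spec, "mrs_dist.untreated"))
  set.seed(112)
  draws <- fit_dir$sampler(200)
  expect_equal(rowSums(draws), rep(1, 200), tolerance = 1e-12)
  expect_equal(colMeans(draws),
               default_parameters()$mrs_dist$untreated, tolerance = 0.05)
  expect_error(
    fit_psa_distribution(list(path = "x", family = "gamma", base = 10,
                              low = 20, high = 15, interpretation = "ci95")),
    "infeasible")
})

test_that("utility rows with off-range base values fall back to quantile matching", {
  spec <- psa_default_spec()
  fit <- fit_psa_distribution(spec_row(spec, "utilities.by_mrs.3")) # base 0.65, range 0.68-0.9
  expect_false(fit$anchored_mean)
  expect_equal(unname(fit$quantile(c(0.025, 0.975))), c(0.68, 0.90),
               tolerance = 0.01)
})

test_that("one-way analysis sorts by spread and is exact at the base point", {
  p <- default_parameters()
  spec <- tibble::tibble(
    path = c("costs.mri", "diagnostic.specificity", "costs.mri"),
    low = c(390, 0.72, 488), high = c(586, 0.84, 488)
  )
  res <- one_way_analysis(p, spec, n = 1500, seed = 4)
  sp <- res$spread[!is.na(res$spread)]
  expect_true(all(diff(sp) <= 1e-9))
  # both endpoints at the base value reproduce the base-case ICER exactly
  base_row <- res[res$low == 488 & res$high == 488, ]
  expect_equal(base_row$icer_low, attr(res, "icer_base"), tolerance = 1e-12)
  expect_equal(base_row$icer_high, attr(res, "icer_base"), tolerance = 1e-12)
  # MRI cost enters only the cost numerator: ICER increases with it
  mri_row <- res[res$path == "costs.mri" & res$high > res$low, ]
  expect_gt(mri_row$icer_high, mri_row$icer_low)
})

test_that("two-way accuracy map has a monotone specificity frontier", {
  p <- default_parameters()
  # degenerate 1x1 grid at the base point: base-case optimum
  cell <- two_way_sensitivity_specificity(p, 0.62, 0.78, n = 1500, seed = 4)
  base <- compare_strategies(p, n = 1500, seed = 4)
  expect_equal(cell$optimal, base$optimal_at_wtp)
  # useless test with an MRI bill: never treat
  worthless <- two_way_sensitivity_specificity(p, 0, 1, n = 1500, seed = 4)
  expect_equal(worthless$optimal, "no_treatment")
  # for fixed Se, optimality of the MRI strategy is monotone in Sp
  map <- two_way_sensitivity_specificity(p, 0.62, seq(0.3, 1, by = 0.1),
                                         n = 1500, seed = 4)
  mri_opt <- map$optimal[order(map$specificity)] == "mri_based"
  expect_true(all(diff(mri_opt) >= 0))
})

test_that("threshold search brackets the NMB sign flip or reports none", {
  p <- default_parameters()
  res <- threshold_search(p, "costs.mri", c(0, 40000), n = 1500, seed = 4,
                          tol = 10)
  expect_true(res$found)
  # the returned value brackets the flip within tolerance
  g <- function(x) {
    cea <- compare_strategies(wakeupcea:::param_set(p, "costs.mri", x),
                              n = 1500, seed = 4, crn = TRUE)
    diff(net_monetary_benefit(cea$strategies, 1e5))
  }
  expect_lte(g(res$value + 20), 0)
  expect_gte(g(res$value - 20), 0)
  none <- threshold_search(p, "costs.mri", c(0, 100), n = 1500, seed = 4)
  expect_false(none$found)
  expect_true(is.na(none$value))
})

test_that("PSA respects fixed specs and CEAC curves are complementary", {
  p <- default_parameters()
  spec <- psa_default_spec(p)
  spec$family <- "fixed"
  psa_fixed <- run_psa(p, spec, draws = 6, n_per_draw = 400, seed = 2,
                       wtp_grid = c(0, 5e4, 1e5))
  expect_equal(length(unique(round(psa_fixed$draws$delta_qalys, 12))), 1)
  psa <- run_psa(p, psa_default_spec(p), draws = 30, n_per_draw = 400,
                 seed = 2, wtp_grid = seq(0, 2e5, 5e4))
  sums <- tapply(psa$ceac$probability, psa$ceac$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(psa$ceac$probability >= 0 & psa$ceac$probability <= 1))
})
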