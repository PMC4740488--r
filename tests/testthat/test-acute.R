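test_that("mismatch classification reproduces sensitivity and specificity", {
  perf <- list(sensitivity = 1, specificity = 1)
  expect_true(all(classify_mismatch(rep(TRUE, 100), perf)))
  expect_false(any(classify_mismatch(rep(FALSE, 100), perf)))
  set.seed(51)
  base <- default_parameters()$diagnostic
  pos_elig <- mean(classify_mismatch(rep(TRUE, 1e5), base))
  pos_inel <- mean(classify_mismatch(rep(FALSE, 1e5), base))
  expect_equal(pos_elig, 0.62, tolerance = 0.005 / 0.62)
  expect_equal(pos_inel, 0.22, tolerance = 0.005 / 0.22)
})

test_that("odds ratios follow the time bands with the boundary extension", {
  sched <- default_parameters()$treatment_effect
  expect_equal(or_for_onset_time(c(0, 100, 180), sched), c(1.75, 1.75, 1.75))
  expect_equal(or_for_onset_time(c(181, 200, 270), sched), c(1.26, 1.26, 1.26))
  expect_equal(or_for_onset_time(c(271, 360), sched), c(1, 1))
  expect_equal(or_for_onset_time(c(500, 5000), sched), c(1, 1))
})

test_that("odds-scale adjustment matches the closed-form algebra", {
  expect_equal(adjusted_favorable_probability(0.451, 1.00), 0.451)
  expect_equal(adjusted_favorable_probability(0.451, 1.75), 0.5897627,
               tolerance = 1e-6)
  expect_equal(adjusted_favorable_probability(0.451, 1.26), 0.5086193,
               tolerance = 1e-6)
  expect_error(adjusted_favorable_probability(1, 1.5), "degenerate")
  expect_error(adjusted_favorable_probability(0, 1.5), "degenerate")
  expect_error(adjusted_favorable_probability(0.5, -1), "odds ratio")
})

test_that("acute mRS assignment hits the target favorable shares", {
  p <- default_parameters()
  n <- 1e5
  set.seed(61)
  untreated <- assign_acute_mrs(rep(FALSE, n), rep(100, n), p$mrs_dist,
                                p$treatment_effect)
  expect_equal(mean(untreated <= 1), 0.451, tolerance = 0.005 / 0.451)
  treated_100 <- assign_acute_mrs(rep(TRUE, n), rep(100, n), p$mrs_dist,
                                  p$treatment_effect)
  expect_equal(mean(treated_100 <= 1), 0.5898, tolerance = 0.005 / 0.59)
  treated_late <- assign_acute_mrs(rep(TRUE, n), rep(400, n), p$mrs_dist,
                                   p$treatment_effect)
  expect_equal(mean(treated_late <= 1), 0.451, tolerance = 0.005 / 0.451)
  expect_true(all(untreated %in% 0:6))
})

test_that("an all-identity OR schedule leaves treated outcomes unchanged", {
  p <- default_parameters()
  p$treatment_effect$odds_ratios <- c(1, 1, 1)
  n <- 1e5
  set.seed(62)
  u <- runif(n)
  t_mrs <- assign_acute_mrs(rep(TRUE, n), rep(100, n), p$mrs_dist,
                            p$treatment_effect, u = u)
  u_mrs <- assign_acute_mrs(rep(FALSE, n), rep(100, n), p$mrs_dist,
                            p$treatment_effect, u = u)
  expect_equal(mean(t_mrs <= 1), mean(u_mrs <= 1), tolerance = 0.005)
})

test_that("acute-phase costs follow strategy and treatment status", {
  costs <- default_parameters()$costs
  expect_equal(acute_phase_cost("no_treatment", FALSE, costs), 11462)
  expect_equal(acute_phase_cost("mri_based", c(FALSE, TRUE), costs),
               c(11462 + 488, 18182 + 488))
})

test_that("population sICH increase is the three-factor product", {
  impact <- default_parameters()$population_impact
  expect_equal(population_sich_increase(impact, 0.31), 0.341)
  expect_equal(population_sich_increase(impact, 0), 0)
  expect_equal(population_sich_increase(
    list(wakeup_share_of_ischemic_strokes = 1, sich_rate_among_treated = 1),
    1), 100)
})

test_that("simulated treated fraction and favorable share match the mixture oracle", {
  p <- default_parameters()
  r <- run_strategy("mri_based", p, n = 1e5, seed = 7, lifetime = FALSE)
  # Se * P(eligible) + (1 - Sp) * P(ineligible)
  expect_equal(r$pct_treated / 100, 0.62 * (112 / 480) + 0.22 * (368 / 480),
               tolerance = 0.005 / 0.31)
  expect_equal(r$pct_mrs01 / 100, oracle_favorable_share(480),
               tolerance = 0.005 / 0.46)
})

test_that("mRS distribution files round-trip and are validated", {
  d <- placeholder_mrs_distribution()
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(d), f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  d2 <- read_mrs_distribution(f)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(provenance(d2), "user")
  bad <- as.data.frame(d)
  bad$untreated[1] <- bad$untreated[1] + 0.01
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_mrs_distribution(f2), "sum to 1")
})
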