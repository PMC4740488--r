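test_that("onset-age samples have the means implied by their distributions", {
  set.seed(11)
  cases <- list(
    list(dist = list(family = "uniform"), mean = 240),
    list(dist = list(family = "beta", alpha = 4, beta = 4), mean = 240),
    list(dist = list(family = "beta", alpha = 3, beta = 5), mean = 480 * 3 / 8)
  )
  for (cs in cases) {
    x <- sample_onset_age(cs$dist, 480, 1e5)
    expect_true(all(x >= 0 & x <= 480))
    expect_equal(mean(x), cs$mean, tolerance = 2 / cs$mean)
  }
  expect_error(sample_onset_age(list(family = "triangular"), 480, 10),
               "family")
})

test_that("onset age at treatment adds the strategy's delay chain", {
  fixed <- tibble::tibble(wake_to_hospital = 51, door_to_needle = 77,
                          mri_time = 30)
  expect_equal(onset_age_at_treatment(322, fixed, "mri_based"), 480)
  expect_equal(onset_age_at_treatment(112, fixed, "mri_based"), 270)
  zero <- tibble::tibble(wake_to_hospital = 0, door_to_needle = 0, mri_time = 0)
  expect_equal(onset_age_at_treatment(0, zero, "mri_based"), 0)
  # no-treatment bookkeeping runs to hospital arrival only
  expect_equal(onset_age_at_treatment(100, fixed, "no_treatment"), 151)
})

test_that("closed-form eligibility probability matches the linear/beta CDFs", {
  u <- list(family = "uniform")
  expect_equal(prob_onset_age_below(u, 480, 158, 270), 112 / 480)
  expect_equal(prob_onset_age_below(list(family = "beta", alpha = 4, beta = 4),
                                    480, 158, 270),
               pbeta(112 / 480, 4, 4))
  # clamps
  expect_equal(prob_onset_age_below(u, 480, 300, 270), 0)
  expect_equal(prob_onset_age_below(u, 480, 0, 1000), 1)
})

test_that("eligibility probability is monotone in delay and threshold", {
  dists <- list(list(family = "uniform"),
                list(family = "beta", alpha = 3, beta = 5))
  for (d in dists) {
    by_delay <- sapply(seq(0, 400, by = 25), function(del)
      prob_onset_age_below(d, 480, del, 270))
    expect_true(all(diff(by_delay) <= 0))
    by_thr <- sapply(seq(0, 700, by = 50), function(thr)
      prob_onset_age_below(d, 480, 158, thr))
    expect_true(all(diff(by_thr) >= 0))
  }
})

test_that("band probabilities match interval lengths and sum to one", {
  u <- list(family = "uniform")
  expect_equal(band_probabilities(u, 480, 158, c(180, 270)),
               c(22, 90, 368) / 480)
  expect_equal(band_probabilities(u, 360, 158, c(180, 270)),
               c(22, 90, 248) / 360)
  # near-degenerate sleep: all mass in the band containing the delay
  expect_equal(band_probabilities(u, 1e-9, 200, c(180, 270)), c(0, 1, 0))
  set.seed(21)
  for (i in 1:20) {
    d <- if (i %% 2) list(family = "uniform")
         else list(family = "beta", alpha = runif(1, 0.5, 6),
                   beta = runif(1, 0.5, 6))
    b <- band_probabilities(d, runif(1, 60, 600), runif(1, 0, 300),
                            sort(runif(4, 0, 700)))
    expect_equal(sum(b), 1, tolerance = 1e-12)
    expect_true(all(b >= 0))
  }
})

test_that("fixed delays return the base-case chain; zero timing gives zeros", {
  p <- default_parameters()
  d <- sample_delays(p$timing, 3)
  expect_equal(unique(d$wake_to_hospital), 51)
  expect_equal(unique(d$door_to_needle), 77)
  expect_equal(unique(d$mri_time), 30)
  z <- p$timing
  z$wake_to_hospital_minutes <- z$door_to_needle_minutes <-
    z$mri_additional_minutes <- 0
  z$stochastic_delays <- TRUE
  dz <- sample_delays(z, 5)
  expect_true(all(as.matrix(dz) == 0))
})

test_that("stochastic delays keep the base-case mean and the IQR ratio", {
  p <- default_parameters()
  p$timing$stochastic_delays <- TRUE
  set.seed(31)
  d <- sample_delays(p$timing, 1e5)
  expect_equal(mean(d$wake_to_hospital), 51, tolerance = 0.01)
  expect_equal(mean(d$door_to_needle), 77, tolerance = 0.01)
  expect_equal(mean(d$mri_time), 30, tolerance = 0.01)
  # dispersion targets: quantile ratios of the stated intervals
  q <- quantile(d$wake_to_hospital, c(0.25, 0.75))
  expect_equal(unname(q[2] / q[1]), 72 / 36, tolerance = 0.02)
  q2 <- quantile(d$mri_time, c(0.025, 0.975))
  expect_equal(unname(q2[2] / q2[1]), 40 / 20, tolerance = 0.02)
})

test_that("simulated band frequencies converge to the closed forms", {
  p <- default_parameters()
  set.seed(41)
  for (sc in list(list(d = list(family = "uniform"), sleep = 480),
                  list(d = list(family = "beta", alpha = 3, beta = 5),
                       sleep = 480))) {
    x <- sample_onset_age(sc$d, sc$sleep, 1e5) + 158
    edges <- c(180, 270)
    emp <- c(mean(x <= 180), mean(x > 180 & x <= 270), mean(x > 270))
    expect_lt(max(abs(emp - band_probabilities(sc$d, sc$sleep, 158, edges))),
              0.01)
  }
})
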