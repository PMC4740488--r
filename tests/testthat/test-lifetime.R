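test_that("synthetic life table follows the Gompertz-Makeham form", {
  lt <- synthesize_life_table(a = 2e-4, b = 3e-5, c = 1.1, max_age = 110)
  expect_equal(lt$qx_male[lt$age == 65],
               1 - exp(-(2e-4 + 3e-5 * 1.1^65)))
  expect_true(all(diff(lt$qx_male) >= 0))
  expect_equal(lt$qx_male[nrow(lt)], 1)
  # immortal limit
  lt0 <- synthesize_life_table(a = 0, b = 1e-12, c = 1.1, max_age = 90)
  expect_true(all(lt0$qx_male[-nrow(lt0)] < 1e-8))
  expect_equal(provenance(lt), "synthetic")
})

test_that("background death probability applies hazard ratios on the hazard scale", {
  lt <- tibble::tibble(age = 60:70, qx_male = 0.1, qx_female = 0.1)
  demo <- list(male_fraction = 0.6)
  expect_equal(annual_nonstroke_death_prob(65, demo, lt, 1), 0.1)
  expect_equal(annual_nonstroke_death_prob(65, demo, lt, 2.37),
               1 - 0.9^2.37)
  # sex blending
  lt2 <- tibble::tibble(age = 65, qx_male = 0.2, qx_female = 0.1)
  expect_equal(annual_nonstroke_death_prob(65, demo, lt2, 1),
               0.6 * 0.2 + 0.4 * 0.1)
  # zero risk stays zero for any hazard ratio
  lt3 <- tibble::tibble(age = 65, qx_male = 0, qx_female = 0)
  expect_equal(annual_nonstroke_death_prob(65, demo, lt3, 5), 0)
  # beyond the table: certain death
  expect_equal(annual_nonstroke_death_prob(120, demo, lt, 1), 1)
})

test_that("recurrent-stroke survivors move uniformly to worse living states", {
  set.seed(71)
  n <- 1e5
  from3 <- recurrent_stroke_destination(rep(3L, n))
  expect_equal(as.numeric(prop.table(table(from3))), c(0.5, 0.5),
               tolerance = 0.02)
  from0 <- recurrent_stroke_destination(rep(0L, n))
  expect_equal(as.numeric(prop.table(table(factor(from0, levels = 1:5)))),
               rep(0.2, 5), tolerance = 0.05)
  expect_true(all(recurrent_stroke_destination(rep(5L, 100)) == 5L))
  expect_true(all(from0 > 0))
})

test_that("one cycle accrues the state's utility and cost; forced events work", {
  p <- params_no_mortality()
  quiet <- list(recur = 1, fatal = 1, dest = 0.5, death = 1)
  s1 <- step_one_cycle(list(mrs = 1L, age = 65), p, u = quiet)
  expect_equal(s1$utility, 0.8)
  expect_equal(s1$cost, 5293)
  expect_equal(s1$state$mrs, 1L)
  s4 <- step_one_cycle(list(mrs = 4L, age = 65), p, u = quiet)
  expect_equal(s4$cost, 13557)
  # forced fatal recurrence from mRS2: dead at cycle end, recurrence cost in
  p$progression$annual_recurrent_stroke_prob <- 0.051
  fatal <- list(recur = 0, fatal = 0, dest = 0.5, death = 1)
  s2 <- step_one_cycle(list(mrs = 2L, age = 65), p, u = fatal)
  expect_equal(s2$state$mrs, 6L)
  expect_equal(s2$cost, 5293 + 20079)
  expect_error(step_one_cycle(list(mrs = 6L, age = 70), p), "dead")
})

test_that("discounted lifetime matches the annuity closed form", {
  p <- params_no_mortality()
  p$utilities$by_mrs <- rep(1, 6)
  res <- simulate_lifetime(0L, p)
  H <- p$demographics$max_age - p$demographics$start_age
  expect_equal(res$qalys, oracle_annuity(H, 0.03), tolerance = 1e-12)
  expect_equal(res$life_years, oracle_annuity(H, 0.03), tolerance = 1e-12)
  p$demographics$annual_discount_rate <- 0
  expect_equal(simulate_lifetime(0L, p)$life_years, H)
  # dead on entry
  expect_equal(simulate_lifetime(6L, p),
               list(life_years = 0, qalys = 0, cost = 0))
})

test_that("discounted totals never exceed undiscounted ones", {
  p <- default_parameters()
  set.seed(81)
  disc <- simulate_lifetimes(rep(0:5, each = 50), p)
  p0 <- p
  p0$demographics$annual_discount_rate <- 0
  set.seed(81)
  undisc <- simulate_lifetimes(rep(0:5, each = 50), p0)
  expect_true(all(disc$life_years <= undisc$life_years + 1e-12))
  expect_true(all(disc$qalys <= undisc$qalys + 1e-12))
  expect_true(all(disc$cost <= undisc$cost + 1e-12))
  expect_true(all(disc$qalys <= disc$life_years + 1e-12))
})

test_that("with equal hazards and no recurrence, survival is mRS-independent", {
  p <- default_parameters()
  p$progression$nonstroke_death_hr_by_mrs <- rep(1, 6)
  p$progression$annual_recurrent_stroke_prob <- 0
  n <- 2000
  # with a shared seed the survival process is driven by the same uniforms,
  # so expected life years cannot depend on the initial state at all
  ly <- sapply(0:5, function(m) {
    set.seed(91)
    mean(simulate_lifetimes(rep(m, n), p)$life_years)
  })
  expect_lt(max(ly) - min(ly), 1e-12)
})

test_that("cohort-expectation engine agrees with Monte Carlo", {
  p <- default_parameters()
  init <- c(0.25, 0.2, 0.15, 0.15, 0.1, 0.1, 0.05)
  set.seed(101)
  n <- 1e5
  mrs0 <- sample(0:6, n, replace = TRUE, prob = init)
  mc <- simulate_lifetimes(mrs0, p)
  ce <- cohort_expectation(unname(prop.table(table(factor(mrs0, levels = 0:6)))), p)
  expect_equal(mean(mc$qalys), ce$qalys, tolerance = 0.005)
  expect_equal(mean(mc$life_years), ce$life_years, tolerance = 0.005)
  expect_equal(mean(mc$cost), ce$cost, tolerance = 0.005)
})

test_that("life tables read back from text with validation", {
  lt <- synthesize_life_table(max_age = 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(lt), f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  lt2 <- read_life_table(f)
  expect_equal(as.data.frame(lt2), as.data.frame(lt), tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- as.data.frame(lt)[c(1:10, 12:20), ] # gap in ages
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(bad, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_life_table(f2), "contiguous")
})
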