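test_that("linear predictor matches a hand-computed dot product", {
  spec <- default_risk_model()
  rec <- toy_cohort()[3, ]  # male, age 70, smoker
  # independent spreadsheet-style arithmetic over the stored spec numbers
  blk <- spec$M
  expected <- 0
  x <- c(age = rec$age, sbp = rec$sbp, tc = rec$tc,
         smoker = as.numeric(rec$smoker), diabetes = 0)
  for (cv in names(blk$coefficients))
    expected <- expected + blk$coefficients[[cv]] * (x[[cv]] - blk$means[[cv]])
  expect_equal(linear_predictor(rec, spec), expected, tolerance = 1e-12)

  # centering identity: covariates at their means give LP = 0
  rec0 <- rec
  rec0$age <- blk$means[["age"]]; rec0$sbp <- blk$means[["sbp"]]
  rec0$tc <- blk$means[["tc"]]; rec0$smoker <- blk$means[["smoker"]]
  expect_equal(linear_predictor(rec0, spec), 0, tolerance = 1e-12)

  # one-term spec
  one <- risk_model_spec(
    male = list(coefficients = c(age = 0.5), means = c(age = 50),
                baseline_survival_10y = 0.95, recalibration_divisor = 1),
    female = list(coefficients = c(age = 0.5), means = c(age = 50),
                  baseline_survival_10y = 0.95, recalibration_divisor = 1))
  rec1 <- rec; rec1$age <- 52
  expect_equal(linear_predictor(rec1, one), 1.0)
})

test_that("log transforms are applied on the declared scale", {
  spec <- risk_model_spec(
    male = list(coefficients = c(sbp = 2), means = c(sbp = log(120)),
                transforms = c(sbp = "log"),
                baseline_survival_10y = 0.95, recalibration_divisor = 1),
    female = list(coefficients = c(sbp = 2), means = c(sbp = log(120)),
                  transforms = c(sbp = "log"),
                  baseline_survival_10y = 0.95, recalibration_divisor = 1))
  rec <- toy_cohort()[1, ]; rec$sbp <- 150
  expect_equal(linear_predictor(rec, spec), 2 * (log(150) - log(120)),
               tolerance = 1e-12)
})

test_that("risk formula, recalibration and clipping behave as specified", {
  # baseline case: LP = 0, S0 = 0.95, divisor 1 -> 0.05
  spec <- risk_model_spec(
    male = list(coefficients = c(age = 0.1), means = c(age = 57),
                baseline_survival_10y = 0.95, recalibration_divisor = 1),
    female = list(coefficients = c(age = 0.1), means = c(age = 57),
                  baseline_survival_10y = 0.95, recalibration_divisor = 1))
  rec <- toy_cohort()[1, ]; rec$age <- 57
  expect_equal(predict_untreated_risk(rec, spec), 0.05, tolerance = 1e-12)

  # recalibration is exact division below the clip: raw 0.159 / 1.59 = 0.10
  solve_age <- function(raw, s0, beta, mean_age) {
    mean_age + log(log(1 - raw) / log(s0)) / beta
  }
  mkspec <- function(div_m, div_f) risk_model_spec(
    male = list(coefficients = c(age = 0.1), means = c(age = 57),
                baseline_survival_10y = 0.95, recalibration_divisor = div_m),
    female = list(coefficients = c(age = 0.1), means = c(age = 57),
                  baseline_survival_10y = 0.95,
                  recalibration_divisor = div_f))
  rec_m <- rec; rec_m$sex <- "M"
  rec_m$age <- solve_age(0.159, 0.95, 0.1, 57)
  expect_equal(predict_untreated_risk(rec_m, mkspec(1.59, 1.72)), 0.10,
               tolerance = 1e-10)
  rec_f <- rec; rec_f$sex <- "F"
  rec_f$age <- solve_age(0.172, 0.95, 0.1, 57)
  expect_equal(predict_untreated_risk(rec_f, mkspec(1.59, 1.72)), 0.10,
               tolerance = 1e-10)

  # closed form with divisor 1, and exact 1/divisor scaling, on a cohort
  coh <- random_mini_cohort(300, seed = 9)
  full <- default_risk_model()
  unity <- full
  unity$M$recalibration_divisor <- 1
  unity$F$recalibration_divisor <- 1
  lp <- linear_predictor(coh, unity)
  s0 <- ifelse(coh$sex == "M", unity$M$baseline_survival_10y,
               unity$F$baseline_survival_10y)
  closed <- 1 - s0 ^ exp(lp)
  r1 <- predict_untreated_risk(coh, unity)
  expect_equal(r1, pmin(closed, 0.999), tolerance = 1e-12)
  div <- ifelse(coh$sex == "M", 1.59, 1.72)
  r2 <- predict_untreated_risk(coh, full)
  below_clip <- r1 / div < 0.999
  expect_equal(r2[below_clip], (r1 / div)[below_clip], tolerance = 1e-12)

  # monotonicity: raising a positive-coefficient covariate raises risk
  bumped <- coh; bumped$sbp <- coh$sbp + 10
  expect_true(all(predict_untreated_risk(bumped, full) > r2))
})

test_that("risk strata use half-open guideline intervals", {
  risks <- c(0.10, 0.075, 0.0499, 0.05, 0.0749, 0.099, 0, 0.5)
  got <- classify_risk(risks)
  expect_equal(as.character(got),
               c("high", "intermediate", "low", "borderline", "borderline",
                 "intermediate", "low", "high"))
  # classify(r) == high  <=>  r >= 0.10 (threshold-eligibility consistency)
  r <- seq(0, 0.5, by = 0.003)
  expect_equal(as.character(classify_risk(r)) == "high", r >= 0.10)
  expect_error(classify_risk(1.0), "\\[0, 1\\)")
  expect_error(classify_risk(-0.1), "\\[0, 1\\)")
})

test_that("risk model JSON round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".json")
  spec <- default_risk_model()
  write_risk_model(spec, path)
  back <- read_risk_model(path)
  expect_equal(back, spec, ignore_attr = TRUE)

  shipped <- system.file("extdata", "risk_model_standin.json",
                         package = "statinbenefit")
  expect_equal(read_risk_model(shipped), spec, ignore_attr = TRUE)

  expect_error(read_risk_model(tempfile()), "not found")
  bad <- spec
  bad$M$baseline_survival_10y <- 1.5
  expect_error(risk_model_spec(male = bad$M, female = bad$F),
               "baseline_survival_10y")
  expect_error(
    risk_model_spec(
      male = list(coefficients = c(age = 1), means = c(sbp = 1),
                  baseline_survival_10y = 0.9, recalibration_divisor = 1),
      female = spec$F),
    "names must match")
})
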