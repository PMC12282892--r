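test_that("events averted, NNT and max iNNT follow their definitions", {
  w <- c(1e6, 1e6, 2e6)
  iarr <- c(0.03, 0.05, 0.02)
  expect_equal(events_averted(w, iarr, c(TRUE, TRUE, FALSE)), 80000)
  expect_equal(events_averted(w, iarr, rep(FALSE, 3)), 0)
  expect_equal(events_averted(w[1], iarr[1], TRUE), w[1] * iarr[1])

  expect_equal(average_nnt(2e6, 80000), 25)
  expect_equal(average_nnt(100, 100), 1)
  expect_error(average_nnt(10, 0), "undefined")

  expect_equal(max_innt(c(0.025, 0.10), c(TRUE, TRUE)), 40)
  expect_equal(max_innt(c(0.05), TRUE), 20)
  expect_error(max_innt(iarr, rep(FALSE, 3)), "empty")
  expect_error(max_innt(c(0, 0.1), c(TRUE, TRUE)), "nonpositive")
})

test_that("uniform-iARR closed forms are exact", {
  a <- 0.04
  w <- runif(20, 0.5, 2) * 1e5
  iarr <- rep(a, 20)
  elig <- rep(TRUE, 20)
  ev <- events_averted(w, iarr, elig)
  expect_equal(average_nnt(sum(w), ev), 1 / a, tolerance = 1e-12)
  expect_equal(max_innt(iarr, elig), 1 / a)
})

test_that("iARR summary uses the lower weighted median", {
  out <- summarize_iarr(c(0.025, 0.042, 0.095), rep(1, 3), rep(TRUE, 3))
  expect_equal(unname(out), c(0.042, 0.025, 0.095))
  out1 <- summarize_iarr(0.03, 5, TRUE)
  expect_equal(unname(out1), c(0.03, 0.03, 0.03))
  # even count, equal weights: lower median by convention (sort oracle)
  x <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(unname(summarize_iarr(x, rep(1, 4), rep(TRUE, 4))[1]),
               sort(x)[2])
  # weighted: smallest value with cumulative weight >= half the total
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 10)), 3)
  expect_equal(weighted_median(c(1, 2, 3), c(10, 1, 1)), 1)
})

test_that("population display units and rounding", {
  expect_equal(project_to_population(2161000, "thousands"), 2161.0)
  expect_equal(project_to_population(50.3e6, "millions"), 50.3)
  expect_equal(project_to_population(0, "millions"), 0.0)
  expect_error(project_to_population(-1), ">= 0")
})

test_that("events averted are additive over a partition of the eligible", {
  coh <- random_mini_cohort(400, seed = 21)
  est <- compute_estimates(coh)
  elig <- est$iarr >= 0.02
  part <- coh$sex == "M"
  total <- events_averted(coh$weight, est$iarr, elig)
  expect_equal(events_averted(coh$weight, est$iarr, elig & part) +
                 events_averted(coh$weight, est$iarr, elig & !part),
               total, tolerance = 1e-9 * total)
  # average NNT equals the weighted identity sum(w)/sum(w*iarr)
  expect_equal(average_nnt(sum(coh$weight[elig]), total),
               sum(coh$weight[elig]) / sum(coh$weight[elig] * est$iarr[elig]))
  # max iNNT is exactly the reciprocal of the minimum eligible iARR
  expect_equal(max_innt(est$iarr, elig), 1 / min(est$iarr[elig]))
})

test_that("bootstrap CI is seed-deterministic and collapses when constant", {
  coh <- data.frame(weight = rep(1000, 50))
  est <- toy_estimates(iarr = rep(0.04, 50))
  strat <- strategy("benefit_threshold", 0.02)
  ci1 <- bootstrap_ci(coh, est, strat, "average_nnt", reps = 200, seed = 7)
  ci2 <- bootstrap_ci(coh, est, strat, "average_nnt", reps = 200, seed = 7)
  expect_identical(ci1, ci2)
  # constant statistic: CI collapses to the point value (1/iARR)
  expect_equal(ci1$lower, 25)
  expect_equal(ci1$upper, 25)
  expect_equal(ci1$point, 25)
  expect_error(bootstrap_ci(coh, est, strat, "events_averted", reps = 1),
               ">= 2")
})

test_that("bootstrap interval widens with iARR variance", {
  n <- 400
  set.seed(33)
  narrow <- toy_estimates(iarr = runif(n, 0.039, 0.041))
  wide <- toy_estimates(iarr = runif(n, 0.01, 0.07))
  coh <- data.frame(weight = rep(1000, n))
  strat <- strategy("benefit_threshold", 0.005)
  ci_n <- bootstrap_ci(coh, narrow, strat, "events_averted",
                       reps = 400, seed = 1)
  ci_w <- bootstrap_ci(coh, wide, strat, "events_averted",
                       reps = 400, seed = 1)
  expect_lte(ci_n$upper - ci_n$lower, ci_w$upper - ci_w$lower)
})

test_that("strategy_result assembles consistent components", {
  coh <- random_mini_cohort(300, seed = 3)
  est <- compute_estimates(coh)
  res <- strategy_result(coh, est, strategy("risk_threshold", 0.10),
                         bootstrap_reps = 100, seed = 5)
  elig <- est$untreated_risk >= 0.10
  expect_equal(res$eligible_persons, sum(coh$weight[elig]))
  expect_equal(res$average_nnt, res$eligible_persons / res$events_averted)
  expect_equal(res$max_innt, 1 / min(est$iarr[elig]))
  expect_true(res$ci$events_averted["lower"] <=
                res$ci$events_averted["upper"])
  expect_output(print(res), "average NNT")
})
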