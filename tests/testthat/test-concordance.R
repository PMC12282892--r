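test_that("cross tabulation reproduces identities and edge cases", {
  w <- c(3, 1, 2, 4)
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  cc <- cross_tabulate(a, b, w)
  expect_equal(cc$both, 3)
  expect_equal(cc$only_a, 1)
  expect_equal(cc$only_b, 2)
  expect_equal(cc$neither, 4)
  expect_equal(cc$either, 6)
  expect_equal(cc$overlap_prop, 0.5)
  # partition conservation
  expect_equal(cc$both + cc$only_a + cc$only_b + cc$neither, sum(w))

  expect_equal(cross_tabulate(a, a, w)$overlap_prop, 1)
  expect_equal(cross_tabulate(a, !a, w)$overlap_prop, 0)
  none <- cross_tabulate(rep(FALSE, 4), rep(FALSE, 4), w)
  expect_true(is.na(none$overlap_prop))
  expect_error(cross_tabulate(a, b[1:2], w), "misaligned")
})

test_that("flow matrix is a margin-conserving weighted contingency table", {
  strata <- factor(c("low", "high", "high", "borderline", "intermediate",
                     "low"),
                   levels = c("low", "borderline", "intermediate", "high"))
  cats <- factor(c("low", "high", "moderate", "high", "low", "low"),
                 levels = c("low", "moderate", "high"))
  w <- c(1, 2, 3, 4, 5, 6)
  m <- flow_matrix(strata, cats, w)
  # hand tally
  expect_equal(m["low", "low"], 7)
  expect_equal(m["high", "high"], 2)
  expect_equal(m["high", "moderate"], 3)
  expect_equal(m["borderline", "high"], 4)
  expect_equal(m["intermediate", "low"], 5)
  expect_equal(sum(m), sum(w))
  # margins equal stratum/category totals
  expect_equal(unname(rowSums(m)),
               as.numeric(tapply(w, strata, sum, default = 0)))
  expect_equal(unname(colSums(m)),
               as.numeric(tapply(w, cats, sum, default = 0)))
  # all mass in one cell
  one <- flow_matrix(factor(rep("high", 3), levels = levels(strata)),
                     factor(rep("high", 3), levels = levels(cats)),
                     c(1, 1, 1))
  expect_equal(one["high", "high"], 3)
  expect_equal(sum(one), 3)
  expect_error(flow_matrix(factor(c("high", NA), levels = levels(strata)),
                           cats[1:2], w[1:2]), "unclassified")
})

test_that("subgroup efficiency matches a spreadsheet oracle", {
  # hand-built 8-record cohort
  w <- c(1, 2, 1, 3, 2, 1, 2, 1)
  iarr <- c(0.05, 0.04, 0.02, 0.06, 0.03, 0.01, 0.045, 0.02)
  er <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  eb <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  ex <- er | eb | c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE)
  out <- subgroup_efficiency(er, eb, ex, iarr, w)
  oracle <- function(idx) c(sum(w[idx]), sum(w[idx] * iarr[idx]))
  both <- oracle(er & eb)
  expect_equal(out$persons[out$subgroup == "both"], both[1])
  expect_equal(out$events[out$subgroup == "both"], both[2])
  expect_equal(out$nnt[out$subgroup == "both"], both[1] / both[2])
  ro <- oracle(er & !eb); bo <- oracle(eb & !er); eo <- oracle(ex & !er & !eb)
  expect_equal(out$nnt[out$subgroup == "risk_only"], ro[1] / ro[2])
  expect_equal(out$nnt[out$subgroup == "benefit_only"], bo[1] / bo[2])
  expect_equal(out$nnt[out$subgroup == "expansion_only"], eo[1] / eo[2])
  # events over disjoint subgroups sum to the expansion strategy's events
  expect_equal(sum(out$events), sum(w[ex] * iarr[ex]), tolerance = 1e-12)
  # uniform iarr 1/22 -> NNT 22
  u <- subgroup_efficiency(rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4),
                           rep(1 / 22, 4), rep(2, 4))
  expect_equal(u$nnt[u$subgroup == "both"], 22)
  expect_error(subgroup_efficiency(er, eb, rep(FALSE, 8), iarr, w),
               "must contain the union")
})

test_that("weighted characteristics are descriptive and correct", {
  coh <- toy_cohort()
  coh$weight <- rep(1, 6)
  out <- compare_characteristics(coh, c(TRUE, TRUE, rep(FALSE, 4)),
                                 c(rep(FALSE, 4), TRUE, TRUE))
  expect_equal(out$mean_a[out$variable == "age"], mean(c(45, 57)))
  # weighted mean with weights {1,3} and values {0,4} is 3
  coh2 <- toy_cohort()[1:2, ]
  coh2$age <- c(0, 4); coh2$weight <- c(1, 3)
  both <- c(TRUE, TRUE)
  out2 <- compare_characteristics(coh2, both, both)
  expect_equal(out2$mean_a[out2$variable == "age"], 3)
  # binary covariate reported as weighted percent
  expect_equal(out$mean_b[out$variable == "smoker_pct"], 50)
  expect_error(compare_characteristics(coh, rep(FALSE, 6), rep(TRUE, 6)),
               "nonempty")
})
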