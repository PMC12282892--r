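# Shared fixture builders. Everything is constructed in code; no data files.

# A small hand-specified cohort covering both sexes and a spread of risk.
toy_cohort <- function() {
  data.frame(
    id = sprintf("t%02d", 1:6),
    age = c(45, 57, 70, 52, 63, 78),
    sex = c("M", "F", "M", "F", "M", "F"),
    smoker = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    sbp = c(118, 130, 165, 124, 142, 150),
    tc = c(4.2, 5.0, 5.8, 4.7, 5.4, 6.1),
    ldl = c(2.2, 3.0, 3.6, 2.6, 3.2, 4.1),
    hdl = c(1.1, 1.4, 1.0, 1.5, 1.2, 1.3),
    weight = c(1e6, 2e6, 1.5e6, 2.5e6, 1e6, 0.5e6),
    cvd_history = FALSE, diabetes = FALSE, statin_use = FALSE,
    stringsAsFactors = FALSE
  )
}

# Minimal estimates frame for functions that only need risk/iarr columns.
toy_estimates <- function(iarr, risk = iarr * 3) {
  data.frame(untreated_risk = risk, iarr = iarr)
}

# Small random cohorts for oracle-equivalence sweeps.
random_mini_cohort <- function(n, seed) {
  cfg <- generator_config(n = n, seed = seed)
  cohort <- generate_cohort(cfg)
  filt <- apply_inclusion_filters(cohort)
  rescale_weights(filt$kept, 324.6e6)
}
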