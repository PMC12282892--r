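# Synthetic survey-weighted cohort generation and inclusion filtering.
#
# The generator emulates the structure of a nationally representative
# middle-aged Chinese cohort (adults 40-80, ~52% women, mean age ~57,
# LDL-C restricted to [1.8, 4.9) mmol/L, weights scaling to 324.6 million
# adults). It is a documented synthetic stand-in, not an estimate of any
# real survey's covariate distribution.

#' Generator configuration for synthetic cohorts
#'
#' Builds a validated configuration object for [generate_cohort()]. Defaults
#' encode the target cohort structure: `n = 7287` records representing
#' 324.6 million adults, 51.7% women, mean age 57 years, and LDL-C
#' truncated to the analytic window \[1.8, 4.9) mmol/L.
#'
#' Covariate structure (a deliberate, documented simplification):
#' age is truncated normal on \[40, 80\]; SBP is linear in age plus noise;
#' total cholesterol (TC) is truncated normal; LDL-C is drawn conditional on
#' TC as `ldl_given_tc_ratio * tc` plus noise, truncated to
#' \[1.8, min(4.9, tc)) so `tc >= ldl` always holds; smoking is Bernoulli
#' with sex-specific probability; exclusion flags are independent Bernoulli.
#'
#' @param n Sample size (records drawn before filtering).
#' @param target_population Persons the cohort represents; uniform weights
#'   `target_population / n` are attached before any filtering.
#' @param prop_female Probability a record is female.
#' @param age_mean,age_sd Age distribution (years), truncated to \[40, 80\].
#' @param sbp_mean,sbp_sd,sbp_age_slope Systolic blood pressure model (mmHg):
#'   `sbp_mean + sbp_age_slope * (age - age_mean) + N(0, sbp_sd)`, truncated
#'   to \[90, 220\].
#' @param tc_mean,tc_sd Total cholesterol (mmol/L), truncated to \[2.8, 10\].
#' @param ldl_given_tc_ratio,ldl_noise_sd LDL-C conditional model (mmol/L).
#' @param hdl_mean,hdl_sd HDL cholesterol (mmol/L), truncated to \[0.5, 3\].
#' @param smoking_prob_male,smoking_prob_female Current-smoking probabilities.
#' @param exclusion_flag_probs Named list/vector with elements `cvd_history`,
#'   `diabetes`, `statin_use`: marginal probabilities of each exclusion flag.
#' @param seed Integer seed; `generate_cohort()` is reproducible given it.
#' @return A list of class `"generator_config"`.
#' @export
#' @examples
#' cfg <- generator_config(n = 500, seed = 1)
#' cohort <- generate_cohort(cfg)
generator_config <- function(n = 7287L,
                             target_population = 324.6e6,
                             prop_female = 0.517,
                             age_mean = 57, age_sd = 9.5,
                             sbp_mean = 130, sbp_sd = 18, sbp_age_slope = 0.5,
                             tc_mean = 4.9, tc_sd = 0.9,
                             ldl_given_tc_ratio = 0.62, ldl_noise_sd = 0.35,
                             hdl_mean = 1.3, hdl_sd = 0.3,
                             smoking_prob_male = 0.50,
                             smoking_prob_female = 0.05,
                             exclusion_flag_probs = list(cvd_history = 0.08,
                                                         diabetes = 0.10,
                                                         statin_use = 0.02),
                             seed = 1L) {
  cfg <- list(n = as.integer(n), target_population = target_population,
              prop_female = prop_female,
              age_mean = age_mean, age_sd = age_sd,
              sbp_mean = sbp_mean, sbp_sd = sbp_sd,
              sbp_age_slope = sbp_age_slope,
              tc_mean = tc_mean, tc_sd = tc_sd,
              ldl_given_tc_ratio = ldl_given_tc_ratio,
              ldl_noise_sd = ldl_noise_sd,
              hdl_mean = hdl_mean, hdl_sd = hdl_sd,
              smoking_prob_male = smoking_prob_male,
              smoking_prob_female = smoking_prob_female,
              exclusion_flag_probs = as.list(exclusion_flag_probs),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid generator config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n) || length(cfg$n) != 1L || is.na(cfg$n) || cfg$n < 1)
    stop_field("n", "must be a single integer >= 1")
  if (!is.numeric(cfg$target_population) || cfg$target_population <= 0)
    stop_field("target_population", "must be > 0")
  probs <- c(prop_female = cfg$prop_female,
             smoking_prob_male = cfg$smoking_prob_male,
             smoking_prob_female = cfg$smoking_prob_female,
             unlist(cfg$exclusion_flag_probs))
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad))
    stop_field(bad[1L], "probability must lie in [0, 1]")
  sds <- c(age_sd = cfg$age_sd, sbp_sd = cfg$sbp_sd, tc_sd = cfg$tc_sd,
           ldl_noise_sd = cfg$ldl_noise_sd, hdl_sd = cfg$hdl_sd)
  bad <- names(sds)[!is.finite(sds) | sds <= 0]
  if (length(bad))
    stop_field(bad[1L], "standard deviation must be > 0")
  need <- c("cvd_history", "diabetes", "statin_use")
  missing <- setdiff(need, names(cfg$exclusion_flag_probs))
  if (length(missing))
    stop_field("exclusion_flag_probs",
               paste("missing elements:", paste(missing, collapse = ", ")))
  invisible(cfg)
}

# Truncated-normal draws by inverse-CDF; a, b may be vectors.
rtruncnorm <- function(n, mean, sd, a, b) {
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  # degenerate windows (both tails beyond machine precision) fall back to
  # the nearer bound
  u <- stats::runif(n)
  q <- stats::qnorm(lo + u * (hi - lo), mean, sd)
  pmin(pmax(q, a), b)
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` person records with uniform survey weights
#' `target_population / n`. Reproducible given `config$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` (one row per person) with columns
#'   `id, age, sex, smoker, sbp, tc, ldl, hdl, weight, cvd_history,
#'   diabetes, statin_use`. `sex` is `"M"`/`"F"`; flag columns are logical.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  validate_generator_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n <- config$n
  sex <- ifelse(stats::runif(n) < config$prop_female, "F", "M")
  age <- rtruncnorm(n, config$age_mean, config$age_sd, 40, 80)
  sbp <- config$sbp_mean + config$sbp_age_slope * (age - config$age_mean) +
    stats::rnorm(n, 0, config$sbp_sd)
  sbp <- pmin(pmax(sbp, 90), 220)
  tc <- rtruncnorm(n, config$tc_mean, config$tc_sd, 2.8, 10)
  ldl_upper <- pmin(4.9, tc)
  ldl <- rtruncnorm(n, config$ldl_given_tc_ratio * tc, config$ldl_noise_sd,
                    1.8, ldl_upper)
  hdl <- rtruncnorm(n, config$hdl_mean, config$hdl_sd, 0.5, 3)
  smoke_p <- ifelse(sex == "M", config$smoking_prob_male,
                    config$smoking_prob_female)
  smoker <- stats::runif(n) < smoke_p
  fp <- config$exclusion_flag_probs
  data.frame(
    id = sprintf("p%06d", seq_len(n)),
    age = age, sex = sex, smoker = smoker,
    sbp = sbp, tc = tc, ldl = ldl, hdl = hdl,
    weight = rep(config$target_population / n, n),
    cvd_history = stats::runif(n) < fp$cvd_history,
    diabetes = stats::runif(n) < fp$diabetes,
    statin_use = stats::runif(n) < fp$statin_use,
    stringsAsFactors = FALSE
  )
}

# Exclusion reasons in the fixed tally order. When a record matches several,
# the first matching reason is charged.
exclusion_reasons <- function() {
  c("age_outside_40_80", "cvd_history", "diabetes",
    "ldl_below_1.8", "ldl_at_or_above_4.9", "statin_use")
}

#' Apply analytic-sample inclusion filters
#'
#' Keeps records with `40 <= age <= 80`, `1.8 <= ldl < 4.9` mmol/L, and no
#' CVD history, diabetes, or prior statin use. Removed records are tallied by
#' the first matching reason in the fixed order
#' `age_outside_40_80, cvd_history, diabetes, ldl_below_1.8,
#' ldl_at_or_above_4.9, statin_use` so counts are reproducible when reasons
#' co-occur.
#'
#' @param cohort Cohort `data.frame` as produced by [generate_cohort()] or
#'   [read_cohort_csv()].
#' @return List with `kept` (filtered data.frame) and `exclusion_tally`
#'   (named integer vector over all reasons, zeros included).
#' @export
apply_inclusion_filters <- function(cohort) {
  reasons <- exclusion_reasons()
  tally <- stats::setNames(integer(length(reasons)), reasons)
  if (nrow(cohort) == 0L) {
    return(list(kept = cohort, exclusion_tally = tally))
  }
  fail <- cbind(
    age_outside_40_80 = cohort$age < 40 | cohort$age > 80,
    cvd_history = as.logical(cohort$cvd_history),
    diabetes = as.logical(cohort$diabetes),
    `ldl_below_1.8` = cohort$ldl < 1.8,
    `ldl_at_or_above_4.9` = cohort$ldl >= 4.9,
    statin_use = as.logical(cohort$statin_use)
  )
  first_reason <- apply(fail, 1L, function(row) {
    w <- which(row)
    if (length(w)) w[1L] else NA_integer_
  })
  excluded <- !is.na(first_reason)
  counts <- table(factor(reasons[first_reason[excluded]], levels = reasons))
  tally[names(counts)] <- as.integer(counts)
  list(kept = cohort[!excluded, , drop = FALSE], exclusion_tally = tally)
}

#' Rescale survey weights to a target population
#'
#' Multiplies every weight by the single constant that makes the weights sum
#' to `target_population`, preserving all pairwise weight ratios.
#'
#' @param cohort Cohort `data.frame` with a `weight` column.
#' @param target_population Persons the filtered cohort should represent.
#' @return The cohort with rescaled weights.
#' @export
rescale_weights <- function(cohort, target_population = 324.6e6) {
  if (nrow(cohort) == 0L)
    stop("cannot rescale weights of an empty cohort", call. = FALSE)
  if (!is.numeric(target_population) || target_population <= 0)
    stop("target_population must be > 0", call. = FALSE)
  total <- sum(cohort$weight)
  if (total <= 0)
    stop("cohort weights must sum to a positive total", call. = FALSE)
  cohort$weight <- cohort$weight * (target_population / total)
  cohort
}
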