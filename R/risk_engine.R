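# Pluggable sex-specific 10-year CVD risk engine.
#
# Functional form: the standard Cox-type 10-year risk
#   raw = 1 - S0^exp(LP),   LP = sum_k beta_k * (t_k(x_k) - mean_k)
# followed by division by a sex-specific recalibration divisor that corrects
# systematic overestimation in the target population (defaults 1.59 for men,
# 1.72 for women). Coefficients are supplied as a versioned spec; a
# documented synthetic stand-in ships with the package because the original
# published coefficient set is not transcribed here.

#' Construct a sex-specific risk model specification
#'
#' @param male,female Per-sex lists with elements `coefficients` (named
#'   numeric, log-hazard units), `means` (named numeric centering values with
#'   identical names), `baseline_survival_10y` (fraction in (0,1)),
#'   `recalibration_divisor` (> 0), and optional `transforms` (named
#'   character, `"identity"` or `"log"`; missing entries default to
#'   identity).
#' @return A list of class `"risk_model_spec"` with elements `M` and `F`.
#' @export
risk_model_spec <- function(male, female) {
  spec <- list(M = normalize_sex_spec(male, "male"),
               F = normalize_sex_spec(female, "female"))
  structure(spec, class = "risk_model_spec")
}

normalize_sex_spec <- function(s, label) {
  err <- function(msg) {
    stop(sprintf("risk model spec (%s): %s", label, msg), call. = FALSE)
  }
  coefs <- unlist(s$coefficients)
  means <- unlist(s$means)
  if (is.null(names(coefs)) || is.null(names(means)))
    err("coefficients and means must be named")
  if (!setequal(names(coefs), names(means)))
    err("coefficient and mean names must match")
  means <- means[names(coefs)]
  s0 <- s$baseline_survival_10y
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0 || s0 >= 1)
    err("baseline_survival_10y must lie in (0, 1)")
  div <- s$recalibration_divisor
  if (!is.numeric(div) || length(div) != 1L || div <= 0)
    err("recalibration_divisor must be > 0")
  transforms <- stats::setNames(rep("identity", length(coefs)), names(coefs))
  if (!is.null(s$transforms)) {
    tr <- unlist(s$transforms)
    unknown <- setdiff(names(tr), names(coefs))
    if (length(unknown))
      err(paste("transform for unknown covariate:", unknown[1L]))
    bad <- tr[!tr %in% c("identity", "log")]
    if (length(bad))
      err(paste("unsupported transform:", bad[1L]))
    transforms[names(tr)] <- tr
  }
  list(coefficients = coefs, means = means, transforms = transforms,
       baseline_survival_10y = s0, recalibration_divisor = div)
}

#' Built-in synthetic stand-in risk model
#'
#' A documented stand-in coefficient set with the same shape as published
#' laboratory-based 10-year CVD equations (age, systolic blood pressure,
#' total cholesterol, current smoking, diabetes). The values are synthetic:
#' chosen to give plausible risk gradients in a middle-aged cohort, not
#' transcribed from any publication. The diabetes term is carried in the
#' spec but evaluates to zero in the analytic cohort because diabetics are
#' excluded. Users wanting realism should supply their own transcribed
#' coefficients via [read_risk_model()].
#'
#' @return A `"risk_model_spec"`.
#' @export
default_risk_model <- function() {
  risk_model_spec(
    male = list(
      coefficients = c(age = 0.075, sbp = 0.018, tc = 0.16,
                       smoker = 0.55, diabetes = 0.65),
      means = c(age = 57, sbp = 130, tc = 4.9, smoker = 0.45, diabetes = 0),
      baseline_survival_10y = 0.95,
      recalibration_divisor = 1.59
    ),
    female = list(
      coefficients = c(age = 0.085, sbp = 0.016, tc = 0.13,
                       smoker = 0.60, diabetes = 0.75),
      means = c(age = 57, sbp = 128, tc = 5.0, smoker = 0.05, diabetes = 0),
      baseline_survival_10y = 0.97,
      recalibration_divisor = 1.72
    )
  )
}

#' Read / write a risk model specification (JSON)
#'
#' The on-disk format is
#' `{"male": {"coefficients": {...}, "means": {...}, "transforms": {...},
#' "baseline_survival_10y": s0, "recalibration_divisor": d}, "female": ...}`.
#' Validation errors name the offending sex block and field.
#'
#' @param path File path.
#' @return `read_risk_model()`: a `"risk_model_spec"`.
#' @export
read_risk_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("risk model file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(c("male", "female"), names(raw))
  if (length(missing))
    stop(sprintf("risk model file %s: missing '%s' block",
                 path, missing[1L]), call. = FALSE)
  risk_model_spec(male = raw$male, female = raw$female)
}

#' @rdname read_risk_model
#' @param spec A `"risk_model_spec"`.
#' @export
write_risk_model <- function(spec, path) {
  stopifnot(inherits(spec, "risk_model_spec"))
  out <- list(
    male = sex_spec_to_list(spec$M),
    female = sex_spec_to_list(spec$F)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

sex_spec_to_list <- function(s) {
  list(coefficients = as.list(s$coefficients),
       means = as.list(s$means),
       transforms = as.list(s$transforms),
       baseline_survival_10y = s$baseline_survival_10y,
       recalibration_divisor = s$recalibration_divisor)
}

sex_block <- function(spec, sex) {
  sex <- as.character(sex)
  if (!sex %in% names(spec))
    stop(sprintf("sex '%s' absent from risk model spec", sex), call. = FALSE)
  spec[[sex]]
}

#' Centered linear predictor (log-hazard units)
#'
#' Computes `sum_k beta_k * (t_k(x_k) - mean_k)` over the spec's covariates
#' for each record, applying declared transforms (the stored centering mean
#' is on the transformed scale). Vectorized over rows.
#'
#' @param cohort Cohort `data.frame`; must contain every covariate named in
#'   the spec (logical columns are coerced to 0/1; a missing `diabetes`
#'   column in an already-filtered cohort is treated as all-zero).
#' @param spec A `"risk_model_spec"`.
#' @return Numeric vector, one value per record.
#' @export
linear_predictor <- function(cohort, spec) {
  stopifnot(inherits(spec, "risk_model_spec"))
  lp <- numeric(nrow(cohort))
  for (sx in unique(as.character(cohort$sex))) {
    block <- sex_block(spec, sx)
    rows <- cohort$sex == sx
    acc <- numeric(sum(rows))
    for (cv in names(block$coefficients)) {
      if (is.null(cohort[[cv]])) {
        if (identical(cv, "diabetes")) next  # excluded cohort: term is zero
        stop(sprintf("covariate '%s' missing from cohort", cv),
             call. = FALSE)
      }
      x <- as.numeric(cohort[[cv]][rows])
      if (block$transforms[[cv]] == "log") x <- log(x)
      acc <- acc + block$coefficients[[cv]] * (x - block$means[[cv]])
    }
    lp[rows] <- acc
  }
  lp
}

#' Predicted untreated 10-year CVD risk
#'
#' `raw = 1 - S0^exp(LP)`; the returned risk is `raw` divided by the
#' sex-specific recalibration divisor and clipped to \[0, 0.999\] (the clip
#' keeps iNNT finite and log-space work defined).
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of risk fractions in \[0, 0.999\].
#' @export
predict_untreated_risk <- function(cohort, spec) {
  lp <- linear_predictor(cohort, spec)
  risk <- numeric(length(lp))
  for (sx in unique(as.character(cohort$sex))) {
    block <- sex_block(spec, sx)
    rows <- cohort$sex == sx
    raw <- 1 - block$baseline_survival_10y ^ exp(lp[rows])
    risk[rows] <- raw / block$recalibration_divisor
  }
  pmin(pmax(risk, 0), 0.999)
}

# Strata bounds shared by classify_risk() and reporting.
risk_strata_levels <- function() {
  c("low", "borderline", "intermediate", "high")
}

#' Classify 10-year risk into guideline strata
#'
#' Strata: low (<5%), borderline (5% to <7.5%), intermediate (7.5% to <10%),
#' high (>=10%). Lower bounds inclusive.
#'
#' @param risk Numeric vector of risk fractions in \[0, 1).
#' @return Factor with levels `low < borderline < intermediate < high`.
#' @export
classify_risk <- function(risk) {
  if (any(!is.finite(risk) | risk < 0 | risk >= 1))
    stop("risk values must lie in [0, 1)", call. = FALSE)
  cut(risk, breaks = c(0, 0.05, 0.075, 0.10, 1),
      labels = risk_strata_levels(),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}
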