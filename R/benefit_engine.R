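# Individualized-benefit chain: expected LDL-C reduction, relative risk of
# treatment, on-treatment risk, iARR = untreated - treated risk, and
# iNNT = 1/iARR.
#
# The per-mmol/L relative risk is a configuration parameter: constant by
# default (the package's documented fixture value is 0.78 per mmol/L), with
# an optional mode that lets RR interact with baseline risk as
# exp(intercept + slope * g(risk)), g in {identity, log, logit}.

#' Treatment specification
#'
#' @param ldl_reduction_prop Proportional LDL-C reduction from baseline under
#'   therapy; default 0.40 (moderate-intensity), sensitivity analyses use
#'   0.30.
#' @param rr_mode `"constant"` or `"risk_interaction"`.
#' @param rr_constant Relative risk of CVD per 1 mmol/L LDL-C reduction,
#'   in (0, 1\]; used in constant mode. 0.78 is a documented fixture
#'   default, to be replaced by a transcribed meta-analysis value for
#'   real-data use.
#' @param rr_interaction List `(intercept, slope, scale)` for interaction
#'   mode: per-mmol/L RR is `exp(intercept + slope * g(risk))`, clipped to
#'   (0, 1\]; `scale` selects g: `"identity"`, `"log"`, or `"logit"`.
#' @return A list of class `"treatment_spec"`.
#' @export
treatment_spec <- function(ldl_reduction_prop = 0.40,
                           rr_mode = c("constant", "risk_interaction"),
                           rr_constant = 0.78,
                           rr_interaction = list(intercept = log(0.78),
                                                 slope = 0,
                                                 scale = "identity")) {
  rr_mode <- match.arg(rr_mode)
  if (!is.numeric(ldl_reduction_prop) || ldl_reduction_prop <= 0 ||
      ldl_reduction_prop >= 1)
    stop("ldl_reduction_prop must lie in (0, 1)", call. = FALSE)
  if (rr_mode == "constant" &&
      (!is.numeric(rr_constant) || rr_constant <= 0 || rr_constant > 1))
    stop("rr_constant must lie in (0, 1]", call. = FALSE)
  if (rr_mode == "risk_interaction") {
    need <- c("intercept", "slope", "scale")
    if (!all(need %in% names(rr_interaction)))
      stop("rr_interaction needs intercept, slope and scale", call. = FALSE)
    if (!rr_interaction$scale %in% c("identity", "log", "logit"))
      stop("rr_interaction scale must be identity, log or logit",
           call. = FALSE)
  }
  structure(list(ldl_reduction_prop = ldl_reduction_prop,
                 rr_mode = rr_mode,
                 rr_constant = rr_constant,
                 rr_interaction = rr_interaction),
            class = "treatment_spec")
}

#' Expected absolute LDL-C reduction
#'
#' @param baseline_ldl Baseline LDL-C in mmol/L (> 0).
#' @param spec A [treatment_spec()].
#' @return `baseline_ldl * ldl_reduction_prop`, in mmol/L.
#' @export
delta_ldl <- function(baseline_ldl, spec = treatment_spec()) {
  if (any(!is.finite(baseline_ldl) | baseline_ldl <= 0))
    stop("baseline LDL-C must be positive", call. = FALSE)
  baseline_ldl * spec$ldl_reduction_prop
}

#' Relative risk per mmol/L of LDL-C reduction
#'
#' Constant mode ignores the risk argument; interaction mode evaluates
#' `exp(intercept + slope * g(risk))` on the declared scale, clipped to
#' (0, 1\].
#'
#' @param untreated_risk Risk fractions in \[0, 1).
#' @inheritParams delta_ldl
#' @return Numeric vector of per-mmol/L relative risks in (0, 1\].
#' @export
rr_per_unit <- function(untreated_risk, spec = treatment_spec()) {
  if (any(!is.finite(untreated_risk) | untreated_risk < 0 |
          untreated_risk >= 1))
    stop("untreated risk must lie in [0, 1)", call. = FALSE)
  if (spec$rr_mode == "constant") {
    return(rep(spec$rr_constant, length(untreated_risk)))
  }
  p <- spec$rr_interaction
  g <- switch(p$scale,
              identity = untreated_risk,
              log = log(untreated_risk),
              logit = stats::qlogis(untreated_risk))
  rr <- exp(p$intercept + p$slope * g)
  pmin(pmax(rr, .Machine$double.xmin), 1)
}

#' Overall relative risk with treatment
#'
#' Per-mmol/L RR raised to the absolute LDL-C reduction, computed in log
#' space: `exp(delta * log(rr_unit))`.
#'
#' @param delta Absolute LDL-C reduction in mmol/L (>= 0).
#' @param rr_unit Per-mmol/L relative risk in (0, 1\].
#' @return Overall RR in (0, 1\].
#' @export
overall_rr <- function(delta, rr_unit) {
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  if (any(rr_unit <= 0 | rr_unit > 1))
    stop("rr_unit must lie in (0, 1]", call. = FALSE)
  exp(delta * log(rr_unit))
}

#' On-treatment risk and individual absolute risk reduction
#'
#' `treated = untreated * rr_overall`; `iarr = untreated - treated`.
#'
#' @param untreated_risk Risk fractions in \[0, 1).
#' @param rr_overall Overall relative risks in (0, 1\].
#' @return `data.frame` with columns `treated_risk` and `iarr`.
#' @export
compute_iarr <- function(untreated_risk, rr_overall) {
  if (any(untreated_risk < 0 | untreated_risk >= 1))
    stop("untreated risk must lie in [0, 1)", call. = FALSE)
  if (any(rr_overall <= 0 | rr_overall > 1))
    stop("rr_overall must lie in (0, 1]", call. = FALSE)
  treated <- untreated_risk * rr_overall
  data.frame(treated_risk = treated, iarr = untreated_risk - treated)
}

#' Individual number needed to treat
#'
#' `iNNT = 1 / iARR`, carried unrounded; rounding to integers is a display
#' concern. A non-positive iARR signals a person with no modelled benefit
#' and is an error.
#'
#' @param iarr Individual absolute risk reductions (> 0).
#' @return Numeric vector of iNNTs.
#' @export
compute_innt <- function(iarr) {
  if (any(!is.finite(iarr) | iarr <= 0))
    stop("iNNT undefined: iARR must be > 0 (person has no modelled benefit)",
         call. = FALSE)
  1 / iarr
}

#' Classify predicted benefit
#'
#' High if `iarr >= high_threshold`; moderate if
#' `moderate_threshold <= iarr < high_threshold`; low otherwise.
#'
#' @param iarr iARR fractions.
#' @param high_threshold,moderate_threshold Benefit thresholds
#'   (`moderate_threshold <= high_threshold`).
#' @return Factor with levels `low < moderate < high`.
#' @export
classify_benefit <- function(iarr, high_threshold, moderate_threshold) {
  if (moderate_threshold > high_threshold)
    stop("moderate_threshold must not exceed high_threshold", call. = FALSE)
  out <- ifelse(iarr >= high_threshold, "high",
                ifelse(iarr >= moderate_threshold, "moderate", "low"))
  factor(out, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Per-person estimates for a cohort
#'
#' Runs the full chain — untreated risk, LDL-C reduction, per-mmol/L and
#' overall RR, on-treatment risk, iARR, iNNT — for every record.
#'
#' @param cohort Cohort `data.frame`.
#' @param risk_model A `"risk_model_spec"` (default: built-in stand-in).
#' @param treatment A [treatment_spec()].
#' @return `data.frame` with columns `id, untreated_risk, risk_stratum,
#'   delta_ldl, rr_unit, rr_overall, treated_risk, iarr, innt`, row-aligned
#'   with `cohort`.
#' @export
compute_estimates <- function(cohort,
                              risk_model = default_risk_model(),
                              treatment = treatment_spec()) {
  untreated <- predict_untreated_risk(cohort, risk_model)
  d <- delta_ldl(cohort$ldl, treatment)
  rru <- rr_per_unit(untreated, treatment)
  rro <- overall_rr(d, rru)
  frag <- compute_iarr(untreated, rro)
  data.frame(
    id = cohort$id,
    untreated_risk = untreated,
    risk_stratum = classify_risk(untreated),
    delta_ldl = d,
    rr_unit = rru,
    rr_overall = rro,
    treated_risk = frag$treated_risk,
    iarr = frag$iarr,
    innt = ifelse(frag$iarr > 0, 1 / frag$iarr, NA_real_),
    stringsAsFactors = FALSE
  )
}
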