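# Agreement between eligibility strategies: weighted overlap, reclassification
# flows between risk strata and benefit categories, subgroup efficiency, and
# weighted group characteristics.

#' Weighted concordance of two eligibility indicators
#'
#' @param elig_a,elig_b Logical indicators (aligned).
#' @param weights Survey weights (aligned).
#' @return A list of class `"concordance_result"` with weighted persons in
#'   `both`, `only_a`, `only_b`, `neither`, `either`, and `overlap_prop =
#'   both / either` (`NA` when nobody is eligible under either strategy).
#' @export
cross_tabulate <- function(elig_a, elig_b, weights) {
  if (length(elig_a) != length(elig_b) ||
      length(elig_a) != length(weights))
    stop("eligibility indicators and weights are misaligned", call. = FALSE)
  both <- sum(weights[elig_a & elig_b])
  only_a <- sum(weights[elig_a & !elig_b])
  only_b <- sum(weights[!elig_a & elig_b])
  neither <- sum(weights[!elig_a & !elig_b])
  either <- both + only_a + only_b
  structure(list(both = both, only_a = only_a, only_b = only_b,
                 neither = neither, either = either,
                 overlap_prop = if (either > 0) both / either else NA_real_),
            class = "concordance_result")
}

#' Weighted flow matrix between risk strata and benefit categories
#'
#' A weighted contingency table whose margins recover the stratum and
#' category totals exactly (the underlying table of a risk-to-benefit
#' reclassification Sankey diagram).
#'
#' @param risk_strata Factor from [classify_risk()] (aligned).
#' @param benefit_categories Factor from [classify_benefit()] (aligned).
#' @param weights Survey weights (aligned).
#' @return Matrix (risk strata x benefit categories) of weighted persons.
#' @export
flow_matrix <- function(risk_strata, benefit_categories, weights) {
  if (length(risk_strata) != length(benefit_categories) ||
      length(risk_strata) != length(weights))
    stop("inputs are misaligned", call. = FALSE)
  if (anyNA(risk_strata) || anyNA(benefit_categories))
    stop("unclassified record: NA stratum or benefit category",
         call. = FALSE)
  risk_strata <- factor(risk_strata, levels = risk_strata_levels())
  benefit_categories <- factor(benefit_categories,
                               levels = c("low", "moderate", "high"))
  tab <- tapply(weights, list(risk_strata, benefit_categories), sum,
                default = 0)
  m <- matrix(tab, nrow = nlevels(risk_strata),
              dimnames = list(risk = levels(risk_strata),
                              benefit = levels(benefit_categories)))
  m
}

#' Treatment efficiency across concordance/discordance subgroups
#'
#' Subgroups: `both` (risk- and benefit-eligible), `risk_only`,
#' `benefit_only`, and `expansion_only` (eligible only under the expanded
#' minimum-benefit strategy). The expansion indicator must contain the union
#' of the other two.
#'
#' @param elig_risk,elig_benefit,elig_expansion Logical indicators (aligned).
#' @param iarrs iARR fractions (aligned).
#' @param weights Survey weights (aligned).
#' @return `data.frame` with one row per subgroup: weighted `persons`,
#'   `events` averted, and `nnt` (`NA` for empty subgroups).
#' @export
subgroup_efficiency <- function(elig_risk, elig_benefit, elig_expansion,
                                iarrs, weights) {
  n <- length(weights)
  if (any(c(length(elig_risk), length(elig_benefit),
            length(elig_expansion), length(iarrs)) != n))
    stop("inputs are misaligned", call. = FALSE)
  if (any((elig_risk | elig_benefit) & !elig_expansion))
    stop("expansion set must contain the union of risk- and benefit-eligible",
         call. = FALSE)
  members <- list(
    both = elig_risk & elig_benefit,
    risk_only = elig_risk & !elig_benefit,
    benefit_only = elig_benefit & !elig_risk,
    expansion_only = elig_expansion & !elig_risk & !elig_benefit
  )
  rows <- lapply(names(members), function(nm) {
    idx <- members[[nm]]
    persons <- sum(weights[idx])
    events <- sum(weights[idx] * iarrs[idx])
    data.frame(subgroup = nm, persons = persons, events = events,
               nnt = if (events > 0) persons / events else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Weighted characteristics of two groups
#'
#' Weighted mean (SD) for continuous covariates and weighted percent for
#' binary ones; descriptive only (no inferential tests). The weighted SD
#' uses the frequency-weight convention (weights as person counts):
#' `sqrt(sum(w (x - m)^2) / (sum(w) - 1))`.
#'
#' @param cohort Cohort `data.frame`.
#' @param group_a,group_b Logical indicators of the two groups (aligned with
#'   `cohort`), both nonempty.
#' @param continuous,binary Column names to summarize.
#' @return `data.frame` with per-variable weighted summaries for both groups
#'   (`mean_a/sd_a/mean_b/sd_b` for continuous variables; `pct_a/pct_b` in
#'   the `mean_*` columns for binary ones, with `NA` SDs).
#' @export
compare_characteristics <- function(cohort, group_a, group_b,
                                    continuous = c("age", "sbp", "tc",
                                                   "ldl", "hdl"),
                                    binary = c("smoker")) {
  if (!any(group_a) || !any(group_b))
    stop("both groups must be nonempty", call. = FALSE)
  wmean <- function(x, w) sum(w * x) / sum(w)
  wsd <- function(x, w) {
    m <- wmean(x, w)
    sqrt(sum(w * (x - m)^2) / (sum(w) - 1))
  }
  summarize <- function(idx) {
    w <- cohort$weight[idx]
    rows <- lapply(continuous, function(v) {
      x <- as.numeric(cohort[[v]][idx])
      c(mean = wmean(x, w), sd = wsd(x, w))
    })
    brows <- lapply(binary, function(v) {
      x <- as.numeric(cohort[[v]][idx])
      c(mean = 100 * wmean(x, w), sd = NA_real_)
    })
    do.call(rbind, c(rows, brows))
  }
  a <- summarize(group_a)
  b <- summarize(group_b)
  data.frame(variable = c(continuous, paste0(binary, "_pct")),
             mean_a = a[, "mean"], sd_a = a[, "sd"],
             mean_b = b[, "mean"], sd_b = b[, "sd"],
             stringsAsFactors = FALSE, row.names = NULL)
}
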