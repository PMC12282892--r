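# Eligibility strategies and the two threshold-setting principles:
# (1) comparable event prevention — search benefit thresholds for the one
#     whose weighted events averted best matches the risk strategy's;
# (2) minimum benefit expansion — use the minimum iARR observed among
#     risk-threshold-eligible people.

#' Define an eligibility strategy
#'
#' @param kind `"risk_threshold"` (treat if untreated risk >= threshold) or
#'   `"benefit_threshold"` (treat if iARR >= threshold); both inclusive.
#' @param threshold Fraction in (0, 1).
#' @param label Display label; defaults to a generated one.
#' @return A list of class `"strategy"`.
#' @export
strategy <- function(kind = c("risk_threshold", "benefit_threshold"),
                     threshold, label = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("strategy threshold must lie in (0, 1)", call. = FALSE)
  if (is.null(label)) {
    label <- sprintf("%s >= %.1f%%",
                     if (kind == "risk_threshold") "risk" else "iARR",
                     100 * threshold)
  }
  structure(list(kind = kind, threshold = threshold, label = label),
            class = "strategy")
}

#' Eligibility indicator under a strategy
#'
#' @param estimates Per-person estimates from [compute_estimates()].
#' @param strategy A [strategy()].
#' @return Logical vector aligned with `estimates`.
#' @export
eligible <- function(estimates, strategy) {
  stopifnot(inherits(strategy, "strategy"))
  switch(strategy$kind,
         risk_threshold = estimates$untreated_risk >= strategy$threshold,
         benefit_threshold = estimates$iarr >= strategy$threshold)
}

#' Minimum-benefit expansion threshold
#'
#' The smallest iARR observed among risk-eligible records; the benefit
#' strategy at this threshold is always an eligible superset of the risk
#' strategy.
#'
#' @param estimates Per-person estimates.
#' @param risk_eligible Logical indicator of risk-strategy eligibility.
#' @return Minimum eligible iARR (fraction).
#' @export
minimum_benefit_threshold <- function(estimates, risk_eligible) {
  if (!any(risk_eligible))
    stop("no risk-eligible records: minimum benefit threshold undefined",
         call. = FALSE)
  min(estimates$iarr[risk_eligible])
}

#' Calibrate a benefit threshold to match events prevented
#'
#' Searches a candidate grid — the sorted distinct observed iARR values,
#' their midpoints, and one value above the maximum (nobody treated) — for
#' the threshold whose weighted events averted
#' (`sum of weight * iarr over records with iarr >= t`) is closest to
#' `target_events`. Ties are broken toward the higher threshold (fewer
#' treated for equal prevention).
#'
#' @param estimates Per-person estimates.
#' @param weights Survey weights aligned with `estimates`.
#' @param target_events Weighted 10-year events to match (> 0 allowed to be
#'   0 for the degenerate nobody-treated case).
#' @return A list of class `"calibration_result"` with `threshold`,
#'   `achieved_events`, `target_events`, `grid`, and `rounded_threshold`
#'   (percent to one decimal).
#' @export
calibrate_benefit_threshold <- function(estimates, weights, target_events) {
  iarr <- estimates$iarr
  if (length(iarr) != length(weights))
    stop("estimates and weights are misaligned", call. = FALSE)
  if (any(!is.finite(iarr)))
    stop("iARR values must be finite for calibration", call. = FALSE)
  if (target_events < 0)
    stop("target_events must be >= 0", call. = FALSE)
  total_events <- sum(weights * pmax(iarr, 0))
  if (target_events > total_events + 1e-9 * max(total_events, 1))
    stop(sprintf(paste0("calibration target unattainable: target %.6g ",
                        "exceeds events averted at threshold 0 (%.6g)"),
                 target_events, total_events), call. = FALSE)
  vals <- sort(unique(iarr))
  mids <- if (length(vals) > 1L) (vals[-1L] + vals[-length(vals)]) / 2
          else numeric(0)
  grid <- sort(unique(c(vals, mids, max(vals) * (1 + 1e-9) + 1e-12)))
  achieved <- vapply(grid,
                     function(t) sum(weights[iarr >= t] * iarr[iarr >= t]),
                     numeric(1))
  gap <- abs(achieved - target_events)
  # ties toward the higher threshold: last index among minimal gaps
  best <- max(which(gap <= min(gap) + 0))
  structure(list(threshold = grid[best],
                 achieved_events = achieved[best],
                 target_events = target_events,
                 grid = grid,
                 rounded_threshold = round(100 * grid[best], 1)),
            class = "calibration_result")
}
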