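# Survey-weighted population projection of strategy outcomes, in the manner
# of prevention impact/efficiency projections: events averted are the
# deterministic expectation sum(weight * iARR) over the eligible set (not a
# Bernoulli simulation); bootstrap resampling of persons captures sampling
# uncertainty.

#' Weighted 10-year CVD events averted
#'
#' @param weights Survey weights (> 0), aligned with `iarrs`.
#' @param iarrs Individual absolute risk reductions.
#' @param eligible Logical eligibility indicator.
#' @return Weighted persons (expected events prevented).
#' @export
events_averted <- function(weights, iarrs, eligible) {
  if (length(weights) != length(iarrs) || length(iarrs) != length(eligible))
    stop("weights, iarrs and eligible are misaligned", call. = FALSE)
  sum(weights[eligible] * iarrs[eligible])
}

#' Average number needed to treat for a strategy
#'
#' Weighted eligible persons divided by weighted events averted, unrounded.
#'
#' @param eligible_persons Weighted persons treated.
#' @param events Weighted events averted.
#' @return Average NNT.
#' @export
average_nnt <- function(eligible_persons, events) {
  if (events <= 0) {
    if (eligible_persons > 0)
      stop("average NNT undefined: nonzero eligible persons avert no events",
           call. = FALSE)
    return(NA_real_)
  }
  eligible_persons / events
}

#' Maximum individual NNT within a strategy
#'
#' The iNNT of the least-benefiting eligible person:
#' `1 / min(iARR over the eligible set)`.
#'
#' @inheritParams events_averted
#' @return Maximum iNNT, unrounded.
#' @export
max_innt <- function(iarrs, eligible) {
  if (!any(eligible))
    stop("maximum iNNT undefined for an empty eligible set", call. = FALSE)
  m <- min(iarrs[eligible])
  if (m <= 0)
    stop("maximum iNNT undefined: eligible person with nonpositive iARR",
         call. = FALSE)
  1 / m
}

#' Lower weighted median
#'
#' Smallest value whose cumulative weight reaches half the total weight.
#'
#' @param x Values.
#' @param w Weights (> 0).
#' @return The lower weighted median.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), length(x) > 0L)
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  x[which(cumsum(w) >= sum(w) / 2)[1L]]
}

#' Summarize the eligible iARR distribution
#'
#' @inheritParams events_averted
#' @return Named numeric vector `(median, min, max)`; the median is the
#'   lower weighted median, min/max are exact extremes over eligible records.
#' @export
summarize_iarr <- function(iarrs, weights, eligible) {
  if (!any(eligible))
    stop("iARR summary undefined for an empty eligible set", call. = FALSE)
  x <- iarrs[eligible]; w <- weights[eligible]
  c(median = weighted_median(x, w), min = min(x), max = max(x))
}

#' Convert weighted persons to display units
#'
#' @param value Weighted persons (>= 0).
#' @param unit `"thousands"` or `"millions"`.
#' @param digits Display rounding (default one decimal).
#' @return Rounded value in the requested unit.
#' @export
project_to_population <- function(value, unit = c("thousands", "millions"),
                                  digits = 1L) {
  unit <- match.arg(unit)
  if (any(value < 0)) stop("value must be >= 0", call. = FALSE)
  round(value / switch(unit, thousands = 1e3, millions = 1e6), digits)
}

# Recompute one strategy-level statistic from a (resampled) cohort slice.
strategy_statistic <- function(statistic, weights, estimates, strategy) {
  elig <- eligible(estimates, strategy)
  switch(statistic,
         eligible_persons = sum(weights[elig]),
         eligible_prop = sum(weights[elig]) / sum(weights),
         events_averted = events_averted(weights, estimates$iarr, elig),
         average_nnt = {
           ev <- events_averted(weights, estimates$iarr, elig)
           if (ev <= 0) NA_real_ else sum(weights[elig]) / ev
         },
         stop(sprintf("unknown statistic '%s'", statistic), call. = FALSE))
}

#' Bootstrap percentile confidence interval for a strategy statistic
#'
#' Resamples records with replacement (weights carried with the records),
#' recomputes the statistic per replicate, and returns the 2.5th/97.5th
#' percentiles. Degenerate replicates (statistic undefined, e.g., zero
#' events averted) are counted and excluded from the percentiles.
#'
#' @param cohort Cohort `data.frame` (supplies weights).
#' @param estimates Row-aligned per-person estimates.
#' @param strategy A [strategy()].
#' @param statistic One of `"events_averted"`, `"average_nnt"`,
#'   `"eligible_persons"`, `"eligible_prop"`.
#' @param reps Number of bootstrap replicates (>= 2; default 1000).
#' @param seed Integer seed; results are reproducible given it.
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `point`, `reps`, `degenerate`
#'   (replicates excluded).
#' @export
bootstrap_ci <- function(cohort, estimates, strategy,
                         statistic = c("events_averted", "average_nnt",
                                       "eligible_persons", "eligible_prop"),
                         reps = 1000L, seed = 1L, level = 0.95) {
  statistic <- match.arg(statistic)
  if (reps < 2L) stop("reps must be >= 2", call. = FALSE)
  if (nrow(cohort) != nrow(estimates))
    stop("cohort and estimates are misaligned", call. = FALSE)
  n <- nrow(cohort)
  point <- strategy_statistic(statistic, cohort$weight, estimates, strategy)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  w <- cohort$weight
  iarr <- estimates$iarr
  key <- if (strategy$kind == "risk_threshold") estimates$untreated_risk
         else estimates$iarr
  elig_all <- key >= strategy$threshold
  stats_out <- numeric(reps)
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    wb <- w[idx]; ib <- iarr[idx]; eb <- elig_all[idx]
    stats_out[b] <- switch(statistic,
      eligible_persons = sum(wb[eb]),
      eligible_prop = sum(wb[eb]) / sum(wb),
      events_averted = sum(wb[eb] * ib[eb]),
      average_nnt = {
        ev <- sum(wb[eb] * ib[eb])
        if (ev <= 0) NA_real_ else sum(wb[eb]) / ev
      })
  }
  degenerate <- sum(is.na(stats_out))
  usable <- stats_out[!is.na(stats_out)]
  if (!length(usable))
    stop("all bootstrap replicates degenerate", call. = FALSE)
  alpha <- (1 - level) / 2
  q <- stats::quantile(usable, c(alpha, 1 - alpha), names = FALSE)
  list(lower = q[1L], upper = q[2L], point = point,
       reps = reps, degenerate = degenerate)
}

#' Full strategy-level projection
#'
#' Computes the population-level block (eligible persons and proportion,
#' events averted, average NNT) and the individual-level block (iARR
#' median/min/max, maximum iNNT), with bootstrap CIs for the population
#' statistics.
#'
#' @inheritParams bootstrap_ci
#' @param bootstrap_reps Replicates for the CIs; 0 skips CI computation.
#' @return A list of class `"strategy_result"`.
#' @export
strategy_result <- function(cohort, estimates, strategy,
                            bootstrap_reps = 1000L, seed = 1L) {
  w <- cohort$weight
  elig <- eligible(estimates, strategy)
  ev <- events_averted(w, estimates$iarr, elig)
  persons <- sum(w[elig])
  res <- list(
    strategy = strategy,
    eligible_persons = persons,
    eligible_prop = persons / sum(w),
    events_averted = ev,
    average_nnt = if (ev > 0) persons / ev else NA_real_,
    max_innt = if (any(elig)) max_innt(estimates$iarr, elig) else NA_real_,
    iarr_summary = if (any(elig)) summarize_iarr(estimates$iarr, w, elig)
                   else c(median = NA_real_, min = NA_real_, max = NA_real_),
    ci = NULL
  )
  if (bootstrap_reps > 0L) {
    stats_wanted <- c("events_averted", "eligible_persons",
                      "eligible_prop", "average_nnt")
    res$ci <- lapply(stats_wanted, function(s) {
      ci <- bootstrap_ci(cohort, estimates, strategy, statistic = s,
                         reps = bootstrap_reps, seed = seed)
      c(lower = ci$lower, upper = ci$upper)
    })
    names(res$ci) <- stats_wanted
  }
  structure(res, class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy: %s\n", x$strategy$label))
  cat(sprintf("  eligible: %.1f million (%.1f%%)\n",
              x$eligible_persons / 1e6, 100 * x$eligible_prop))
  cat(sprintf("  events averted: %.1f thousand\n", x$events_averted / 1e3))
  cat(sprintf("  average NNT: %.0f   maximum iNNT: %.0f\n",
              x$average_nnt, x$max_innt))
  cat(sprintf("  iARR median (range): %.1f%% (%.1f%%, %.1f%%)\n",
              100 * x$iarr_summary["median"], 100 * x$iarr_summary["min"],
              100 * x$iarr_summary["max"]))
  invisible(x)
}
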