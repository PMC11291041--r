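#' Time-dependent concordance with tie adjustment
#'
#' Over pairs `(i, j)` with `d_i = 1` and `T_i < T_j` — plus pairs with
#' `T_i = T_j` where `d_i = 1, d_j = 0` — a pair is concordant when the
#' predicted survival of the patient who died first, evaluated at their own
#' event time, is lower: `S(T_i | x_i) < S(T_i | x_j)`. Tied predicted
#' survival contributes weight 0.5. Returns concordant weight over
#' comparable pairs; 0.5 is chance.
#'
#' @param curves list of [survival_curve()]s, one per patient.
#' @param durations observed times.
#' @param events 0/1 event indicators.
#' @return concordance in `[0, 1]`.
#' @export
concordance <- function(curves, durations, events) {
  n <- length(durations)
  stopifnot(length(curves) == n, length(events) == n)
  ev <- which(events == 1)
  if (length(ev) == 0) stopf("no comparable pairs: no events")
  num <- 0; den <- 0
  for (i in ev) {
    comparable <- (durations > durations[i]) |
      (durations == durations[i] & events == 0)
    comparable[i] <- FALSE
    if (!any(comparable)) next
    s_i <- curve_at(curves[[i]], durations[i])
    s_j <- vapply(which(comparable), function(j) curve_at(curves[[j]], durations[i]),
                  numeric(1))
    num <- num + sum(s_i < s_j) + 0.5 * sum(s_i == s_j)
    den <- den + length(s_j)
  }
  if (den == 0) stopf("no comparable pairs")
  num / den
}

metric_report <- function(c_index, mad, nmad, n_evaluated, n_censored_excluded) {
  structure(list(c_index = c_index, mad = mad, nmad = nmad,
                 n_evaluated = n_evaluated,
                 n_censored_excluded = n_censored_excluded),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> c_index=%.4f mad=%.3f nmad=%.3f (n=%d, %d censored excluded)\n",
              x$c_index, x$mad, x$nmad, x$n_evaluated, x$n_censored_excluded))
  invisible(x)
}

#' Median absolute difference metrics
#'
#' Censored patients are excluded ("measured survival" only): `mad` is the
#' median of `|t_hat - t|` and `nmad` the median of `|t_hat - t| / t`,
#' normalising so deviations in short and long survivors count equally.
#'
#' @param medians predicted median survival times.
#' @param durations observed times.
#' @param events 0/1 event indicators.
#' @return a `metric_report` with the `mad`/`nmad` fields set
#'   (`c_index = NA`).
#' @export
mad_metrics <- function(medians, durations, events) {
  stopifnot(length(medians) == length(durations),
            length(events) == length(durations))
  keep <- events == 1
  if (!any(keep)) stopf("no uncensored patients to evaluate")
  err <- abs(as.numeric(medians)[keep] - durations[keep])
  metric_report(NA_real_, median(err), median(err / durations[keep]),
                sum(keep), sum(!keep))
}

# full report from per-patient curves
score_curves <- function(curves, durations, events) {
  meds <- vapply(curves, function(cv) as.numeric(median_survival(cv)), numeric(1))
  mm <- mad_metrics(meds, durations, events)
  metric_report(concordance(curves, durations, events), mm$mad, mm$nmad,
                mm$n_evaluated, mm$n_censored_excluded)
}

# Harrell-style concordance of a raw prognostic score (higher score =
# longer predicted survival); used as the oracle ceiling on synthetic data
# where the true linear predictor is known
#' Concordance of a raw prognostic score
#'
#' Harrell-type pairwise concordance of a score whose larger values mean
#' longer predicted survival; on synthetic cohorts the true linear predictor
#' gives the oracle ceiling for any fitted model.
#'
#' @param score numeric prognostic score, higher = longer survival.
#' @param durations observed times.
#' @param events 0/1 event indicators.
#' @return concordance in `[0, 1]`.
#' @export
score_concordance <- function(score, durations, events) {
  n <- length(durations)
  num <- 0; den <- 0
  for (i in which(events == 1)) {
    comparable <- (durations > durations[i]) |
      (durations == durations[i] & events == 0)
    comparable[i] <- FALSE
    if (!any(comparable)) next
    num <- num + sum(score[i] < score[comparable]) +
      0.5 * sum(score[i] == score[comparable])
    den <- den + sum(comparable)
  }
  if (den == 0) stopf("no comparable pairs")
  num / den
}
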