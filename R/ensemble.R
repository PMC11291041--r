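#' Focused-training ensemble configuration
#'
#' @param window dynamic window fraction `f`: the stage-2 focused cohort
#'   holds training patients with measured survival within
#'   `[t1 (1 - f), t1 (1 + f)]` of the stage-1 prediction `t1`, so the
#'   absolute window is larger for longer predictions.
#' @param extra_epochs additional training epochs on the focused cohort.
#' @param min_cohort smallest focused cohort worth retraining on; below it
#'   stage 2 is skipped and the stage-1 prediction stands (fallback).
#' @param lr stage-2 learning rate; `NULL` reuses the stage-1 rate.
#' @param include_censored also admit censored rows whose censoring time
#'   falls inside the window (off by default: the cohort is defined on
#'   measured survival).
#' @param cache_digits significant digits of `t1` used as the batch-mode
#'   cache key: patients whose stage-1 predictions agree to this precision
#'   share one fine-tuned stage-2 model. Smaller values bound compute at a
#'   small fidelity cost.
#' @return an `ensemble_config`.
#' @export
ensemble_config <- function(window = 0.7, extra_epochs = 200, min_cohort = 50,
                            lr = NULL, include_censored = FALSE,
                            cache_digits = 2) {
  stopifnot(window > 0, window < 1, extra_epochs >= 0, min_cohort >= 0,
            cache_digits >= 1)
  structure(list(window = window, extra_epochs = as.integer(extra_epochs),
                 min_cohort = as.integer(min_cohort), lr = lr,
                 include_censored = isTRUE(include_censored),
                 cache_digits = as.integer(cache_digits)),
            class = "ensemble_config")
}

#' Select the focused training cohort around a stage-1 prediction
#'
#' Rows with an observed event and duration within `t1 * (1 - f)` to
#' `t1 * (1 + f)`; censored rows are excluded unless `include_censored`.
#'
#' @param train the training `survival_dataset`.
#' @param t1 stage-1 predicted median survival (positive).
#' @param f window fraction in (0, 1).
#' @param include_censored admit censored rows inside the window.
#' @return integer row indices into `train` (possibly empty).
#' @export
select_focused_cohort <- function(train, t1, f, include_censored = FALSE) {
  stopifnot(t1 > 0)
  lo <- t1 * (1 - f); hi <- t1 * (1 + f)
  inside <- train$durations >= lo & train$durations <= hi
  which(inside & (train$events == 1 | include_censored))
}

#' Two-stage focused-training ensemble prediction
#'
#' Stage 1 predicts a median survival `t1` with the trained model. Stage 2
#' copies the model and continues training it for `extra_epochs` on the
#' focused cohort only — training patients whose measured survival lies
#' within the `+/- window` dynamic range of `t1` — with the grid and
#' encoding frozen, then re-predicts. If the focused cohort is smaller than
#' `min_cohort` the stage-1 prediction is returned with the fallback flag
#' set. The stage-1 model object is never mutated.
#'
#' @param stage1 a fitted `hazard_model` trained on `train`'s encoding.
#' @param train the training `survival_dataset` (complete).
#' @param x encoded design row, or one-row data.frame of raw covariates.
#' @param config an [ensemble_config()].
#' @param seed seed for the stage-2 training stream.
#' @param cache optional environment: stage-2 models are cached keyed by
#'   `signif(t1, 2)` so batch prediction stays tractable (patients with
#'   near-identical stage-1 predictions share a focused cohort).
#' @return an `ensemble_prediction`: `t1`, `t2` (final), `cohort_size`,
#'   `fallback`, per-stage extrapolation flags.
#' @export
ensemble_predict <- function(stage1, train, x, config = ensemble_config(),
                             seed = 0, cache = NULL) {
  X <- if (is.data.frame(x)) encode_rows(stage1, x, train$schema) else
    encode_rows(stage1, x)
  m1 <- median_survival(predict_curve(stage1, X[1, ]))
  t1 <- as.numeric(m1)
  idx <- select_focused_cohort(train, t1, config$window,
                               config$include_censored)
  if (length(idx) < config$min_cohort || config$extra_epochs == 0) {
    return(structure(list(t1 = t1, t2 = t1, cohort_size = length(idx),
                          fallback = TRUE,
                          extrapolated = c(stage1 = attr(m1, "extrapolated"),
                                           stage2 = attr(m1, "extrapolated"))),
                     class = "ensemble_prediction"))
  }
  key <- as.character(signif(t1, config$cache_digits))
  if (is.null(stage1$provenance))
    stopf("stage-1 model must carry encoding provenance (fit it on an encode() design)")
  model2 <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
  else {
    design2 <- encode(subset_dataset(train, idx),
                      fit_stats = stage1$provenance)
    mod <- continue_training(stage1, design2, train$durations[idx],
                             train$events[idx], config$extra_epochs,
                             lr = config$lr, seed = seed)
    if (!is.null(cache)) cache[[key]] <- mod
    mod
  }
  m2 <- median_survival(predict_curve(model2, X[1, ]))
  structure(list(t1 = t1, t2 = as.numeric(m2), cohort_size = length(idx),
                 fallback = FALSE,
                 extrapolated = c(stage1 = attr(m1, "extrapolated"),
                                  stage2 = attr(m2, "extrapolated"))),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> t1=%.2f t2=%.2f (focused n=%d%s)\n",
              x$t1, x$t2, x$cohort_size, if (x$fallback) ", fallback" else ""))
  invisible(x)
}
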