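#' Rank-combined model selection
#'
#' Configurations are ranked separately by concordance (descending), median
#' absolute difference (ascending) and normalised median absolute difference
#' (ascending); tied values share the mean rank. The configuration with the
#' lowest rank sum wins; rank-sum ties break by higher concordance, then
#' lower mad, then configuration order (logged).
#'
#' @param reports list of `metric_report`s, one per configuration; names
#'   label the configurations.
#' @return a `tuning_result` with the rank table and `selected` index.
#' @export
rank_select <- function(reports) {
  stopifnot(length(reports) >= 1)
  tab <- data.frame(
    configuration = names(reports) %||% paste0("config", seq_along(reports)),
    c_index = vapply(reports, `[[`, numeric(1), "c_index"),
    mad = vapply(reports, `[[`, numeric(1), "mad"),
    nmad = vapply(reports, `[[`, numeric(1), "nmad"),
    stringsAsFactors = FALSE)
  tab$rank_c <- rank(-tab$c_index, ties.method = "average")
  tab$rank_mad <- rank(tab$mad, ties.method = "average")
  tab$rank_nmad <- rank(tab$nmad, ties.method = "average")
  tab$rank_sum <- tab$rank_c + tab$rank_mad + tab$rank_nmad
  best <- which(tab$rank_sum == min(tab$rank_sum))
  if (length(best) > 1) {
    tte_log("rank_select.tie", candidates = tab$configuration[best])
    best <- best[order(-tab$c_index[best], tab$mad[best], best)]
  }
  structure(list(table = tab, selected = best[1],
                 selected_configuration = tab$configuration[best[1]]),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> selected:", x$selected_configuration, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Define a staged hyperparameter grid
#'
#' The search space is explored in discrete stages — model family, then
#' layer structure, then learning rate, then interval/knot count — each
#' stage fixing the winner of the previous one, so a `k1 x k2 x ... grid`
#' costs `k1 + k2 + ...` evaluations instead of the full product. "Knots"
#' means the number of hazard intervals for the deep model and the number of
#' internal spline knots for the parametric model; layer-structure and
#' learning-rate stages do not apply to the parametric family and are
#' skipped when it wins.
#'
#' @param family candidate families.
#' @param hidden list of hidden-layer vectors.
#' @param lr candidate learning rates.
#' @param knots candidate interval/knot counts.
#' @param epochs,batch_size fixed training settings used throughout.
#' @return a `staged_grid`.
#' @export
staged_grid <- function(family = list("pchazard", "royston_parmar"),
                        hidden = list(16, c(32, 32)),
                        lr = list(0.1, 0.01),
                        knots = list(5, 10),
                        epochs = 50, batch_size = 256) {
  structure(list(stages = list(family = family, hidden = hidden, lr = lr,
                               knots = knots),
                 epochs = epochs, batch_size = batch_size),
            class = "staged_grid")
}

grid_config <- function(grid, choices) {
  if (choices$family == "royston_parmar") {
    # spline knot counts: reuse the knots axis, but a Weibull baseline needs
    # 0 internal knots available, so map interval counts >= 5 down
    model_config("royston_parmar",
                 internal_knots = min(choices$knots %||% 0, 3))
  } else {
    model_config("pchazard",
                 net = hazardnet_config(hidden = choices$hidden,
                                        lr = choices$lr,
                                        m = max(1, choices$knots),
                                        epochs = grid$epochs,
                                        batch_size = grid$batch_size))
  }
}

# evaluate one configuration by inner "10-fold" resampling: each fold is a
# fresh random 80/20 split of the inner data with its own seed; per-patient
# curves from the folds where the patient was held out are median-aggregated
# before scoring
evaluate_config <- function(config, data, folds = 10, seed = 1,
                            train_frac = 0.8) {
  n <- data$n
  enc <- NULL # per-fold encodings: stats always come from the fold's train
  per_patient <- vector("list", n)
  for (f in seq_len(folds)) {
    fseed <- derive_seed(seed, "inner_fold", f)
    tr <- with_seed(fseed, sort(sample.int(n, max(2, floor(train_frac * n)))))
    va <- setdiff(seq_len(n), tr)
    if (!length(va)) next
    dtr <- subset_dataset(data, tr)
    etr <- encode(dtr)
    fit <- fit_survival_model(config, etr, dtr$durations, dtr$events,
                              seed = fseed)
    dva <- subset_dataset(data, va)
    eva <- encode(dva, fit_stats = etr)
    for (ii in seq_along(va)) {
      cv <- predict_curve(fit, eva$matrix[ii, ])
      pid <- va[ii]
      per_patient[[pid]] <- c(per_patient[[pid]], list(cv))
    }
  }
  seen <- which(vapply(per_patient, length, integer(1)) > 0)
  if (!length(seen)) stopf("no held-out patients across folds")
  curves <- lapply(per_patient[seen], function(cs)
    if (length(cs) == 1L) cs[[1]] else aggregate_curves(cs))
  score_curves(curves, data$durations[seen], data$events[seen])
}

#' Nested, staged hyperparameter tuning
#'
#' The data are split 80/20 once (outer); the staged grid is searched inside
#' the 80% with [evaluate_config()] (10 random 80/20 folds per
#' configuration, median-aggregated per-patient predictions, rank-combined
#' selection per stage). The final winner is retrained as a
#' `folds`-member bag on the inner data and re-evaluated on the untouched
#' outer 20%. Outer rows never influence encodings or fits before that
#' final evaluation.
#'
#' @param grid a [staged_grid()].
#' @param data a complete `survival_dataset`.
#' @param seed master seed.
#' @param folds inner folds per configuration (default 10).
#' @param outer_frac outer holdout fraction (default 0.2).
#' @return a `tuning_result` with `trace` (per-stage rank tables),
#'   `selected_config`, `n_evaluated` and `outer_report`.
#' @export
nested_tune <- function(grid, data, seed = 1, folds = 10, outer_frac = 0.2) {
  stopifnot(inherits(grid, "staged_grid"))
  if (!all(lengths(grid$stages) >= 1)) stopf("every grid stage needs candidates")
  n <- data$n
  outer <- with_seed(derive_seed(seed, "outer_split"),
                     sort(sample.int(n, floor(outer_frac * n))))
  inner <- setdiff(seq_len(n), outer)
  tte_log("nested_tune.outer_split", n_outer = length(outer),
          n_inner = length(inner))
  dinner <- subset_dataset(data, inner)

  defaults <- list(family = grid$stages$family[[1]],
                   hidden = grid$stages$hidden[[1]],
                   lr = grid$stages$lr[[1]],
                   knots = grid$stages$knots[[1]])
  choices <- defaults
  trace <- list()
  n_evaluated <- 0L
  for (stage in names(grid$stages)) {
    cands <- grid$stages[[stage]]
    if (choices$family == "royston_parmar" && stage %in% c("hidden", "lr")) {
      tte_log("nested_tune.stage_skipped", stage = stage,
              reason = "not applicable to parametric family")
      next
    }
    if (length(cands) == 1L) {
      choices[[stage]] <- cands[[1]]
      next
    }
    reports <- list()
    for (ci in seq_along(cands)) {
      trial <- choices
      trial[[stage]] <- cands[[ci]]
      cfg <- grid_config(grid, trial)
      lab <- paste0(stage, "=", paste(format(cands[[ci]]), collapse = "x"))
      reports[[lab]] <- evaluate_config(cfg, dinner, folds = folds,
                                        seed = derive_seed(seed, stage, ci))
      n_evaluated <- n_evaluated + 1L
    }
    sel <- rank_select(reports)
    trace[[stage]] <- sel$table
    choices[[stage]] <- cands[[sel$selected]]
    tte_log("nested_tune.stage", stage = stage,
            winner = sel$selected_configuration)
  }

  final_config <- grid_config(grid, choices)
  bag <- train_bag(final_config, dinner, bag_size = folds, subsample = 0.8,
                   seed = derive_seed(seed, "final_bag"))
  douter <- subset_dataset(data, outer)
  curves <- lapply(seq_len(douter$n), function(i)
    bag_predict(bag, douter$data[i, , drop = FALSE]))
  outer_report <- score_curves(curves, douter$durations, douter$events)
  structure(list(trace = trace, choices = choices,
                 selected_config = final_config, n_evaluated = n_evaluated,
                 outer_report = outer_report, bag = bag,
                 outer_rows = outer),
            class = "nested_tuning_result")
}
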