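#' Imputation configuration
#'
#' @param rounds number of independently seeded imputation rounds averaged
#'   into the final value (continuous: mean; categorical: majority vote).
#' @param max_iterations cap on column sweeps within a round; a round also
#'   stops when the change in the imputed matrix first increases (the
#'   original MissForest criterion).
#' @param trees trees per random forest.
#' @param include_outcome add log(duration) and the event indicator to the
#'   predictor set of every forest.
#' @param seed integer master seed for the imputation streams.
#' @return an `imputation_config`.
#' @export
imputation_config <- function(rounds = 10, max_iterations = 10, trees = 100,
                              include_outcome = FALSE, seed = 1) {
  stopifnot(rounds >= 1, trees >= 1, max_iterations >= 1)
  structure(list(rounds = as.integer(rounds),
                 max_iterations = as.integer(max_iterations),
                 trees = as.integer(trees),
                 include_outcome = isTRUE(include_outcome),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

# one-hot/raw predictor matrix from the current (complete) imputed table,
# excluding one column, optionally with outcome predictors appended
encode_predictors <- function(cur, covs, exclude, outcome_pred = NULL) {
  pieces <- list()
  for (nm in names(covs)) {
    if (nm == exclude) next
    col <- covs[[nm]]
    if (col$kind == "continuous") {
      pieces[[nm]] <- matrix(cur[[nm]], ncol = 1)
    } else {
      x <- as.character(cur[[nm]])
      pieces[[nm]] <- vapply(col$levels, function(lv) as.numeric(x == lv),
                             numeric(nrow(cur)))
      if (nrow(cur) == 1L) pieces[[nm]] <- matrix(pieces[[nm]], nrow = 1)
    }
  }
  if (!is.null(outcome_pred)) pieces[["..outcome"]] <- outcome_pred
  do.call(cbind, pieces)
}

col_mode <- function(x) {
  # modal level; ties break to the lowest level index
  tab <- table(x)
  levels(x)[levels(x) == names(tab)[which.max(tab)]][1]
}

# One full MissForest run (R rounds, averaged). `mask` marks cells to treat
# as missing. `outcome_pred` is an n x 2 matrix (log duration, event) or NULL.
# `freeze` is an optional logical vector of rows whose outcome_pred entries
# were neutralised by the caller (single-patient validation imputation).
missforest_engine <- function(data, mask, covs, outcome_pred, config) {
  n <- nrow(data)
  miss_count <- colSums(mask)
  target_cols <- names(covs)[miss_count > 0]
  if (length(target_cols) == 0L) return(data)
  for (nm in target_cols) {
    if (miss_count[nm] == n) stopf("column '%s' is entirely missing", nm)
  }
  order_cols <- target_cols[order(miss_count[target_cols])] # least missing first

  work <- data
  for (nm in target_cols) work[[nm]][mask[, nm]] <- NA

  round_results <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    rseed <- derive_seed(config$seed, "missforest.round", r)
    cur <- work
    # initialisation: column mean (continuous) / mode (categorical)
    for (nm in target_cols) {
      obs <- !mask[, nm]
      if (covs[[nm]]$kind == "continuous") {
        cur[[nm]][mask[, nm]] <- mean(data[[nm]][obs])
      } else {
        cur[[nm]][mask[, nm]] <- col_mode(data[[nm]][obs])
      }
    }
    prev_change <- Inf
    best <- cur
    for (it in seq_len(config$max_iterations)) {
      before <- cur
      for (j in seq_along(order_cols)) {
        nm <- order_cols[j]
        obs <- !mask[, nm]
        Xall <- encode_predictors(cur, covs, nm, outcome_pred)
        fseed <- derive_seed(rseed, "col", (it - 1L) * length(order_cols) + j)
        y <- if (covs[[nm]]$kind == "continuous") data[[nm]][obs]
             else droplevels_keep(data[[nm]][obs])
        fit <- rf_fit(Xall[obs, , drop = FALSE], y, ntree = config$trees,
                      seed = fseed)
        pred <- rf_predict(fit, Xall[mask[, nm], , drop = FALSE])
        if (covs[[nm]]$kind == "continuous") {
          cur[[nm]][mask[, nm]] <- pred
        } else {
          cur[[nm]][mask[, nm]] <- as.character(pred)
        }
      }
      change <- sweep_change(before, cur, mask, covs, target_cols)
      if (change > prev_change) { cur <- before; break } # first increase: revert
      best <- cur
      prev_change <- change
      if (change == 0) break
    }
    round_results[[r]] <- best
  }

  # aggregate rounds: mean (continuous), majority vote with lowest-level
  # tie-break (categorical)
  out <- data
  for (nm in target_cols) {
    cells <- which(mask[, nm])
    if (covs[[nm]]$kind == "continuous") {
      vals <- vapply(round_results, function(d) d[[nm]][cells],
                     numeric(length(cells)))
      if (length(cells) == 1L) vals <- matrix(vals, nrow = 1)
      out[[nm]][cells] <- rowMeans(vals)
    } else {
      levs <- covs[[nm]]$levels
      votes <- vapply(round_results, function(d) as.character(d[[nm]][cells]),
                      character(length(cells)))
      if (length(cells) == 1L) votes <- matrix(votes, nrow = 1)
      win <- apply(votes, 1, function(v) {
        counts <- vapply(levs, function(lv) sum(v == lv), numeric(1))
        levs[which.max(counts)]
      })
      out[[nm]][cells] <- win
    }
  }
  out
}

# keep all schema levels on the factor (forest must be able to predict any)
droplevels_keep <- function(x) x

sweep_change <- function(before, cur, mask, covs, target_cols) {
  num <- 0; den <- 0; cat_changed <- 0; cat_total <- 0
  for (nm in target_cols) {
    cells <- mask[, nm]
    if (covs[[nm]]$kind == "continuous") {
      num <- num + sum((cur[[nm]][cells] - before[[nm]][cells])^2)
      den <- den + sum(cur[[nm]][cells]^2)
    } else {
      cat_changed <- cat_changed +
        sum(as.character(cur[[nm]][cells]) != as.character(before[[nm]][cells]))
      cat_total <- cat_total + sum(cells)
    }
  }
  val <- 0
  if (den > 0) val <- val + num / den
  if (cat_total > 0) val <- val + cat_changed / cat_total
  val
}

outcome_predictors <- function(dataset) {
  cbind(log_duration = log(dataset$durations), event = dataset$events)
}

#' Iterative random-forest imputation of missing covariates
#'
#' Each round initialises missing cells with the column mean/mode, then
#' repeatedly sweeps the covariates in ascending order of missing count,
#' fitting a random forest for each on the rows where it is observed
#' (predictors: all other covariates, plus log-duration and the event
#' indicator when `include_outcome`) and predicting its missing cells. A
#' round stops when the change in the imputed matrix first increases, or
#' after `max_iterations` sweeps. The final value of a cell is the mean over
#' rounds (continuous) or the modal value over rounds (categorical).
#'
#' @param dataset a `survival_dataset`, possibly with missing covariates.
#' @param config an [imputation_config()].
#' @return a complete `survival_dataset`; observed cells are never altered.
#' @export
missforest_impute <- function(dataset, config = imputation_config()) {
  mask <- missing_mask(dataset)
  if (!any(mask)) return(dataset)
  covs <- schema_covariates(dataset$schema)
  op <- if (config$include_outcome) outcome_predictors(dataset) else NULL
  done <- missforest_engine(dataset$data, mask, covs, op, config)
  tte_log("missforest_impute", n = dataset$n, n_missing = sum(mask),
          rounds = config$rounds, include_outcome = config$include_outcome)
  survival_dataset(done, dataset$durations, dataset$events, dataset$schema)
}

#' Leakage-safe imputation of one validation patient
#'
#' The imputation is run on the concatenation of the training cohort and
#' exactly this one patient, and only the patient's completed row is
#' returned; separate calls for different validation patients never see each
#' other's rows. The patient's own outcome never feeds the imputation, even
#' with `include_outcome = TRUE` (it is unknown at prediction time): the
#' patient's outcome-predictor entries are neutralised to the training means
#' while training rows contribute their true outcomes.
#'
#' @param train the training `survival_dataset`.
#' @param patient a single-row `survival_dataset` (its duration/event are
#'   carried through but never used), or a one-row data.frame of covariates.
#' @param config an [imputation_config()].
#' @return the patient with covariates completed, same type as supplied.
#' @export
impute_validation_patient <- function(train, patient,
                                      config = imputation_config()) {
  as_df <- is.data.frame(patient)
  if (as_df) {
    pdata <- patient
    pdur <- NA_real_; pevt <- NA_real_
  } else {
    stopifnot(inherits(patient, "survival_dataset"), patient$n == 1L)
    pdata <- patient$data
    pdur <- patient$durations; pevt <- patient$events
  }
  covs <- schema_covariates(train$schema)
  pdata <- as.data.frame(pdata)[, names(covs), drop = FALSE]
  data <- rbind(train$data, stats::setNames(pdata, names(train$data)))
  mask <- rbind(missing_mask(train), vapply(pdata, is.na, logical(1)))
  if (!any(mask[nrow(data), ])) return(patient)
  op <- NULL
  if (config$include_outcome) {
    op <- outcome_predictors(train)
    # neutral outcome for the patient: training means, never its own outcome
    op <- rbind(op, colMeans(op))
  }
  done <- missforest_engine(data, mask, covs, op, config)
  prow <- done[nrow(done), , drop = FALSE]
  rownames(prow) <- NULL
  tte_log("impute_validation_patient", n_train = train$n,
          include_outcome = config$include_outcome)
  if (as_df) prow
  else survival_dataset(prow, pdur, pevt, train$schema)
}

#' Mask-and-score evaluation of imputation accuracy
#'
#' Per round, `points_per_covariate` observed cells of every evaluated
#' covariate are masked uniformly at random and re-imputed with
#' [missforest_impute()]; (imputed, true) pairs are pooled across rounds and
#' scored — Pearson correlation with a two-sided zero-correlation p-value
#' for continuous covariates, accuracy for categorical ones.
#'
#' @param dataset a `survival_dataset`.
#' @param points_per_covariate cells masked per covariate per round.
#' @param rounds masking rounds.
#' @param config an [imputation_config()]; its `seed` also drives masking.
#' @return an `imputation_report`: data.frame `per_covariate` plus settings.
#' @export
mask_and_score <- function(dataset, points_per_covariate = 50, rounds = 50,
                           config = imputation_config()) {
  covs <- schema_covariates(dataset$schema)
  mask0 <- missing_mask(dataset)
  n_obs <- colSums(!mask0)
  eval_cols <- names(covs)[n_obs > points_per_covariate]
  skipped <- setdiff(names(covs), eval_cols)
  if (length(skipped))
    warnf("excluding covariate(s) with too few observed values: %s",
          paste(skipped, collapse = ", "))
  if (!length(eval_cols)) stopf("no covariate has enough observed values")

  pairs <- stats::setNames(
    lapply(eval_cols, function(nm) list(imputed = c(), truth = c())), eval_cols)
  for (r in seq_len(rounds)) {
    rseed <- derive_seed(config$seed, "mask_and_score.round", r)
    masked_cells <- with_seed(rseed, {
      lapply(eval_cols, function(nm) {
        sample(which(!mask0[, nm]), points_per_covariate)
      })
    })
    names(masked_cells) <- eval_cols
    ds_masked <- dataset
    for (nm in eval_cols) ds_masked$data[[nm]][masked_cells[[nm]]] <- NA
    rconfig <- config
    rconfig$seed <- derive_seed(config$seed, "mask_and_score.impute", r)
    done <- missforest_impute(ds_masked, rconfig)
    for (nm in eval_cols) {
      cells <- masked_cells[[nm]]
      imp <- done$data[[nm]][cells]
      tru <- dataset$data[[nm]][cells]
      if (covs[[nm]]$kind != "continuous") {
        imp <- as.character(imp); tru <- as.character(tru)
      }
      pairs[[nm]]$imputed <- c(pairs[[nm]]$imputed, imp)
      pairs[[nm]]$truth <- c(pairs[[nm]]$truth, tru)
    }
  }

  per_cov <- do.call(rbind, lapply(eval_cols, function(nm) {
    imp <- pairs[[nm]]$imputed; tru <- pairs[[nm]]$truth
    if (covs[[nm]]$kind == "continuous") {
      ct <- stats::cor.test(imp, tru)
      data.frame(covariate = nm, kind = "continuous",
                 statistic = unname(ct$estimate), p_value = ct$p.value,
                 n_pairs = length(imp), stringsAsFactors = FALSE)
    } else {
      data.frame(covariate = nm, kind = covs[[nm]]$kind,
                 statistic = mean(imp == tru), p_value = NA_real_,
                 n_pairs = length(imp), stringsAsFactors = FALSE)
    }
  }))
  structure(list(per_covariate = per_cov,
                 points_per_covariate = points_per_covariate,
                 rounds = rounds, excluded = skipped,
                 pairs = pairs),
            class = "imputation_report")
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("<imputation_report> %d rounds x %d points per covariate\n",
              x$rounds, x$points_per_covariate))
  print(x$per_covariate, row.names = FALSE)
  invisible(x)
}
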