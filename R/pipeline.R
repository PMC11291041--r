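#' Run the full prediction pipeline from one configuration
#'
#' Wires the stages simulate (optional) -> train/validation split ->
#' imputation -> tune (optional) -> bag training -> prediction (optionally
#' with the focused-training ensemble) -> evaluation -> counterfactual
#' (optional), writing every artifact plus the resolved configuration and
#' seed under `outdir`. Validation rows only ever pass through
#' [impute_validation_patient()] and frozen encoders; structured log events
#' (see [tte_log()]) record which rows each stage touched so the leakage
#' audit can assert this.
#'
#' @param config a named list (or path to a YAML file) with blocks:
#'   `seed`, `outdir`, and either `cohort`/`schema` paths or
#'   `simulate = list(preset = "als"|"af", n = )`; optional blocks
#'   `split` (validation fraction), `imputation`, `model`, `ensemble`,
#'   `tune`, `counterfactual`. Unset values take module defaults.
#' @return invisibly, a list with the artifacts' paths, the validation
#'   metrics and the trained bag.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  outdir <- config$outdir %||% stopf("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  old_log <- getOption("pchaz.log_file")
  if (is.null(old_log)) {
    options(pchaz.log_file = file.path(outdir, "events.jsonl"))
    on.exit(options(pchaz.log_file = old_log), add = TRUE)
  }

  # ---- stage: load or simulate ------------------------------------------
  if (!is.null(config$simulate)) {
    preset <- switch(config$simulate$preset %||% "als",
                     als = als_like_preset(config$simulate$n %||% 1000, seed),
                     af = af_like_preset(config$simulate$n %||% 1000, seed),
                     stopf("unknown preset '%s'", config$simulate$preset))
    cohort <- generate_cohort(preset)
    write_cohort(cohort, file.path(outdir, "cohort.csv"))
    truth <- attr(cohort, "truth")
    write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
    tte_log("pipeline.simulate", preset = config$simulate$preset %||% "als",
            n = cohort$n)
  } else {
    schema <- read_schema(config$schema)
    cohort <- read_cohort(config$cohort, schema)
    tte_log("pipeline.load", path = config$cohort, n = cohort$n)
  }

  # ---- stage: outer split ------------------------------------------------
  val_frac <- config$split %||% 0.2
  val_idx <- with_seed(derive_seed(seed, "pipeline.split"),
                       sort(sample.int(cohort$n, floor(val_frac * cohort$n))))
  train_idx <- setdiff(seq_len(cohort$n), val_idx)
  train <- subset_dataset(cohort, train_idx)
  validation <- subset_dataset(cohort, val_idx)
  tte_log("pipeline.split", n_train = train$n, n_validation = validation$n,
          validation_rows = val_idx)

  # ---- stage: imputation -------------------------------------------------
  imp_cfg <- do.call(imputation_config,
                     modifyList(list(seed = derive_seed(seed, "impute")),
                                config$imputation %||% list()))
  train_imp <- missforest_impute(train, imp_cfg)
  tte_log("pipeline.impute_train", rows = train_idx)
  write_cohort(train_imp, file.path(outdir, "imputed_train.csv"))

  val_rows <- vector("list", validation$n)
  for (i in seq_len(validation$n)) {
    val_rows[[i]] <- impute_validation_patient(
      train_imp, subset_dataset(validation, i), imp_cfg)
    tte_log("pipeline.impute_validation_patient", row = val_idx[i])
  }
  validation_imp <- Reduce(bind_datasets, val_rows)

  # ---- stage: tune (optional) -------------------------------------------
  model_block <- config$model %||% list()
  if (isTRUE(config$tune$enabled %||% FALSE)) {
    grid <- do.call(staged_grid, config$tune$grid %||% list())
    tuned <- nested_tune(grid, train_imp, seed = derive_seed(seed, "tune"),
                         folds = config$tune$folds %||% 10)
    jsonlite::write_json(
      list(choices = tuned$choices,
           n_evaluated = tuned$n_evaluated,
           outer = unclass(tuned$outer_report),
           trace = lapply(tuned$trace, as.list)),
      file.path(outdir, "tuning.json"), auto_unbox = TRUE, digits = NA)
    mc <- tuned$selected_config
    tte_log("pipeline.tune", n_evaluated = tuned$n_evaluated)
  } else {
    net <- do.call(hazardnet_config,
                   modifyList(list(seed = derive_seed(seed, "net")),
                              model_block$net %||% list()))
    mc <- model_config(model_block$family %||% "pchazard", net = net,
                       internal_knots = model_block$internal_knots %||% 0)
  }

  # ---- stage: train bag --------------------------------------------------
  bag <- train_bag(mc, train_imp,
                   bag_size = model_block$bag_size %||% 10,
                   subsample = model_block$subsample %||% 0.8,
                   seed = derive_seed(seed, "bag"))
  save_hazard_model(bag$models[[1]], file.path(outdir, "model_member1"))

  # ---- stage: predict ----------------------------------------------------
  ens_block <- config$ensemble %||% list()
  use_ensemble <- isTRUE(ens_block$enabled %||% FALSE)
  enc_val <- encode(validation_imp, fit_stats = bag$provenance)
  tte_log("pipeline.encode_validation", rows = val_idx, frozen = TRUE)
  preds <- data.frame(row = val_idx,
                      duration = validation$durations,
                      event = validation$events)
  curves <- vector("list", validation$n)
  if (use_ensemble) {
    ecfg <- do.call(ensemble_config,
                    ens_block[setdiff(names(ens_block), "enabled")])
    caches <- lapply(bag$models, function(m) new.env())
    for (i in seq_len(validation$n)) {
      per_member <- lapply(seq_along(bag$models), function(b)
        ensemble_predict(bag$models[[b]], train_imp, enc_val$matrix[i, ],
                         ecfg, seed = derive_seed(seed, "ensemble", b),
                         cache = caches[[b]]))
      preds$stage1[i] <- median(vapply(per_member, `[[`, numeric(1), "t1"))
      preds$stage2[i] <- median(vapply(per_member, `[[`, numeric(1), "t2"))
      preds$fallback[i] <- all(vapply(per_member, `[[`, logical(1), "fallback"))
      preds$median_survival[i] <- preds$stage2[i]
      curves[[i]] <- bag_predict(bag, enc_val$matrix[i, ])
    }
  } else {
    for (i in seq_len(validation$n)) {
      curves[[i]] <- bag_predict(bag, enc_val$matrix[i, ])
      med <- median_survival(curves[[i]])
      preds$median_survival[i] <- as.numeric(med)
      preds$extrapolated[i] <- isTRUE(attr(med, "extrapolated"))
    }
  }
  tte_log("pipeline.predict", rows = val_idx, ensemble = use_ensemble)
  write.csv(preds, file.path(outdir, "predictions.csv"), row.names = FALSE)

  curves_long <- do.call(rbind, lapply(seq_along(curves), function(i)
    data.frame(row = val_idx[i], time = curves[[i]]$times,
               survival = curves[[i]]$surv)))
  write.csv(curves_long, file.path(outdir, "curves.csv"), row.names = FALSE)

  # ---- stage: evaluate ---------------------------------------------------
  metrics <- mad_metrics(preds$median_survival, validation$durations,
                         validation$events)
  metrics$c_index <- concordance(curves, validation$durations,
                                 validation$events)
  jsonlite::write_json(unclass(metrics), file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  tte_log("pipeline.evaluate", c_index = metrics$c_index, mad = metrics$mad)

  # ---- stage: counterfactual (optional) ---------------------------------
  if (isTRUE(config$counterfactual$enabled %||% FALSE)) {
    kinds <- schema_kinds(train$schema)
    tcol <- train$schema$columns[[which(kinds == "treatment")]]
    grid <- quartile_grid(train_imp)
    recs <- recommend_grid(bag, grid, tcol)
    write.csv(recs, file.path(outdir, "recommendations.csv"),
              row.names = FALSE)
    tte_log("pipeline.counterfactual", n_patients = nrow(recs))
  }

  jsonlite::write_json(list(config = config, seed = seed),
                       file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(outdir = outdir, metrics = metrics, bag = bag,
                 predictions = preds))
}
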