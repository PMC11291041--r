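#' Manufacture a quartile grid of synthetic patients
#'
#' Every continuous covariate contributes four representative values (the
#' within-quartile medians of its observed values; covariates with fewer
#' than four distinct values contribute their distinct values, logged);
#' every categorical covariate contributes its levels. The grid is the
#' Cartesian product over all covariates except the treatment column, so
#' treatment can be varied per synthetic patient afterwards.
#'
#' @param dataset a complete `survival_dataset`.
#' @param schema optional schema (defaults to the dataset's).
#' @return a `patient_grid`: data.frame of synthetic patients with a
#'   `representatives` attribute recording each value's provenance.
#' @export
quartile_grid <- function(dataset, schema = NULL) {
  schema <- schema %||% dataset$schema
  if (anyNA(dataset$data)) stopf("dataset must be complete (impute first)")
  covs <- schema_covariates(schema)
  covs <- covs[vapply(covs, `[[`, character(1), "kind") != "treatment"]
  if (!any(vapply(covs, `[[`, character(1), "kind") == "continuous"))
    stopf("need at least one continuous covariate")
  reps <- list()
  for (nm in names(covs)) {
    col <- covs[[nm]]
    if (col$kind == "continuous") {
      x <- dataset$data[[nm]]
      if (length(unique(x)) < 4) {
        tte_log("quartile_grid.few_distinct", covariate = nm,
                n_distinct = length(unique(x)))
        reps[[nm]] <- sort(unique(x))
      } else {
        qs <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
        grp <- findInterval(x, qs, left.open = FALSE) + 1L # 1..4
        reps[[nm]] <- unname(vapply(1:4, function(g) {
          vals <- x[grp == g]
          if (length(vals)) median(vals) else unname(qs[min(g, 3)])
        }, numeric(1)))
      }
    } else {
      reps[[nm]] <- col$levels
    }
  }
  grid <- expand.grid(reps, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(grid, representatives = reps, class = c("patient_grid",
                                                    "data.frame"))
}

#' Best treatment for one synthetic patient
#'
#' The patient row is duplicated once per treatment level, the treatment
#' column set accordingly, and each copy's median survival predicted with
#' the bag; the recommendation is the level with the largest predicted
#' median. Extrapolated medians are flagged in the output, never
#' suppressed.
#'
#' @param bag a [train_bag()] result whose models were trained with the
#'   treatment column as a covariate.
#' @param patient one-row data.frame of covariates (any existing treatment
#'   value is overwritten).
#' @param treatment the treatment `tte_column` (>= 2 levels).
#' @return a `treatment_recommendation`: per-level predicted medians,
#'   recommended level, margin over the runner-up, extrapolation flags.
#' @export
best_treatment <- function(bag, patient, treatment) {
  stopifnot(inherits(treatment, "tte_column"),
            length(treatment$levels) >= 2)
  patient <- as.data.frame(patient)
  medians <- numeric(0)
  extrap <- logical(0)
  for (lv in treatment$levels) {
    row <- patient
    row[[treatment$name]] <- lv
    med <- median_survival(bag_predict(bag, row))
    medians[lv] <- as.numeric(med)
    extrap[lv] <- isTRUE(attr(med, "extrapolated"))
  }
  ord <- order(-medians)
  best <- treatment$levels[ord[1]]
  margin <- medians[ord[1]] - medians[ord[2]]
  structure(list(patient = patient, medians = medians,
                 recommended = best, margin = unname(margin),
                 extrapolated = extrap),
            class = "treatment_recommendation")
}

#' Treatment recommendations over a whole patient grid
#'
#' @param bag a [train_bag()] result.
#' @param grid a [quartile_grid()] (or any data.frame of patients).
#' @param treatment the treatment `tte_column`.
#' @return data.frame: one row per synthetic patient with per-level
#'   predicted medians, recommended level and margin.
#' @export
recommend_grid <- function(bag, grid, treatment) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rec <- best_treatment(bag, grid[i, , drop = FALSE], treatment)
    out <- grid[i, , drop = FALSE]
    for (lv in treatment$levels)
      out[[paste0("median_", lv)]] <- rec$medians[[lv]]
    out$recommended <- rec$recommended
    out$margin <- rec$margin
    out$any_extrapolated <- any(rec$extrapolated)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
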