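#' Column schema constructors
#'
#' A cohort schema is an ordered list of column descriptions: exactly one
#' duration column (time to event or censoring, in declared units), exactly
#' one binary event column (1 = observed, 0 = censored), and any number of
#' continuous, categorical and treatment covariates. A treatment column is a
#' categorical covariate singled out for counterfactual prediction.
#'
#' @param name column name as it appears in the CSV header.
#' @param units time units of the duration column (e.g. `"months"`).
#' @param levels ordered, duplicate-free character vector of category labels.
#' @return a `tte_column` object.
#' @name columns
NULL

new_column <- function(name, kind, units = NULL, levels = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind %in% c("categorical", "treatment")) {
    if (is.null(levels) || length(levels) == 0L)
      stopf("column '%s': %s columns need a non-empty 'levels'", name, kind)
    if (anyDuplicated(levels))
      stopf("column '%s': duplicate levels", name)
    levels <- as.character(levels)
  }
  structure(list(name = name, kind = kind, units = units, levels = levels),
            class = "tte_column")
}

#' @rdname columns
#' @export
col_continuous <- function(name) new_column(name, "continuous")

#' @rdname columns
#' @export
col_categorical <- function(name, levels) new_column(name, "categorical", levels = levels)

#' @rdname columns
#' @export
col_duration <- function(name, units = "months") new_column(name, "duration", units = units)

#' @rdname columns
#' @export
col_event <- function(name) new_column(name, "event")

#' @rdname columns
#' @export
col_treatment <- function(name, levels) new_column(name, "treatment", levels = levels)

#' Assemble a cohort schema
#'
#' @param ... `tte_column` objects (see [col_continuous()] and friends).
#' @return a `tte_schema` object.
#' @examples
#' tte_schema(
#'   col_continuous("age"),
#'   col_categorical("sex", c("F", "M")),
#'   col_duration("survival_months", units = "months"),
#'   col_event("died")
#' )
#' @export
tte_schema <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && !inherits(cols[[1]], "tte_column")) cols <- cols[[1]]
  stopifnot(all(vapply(cols, inherits, logical(1), "tte_column")))
  kinds <- vapply(cols, `[[`, character(1), "kind")
  names(cols) <- vapply(cols, `[[`, character(1), "name")
  if (anyDuplicated(names(cols))) stopf("duplicate column names in schema")
  if (sum(kinds == "duration") != 1L) stopf("schema needs exactly one duration column")
  if (sum(kinds == "event") != 1L) stopf("schema needs exactly one event column")
  if (sum(kinds == "treatment") > 1L) stopf("at most one treatment column")
  structure(list(columns = cols), class = "tte_schema")
}

schema_kinds <- function(schema) vapply(schema$columns, `[[`, character(1), "kind")

schema_covariates <- function(schema) {
  schema$columns[schema_kinds(schema) %in% c("continuous", "categorical", "treatment")]
}

duration_column <- function(schema) schema$columns[[which(schema_kinds(schema) == "duration")]]
event_column <- function(schema) schema$columns[[which(schema_kinds(schema) == "event")]]

#' Construct a survival dataset
#'
#' The universal input object: a covariate table with an explicit missingness
#' mask, positive durations and binary event indicators. Durations and events
#' are never missing (such rows are rejected at read time by [read_cohort()]).
#'
#' @param data data.frame of covariates only, `NA` marking missing cells;
#'   categorical columns may be character or factor and are stored as factors
#'   with the schema's level order.
#' @param durations positive numeric vector, one per row of `data`.
#' @param events binary (0/1) vector, one per row.
#' @param schema a [tte_schema()].
#' @return a `survival_dataset`.
#' @export
survival_dataset <- function(data, durations, events, schema) {
  covs <- schema_covariates(schema)
  data <- as.data.frame(data)[, names(covs), drop = FALSE]
  for (nm in names(covs)) {
    col <- covs[[nm]]
    if (col$kind == "continuous") {
      data[[nm]] <- as.numeric(data[[nm]])
    } else {
      x <- as.character(data[[nm]])
      bad <- !is.na(x) & !(x %in% col$levels)
      if (any(bad)) stopf("column '%s': unknown level(s) %s", nm,
                          paste(unique(x[bad]), collapse = ", "))
      data[[nm]] <- factor(x, levels = col$levels)
    }
  }
  durations <- as.numeric(durations)
  events <- as.numeric(events)
  stopifnot(length(durations) == nrow(data), length(events) == nrow(data))
  if (anyNA(durations) || anyNA(events))
    stopf("durations/events must be complete; filter rows first (read_cohort does)")
  if (any(durations <= 0)) stopf("durations must be positive")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  structure(list(data = data, durations = durations, events = events,
                 schema = schema, n = nrow(data)),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset> %d patients, %d covariates, %d events (%.0f%%), %d missing cells\n",
              x$n, ncol(x$data), sum(x$events), 100 * mean(x$events),
              sum(is.na(x$data))))
  invisible(x)
}

#' Missingness mask of a dataset
#'
#' @param dataset a `survival_dataset`.
#' @return logical matrix, `TRUE` exactly where a covariate cell is absent.
#' @export
missing_mask <- function(dataset) {
  m <- vapply(dataset$data, is.na, logical(dataset$n))
  if (dataset$n == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(dataset$data)))
  m
}

subset_dataset <- function(dataset, idx) {
  survival_dataset(dataset$data[idx, , drop = FALSE],
                   dataset$durations[idx], dataset$events[idx], dataset$schema)
}

bind_datasets <- function(a, b) {
  survival_dataset(rbind(a$data, b$data), c(a$durations, b$durations),
                   c(a$events, b$events), a$schema)
}

#' Read a cohort CSV against a schema
#'
#' Rows with a missing duration or event indicator, a non-positive duration,
#' or an unrecognised categorical level are dropped with a logged count and
#' reason; missing covariate cells (empty string or `NA`) are retained for
#' imputation.
#'
#' @param path CSV file with a header naming every schema column.
#' @param schema a [tte_schema()].
#' @return a `survival_dataset`.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  check.names = FALSE)
  need <- names(schema$columns)
  if (!all(need %in% names(raw)))
    stopf("CSV is missing schema columns: %s",
          paste(setdiff(need, names(raw)), collapse = ", "))
  dcol <- duration_column(schema)$name
  ecol <- event_column(schema)$name
  dur <- suppressWarnings(as.numeric(raw[[dcol]]))
  evt <- suppressWarnings(as.numeric(raw[[ecol]]))

  drop_missing_outcome <- is.na(dur) | is.na(evt)
  drop_bad_duration <- !drop_missing_outcome & dur <= 0
  drop_bad_event <- !drop_missing_outcome & !drop_bad_duration & !(evt %in% c(0, 1))
  covs <- schema_covariates(schema)
  drop_bad_level <- rep(FALSE, nrow(raw))
  for (nm in names(covs)) {
    col <- covs[[nm]]
    if (col$kind != "continuous") {
      x <- as.character(raw[[nm]])
      drop_bad_level <- drop_bad_level | (!is.na(x) & !(x %in% col$levels))
    }
  }
  drop <- drop_missing_outcome | drop_bad_duration | drop_bad_event | drop_bad_level
  if (any(drop)) {
    tte_log("read_cohort.dropped", path = path, n_dropped = sum(drop),
            missing_outcome = sum(drop_missing_outcome),
            nonpositive_duration = sum(drop_bad_duration),
            bad_event = sum(drop_bad_event), unknown_level = sum(drop_bad_level))
    message(sprintf("read_cohort: dropped %d row(s) (%d missing outcome, %d non-positive duration, %d bad event, %d unknown level)",
                    sum(drop), sum(drop_missing_outcome), sum(drop_bad_duration),
                    sum(drop_bad_event), sum(drop_bad_level)))
  }
  keep <- !drop
  survival_dataset(raw[keep, names(covs), drop = FALSE], dur[keep], evt[keep], schema)
}

#' Write a cohort back to CSV
#'
#' Inverse of [read_cohort()] on complete data: missing cells become empty
#' strings, column order follows the schema.
#'
#' @param dataset a `survival_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  out <- dataset$data
  for (nm in names(out)) if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  out[[duration_column(dataset$schema)$name]] <- dataset$durations
  out[[event_column(dataset$schema)$name]] <- dataset$events
  out <- out[, names(dataset$schema$columns), drop = FALSE]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Encode a complete dataset as a numeric design matrix
#'
#' Continuous covariates are standardised to mean 0, population (1/n) sd 1;
#' categorical covariates expand to one indicator column per level (no
#' reference level is dropped — downstream models carry their own bias
#' terms). When `fit_stats` is supplied (the provenance of a previously
#' encoded training set), its means, sds and level sets are reused verbatim,
#' so validation data can never leak into the encoding.
#'
#' @param dataset a complete `survival_dataset` (run imputation first).
#' @param fit_stats optional `design_matrix` (or its `provenance`) from the
#'   training encode.
#' @return a `design_matrix`: list with `matrix` (n x q numeric) and
#'   `provenance` (per output column: source covariate, kind, level, mu, sigma).
#' @export
encode <- function(dataset, fit_stats = NULL) {
  if (anyNA(dataset$data))
    stopf("dataset has missing covariates; impute before encoding")
  prov <- NULL
  if (!is.null(fit_stats)) {
    prov <- if (inherits(fit_stats, "design_matrix")) fit_stats$provenance else fit_stats
  }
  covs <- schema_covariates(dataset$schema)
  pieces <- list()
  rows <- list()
  for (nm in names(covs)) {
    col <- covs[[nm]]
    if (col$kind == "continuous") {
      x <- dataset$data[[nm]]
      if (is.null(prov)) {
        mu <- mean(x)
        sigma <- sqrt(mean((x - mu)^2)) # population sd: fixed convention
        if (sigma == 0) stopf("zero-variance continuous column '%s'", nm)
      } else {
        row <- prov[prov$source == nm & prov$kind == "continuous", ]
        if (nrow(row) != 1L) stopf("no encoding stats for column '%s'", nm)
        mu <- row$mu; sigma <- row$sigma
      }
      pieces[[nm]] <- matrix((x - mu) / sigma, ncol = 1,
                             dimnames = list(NULL, nm))
      rows[[nm]] <- data.frame(column = nm, source = nm, kind = "continuous",
                               level = NA_character_, mu = mu, sigma = sigma,
                               stringsAsFactors = FALSE)
    } else {
      levs <- col$levels
      if (!is.null(prov)) {
        known <- prov$level[prov$source == nm]
        missing_lv <- setdiff(levs, known)
        if (length(missing_lv))
          stopf("levels %s of '%s' absent from encoding provenance",
                paste(missing_lv, collapse = ", "), nm)
        levs <- known
      }
      x <- as.character(dataset$data[[nm]])
      ind <- vapply(levs, function(lv) as.numeric(x == lv), numeric(dataset$n))
      if (dataset$n == 1L) ind <- matrix(ind, nrow = 1)
      colnames(ind) <- paste0(nm, "=", levs)
      pieces[[nm]] <- ind
      rows[[nm]] <- data.frame(column = colnames(ind), source = nm,
                               kind = col$kind, level = levs,
                               mu = NA_real_, sigma = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(matrix = do.call(cbind, pieces),
                 provenance = do.call(rbind, rows)),
            class = "design_matrix")
}

#' Independently permute each covariate column
#'
#' The randomised-covariate ablation: every covariate column is shuffled
#' across patients independently (destroying covariate-outcome and
#' covariate-covariate structure) while the joint (duration, event) marginal
#' is untouched. Deterministic given `seed`.
#'
#' @param dataset a `survival_dataset`.
#' @param seed integer seed.
#' @return a `survival_dataset` with permuted covariates.
#' @export
shuffle_covariates <- function(dataset, seed) {
  data <- dataset$data
  with_seed(derive_seed(seed, "shuffle_covariates"), {
    for (nm in names(data)) data[[nm]] <- data[[nm]][sample.int(dataset$n)]
  })
  survival_dataset(data, dataset$durations, dataset$events, dataset$schema)
}
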