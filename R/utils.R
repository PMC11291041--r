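#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in the package flows from one master seed; independent
#' random streams (covariate draws, censoring, missingness, per-round
#' imputation, bag members, ...) get their own sub-seed via a fixed string
#' hash so that adding a stream never perturbs the others.
#'
#' @param seed master seed (integer).
#' @param label character tag naming the stream.
#' @param k optional stream index appended to the label.
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label, k = NULL) {
  if (!is.null(k)) label <- paste0(label, "#", k)
  m <- 2147483647 # 2^31 - 1, keeps everything a valid R integer
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

#' Emit a structured log event
#'
#' When `options(pchaz.log_file = <path>)` is set, events are appended as one
#' JSON object per line. The pipeline's leakage audit parses these events to
#' prove that validation rows only ever pass through single-patient
#' imputation and frozen encoders.
#'
#' @param event short event name, e.g. `"read_cohort.dropped"`.
#' @param ... named fields stored with the event.
#' @return the event record, invisibly.
#' @export
tte_log <- function(event, ...) {
  rec <- c(list(event = event), list(...))
  path <- getOption("pchaz.log_file", NULL)
  if (!is.null(path)) {
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    cat(line, "\n", sep = "", file = path, append = TRUE)
  }
  if (isTRUE(getOption("pchaz.verbose", FALSE))) {
    message(sprintf("[pchaz] %s", event))
  }
  invisible(rec)
}

# read a JSONL log back as a list of events
read_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so package randomness never perturbs user scripts.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
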