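#' Read or write a cohort schema as YAML
#'
#' The on-disk form is a list of column blocks:
#' ```yaml
#' columns:
#'   - {name: age, kind: continuous}
#'   - {name: sex, kind: categorical, levels: [F, M]}
#'   - {name: survival_months, kind: duration, units: months}
#'   - {name: died, kind: event}
#' ```
#'
#' @param path YAML file path.
#' @return a [tte_schema()] (read) or `path` invisibly (write).
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  cols <- lapply(y$columns, function(cc) {
    switch(cc$kind,
           continuous = col_continuous(cc$name),
           categorical = col_categorical(cc$name, unlist(cc$levels)),
           treatment = col_treatment(cc$name, unlist(cc$levels)),
           duration = col_duration(cc$name, cc$units %||% "months"),
           event = col_event(cc$name),
           stopf("unknown column kind '%s'", cc$kind))
  })
  tte_schema(cols)
}

#' @rdname read_schema
#' @param schema a [tte_schema()].
#' @export
write_schema <- function(schema, path) {
  cols <- lapply(schema$columns, function(col) {
    out <- list(name = col$name, kind = col$kind)
    if (!is.null(col$units)) out$units <- col$units
    if (!is.null(col$levels)) out$levels <- as.list(col$levels)
    out
  })
  yaml::write_yaml(list(columns = unname(cols)), path)
  invisible(path)
}
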