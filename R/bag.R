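#' Model configuration for training (family + hyperparameters)
#'
#' The family-agnostic handle used by bagging and tuning: either the
#' piecewise-constant-hazard network (with its [hazardnet_config()]) or the
#' Royston-Parmar flexible parametric model (with its internal knot count).
#'
#' @param family `"pchazard"` or `"royston_parmar"`.
#' @param net a [hazardnet_config()] (pchazard only).
#' @param internal_knots internal spline knots (royston_parmar only).
#' @return a `model_config`.
#' @export
model_config <- function(family = c("pchazard", "royston_parmar"),
                         net = hazardnet_config(), internal_knots = 0) {
  family <- match.arg(family)
  structure(list(family = family, net = net,
                 internal_knots = as.integer(internal_knots)),
            class = "model_config")
}

fit_survival_model <- function(config, design, durations, events, seed = NULL) {
  if (config$family == "pchazard") {
    net <- config$net
    if (!is.null(seed)) net$seed <- as.integer(seed)
    fit_pchazard(design, durations, events, net)
  } else {
    fit_royston_parmar(design, durations, events, config$internal_knots)
  }
}

#' Train a bag of independently subsampled models
#'
#' Each of `bag_size` members is trained on its own random `subsample`
#' fraction of the training rows (drawn without replacement) with its own
#' derived seed; the bag's prediction ([bag_predict()]) is the pointwise
#' median of the member curves. Encoding statistics are fitted once on the
#' full training data and shared by all members.
#'
#' @param config a [model_config()].
#' @param data a complete `survival_dataset` (post-imputation).
#' @param bag_size number of members (default 10).
#' @param subsample fraction of rows per member (default 0.8).
#' @param seed master seed; member seeds derive from it.
#' @return a `model_bag`.
#' @export
train_bag <- function(config, data, bag_size = 10, subsample = 0.8, seed = 1) {
  stopifnot(inherits(data, "survival_dataset"), bag_size >= 1,
            subsample > 0, subsample <= 1)
  enc <- encode(data)
  n <- data$n
  models <- vector("list", bag_size)
  seeds <- integer(bag_size)
  for (b in seq_len(bag_size)) {
    mseed <- derive_seed(seed, "bag_member", b)
    seeds[b] <- mseed
    idx <- if (subsample < 1)
      with_seed(derive_seed(seed, "bag_subsample", b),
                sort(sample.int(n, floor(subsample * n))))
    else seq_len(n)
    design_b <- structure(list(matrix = enc$matrix[idx, , drop = FALSE],
                               provenance = enc$provenance),
                          class = "design_matrix")
    models[[b]] <- fit_survival_model(config, design_b, data$durations[idx],
                                      data$events[idx], seed = mseed)
  }
  tte_log("train_bag", bag_size = bag_size, n = n, subsample = subsample)
  structure(list(models = models, provenance = enc$provenance,
                 schema = data$schema, config = config, seeds = seeds),
            class = "model_bag")
}

bag_encode_row <- function(bag, x) {
  if (is.data.frame(x)) {
    ds <- survival_dataset(x, rep(1, nrow(x)), rep(1, nrow(x)), bag$schema)
    encode(ds, fit_stats = bag$provenance)$matrix
  } else if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

# pointwise median of member curves on a shared mesh
aggregate_curves <- function(curves) {
  mesh <- sort(unique(c(0, unlist(lapply(curves, `[[`, "times")))))
  S <- vapply(curves, function(cv) curve_at(cv, mesh), numeric(length(mesh)))
  if (length(mesh) == 1L) S <- matrix(S, nrow = 1)
  med <- apply(S, 1, median)
  if (any(diff(med) > 1e-12)) {
    # medians of monotone curves on a shared mesh are monotone; this is a
    # safety net for numerical wiggle only
    tte_log("bag_predict.monotonicity_clip")
    med <- cummin(med)
  }
  med[1] <- 1
  survival_curve(mesh, pmin(med, 1))
}

#' Median-aggregated bag prediction
#'
#' Evaluates every member's survival curve on the union of their meshes and
#' returns the pointwise median curve (clipped to be non-increasing only if
#' numerical wiggle violates monotonicity, which is logged).
#'
#' @param bag a [train_bag()] result.
#' @param x one patient: encoded design row or one-row data.frame of raw
#'   covariates.
#' @return a [survival_curve()].
#' @export
bag_predict <- function(bag, x) {
  X <- bag_encode_row(bag, x)
  curves <- lapply(bag$models, function(mod) predict_curve(mod, X[1, ]))
  aggregate_curves(curves)
}
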