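#' Configuration of the piecewise-constant-hazard network
#'
#' @param hidden integer vector of hidden layer sizes.
#' @param dropout dropout rate in `[0, 1)`.
#' @param batch_norm apply batch normalisation to hidden pre-activations.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param m number of hazard intervals (grid cut points come from
#'   [make_grid()]).
#' @param seed integer seed; training is deterministic given it.
#' @return a `hazardnet_config`.
#' @export
hazardnet_config <- function(hidden = c(32, 32), dropout = 0,
                             batch_norm = FALSE, lr = 0.01, epochs = 100,
                             batch_size = 256, m = 10, seed = 1) {
  stopifnot(all(hidden >= 1), lr > 0, m >= 1, epochs >= 0, batch_size >= 1,
            dropout >= 0, dropout < 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 batch_norm = isTRUE(batch_norm), lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), m = as.integer(m),
                 seed = as.integer(seed)),
            class = "hazardnet_config")
}

as_design <- function(design) {
  if (inherits(design, "design_matrix")) {
    list(X = design$matrix, provenance = design$provenance)
  } else {
    X <- as.matrix(design)
    if (ncol(X) == 0L) X <- matrix(1, nrow(X), 1, dimnames = list(NULL, "intercept"))
    list(X = X, provenance = NULL)
  }
}

# per-observation pieces of the piecewise-exponential NLL:
# Hmat[i, j] premultiplies lambda[i, j] in H(t_i); k is the interval of t_i
nll_pieces <- function(grid, durations, events) {
  m <- grid$m
  cuts <- grid$cuts
  delta <- diff(cuts)
  k <- pmin(grid_interval(grid, pmin(durations, cuts[m + 1])), m)
  n <- length(durations)
  Hmat <- matrix(0, n, m)
  for (j in seq_len(m)) {
    Hmat[, j] <- ifelse(j < k, delta[j],
                        ifelse(j == k, pmin(durations, cuts[m + 1]) - cuts[j], 0))
  }
  list(Hmat = Hmat, k = k, delta = delta)
}

batch_loss_grad <- function(lambda, pieces, events, idx) {
  n <- length(idx)
  lam <- lambda
  kk <- pieces$k[idx]
  lam_k <- lam[cbind(seq_len(n), kk)]
  H <- rowSums(lam * pieces$Hmat[idx, , drop = FALSE])
  loss <- sum(H - events[idx] * log(pmax(lam_k, 1e-12))) / n
  G <- pieces$Hmat[idx, , drop = FALSE]
  G[cbind(seq_len(n), kk)] <- G[cbind(seq_len(n), kk)] -
    events[idx] / pmax(lam_k, 1e-12)
  list(loss = loss, dlambda = G / n)
}

train_epochs <- function(params, state, X, pieces, events, config, epochs, lr,
                         seed) {
  n <- nrow(X)
  trace <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        fwd <- nn_forward(params, X[idx, , drop = FALSE],
                          dropout = config$dropout,
                          batch_norm = config$batch_norm, training = TRUE)
        params <- fwd$params # batch-norm running stats updated
        lg <- batch_loss_grad(fwd$lambda, pieces, events, idx)
        grads <- nn_backward(params, fwd$cache, lg$dlambda,
                             dropout = config$dropout,
                             batch_norm = config$batch_norm)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      if (!is.finite(ep_loss))
        stopf("non-finite training loss at epoch %d", ep)
      trace <- c(trace, ep_loss / n)
    }
  })
  list(params = params, state = state, trace = trace)
}

#' Fit the piecewise-constant-hazard neural model
#'
#' A feed-forward network maps a design-matrix row to `m` non-negative
#' interval hazards (softplus outputs); training minimises the mean exact
#' piecewise-exponential negative log-likelihood ([pchazard_nll()]) by
#' mini-batch Adam. Deterministic given `config$seed`.
#'
#' @param design a `design_matrix` from [encode()], or a plain numeric
#'   matrix (a zero-column matrix gets an intercept column, giving a
#'   covariate-free model).
#' @param durations positive durations.
#' @param events 0/1 event indicators.
#' @param config a [hazardnet_config()].
#' @param grid optional frozen [make_grid()] result (defaults to a fresh
#'   grid with `config$m` intervals).
#' @return a `hazard_model` (network parameters, grid, config, encoding
#'   provenance, training-loss trace).
#' @export
fit_pchazard <- function(design, durations, events, config = hazardnet_config(),
                         grid = NULL) {
  d <- as_design(design)
  n <- nrow(d$X)
  if (n == 0) stopf("empty dataset")
  stopifnot(length(durations) == n, length(events) == n)
  if (is.null(grid)) grid <- make_grid(durations, config$m)
  pieces <- nll_pieces(grid, durations, events)
  params <- nn_init(c(ncol(d$X), config$hidden, grid$m),
                    derive_seed(config$seed, "nn_init"))
  state <- adam_init(params)
  res <- train_epochs(params, state, d$X, pieces, events, config,
                      config$epochs, config$lr,
                      derive_seed(config$seed, "train"))
  structure(list(params = res$params, grid = grid, config = config,
                 provenance = d$provenance, loss_trace = res$trace,
                 family = "pchazard"),
            class = "hazard_model")
}

# continue training a (copied) fitted model on new data with a frozen grid
# and encoding; used by the focused-training ensemble's second stage
continue_training <- function(model, design, durations, events, epochs,
                              lr = NULL, seed = 0) {
  d <- as_design(design)
  if (epochs == 0) return(model)
  pieces <- nll_pieces(model$grid, durations, events)
  state <- adam_init(model$params)
  res <- train_epochs(model$params, state, d$X, pieces, events, model$config,
                      epochs, lr %||% model$config$lr,
                      derive_seed(seed, "continue"))
  model$params <- res$params
  model$loss_trace <- c(model$loss_trace, res$trace)
  model
}

model_hazards <- function(model, X) {
  fwd <- nn_forward(model$params, X, dropout = 0,
                    batch_norm = model$config$batch_norm, training = FALSE)
  fwd$lambda
}

encode_rows <- function(model, x, schema = NULL) {
  # accept an already-encoded numeric vector/matrix, or raw covariate rows
  # (data.frame) encoded with the model's frozen training provenance
  if (is.data.frame(x)) {
    if (is.null(model$provenance))
      stopf("model has no encoding provenance; pass an encoded row")
    if (is.null(schema)) stopf("schema required to encode raw covariate rows")
    ds <- survival_dataset(x, rep(1, nrow(x)), rep(1, nrow(x)), schema)
    encode(ds, fit_stats = model$provenance)$matrix
  } else if (is.null(dim(x))) {
    matrix(x, nrow = 1)
  } else {
    as.matrix(x)
  }
}

#' Predict a survival curve for one patient
#'
#' `S(t) = exp(-H(t))` with the model's interval hazards: piecewise
#' exponential (log-linear) between cut points.
#'
#' @param model a fitted model (`hazard_model` or `rp_model`).
#' @param x an encoded design row (numeric vector) or a one-row data.frame
#'   of raw covariates (then `schema` is required).
#' @param schema the cohort schema, for raw-covariate input.
#' @return a [survival_curve()].
#' @export
predict_curve <- function(model, x, schema = NULL) UseMethod("predict_curve")

#' @export
predict_curve.hazard_model <- function(model, x, schema = NULL) {
  X <- encode_rows(model, x, schema)
  lambda <- as.numeric(model_hazards(model, X[1, , drop = FALSE]))
  pch_curve(model$grid, lambda)
}

#' Save / load a fitted piecewise-constant-hazard model
#'
#' Persistence is a directory of plain-text parameter arrays (one CSV per
#' weight matrix) plus a JSON model card holding the grid, configuration and
#' encoding provenance.
#'
#' @param model a `hazard_model`.
#' @param dir target directory.
#' @return `dir` (save) or the restored `hazard_model` (load).
#' @export
save_hazard_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_along(model$params$W)) {
    write.csv(model$params$W[[l]], file.path(dir, sprintf("W%d.csv", l)),
              row.names = FALSE)
    write.csv(data.frame(b = model$params$b[[l]]),
              file.path(dir, sprintf("b%d.csv", l)), row.names = FALSE)
  }
  card <- list(family = model$family, cuts = model$grid$cuts,
               config = unclass(model$config), sizes = model$params$sizes,
               bn_mean = model$params$bn_mean, bn_var = model$params$bn_var,
               provenance = model$provenance,
               package_version = as.character(utils::packageVersion("pchaz")))
  jsonlite::write_json(card, file.path(dir, "model_card.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_hazard_model
#' @param dir directory written by [save_hazard_model()].
#' @export
load_hazard_model <- function(dir) {
  card <- jsonlite::fromJSON(file.path(dir, "model_card.json"))
  sizes <- as.integer(card$sizes)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- as.matrix(read.csv(file.path(dir, sprintf("W%d.csv", l))))
    dimnames(W[[l]]) <- NULL
    b[[l]] <- read.csv(file.path(dir, sprintf("b%d.csv", l)))$b
  }
  params <- list(W = W, b = b,
                 bn_mean = lapply(card$bn_mean, as.numeric),
                 bn_var = lapply(card$bn_var, as.numeric), sizes = sizes)
  cfg <- do.call(hazardnet_config, card$config[c("hidden", "dropout",
                                                 "batch_norm", "lr", "epochs",
                                                 "batch_size", "m", "seed")])
  grid <- structure(list(cuts = as.numeric(card$cuts),
                         m = length(card$cuts) - 1L),
                    class = "discretization_grid")
  prov <- if (!is.null(card$provenance)) as.data.frame(card$provenance) else NULL
  structure(list(params = params, grid = grid, config = cfg,
                 provenance = prov, loss_trace = numeric(0),
                 family = "pchazard"),
            class = "hazard_model")
}
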