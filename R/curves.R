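#' Build a discretization grid from observed durations
#'
#' Cut points sit at the `j/m` quantiles (type-7, midpoint interpolation) of
#' the observed durations, `j = 1..m`, with the last cut at the maximum
#' duration so the grid covers the data. Duplicate quantiles (heavily tied
#' durations) are collapsed with a logged reduction of `m`.
#'
#' @param durations positive observed durations.
#' @param m requested number of intervals (must not exceed the number of
#'   distinct durations).
#' @return a `discretization_grid` with `cuts` (`tau_0 = 0 < ... < tau_m`)
#'   and `m`.
#' @export
make_grid <- function(durations, m) {
  stopifnot(length(durations) > 0, m >= 1)
  if (m > length(unique(durations)))
    stopf("m = %d exceeds the number of distinct durations (%d)",
          m, length(unique(durations)))
  cuts <- unname(quantile(durations, probs = seq_len(m) / m, type = 7))
  cuts[m] <- max(durations)
  cuts <- unique(cuts)
  if (length(cuts) < m)
    tte_log("make_grid.collapsed", requested = m, effective = length(cuts))
  cuts <- c(0, cuts)
  structure(list(cuts = cuts, m = length(cuts) - 1L),
            class = "discretization_grid")
}

# index k with tau_{k-1} < t <= tau_k; t > tau_m yields m + 1
grid_interval <- function(grid, t) {
  pmax(1L, findInterval(t, grid$cuts, left.open = TRUE))
}

# H(t) under piecewise-constant hazards; t beyond tau_m extrapolates with
# the last interval's hazard (needed when scoring test durations outside
# the training range)
pch_cumhaz <- function(grid, lambda, t) {
  cuts <- grid$cuts
  m <- grid$m
  delta <- diff(cuts)
  Hcum <- c(0, cumsum(lambda * delta)) # H at cut points
  k <- pmin(grid_interval(grid, t), m)
  Hcum[k] + lambda[k] * (pmin(t, cuts[m + 1]) - cuts[k]) +
    lambda[m] * pmax(t - cuts[m + 1], 0)
}

#' Piecewise-exponential negative log-likelihood of one observation
#'
#' With `k` the interval containing `t`, interval widths `Delta_j` and
#' `rho = (t - tau_(k-1)) / Delta_k`, the cumulative hazard is
#' `H(t) = sum_(j<k) lambda_j Delta_j + rho lambda_k Delta_k` and the exact
#' negative log-likelihood is `-d log(lambda_k) + H(t)`.
#'
#' @param lambda non-negative interval hazards, length `m`.
#' @param grid a [make_grid()] result.
#' @param t duration, in `(0, tau_m]`.
#' @param d event indicator (1 observed, 0 censored).
#' @return non-negative real.
#' @export
pchazard_nll <- function(lambda, grid, t, d) {
  stopifnot(length(lambda) == grid$m, length(t) == 1, d %in% c(0, 1))
  if (t <= 0) stopf("t must be positive")
  if (t > grid$cuts[grid$m + 1] * (1 + 1e-12)) stopf("t = %g beyond grid end", t)
  k <- min(grid_interval(grid, t), grid$m)
  if (d == 1 && lambda[k] == 0)
    stopf("event in interval %d with zero hazard: infinite loss", k)
  H <- pch_cumhaz(grid, lambda, t)
  -d * log(ifelse(d == 1, lambda[k], 1)) + H
}

#' Construct a survival curve
#'
#' A monotone non-increasing survival function tabulated on a mesh (always
#' including `t = 0` with `S = 1`), optionally backed by an exact evaluator
#' `fn` used to refine median crossings. Between mesh points the curve is
#' interpolated log-linearly, which is exact for piecewise-exponential
#' models whose cut points are all in the mesh.
#'
#' @param times increasing evaluation times starting at 0.
#' @param surv survival probabilities, `S(0) = 1`, non-increasing in `[0,1]`.
#' @param fn optional vectorised exact evaluator `S(t)`.
#' @return a `survival_curve`.
#' @export
survival_curve <- function(times, surv, fn = NULL) {
  stopifnot(length(times) == length(surv), times[1] == 0, surv[1] == 1)
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(surv < -1e-9 | surv > 1 + 1e-9)) stopf("survival outside [0,1]")
  if (any(diff(surv) > 1e-9)) stopf("survival must be non-increasing")
  structure(list(times = times, surv = pmin(pmax(surv, 0), 1), fn = fn),
            class = "survival_curve")
}

#' Evaluate a survival curve at arbitrary times
#'
#' Log-linear (piecewise-exponential) interpolation between mesh points;
#' beyond the mesh the last segment's hazard is carried forward.
#'
#' @param curve a `survival_curve`.
#' @param t times (vector).
#' @return survival probabilities.
#' @export
curve_at <- function(curve, t) {
  if (!is.null(curve$fn)) return(pmin(pmax(curve$fn(t), 0), 1))
  tt <- curve$times
  ss <- pmax(curve$surv, 1e-300)
  k <- length(tt)
  i <- pmax(findInterval(t, tt), 1L)
  out <- numeric(length(t))
  inside <- i < k
  if (any(inside)) {
    i0 <- i[inside]
    w <- (t[inside] - tt[i0]) / (tt[i0 + 1] - tt[i0])
    out[inside] <- ss[i0] * (ss[i0 + 1] / ss[i0])^w
  }
  if (any(!inside)) {
    h_tail <- tail_hazard(tt, ss)
    out[!inside] <- ss[k] * exp(-h_tail * (t[!inside] - tt[k]))
  }
  out[t <= 0] <- 1
  pmin(pmax(out, 0), 1)
}

tail_hazard <- function(tt, ss) {
  k <- length(tt)
  log(ss[k - 1] / ss[k]) / (tt[k] - tt[k - 1])
}

#' Median predicted survival time
#'
#' The first time with `S(t) <= 0.5`, solved exactly within the crossing
#' mesh interval under the log-linear (piecewise-exponential) form, refined
#' with the curve's exact evaluator when available. If the curve never
#' reaches 0.5 on its mesh, the last segment's hazard is extrapolated and
#' the result is flagged with `attr(, "extrapolated") = TRUE`; a flat tail
#' (zero hazard) makes the median undefined and raises an error.
#'
#' @param curve a `survival_curve`.
#' @return the median time, with attribute `extrapolated`.
#' @export
median_survival <- function(curve) {
  tt <- curve$times
  ss <- curve$surv
  idx <- which(ss <= 0.5)
  if (length(idx) == 0) {
    h <- tail_hazard(tt, pmax(ss, 1e-300))
    if (!is.finite(h) || h <= 0)
      stopf("median survival undefined: curve never reaches 0.5 and its tail hazard is zero")
    k <- length(tt)
    med <- tt[k] + log(ss[k] / 0.5) / h
    return(structure(med, extrapolated = TRUE))
  }
  i <- idx[1]
  if (ss[i] == 0.5 || i == 1) return(structure(tt[i], extrapolated = FALSE))
  lo <- tt[i - 1]; hi <- tt[i]
  if (!is.null(curve$fn)) {
    med <- uniroot(function(t) curve$fn(t) - 0.5, c(lo, hi),
                   tol = 1e-10 * max(1, hi))$root
  } else {
    h <- log(max(ss[i - 1], 1e-300) / max(ss[i], 1e-300)) / (hi - lo)
    med <- lo + log(ss[i - 1] / 0.5) / h
  }
  structure(med, extrapolated = FALSE)
}

# mesh for a piecewise-constant-hazard model: all cuts plus a few interior
# points per interval (purely cosmetic; interpolation is already exact)
pch_mesh <- function(grid, per_interval = 4L) {
  cuts <- grid$cuts
  pts <- unlist(lapply(seq_len(grid$m), function(j) {
    seq(cuts[j], cuts[j + 1], length.out = per_interval + 1L)[-1]
  }))
  sort(unique(c(0, pts)))
}

# exact survival curve of a hazard vector on a grid
pch_curve <- function(grid, lambda, per_interval = 4L) {
  times <- pch_mesh(grid, per_interval)
  surv <- exp(-pch_cumhaz(grid, lambda, times))
  surv[times == 0] <- 1
  survival_curve(times, surv)
}
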