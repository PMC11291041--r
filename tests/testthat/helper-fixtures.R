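# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

toy_schema <- function() {
  tte_schema(
    col_continuous("age"),
    col_continuous("slope"),
    col_categorical("sex", c("F", "M")),
    col_duration("months", units = "months"),
    col_event("died")
  )
}

# complete toy dataset with a deterministic structure
toy_dataset <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(
      age = round(rnorm(n, 60, 10), 1),
      slope = round(rlnorm(n, 0, 0.5), 3),
      sex = sample(c("F", "M"), n, replace = TRUE)
    )
    survival_dataset(df, round(rlnorm(n, log(20), 0.7), 2),
                     rbinom(n, 1, 0.8), toy_schema())
  })
}

# 200-row fixture with a near-duplicated continuous pair (x ~ y) and a
# categorical column tied to x; used for imputation recovery tests
correlated_dataset <- function(n = 200, seed = 1, noise = 0.1) {
  withr::with_seed(seed, {
    x <- rnorm(n, 10, 2)
    y <- x + rnorm(n) * noise
    g <- ifelse(x > 10, "hi", "lo")
    sch <- tte_schema(col_continuous("x"), col_continuous("y"),
                     col_categorical("g", c("hi", "lo")),
                     col_duration("t"), col_event("d"))
    survival_dataset(data.frame(x = x, y = y, g = g),
                     rlnorm(n, log(10), 0.5), rbinom(n, 1, 0.8), sch)
  })
}

write_toy_csv <- function(lines, path = withr::local_tempfile(fileext = ".csv",
                                                              .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

random_grid <- function(m, tmax = 5, seed = NULL) {
  draw <- function() {
    cuts <- sort(runif(m, 0, tmax))
    structure(list(cuts = c(0, cuts), m = m), class = "discretization_grid")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# ---- independent oracles --------------------------------------------------

# numerically integrated piecewise-exponential NLL: the cumulative hazard is
# obtained by trapezoid integration of the step hazard, subdividing each
# constant segment (where the trapezoid rule is exact) with ~1e4 points total
nll_numeric_oracle <- function(lambda, grid, t, d, points = 1e4) {
  cuts <- grid$cuts
  m <- grid$m
  k <- max(1, findInterval(t, cuts, left.open = TRUE))
  H <- 0
  per <- max(2, ceiling(points / m))
  for (j in seq_len(k)) {
    hi <- min(t, cuts[j + 1])
    if (hi <= cuts[j]) break
    xs <- seq(cuts[j], hi, length.out = per)
    ys <- rep(lambda[j], per)
    H <- H + sum((ys[-1] + ys[-per]) / 2 * diff(xs))
  }
  -d * log(if (d == 1) lambda[k] else 1) + H
}

# brute-force O(n^2) pair enumeration of the tie-adjusted time-dependent
# concordance, written directly from its definition
concordance_oracle <- function(curves, durations, events) {
  n <- length(durations)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- events[i] == 1 &&
        (durations[i] < durations[j] ||
           (durations[i] == durations[j] && events[j] == 0))
      if (!comparable) next
      si <- curve_at(curves[[i]], durations[i])
      sj <- curve_at(curves[[j]], durations[i])
      num <- num + if (si < sj) 1 else if (si == sj) 0.5 else 0
      den <- den + 1
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# random piecewise-constant-hazard curve for metric property tests
random_pch_curve <- function(m = 4, tmax = 10) {
  grid <- structure(list(cuts = c(0, sort(runif(m - 1, 0, tmax)), tmax),
                         m = m), class = "discretization_grid")
  pchaz:::pch_curve(grid, runif(m, 0.01, 0.6))
}

# proportional-hazards data with one strong covariate: exponential baseline,
# hazard h0 * exp(b * x); returns dataset pieces plus the true risk score
ph_one_covariate <- function(n, b = 1, h0 = 0.05, cens_max = Inf, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    t <- rexp(n, rate = h0 * exp(b * x))
    cens <- if (is.finite(cens_max)) runif(n, 0, cens_max) else rep(Inf, n)
    list(x = matrix(x, ncol = 1), durations = pmin(t, cens),
         events = as.numeric(t <= cens), risk = b * x)
  })
}
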