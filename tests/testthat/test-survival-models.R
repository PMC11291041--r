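test_that("make_grid places quantile cuts and covers the data", {
  g <- make_grid(c(1, 2, 3, 4), 2)
  expect_equal(g$cuts, c(0, 2.5, 4))
  g1 <- make_grid(c(5, 9, 2), 1)
  expect_equal(g1$cuts, c(0, 9))
  expect_error(make_grid(rep(3, 10), 2), "distinct")
  # duplicate quantiles collapse with reduced m
  g2 <- make_grid(c(1, 1, 1, 1, 1, 2, 3), 3)
  expect_true(g2$m < 3)
  expect_equal(max(g2$cuts), 3)
})

test_that("pchazard_nll matches closed forms and rejects bad input", {
  g1 <- structure(list(cuts = c(0, 1), m = 1L), class = "discretization_grid")
  expect_equal(pchazard_nll(1, g1, 0.5, 1), 0.5)
  expect_equal(pchazard_nll(1, g1, 0.5, 0), 0.5)
  g2 <- structure(list(cuts = c(0, 1, 2), m = 2L), class = "discretization_grid")
  expect_equal(pchazard_nll(c(2, 0.5), g2, 1.5, 1), -log(0.5) + 2 + 0.25)
  expect_error(pchazard_nll(c(0, 1), g2, 0.5, 1), "zero hazard")
  expect_error(pchazard_nll(c(1, 1), g2, 2.5, 1), "beyond grid")
})

test_that("pchazard_nll agrees with the numerically integrated oracle", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      m <- sample(1:5, 1)
      grid <- random_grid(m)
      lambda <- runif(m, 0.05, 3)
      t <- runif(1, 1e-3, max(grid$cuts))
      d <- rbinom(1, 1, 0.5)
      expect_equal(pchazard_nll(lambda, grid, t, d),
                   nll_numeric_oracle(lambda, grid, t, d),
                   tolerance = 1e-6)
    }
  })
})

test_that("predict_curve is exp(-H) with exact values at cut points", {
  g2 <- structure(list(cuts = c(0, 1, 2), m = 2L), class = "discretization_grid")
  cv <- pchaz:::pch_curve(g2, c(2, 0.5))
  expect_equal(curve_at(cv, 0.5), exp(-1))
  expect_equal(curve_at(cv, 1.5), exp(-2.25))
  expect_equal(curve_at(cv, 1), exp(-2))
  expect_equal(curve_at(cv, 0), 1)
  # all-zero hazards: survival identically 1
  cv0 <- pchaz:::pch_curve(g2, c(0, 0))
  expect_equal(curve_at(cv0, 1.7), 1)
  # non-increasing invariant on a random batch
  withr::with_seed(7, {
    for (i in 1:20) {
      cvr <- random_pch_curve()
      expect_true(all(diff(cvr$surv) <= 1e-12))
    }
  })
})

test_that("median_survival solves the crossing exactly and flags extrapolation", {
  g1 <- structure(list(cuts = c(0, 1), m = 1L), class = "discretization_grid")
  # constant hazard: median = ln2 / lambda, found by tail extrapolation
  m <- median_survival(pchaz:::pch_curve(g1, 0.1))
  expect_equal(as.numeric(m), log(2) / 0.1)
  expect_true(attr(m, "extrapolated"))
  g2 <- structure(list(cuts = c(0, 1, 2), m = 2L), class = "discretization_grid")
  m2 <- median_survival(pchaz:::pch_curve(g2, c(2, 0.5)))
  expect_equal(as.numeric(m2), log(2) / 2)
  expect_false(attr(m2, "extrapolated"))
  # exact hit at a cut point
  cv <- survival_curve(c(0, 1, 2), c(1, 0.5, 0.25))
  expect_equal(as.numeric(median_survival(cv)), 1)
  # flat tail above 0.5: undefined
  expect_error(median_survival(pchaz:::pch_curve(g2, c(0, 0))), "undefined")
})

test_that("median is equivariant under time rescaling (months <-> years)", {
  withr::with_seed(11, {
    for (i in 1:10) {
      grid <- random_grid(3)
      lambda <- runif(3, 0.2, 1)
      grid_y <- structure(list(cuts = grid$cuts / 12, m = 3L),
                          class = "discretization_grid")
      m_months <- median_survival(pchaz:::pch_curve(grid, lambda))
      m_years <- median_survival(pchaz:::pch_curve(grid_y, lambda * 12))
      expect_equal(as.numeric(m_months), as.numeric(m_years) * 12,
                   tolerance = 1e-9)
    }
  })
})

test_that("fit_pchazard recovers a constant hazard and is seed-deterministic", {
  withr::with_seed(101, durations <- rexp(2000, 0.1))
  cfg <- hazardnet_config(hidden = 16, lr = 0.05, epochs = 100, m = 5, seed = 3)
  fit <- fit_pchazard(matrix(numeric(0), 2000, 0), durations,
                      rep(1, 2000), cfg)
  lam <- as.numeric(pchaz:::model_hazards(fit, matrix(1, 1, 1)))
  expect_true(all(abs(lam - 0.1) / 0.1 < 0.15))
  fit2 <- fit_pchazard(matrix(numeric(0), 2000, 0), durations,
                       rep(1, 2000), cfg)
  expect_identical(fit$params$W, fit2$params$W)
  expect_error(fit_pchazard(matrix(0, 0, 1), numeric(0), numeric(0), cfg),
               "empty")
})

test_that("fit_pchazard learns a strong proportional-hazards signal", {
  dat <- ph_one_covariate(1500, b = 1, seed = 5)
  oracle <- score_concordance(-dat$risk, dat$durations, dat$events)
  cfg <- hazardnet_config(hidden = c(16, 16), lr = 0.02, epochs = 80, m = 8,
                          seed = 4)
  idx <- 1:1000
  fit <- fit_pchazard(dat$x[idx, , drop = FALSE], dat$durations[idx],
                      dat$events[idx], cfg)
  hold <- 1001:1500
  curves <- lapply(hold, function(i) predict_curve(fit, dat$x[i, ]))
  cc <- concordance(curves, dat$durations[hold], dat$events[hold])
  expect_gt(cc, 0.7)
  expect_gt(oracle, 0.72) # simulation ceiling sanity
})

test_that("dropout and batch-norm configurations train without error", {
  dat <- ph_one_covariate(300, seed = 8)
  cfg <- hazardnet_config(hidden = c(8, 8), dropout = 0.2, batch_norm = TRUE,
                          lr = 0.02, epochs = 10, m = 4, seed = 2)
  fit <- fit_pchazard(dat$x, dat$durations, dat$events, cfg)
  expect_length(fit$loss_trace, 10)
  lam <- pchaz:::model_hazards(fit, dat$x[1:5, ])
  expect_true(all(lam >= 0))
})

test_that("hazard models persist to plain text and round-trip", {
  dat <- ph_one_covariate(200, seed = 3)
  cfg <- hazardnet_config(hidden = 8, epochs = 5, m = 3, seed = 1)
  fit <- fit_pchazard(dat$x, dat$durations, dat$events, cfg)
  dir <- withr::local_tempdir()
  save_hazard_model(fit, dir)
  back <- load_hazard_model(dir)
  expect_equal(back$params$W, fit$params$W, tolerance = 1e-12)
  x <- dat$x[1, ]
  expect_equal(curve_at(predict_curve(back, x), 5),
               curve_at(predict_curve(fit, x), 5), tolerance = 1e-10)
})

test_that("zero-knot Royston-Parmar is exactly Weibull PH", {
  withr::with_seed(21, durations <- rweibull(2000, shape = 1.5, scale = 20))
  events <- rep(1, 2000)
  fit <- fit_royston_parmar(NULL, durations, events, 0)
  expect_equal(fit$gamma[2], 1.5, tolerance = 0.1)
  mle <- pchaz:::weibull_mle(durations, events)
  expect_equal(fit$loglik, mle$loglik, tolerance = 1e-4)
  # exponential data: shape ~ 1
  withr::with_seed(22, d2 <- rexp(1500, 0.05))
  fit2 <- fit_royston_parmar(NULL, d2, rep(1, 1500), 0)
  expect_equal(fit2$gamma[2], 1, tolerance = 0.1)
})

test_that("Royston-Parmar with covariates and knots predicts sane curves", {
  withr::with_seed(31, {
    x <- matrix(rnorm(800), 400, 2)
    t0 <- exp(log(20) + 0.5 * x[, 1] + rnorm(400) * 0.7)
    cens <- runif(400, 1, 80)
  })
  d <- as.numeric(t0 <= cens)
  fit <- fit_royston_parmar(x, pmin(t0, cens), d, 2)
  expect_true(fit$monotone)
  cv <- predict_curve(fit, c(1, 0)) # high x1: longer survival
  cv0 <- predict_curve(fit, c(-1, 0))
  expect_gt(as.numeric(median_survival(cv)), as.numeric(median_survival(cv0)))
  expect_true(all(diff(cv$surv) <= 1e-9))
  expect_error(fit_royston_parmar(NULL, c(1, 2), c(1, 0), 3), "events")
})
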