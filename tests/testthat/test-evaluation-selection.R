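step_curve <- function(times, surv) survival_curve(c(0, times), c(1, surv))

test_that("concordance closed cases: perfect ordering 1.0, constant 0.5", {
  # three patients, all events; lower survival curve for earlier deaths
  curves <- list(
    step_curve(c(5, 10), c(0.3, 0.1)),
    step_curve(c(5, 10), c(0.6, 0.4)),
    step_curve(c(5, 10), c(0.9, 0.8))
  )
  expect_equal(concordance(curves, c(2, 6, 12), c(1, 1, 1)), 1)
  same <- replicate(4, step_curve(c(5, 10), c(0.7, 0.5)), simplify = FALSE)
  expect_equal(concordance(same, c(1, 3, 7, 9), c(1, 1, 1, 1)), 0.5)
  expect_error(concordance(same, c(1, 2, 3, 4), c(0, 0, 0, 0)), "comparable")
})

test_that("concordance equals the brute-force pair oracle on random instances", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      n <- sample(5:30, 1)
      curves <- replicate(n, random_pch_curve(), simplify = FALSE)
      durations <- runif(n, 0.5, 9)
      # inject duration ties with mixed censoring to exercise tie handling
      if (n > 6) {
        durations[2] <- durations[1]
        durations[4] <- durations[3]
      }
      events <- rbinom(n, 1, 0.7)
      expect_equal(concordance(curves, durations, events),
                   concordance_oracle(curves, durations, events))
    }
  })
})

test_that("mad metrics follow the worked arithmetic and exclude censored", {
  r <- mad_metrics(c(12, 16), c(10, 20), c(1, 1))
  expect_equal(r$mad, 3)       # median(2, 4)
  expect_equal(r$nmad, 0.2)    # median(0.2, 0.2)
  perfect <- mad_metrics(c(7, 9), c(7, 9), c(1, 1))
  expect_equal(perfect$mad, 0)
  expect_equal(perfect$nmad, 0)
  one <- mad_metrics(c(5, 8), c(6, 100), c(1, 0))
  expect_equal(one$n_evaluated, 1)
  expect_equal(one$n_censored_excluded, 1)
  expect_equal(one$mad, 1)
  expect_error(mad_metrics(1, 2, 0), "uncensored")
})

test_that("rank_select implements lowest-rank-sum with mean ranks for ties", {
  mk <- function(c_index, mad, nmad)
    pchaz:::metric_report(c_index, mad, nmad, 10, 0)
  # worked example: A = (1,2,1), B = (2,1,2), C = (3,3,3)
  reports <- list(A = mk(0.8, 6, 0.3), B = mk(0.7, 5, 0.4),
                  C = mk(0.6, 7, 0.5))
  sel <- rank_select(reports)
  expect_equal(sel$selected_configuration, "A")
  expect_equal(sel$table$rank_sum, c(4, 5, 9))
  # single configuration trivially wins
  expect_equal(rank_select(reports["B"])$selected_configuration, "B")
  # dominance: best on all three always wins
  dom <- list(X = mk(0.9, 1, 0.1), Y = mk(0.7, 5, 0.4), Z = mk(0.8, 3, 0.2))
  expect_equal(rank_select(dom)$selected_configuration, "X")
  # restricted to one varying metric it is argmax/argmin of that metric
  onem <- list(P = mk(0.6, 2, 0.2), Q = mk(0.75, 2, 0.2), R = mk(0.7, 2, 0.2))
  expect_equal(rank_select(onem)$selected_configuration, "Q")
})

test_that("train_bag with bag_size 1 and full subsample equals a single fit", {
  dat <- ph_one_covariate(250, seed = 12)
  sch <- tte_schema(col_continuous("x"), col_duration("t"), col_event("d"))
  ds <- survival_dataset(data.frame(x = as.numeric(dat$x)), dat$durations,
                         dat$events, sch)
  net <- hazardnet_config(hidden = 8, epochs = 10, m = 4)
  bag <- train_bag(model_config("pchazard", net = net), ds, bag_size = 1,
                   subsample = 1, seed = 6)
  net1 <- net
  net1$seed <- derive_seed(6, "bag_member", 1)
  single <- fit_pchazard(encode(ds), ds$durations, ds$events, net1)
  expect_identical(bag$models[[1]]$params$W, single$params$W)
  # determinism of the whole bag
  bag2 <- train_bag(model_config("pchazard", net = net), ds, bag_size = 1,
                    subsample = 1, seed = 6)
  expect_identical(bag$models[[1]]$params, bag2$models[[1]]$params)
})

test_that("bag_predict is the pointwise median and stays monotone", {
  g <- structure(list(cuts = c(0, 1, 2), m = 2L), class = "discretization_grid")
  curves <- list(pchaz:::pch_curve(g, c(0.2, 0.2)),
                 pchaz:::pch_curve(g, c(0.7, 0.7)),
                 pchaz:::pch_curve(g, c(2, 2)))
  agg <- pchaz:::aggregate_curves(curves)
  expect_equal(curve_at(agg, 1), exp(-0.7), tolerance = 1e-9)
  expect_true(all(diff(agg$surv) <= 1e-12))
  # identical members return that curve
  same <- pchaz:::aggregate_curves(curves[c(2, 2, 2)])
  expect_equal(curve_at(same, 1.5), curve_at(curves[[2]], 1.5),
               tolerance = 1e-12)
  # property: median of random monotone curves is monotone (no clipping)
  withr::with_seed(5, {
    for (i in 1:10) {
      cs <- replicate(5, random_pch_curve(), simplify = FALSE)
      expect_true(all(diff(pchaz:::aggregate_curves(cs)$surv) <= 1e-12))
    }
  })
})

test_that("staged search evaluates stage sums, not the full product", {
  withr::with_seed(3, {
    dat <- ph_one_covariate(160, b = 0.8, seed = 33)
    sch <- tte_schema(col_continuous("x"), col_duration("t"), col_event("d"))
    ds <- survival_dataset(data.frame(x = as.numeric(dat$x)), dat$durations,
                           dat$events, sch)
  })
  grid <- staged_grid(family = list("pchazard"),
                      hidden = list(4, 8, c(8, 8)),
                      lr = list(0.05, 0.02, 0.01),
                      knots = list(2, 3, 4),
                      epochs = 4, batch_size = 64)
  res <- nested_tune(grid, ds, seed = 2, folds = 2)
  expect_lte(res$n_evaluated, 9) # 3 + 3 + 3, never 27
  expect_s3_class(res$outer_report, "metric_report")
  expect_true(res$choices$knots %in% c(2, 3, 4))
  # single-configuration grid returns it with metrics
  g1 <- staged_grid(family = list("pchazard"), hidden = list(4),
                    lr = list(0.05), knots = list(2), epochs = 3,
                    batch_size = 64)
  r1 <- nested_tune(g1, ds, seed = 2, folds = 2)
  expect_equal(r1$n_evaluated, 0)
  expect_equal(r1$choices$hidden, 4)
  expect_true(is.finite(r1$outer_report$c_index))
})

test_that("model-family stage can prefer the well-specified parametric model", {
  # Weibull-generated data at small n: the 0-knot spline (exact family)
  # competes against the deep model in the family stage
  withr::with_seed(41, {
    x <- matrix(rnorm(220), 220, 1)
    t0 <- rweibull(220, shape = 1.4, scale = 25 * exp(0.4 * x[, 1]))
  })
  sch <- tte_schema(col_continuous("x"), col_duration("t"), col_event("d"))
  ds <- survival_dataset(data.frame(x = x[, 1]), t0, rep(1, 220), sch)
  grid <- staged_grid(family = list("royston_parmar", "pchazard"),
                      hidden = list(8), lr = list(0.02), knots = list(0),
                      epochs = 8, batch_size = 64)
  wins <- 0
  for (s in 1:3) {
    res <- nested_tune(grid, ds, seed = s, folds = 3)
    if (res$choices$family == "royston_parmar") wins <- wins + 1
  }
  expect_gte(wins, 2)
})
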