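test_that("quartile_grid builds the Cartesian product of representatives", {
  sch <- tte_schema(col_continuous("a"), col_continuous("b"),
                    col_categorical("g", c("x", "y")),
                    col_treatment("trt", c("p", "q")),
                    col_duration("t"), col_event("d"))
  withr::with_seed(1, {
    df <- data.frame(a = runif(64), b = runif(64),
                     g = sample(c("x", "y"), 64, TRUE),
                     trt = sample(c("p", "q"), 64, TRUE))
  })
  ds <- survival_dataset(df, rep(1, 64), rep(1, 64), sch)
  grid <- quartile_grid(ds)
  expect_equal(nrow(grid), 4 * 4 * 2) # treatment column excluded
  expect_false("trt" %in% names(grid))
  expect_false(anyNA(grid))
})

test_that("quartile representatives are within-quartile medians", {
  sch <- tte_schema(col_continuous("v"), col_categorical("g", "only"),
                    col_duration("t"), col_event("d"))
  ds <- survival_dataset(data.frame(v = 1:8, g = "only"), rep(1, 8),
                         rep(1, 8), sch)
  grid <- quartile_grid(ds)
  expect_equal(sort(unique(grid$v)), c(1.5, 3.5, 5.5, 7.5))
  # fewer than 4 distinct values: the distinct values are used
  ds2 <- survival_dataset(data.frame(v = rep(c(1, 2), 4), g = "only"),
                          rep(1, 8), rep(1, 8), sch)
  expect_equal(sort(unique(quartile_grid(ds2)$v)), c(1, 2))
})

af_bag <- function(seed, n = 1200, interaction = 0.012, bag_size = 2,
                   epochs = 40) {
  spec <- af_like_preset(n, seed = seed, interaction_strength = interaction)
  spec$missingness <- list() # keep the unit test fast; imputation is
                             # exercised elsewhere
  ds <- generate_cohort(spec)
  mc <- model_config("pchazard",
                     net = hazardnet_config(hidden = c(16, 16), lr = 0.02,
                                            epochs = epochs, m = 6,
                                            seed = derive_seed(seed, "n")))
  list(ds = ds,
       bag = train_bag(mc, ds, bag_size = bag_size, subsample = 0.8,
                       seed = derive_seed(seed, "bag")),
       tcol = ds$schema$columns[["doac"]])
}

test_that("best_treatment reports argmax, margin and all per-level medians", {
  fx <- af_bag(seed = 2)
  patient <- data.frame(age = 74, sex = "M", weight = 80, egfr = 95,
                        chads_vasc = 3.5)
  rec <- best_treatment(fx$bag, patient, fx$tcol)
  expect_length(rec$medians, 3)
  expect_equal(rec$recommended,
               names(rec$medians)[which.max(rec$medians)])
  expect_gte(rec$margin, 0)
  expect_equal(rec$margin,
               unname(sort(rec$medians, decreasing = TRUE)[1] -
                        sort(rec$medians, decreasing = TRUE)[2]))
  # two-level treatment: margin is the plain difference
  t2 <- col_treatment("doac", c("apixaban", "rivaroxaban"))
  rec2 <- best_treatment(fx$bag, patient, t2)
  expect_equal(unname(rec2$margin), unname(abs(diff(rec2$medians))))
})

test_that("recommendations are invariant to treatment level ordering", {
  fx <- af_bag(seed = 4)
  patient <- data.frame(age = 70, sex = "F", weight = 75, egfr = 45,
                        chads_vasc = 4)
  fwd <- best_treatment(fx$bag, patient, fx$tcol)
  rev_col <- col_treatment("doac", rev(fx$tcol$levels))
  bwd <- best_treatment(fx$bag, patient, rev_col)
  expect_equal(fwd$recommended, bwd$recommended)
  expect_equal(fwd$medians[fx$tcol$levels], bwd$medians[fx$tcol$levels])
})

test_that("a treatment-by-covariate interaction flips the recommendation", {
  fx <- af_bag(seed = 6, n = 1500, epochs = 60)
  lo <- data.frame(age = 74, sex = "M", weight = 80, egfr = 40,
                   chads_vasc = 3.5)
  hi <- data.frame(age = 74, sex = "M", weight = 80, egfr = 100,
                   chads_vasc = 3.5)
  rec_lo <- best_treatment(fx$bag, lo, fx$tcol)
  rec_hi <- best_treatment(fx$bag, hi, fx$tcol)
  # generator: apixaban favoured at low eGFR, rivaroxaban at high; a single
  # seed may confuse rivaroxaban with the neutral drug at high eGFR, so the
  # unit test asserts the flip away from apixaban (the strict majority-of-
  # seeds recovery is an acceptance criterion)
  expect_equal(rec_lo$recommended, "apixaban")
  expect_true(rec_hi$recommended != "apixaban")
  expect_gt(rec_hi$medians["rivaroxaban"], rec_hi$medians["apixaban"])
})
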