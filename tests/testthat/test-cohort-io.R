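test_that("schema construction enforces its invariants", {
  expect_s3_class(toy_schema(), "tte_schema")
  expect_error(tte_schema(col_continuous("x"), col_event("d")),
               "duration")
  expect_error(tte_schema(col_continuous("x"), col_duration("t")),
               "event")
  expect_error(col_categorical("g", character(0)), "levels")
  expect_error(col_categorical("g", c("a", "a")), "duplicate")
})

test_that("read_cohort drops rows with unusable outcome and logs the count", {
  path <- write_toy_csv(c(
    "age,slope,sex,months,died",
    "60,1.2,F,12,1",
    "55,0.8,M,,1",     # missing duration -> dropped
    "70,1.5,F,8,0",
    "65,0.9,M,30,1",
    "50,1.1,F,5,1"
  ))
  expect_message(ds <- read_cohort(path, toy_schema()), "dropped 1 row")
  expect_equal(ds$n, 4)
  expect_false(any(missing_mask(ds)))
})

test_that("read_cohort records missing covariate cells in the mask", {
  path <- write_toy_csv(c(
    "age,slope,sex,months,died",
    "60,,F,12,1",
    "55,0.8,M,9,1",
    "70,,F,8,0",
    "65,0.9,M,30,1",
    "50,1.1,F,5,1",
    "48,0.7,M,22,1"
  ))
  ds <- read_cohort(path, toy_schema())
  mask <- missing_mask(ds)
  expect_equal(unname(which(mask[, "slope"])), c(1, 3))
  expect_equal(sum(mask), 2)
})

test_that("read_cohort rejects bad durations, events and levels row-wise", {
  path <- write_toy_csv(c(
    "age,slope,sex,months,died",
    "60,1.2,F,-3,1",   # non-positive duration
    "55,0.8,X,9,1",    # unknown level
    "70,1.5,F,8,2",    # bad event code
    "65,0.9,M,30,1"
  ))
  expect_message(ds <- read_cohort(path, toy_schema()), "dropped 3")
  expect_equal(ds$n, 1)
})

test_that("write_cohort / read_cohort round-trips a complete dataset", {
  ds <- toy_dataset(n = 25, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ds, path)
  back <- read_cohort(path, toy_schema())
  expect_equal(back$data, ds$data)
  expect_equal(back$durations, ds$durations)
  expect_equal(back$events, ds$events)
})

test_that("encode standardises with population sd and one-hot encodes all levels", {
  sch <- tte_schema(col_continuous("x"), col_categorical("g", c("M", "F")),
                    col_duration("t"), col_event("d"))
  ds <- survival_dataset(data.frame(x = c(1, 2, 3), g = c("M", "F", "M")),
                         c(1, 2, 3), c(1, 1, 0), sch)
  enc <- encode(ds)
  expect_equal(enc$matrix[, "x"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(unname(enc$matrix[, "g=M"] + enc$matrix[, "g=F"]), rep(1, 3))
  expect_equal(ncol(enc$matrix), 3) # x + two indicators, no reference drop
})

test_that("encode with training stats never re-fits on validation data", {
  sch <- tte_schema(col_continuous("x"), col_duration("t"), col_event("d"))
  train <- survival_dataset(data.frame(x = c(1, 2, 3)), 1:3, c(1, 1, 1), sch)
  enc_tr <- encode(train)
  val <- survival_dataset(data.frame(x = 5), 4, 1, sch)
  enc_va <- encode(val, fit_stats = enc_tr)
  mu <- enc_tr$provenance$mu[1]; sigma <- enc_tr$provenance$sigma[1]
  expect_equal(unname(enc_va$matrix[1, "x"]), (5 - mu) / sigma)
  expect_identical(enc_va$provenance$mu, enc_tr$provenance$mu)
  # closed form from the spec's worked example (mu = 2, sigma = 1)
  val2 <- survival_dataset(data.frame(x = 5), 4, 1, sch)
  prov <- enc_tr$provenance
  prov$mu <- 2; prov$sigma <- 1
  expect_equal(unname(encode(val2, fit_stats = prov)$matrix[1, "x"]), 3)
})

test_that("encode errors on zero variance and missing values", {
  sch <- tte_schema(col_continuous("x"), col_duration("t"), col_event("d"))
  flat <- survival_dataset(data.frame(x = c(2, 2, 2)), 1:3, c(1, 1, 1), sch)
  expect_error(encode(flat), "zero-variance.*x")
  ds <- toy_dataset(10)
  ds$data$age[1] <- NA
  expect_error(encode(ds), "missing")
})

test_that("shuffle_covariates permutes columns independently and deterministically", {
  ds <- toy_dataset(n = 60, seed = 2)
  sh1 <- shuffle_covariates(ds, seed = 9)
  sh2 <- shuffle_covariates(ds, seed = 9)
  expect_identical(sh1$data, sh2$data)
  # multisets preserved per column, outcome untouched
  for (nm in names(ds$data))
    expect_equal(sort(as.character(sh1$data[[nm]])),
                 sort(as.character(ds$data[[nm]])))
  expect_identical(sh1$durations, ds$durations)
  expect_identical(sh1$events, ds$events)
  # columns permuted independently (joint structure broken for some seed)
  expect_false(identical(sh1$data, ds$data))
  # n = 1 is a no-op
  one <- survival_dataset(ds$data[1, , drop = FALSE], ds$durations[1],
                          ds$events[1], ds$schema)
  expect_identical(shuffle_covariates(one, 5)$data, one$data)
})

test_that("schema YAML round-trips", {
  sch <- toy_schema()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(sch, path)
  back <- read_schema(path)
  expect_equal(names(back$columns), names(sch$columns))
  expect_equal(back$columns[["sex"]]$levels, c("F", "M"))
  expect_equal(back$columns[["months"]]$units, "months")
})
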