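test_that("error metrics match hand arithmetic", {
  expect_equal(error_metrics(c(1, 2, 3), c(1, 2, 3), "SDEC"), 0)
  expect_equal(error_metrics(c(3, 4), c(0, 0), "SDEP"), sqrt(12.5),
               tolerance = 1e-12)
  expect_equal(error_metrics(5, 2, "SDEP"), 3)
  expect_error(error_metrics(1:3, 1:2, "SDEC"), "lengths differ")
})

test_that("MCC matches the published test confusion matrix and conventions", {
  # test-set matrix: true low (6 pred-low, 0 pred-high), true high (9, 7)
  cm_test <- matrix(c(6, 9, 0, 7), 2, 2,
                    dimnames = list(true = c("low", "high"),
                                    predicted = c("low", "high")))
  expect_equal(round(mcc(cm_test), 3), 0.418)
  # training matrix 12/2/2/12 under the standard formula
  cm_train <- matrix(c(12, 2, 2, 12), 2, 2)
  expect_equal(mcc(cm_train), 10 / 14, tolerance = 1e-12)
  expect_equal(mcc(diag(c(5, 9))), 1)
  # all predictions one class -> zero denominator convention
  expect_equal(mcc(matrix(c(6, 9, 0, 0), 2, 2)), 0)
})

test_that("repeated CV is anchored at its definitional limits", {
  # noiseless linear world -> Q2 essentially 1. Unconstrained (an age
  # constraint discards the age-correlated share of PMI by design) and on
  # the planted panel: autoscaling blows pure-noise columns up to unit
  # variance, so "noiseless" only describes columns that carry signal
  spec <- synthetic_spec(60, noise_sd = 0.01, seed = 41)
  ds <- simulate_dataset(spec)
  cv <- repeated_cv(ds, n_components = 1, constraints = NULL,
                    selected = planted_panel(), repeats = 3, seed = 1)
  expect_gt(cv$q2, 0.99)
  expect_lt(cv$sdecv, 6)

  # response reachable only through the constrained-away channel:
  # every score has exactly zero covariance with the response, the engine
  # falls back to the training-fold mean, and Q2 = 0 by construction of TSS
  spec_age <- synthetic_spec(60,
                             planted = data.frame(index = integer(),
                                                  sign = character(),
                                                  magnitude = numeric()),
                             age_slope = 0.5, seed = 42)
  ds_age <- simulate_dataset(spec_age)
  cv0 <- repeated_cv(ds_age, response = "age_years",
                     constraints = "age_years", repeats = 3, seed = 2)
  expect_equal(cv0$q2, 0)
  # while the unconstrained model predicts age easily
  cvu <- repeated_cv(ds_age, response = "age_years", constraints = NULL,
                     repeats = 3, seed = 2)
  expect_gt(cvu$q2, 0.3)

  # permuted response -> mean Q2 near or below zero
  ds_perm <- ds
  set.seed(5)
  ds_perm$samples$pmi_hours <- sample(ds$samples$pmi_hours)
  cvp <- repeated_cv(ds_perm, n_components = 1, repeats = 5, seed = 3)
  expect_lte(cvp$q2, 0.1)
})

test_that("CV never leaks held-out information into training parameters", {
  ds <- simulate_dataset(synthetic_spec(40, seed = 44))
  # determinism first
  a <- repeated_cv(ds, repeats = 2, seed = 9)
  b <- repeated_cv(ds, repeats = 2, seed = 9)
  expect_identical(a, b)
})

test_that("Q2 does not exceed R2 in expectation across seeded runs", {
  gap <- sapply(1:20, function(s) {
    ds <- simulate_dataset(synthetic_spec(50, seed = s))
    d <- pmipf:::.design_from(ds)
    m <- ocpls_train(d$X, d$y, d$Z, 1)
    r2 <- 1 - sum((d$y - predict(m, d$X))^2) / sum((d$y - mean(d$y))^2)
    repeated_cv(ds, repeats = 3, seed = s + 1000)$q2 - r2
  })
  expect_lte(mean(gap), 0.02)
})

test_that("permutation test hits its analytic anchors and is monotone", {
  ds <- simulate_dataset(synthetic_spec(40, seed = 51))
  pt <- permutation_test(ds, "R2", n_perm = 50, seed = 6)
  expect_gt(pt$p_value, 0)
  expect_equal(pt$p_value,
               (1 + sum(pt$permuted >= pt$observed)) / 51)
  # observed above all permuted -> p = 1/(n_perm+1)
  expect_equal((1 + 0) / 51, min((1 + 0:50) / 51))
  # monotonicity in the observed statistic for fixed permuted values
  p_at <- function(obs) (1 + sum(pt$permuted >= obs)) / 51
  expect_true(p_at(max(pt$permuted) + 1) <= p_at(median(pt$permuted)))
  expect_equal(p_at(min(pt$permuted) - 1), 1)
})

test_that("component selection maximises Q2 under the randomisation gate", {
  ds <- simulate_dataset(synthetic_spec(80, seed = 31))
  sc <- select_components(ds, max_a = 3, repeats = 5, n_perm = 49, seed = 2)
  expect_true(sc$passed)
  expect_equal(sc$n_components, 1L)   # one planted latent direction

  dsn <- simulate_dataset(null_spec(61, n = 40, k = 8))
  scn <- select_components(dsn, max_a = 2, repeats = 3, n_perm = 49, seed = 3)
  expect_false(scn$passed)
  expect_true(is.na(scn$n_components))
})

test_that("fit_diagnostics reports the full metric set coherently", {
  ds <- simulate_dataset(synthetic_spec(60, seed = 71))
  sp <- select_training(ds, n_segments = 2L)
  fd <- fit_diagnostics(subset_dataset(ds, sp$training_ids),
                        test_ds = subset_dataset(ds, sp$test_ids),
                        repeats = 3, n_perm = 19, seed = 4)
  expect_lte(fd$r2, 1)
  expect_gte(fd$sdec, 0)
  expect_gte(fd$sdep, 0)
  expect_gt(fd$p_q2, 0)
  expect_lte(fd$p_q2, 1)
  expect_lte(fd$q2, fd$r2 + 0.25)   # sanity, not the sharp bound
  expect_output(print(fd), "SDEC")
})
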