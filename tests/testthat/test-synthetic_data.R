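test_that("covariate generator hits the target PMI-age correlation", {
  spec <- synthetic_spec(2000, seed = 101)
  cv <- generate_covariates(spec)
  expect_lte(abs(cor(cv$pmi_hours, cv$age_years) - 0.35), 0.05)
  expect_true(all(cv$pmi_hours >= 16 & cv$pmi_hours <= 199))
  expect_true(all(cv$age_years >= 15 & cv$age_years <= 90))
  # roughly 2:1 M:F
  expect_lte(abs(mean(cv$sex == "M") - 2 / 3), 0.05)

  spec0 <- synthetic_spec(2000, age_confound = 0, seed = 102)
  cv0 <- generate_covariates(spec0)
  expect_lt(abs(cor(cv0$pmi_hours, cv0$age_years)), 0.05)
})

test_that("generator is deterministic under seed and leaves the caller's RNG alone", {
  spec <- synthetic_spec(50, seed = 7)
  a <- generate_covariates(spec)
  set.seed(999)
  before <- runif(1)
  b <- generate_covariates(spec)
  expect_identical(a, b)
  set.seed(999)
  expect_identical(runif(1), before)  # with_seed restored the stream

  d1 <- simulate_dataset(spec)
  d2 <- simulate_dataset(spec)
  expect_identical(d1$concentrations, d2$concentrations)
})

test_that("noiseless planted column is an exact affine function of PMI", {
  spec <- synthetic_spec(30, n_metabolites = 6,
                         planted = data.frame(index = 2L, sign = "+",
                                              magnitude = 0.1),
                         age_driven = integer(), noise_sd = 0, seed = 5)
  ds <- simulate_dataset(spec)
  fit <- lm(ds$concentrations[, 2] ~ ds$samples$pmi_hours)
  expect_equal(unname(coef(fit)[2]), 0.1, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("OLS on a planted column recovers the generating PMI slope", {
  spec <- synthetic_spec(500, seed = 11)
  ds <- simulate_dataset(spec)
  fit <- summary(lm(ds$concentrations[, "Choline"] ~
                      ds$samples$age_years + ds$samples$pmi_hours))
  est <- fit$coefficients[3, "Estimate"]
  se <- fit$coefficients[3, "Std. Error"]
  expect_lt(abs(est - 0.08), 2 * se)
})

test_that("all-null generator produces calibrated chance correlations", {
  # fraction of columns whose |r| with PMI clears the 5%-level critical
  # value should itself be about 5%
  hits <- unlist(lapply(1:30, function(s) {
    ds <- simulate_dataset(null_spec(s, n = 40, k = 10))
    sapply(seq_len(10), function(j) {
      pearson(ds$concentrations[, j], ds$samples$pmi_hours)$p_value < 0.05
    })
  }))
  expect_lte(abs(mean(hits) - 0.05), 0.04)
})

test_that("replicate batch has controllable per-column noise", {
  spec <- synthetic_spec(40, batch_noise_sd = 0, seed = 13)
  both <- simulate_dataset(spec, batches = 2)
  sim0 <- cosine_batch_similarity(both$batch1, both$batch2)
  expect_equal(sim0$cosine, rep(1, 46), tolerance = 1e-12)

  # tuned noise: exactly the stable columns clear the 0.90 flag, and the
  # unstable ones always rank below every stable one
  unstable <- c(20L, 21L, 22L, 23L)
  spec2 <- synthetic_spec(40, batch_noise_sd = 1.6,
                          unstable_metabolites = unstable, seed = 13)
  both2 <- simulate_dataset(spec2, batches = 2)
  sim <- cosine_batch_similarity(both2$batch1, both2$batch2)
  bad_names <- default_metabolite_names(46)[unstable]
  expect_lt(max(sim$cosine[sim$metabolite %in% bad_names]),
            min(sim$cosine[!sim$metabolite %in% bad_names]))
  expect_setequal(sim$metabolite[!sim$strong], bad_names)

  # determinism of the replicate
  both3 <- simulate_dataset(spec2, batches = 2)
  expect_identical(both2$batch2$concentrations, both3$batch2$concentrations)
})

test_that("generated datasets satisfy the container invariants", {
  for (s in 1:3) {
    ds <- simulate_dataset(synthetic_spec(25, seed = s))
    expect_true(all(ds$concentrations >= 0))
    expect_false(anyNA(ds$concentrations))
    expect_equal(rownames(ds$concentrations), ds$samples$sample_id)
    expect_false(anyDuplicated(colnames(ds$concentrations)) > 0)
  }
})

test_that("spec validation rejects inconsistent worlds", {
  expect_error(synthetic_spec(2), "n_samples")
  expect_error(synthetic_spec(20, age_confound = 1), "age_confound")
  expect_error(synthetic_spec(20, planted = data.frame(index = c(3L, 3L),
                                                       sign = "+",
                                                       magnitude = 0.1)),
               "distinct")
  expect_error(synthetic_spec(20, n_metabolites = 4,
                              planted = data.frame(index = 9L, sign = "+",
                                                   magnitude = 0.1)),
               "1..n_metabolites")
  expect_error(synthetic_spec(20, pmi_range = c(100, 50)), "pmi_range")
})
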