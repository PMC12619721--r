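test_that("binary matrix sampling has the stated marginal rates", {
  masks <- binary_matrix_sample(100, 40, p = 0.7, n_subsets = 200, seed = 1)
  rows <- sapply(masks, function(m) length(m$rows))
  cols <- sapply(masks, function(m) length(m$cols))
  expect_equal(mean(rows), 70, tolerance = 3 / 70)   # 70 +- 3
  expect_equal(mean(cols), 28, tolerance = 0.1)
  expect_true(all(rows >= 10) && all(cols >= 2))

  # p near 1 -> essentially full masks
  full <- binary_matrix_sample(50, 10, p = 0.999, n_subsets = 20, seed = 2)
  expect_true(all(sapply(full, function(m) length(m$rows)) >= 49))

  # seeded determinism
  expect_identical(binary_matrix_sample(30, 8, seed = 3),
                   binary_matrix_sample(30, 8, seed = 3))
  # the validity floor is enforced by redrawing
  tight <- binary_matrix_sample(12, 3, p = 0.7, n_subsets = 50, seed = 4)
  expect_true(all(sapply(tight, function(m) length(m$rows)) >= 10))
  expect_error(binary_matrix_sample(5, 3, seed = 1), "cannot sample")
  expect_error(binary_matrix_sample(20, 3, p = 1.2), "p must lie")
})

test_that("per-subset VIP selection recovers a complementary planted panel", {
  # each planted column carries the PMI trend plus independent noise, so
  # every additional planted column improves CV error materially while the
  # null columns add nothing (noiseless deterministic predictors would be
  # redundant: one column predicts perfectly and the smaller-set tie-break
  # correctly returns a singleton)
  set.seed(10)
  n <- 60
  pmi <- runif(n, 16, 199)
  X <- cbind(a = 40 + 0.15 * pmi + rnorm(n, 0, 5),
             b = 60 - 0.15 * pmi + rnorm(n, 0, 5),
             c = 35 + 0.15 * pmi + rnorm(n, 0, 5),
             matrix(abs(rnorm(n * 5, 25, 3)), n, 5,
                    dimnames = list(NULL, paste0("n", 1:5))))
  sel <- select_in_subset(X, pmi, NULL)
  expect_setequal(as.character(sel), c("a", "b", "c"))
  expect_gt(attr(sel, "q2"), 0.7)

  # single-candidate subset
  one <- select_in_subset(X[, "a", drop = FALSE], pmi, NULL)
  expect_equal(as.character(one), "a")

  # pure noise: flagged, constant response: empty
  noise <- X[, 4:8]
  seln <- select_in_subset(noise, pmi, NULL)
  expect_true(isTRUE(attr(seln, "no_positive_q2")) || length(seln) <= 2)
  expect_warning(out <- select_in_subset(X, rep(1, n), NULL), "constant")
  expect_length(out, 0)
})

test_that("stability selection recovers a planted panel on the training scale", {
  ds <- simulate_dataset(synthetic_spec(200, seed = 81))
  sel <- stability_select(ds, n_subsets = 60, seed = 81)
  got <- selected_metabolites(sel)
  expect_gte(sum(planted_panel() %in% got), 6)
  expect_lte(sum(!got %in% c(planted_panel(), age_driven_panel())), 2)
  # result table invariants
  df <- as.data.frame(sel)
  expect_true(all(df$frequency >= 0 & df$frequency <= 1, na.rm = TRUE))
  expect_true(all(df$p_value[df$selected] < 0.05))
  expect_identical(attr(sel, "selected_names"),
                   df$metabolite[df$selected])
})

test_that("metabolites never sampled get NA p-values and are never selected", {
  ds <- simulate_dataset(synthetic_spec(40, n_metabolites = 30, seed = 82))
  sel <- stability_select(ds, n_subsets = 2, seed = 82)
  df <- as.data.frame(sel)
  unsampled <- df$n_eligible == 0
  expect_gt(sum(unsampled), 0)        # 2 subsets at p=0.7 leave gaps
  expect_true(all(is.na(df$p_value[unsampled])))
  expect_true(all(!df$selected[unsampled]))
})

test_that("raising a planted slope never lowers selection frequency (paired seeds)", {
  freq_of <- function(mag, seed) {
    spec <- synthetic_spec(80, n_metabolites = 12,
                           planted = data.frame(index = 1L, sign = "+",
                                                magnitude = mag),
                           age_driven = integer(), seed = seed)
    ds <- simulate_dataset(spec)
    sel <- stability_select(ds, n_subsets = 40, seed = seed + 7)
    as.data.frame(sel)$frequency[1]
  }
  lo <- mean(sapply(1:4, freq_of, mag = 0.02))
  hi <- mean(sapply(1:4, freq_of, mag = 0.12))
  expect_gte(hi, lo)
})

test_that("the permutation null is calibrated on all-noise data", {
  fp <- sapply(1:2, function(s) {
    ds <- simulate_dataset(null_spec(s, n = 60, k = 15))
    sel <- stability_select(ds, n_subsets = 25, null_method = "empirical",
                            n_null = 39, seed = s)
    length(selected_metabolites(sel))
  })
  expect_lte(mean(fp), 2 * 0.05 * 15)
})

test_that("selection results export to CSV", {
  ds <- simulate_dataset(synthetic_spec(40, n_metabolites = 10, seed = 83))
  sel <- stability_select(ds, n_subsets = 15, seed = 83)
  path <- tempfile(fileext = ".csv")
  write_selection(sel, path)
  back <- read.csv(path)
  expect_equal(back$metabolite, as.data.frame(sel)$metabolite)
  expect_equal(back$selected, as.data.frame(sel)$selected)
})
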