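test_that("pearson agrees with the cor.test oracle and the fixture", {
  set.seed(1)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  mine <- pearson(x, y)
  oracle <- cor.test(x, y)
  expect_equal(mine$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)

  # exact linear relation
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)

  # full-window PMI-age correlations computed from the covariate table
  # (the study's printed 0.35/0.37/0.23 were training-set values; see the
  # methods vignette)
  ext <- load_table1_fixture(extended_only = TRUE)
  expect_equal(round(pearson(ext$pmi_hours, ext$age_years)$r, 2), 0.36)
  w130 <- filter_by_pmi(ext, 16, 130)
  expect_equal(round(pearson(w130$pmi_hours, w130$age_years)$r, 2), 0.40)
  w100 <- filter_by_pmi(ext, 16, 100)
  expect_equal(round(pearson(w100$pmi_hours, w100$age_years)$r, 2), 0.25)

  expect_error(pearson(c(1, 1, 1), 1:3), "zero-variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("age correction returns OLS residuals with the stated degeneracies", {
  age <- c(20, 30, 40, 50, 60)
  expect_equal(age_correct(2 * age, age), rep(0, 5), tolerance = 1e-12)
  conc <- c(5, 9, 2, 7, 4)
  expect_warning(res <- age_correct(conc, rep(42, 5)), "constant age")
  expect_equal(res, conc - mean(conc))
  expect_equal(mean(age_correct(conc, age)), 0, tolerance = 1e-12)

  # partial correlation recovered within 2 SE on a planted world
  ds <- simulate_dataset(synthetic_spec(400, seed = 55))
  resid_c <- age_correct(ds$concentrations[, "Glycine"], ds$samples$age_years)
  r <- pearson(resid_c, ds$samples$pmi_hours)$r
  expect_gt(r, 0.4)   # strongly positive planted trend survives correction
})

test_that("MLR screen controls FDR and finds planted directions", {
  ds <- simulate_dataset(synthetic_spec(120, seed = 9))
  scr <- mlr_screen(ds)
  expect_true(all(scr$q_value >= scr$p_value))
  hits <- scr$metabolite[scr$significant]
  expect_true(all(planted_panel() %in% hits))
  dirs <- scr$direction[match(planted_panel(), scr$metabolite)]
  expect_equal(dirs, c("+", "+", "+", "+", "+", "-", "-", "-"))

  # partialling consistency: MLR slope and age-corrected r share signs
  expect_equal(sign(scr$coefficient), sign(scr$r))

  # BH step-up is order invariant: permuting metabolites permutes q-values
  perm <- sample(ncol(ds$concentrations))
  ds2 <- pmi_dataset(ds$concentrations[, perm], ds$samples)
  scr2 <- mlr_screen(ds2)
  expect_equal(scr2$q_value[match(scr$metabolite, scr2$metabolite)],
               scr$q_value)
})

test_that("MLR screen stays quiet on null data and rejects singular designs", {
  fd <- sapply(1:10, function(s) {
    ds <- simulate_dataset(null_spec(s, n = 40, k = 10))
    sum(mlr_screen(ds)$significant)
  })
  expect_lte(mean(fd), 2 * 0.05 * 10)

  ds <- simulate_dataset(null_spec(99, n = 20, k = 5))
  ds$samples$age_years <- ds$samples$pmi_hours / 2   # collinear
  expect_error(mlr_screen(ds), "singular")
})

test_that("logistic screen flags shifted metabolites and only those", {
  spec <- synthetic_spec(120, seed = 14)
  ds <- simulate_dataset(spec)
  cls <- classify_pmi(ds$samples$pmi_hours, 100)
  scr <- logistic_screen(ds, cls)
  # strongly PMI-linked planted columns separate the classes, positive for high
  chol <- scr[scr$metabolite == "Choline", ]
  expect_true(chol$significant)
  expect_equal(chol$direction, "+")

  # a metabolite identical in both classes is null
  flat <- ds
  flat$concentrations[, "Uridine"] <- rep(c(10, 12), length.out = 120)
  s2 <- logistic_screen(flat, cls)
  expect_false(s2$significant[s2$metabolite == "Uridine"])
  expect_gt(s2$p_value[s2$metabolite == "Uridine"], 0.2)

  # quasi-separation is flagged with missing p
  sep <- ds
  sep$concentrations[, "Citrate"] <- ifelse(cls == "high", 100, 1)
  s3 <- suppressWarnings(logistic_screen(sep, cls))
  row <- s3[s3$metabolite == "Citrate", ]
  expect_true(row$separation)
  expect_true(is.na(row$p_value))

  # null calibration at plain alpha
  frac <- sapply(1:6, function(s) {
    dsn <- simulate_dataset(null_spec(s, n = 60, k = 10))
    cl <- classify_pmi(dsn$samples$pmi_hours, median(dsn$samples$pmi_hours))
    mean(logistic_screen(dsn, cl)$significant)
  })
  expect_lte(mean(frac), 0.15)
  expect_error(logistic_screen(ds, factor(rep("low", 120))), "two levels")
})
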