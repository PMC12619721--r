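# The constrained-PLS core: oracle equivalences, the orthogonality contract,
# and VIP identities.

scaled_xy <- function(n = 20, k = 5, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * k), n, k))
  y <- scale(rnorm(n))
  list(X = X, y = y)
}

test_that("full-component PLS2 equals ordinary least squares", {
  for (seed in 1:5) {
    d <- scaled_xy(20, 5, seed)
    m <- fit_pls2(d$X, d$y, 5)
    ols <- unname(coef(lm(d$y ~ d$X - 1)))        # independent oracle
    expect_equal(unname(drop(m$coefficients)), ols, tolerance = 1e-6)
  }
})

test_that("one-component PLS1 weight is the X'y direction", {
  d <- scaled_xy(30, 4, 2)
  m <- fit_pls2(d$X, d$y, 1)
  v <- drop(crossprod(d$X, d$y)); v <- v / sqrt(sum(v^2))
  b <- drop(m$coefficients)
  expect_equal(abs(cor(b, v)), 1, tolerance = 1e-10)
})

test_that("noiseless single-direction response is fitted exactly", {
  # orthogonal predictors: one component along X'y then captures y entirely
  set.seed(4)
  X <- qr.Q(qr(matrix(rnorm(60), 20, 3))) * sqrt(19)
  y <- X[, 1]
  m <- fit_pls2(X, y, 1)
  expect_lt(max(abs(X %*% m$coefficients - y)), 1e-8)
})

test_that("score orthogonality to the constraint holds on every fit", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- scale(matrix(rnorm(30 * 8), 30, 8))
    y <- scale(rnorm(30))
    Z <- matrix(rnorm(30 * 2), 30, 2)
    m <- fit_ocpls2(X, y, Z, 3)
    Zc <- sweep(Z, 2, colMeans(Z))
    expect_lt(max(abs(crossprod(Zc, m$scores))), 1e-8)
    # score columns mutually orthogonal
    off <- crossprod(m$scores); diag(off) <- 0
    expect_lt(max(abs(off)), 1e-8)
  }
})

test_that("vacuous constraints reduce bitwise to plain PLS2", {
  d <- scaled_xy(20, 5, 3)
  plain <- fit_pls2(d$X, d$y, 3)
  vac <- fit_ocpls2(d$X, d$y, matrix(1, 20, 1), 3)  # constant -> centred zero
  expect_identical(vac$coefficients, plain$coefficients)
  expect_identical(vac$scores, plain$scores)
})

test_that("constraining on age shrinks an age-only predictor's coefficient", {
  shrunk <- sapply(1:5, function(seed) {
    set.seed(seed)
    n <- 80
    age <- rnorm(n)
    X <- cbind(agecol = 2 * age + rnorm(n, 0, 0.2),
               matrix(rnorm(n * 4), n, 4))
    y <- 0.5 * age + rnorm(n, 0, 0.5)   # response reachable only via age
    Xs <- scale(X); ys <- scale(y)
    mu <- fit_pls2(Xs, ys, 2)
    mc <- fit_ocpls2(Xs, ys, matrix(age), 2)
    abs(mc$coefficients[1, 1]) < abs(mu$coefficients[1, 1])
  })
  expect_true(all(shrunk))
})

test_that("constraint exhaustion and invalid shapes error", {
  set.seed(9)
  X <- scale(matrix(rnorm(40), 20, 2))
  Z <- X  # Z'X full rank = K
  expect_error(fit_ocpls2(X, scale(rnorm(20)), Z, 1), "exhaust")
  expect_error(fit_pls2(X, scale(rnorm(20)), 10), "n_components")
  expect_error(fit_pls2(X, rep(1, 20), 1), "zero-variance")
})

test_that("prediction applies stored scalings and centring", {
  set.seed(12)
  n <- 40
  X <- matrix(abs(rnorm(n * 5, 20, 4)), n, 5,
              dimnames = list(NULL, paste0("M", 1:5)))
  y <- drop(X %*% c(1, -0.5, 0, 0, 0)) + 3
  m <- ocpls_train(X, y, NULL, n_components = 5)
  # in-sample fitted values (SDEC input)
  expect_lt(error_metrics(y, predict(m, X), "SDEC"), 1e-6)
  # row of training means predicts the training response mean
  expect_equal(unname(predict(m, matrix(colMeans(X), 1))), mean(y),
               tolerance = 1e-8)
  # noiseless new rows predicted exactly
  Xnew <- matrix(abs(rnorm(10 * 5, 20, 4)), 10, 5)
  expect_lt(max(abs(predict(m, Xnew) - (drop(Xnew %*% c(1, -0.5, 0, 0, 0)) + 3))),
            1e-6)
  expect_error(predict(m, matrix(0, 2, 3)), "columns")
})

test_that("VIP satisfies its normalisation and concentration identities", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- scale(matrix(rnorm(30 * 7), 30, 7))
    y <- scale(rnorm(30))
    m <- fit_pls2(X, y, 3)
    v <- vip(m)
    expect_equal(sum(v^2), 7, tolerance = 1e-10)
    expect_true(all(v >= 0))
  }
  # equal |weights| -> all VIP 1; handcrafted single-variable weight -> sqrt(K)
  k <- 6
  X <- matrix(0, 10, k)
  base <- scale(rnorm(10))
  for (j in 1:k) X[, j] <- base       # identical columns: w spreads equally
  y <- base
  m <- fit_pls2(X, y, 1)
  expect_equal(unname(vip(m)), rep(1, k), tolerance = 1e-8)

  X2 <- cbind(base, matrix(rnorm(10 * (k - 1), 0, 1e-8), 10, k - 1))
  m2 <- fit_pls2(X2, y, 1)
  v2 <- vip(m2)
  expect_equal(unname(v2[1]), sqrt(k), tolerance = 1e-2)
})

test_that("classifier codes, thresholds and reduces as specified", {
  set.seed(20)
  n <- 30
  x1 <- c(rnorm(n / 2, -4), rnorm(n / 2, 4))
  cls <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  # perfectly separated single predictor -> diagonal training confusion
  m1 <- fit_ocpls2c(scale(cbind(x1)), cls, NULL, 1)
  expect_equal(mcc(confusion_matrix(cls, predict(m1, scale(cbind(x1))))), 1)

  X <- scale(cbind(x1, matrix(rnorm(n * 3), n, 3)))
  m <- fit_ocpls2c(X, cls, NULL, 1)
  # vacuous constraint equals plain PLS-DA
  mv <- fit_ocpls2c(X, cls, matrix(1, n, 1), 1)
  expect_identical(mv$coefficients, m$coefficients)
  # balanced coding centres the threshold at zero
  expect_equal(m$y_scaling$center, 0)
  expect_error(fit_ocpls2c(X, factor(rep("low", n)), NULL, 1), "two classes")
})

test_that("models serialise to JSON and replay identically", {
  set.seed(31)
  X <- matrix(abs(rnorm(25 * 4, 15, 3)), 25, 4,
              dimnames = list(NULL, paste0("M", 1:4)))
  y <- rnorm(25, 50, 10)
  Z <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "age_years"))
  m <- ocpls_train(X, y, Z, 2)
  path <- tempfile(fileext = ".json")
  write_ocpls_model(m, path)
  back <- read_ocpls_model(path)
  Xnew <- matrix(abs(rnorm(5 * 4, 15, 3)), 5, 4)
  expect_equal(predict(back, Xnew), predict(m, Xnew), tolerance = 1e-12)
})
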