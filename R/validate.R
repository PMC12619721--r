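# Validation: repeated stratified k-fold CV with Q2/SDECV, error metrics,
# response-permutation tests, component-number selection, MCC.
#
# Leakage discipline: inside every CV fold the autoscaling parameters, the
# response scaling and the constraint null-space basis are re-estimated on
# the training folds only; held-out samples are projected with the stored
# parameters.

#' Root-mean-square prediction error (SDEC / SDECV / SDEP)
#'
#' `sqrt(sum((y - yhat)^2) / n)` in response units; the three names only
#' record where the residuals came from (training, cross-validation,
#' independent test set).
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param kind label, one of `"SDEC"`, `"SDECV"`, `"SDEP"`.
#' @return non-negative scalar.
#' @export
error_metrics <- function(y_true, y_pred, kind = c("SDEC", "SDECV", "SDEP")) {
  match.arg(kind)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ")
  }
  if (length(y_true) == 0L) stop("need at least one residual")
  sqrt(mean((y_true - y_pred)^2))
}

#' Matthews correlation coefficient from a 2x2 confusion matrix
#'
#' Rows are true classes (low, high), columns predicted classes. Any zero
#' factor in the denominator gives MCC = 0 by convention.
#'
#' @param cm 2x2 matrix of non-negative counts.
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(all(dim(cm) == c(2L, 2L)), all(cm >= 0))
  tn <- cm[1L, 1L]; fp <- cm[1L, 2L]; fn <- cm[2L, 1L]; tp <- cm[2L, 2L]
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Two-class confusion matrix
#'
#' @param true,predicted vectors coercible to factors on `levels`.
#' @param levels class levels, first = "low" row/column.
#' @return 2x2 integer matrix, rows true, columns predicted.
#' @export
confusion_matrix <- function(true, predicted, levels = c("low", "high")) {
  t_f <- factor(as.character(true), levels = levels)
  p_f <- factor(as.character(predicted), levels = levels)
  if (anyNA(t_f) || anyNA(p_f)) stop("labels outside the stated levels")
  as.matrix(table(true = t_f, predicted = p_f))
}

#' Dichotomise PMI into low/high classes
#'
#' @param pmi numeric PMI vector (hours).
#' @param threshold boundary in hours; `low` is PMI <= threshold (inclusive,
#'   which is what reproduces the published class sizes).
#' @return factor with levels `low`, `high`.
#' @export
classify_pmi <- function(pmi, threshold = 48) {
  factor(ifelse(pmi <= threshold, "low", "high"), levels = c("low", "high"))
}

# ---- fold construction ------------------------------------------------------

# stratified fold assignment; regression: random within consecutive
# response-quantile blocks; classification: random within class, re-drawn
# (<= 100 times) until every training complement contains both classes
.make_folds <- function(y, folds, type) {
  n <- length(y)
  if (folds < 2L || folds > n) stop("folds must lie in [2, n]")
  fold <- integer(n)
  if (type == "regression") {
    ord <- order(y, sample.int(n))
    blocks <- split(ord, ceiling(seq_along(ord) / folds))
    for (b in blocks) fold[b] <- sample(rep_len(seq_len(folds), length(b)))
    return(fold)
  }
  for (try in seq_len(100L)) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(y[fold != f])) == 2L
    }, logical(1L)))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes in every training set")
}

# ---- the CV engine ----------------------------------------------------------

# X raw, y numeric (regression) or factor (classification), Z raw or NULL.
# Constant training-fold columns are centred and given unit scale so they
# contribute nothing rather than aborting a fold.
.scale_train <- function(Xtr) {
  mu <- colMeans(Xtr)
  sds <- col_sds(Xtr)
  sds[!is.finite(sds) | sds == 0] <- 1
  list(center = mu, scale = sds)
}

.cv_engine <- function(X, y, Z, n_components, folds = 5L, repeats = 20L,
                       type = c("regression", "classification")) {
  type <- match.arg(type)
  n <- nrow(X)
  per_repeat <- vector("list", repeats)
  fold_mse <- numeric(0L)         # per-fold MSEs, for the 1-SE parsimony rule
  for (r in seq_len(repeats)) {
    fold <- .make_folds(y, folds, type)
    pred <- rep(NA_real_, n)
    ref <- rep(NA_real_, n)       # training-fold mean composed per fold
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      xs <- .scale_train(X[tr, , drop = FALSE])
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, xs$center), 2L, xs$scale, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, xs$center), 2L, xs$scale, "/")
      if (type == "regression") {
        ytr <- y[tr]
        yc <- mean(ytr); ysd <- sd(ytr)
        if (ysd == 0) ysd <- 1
        ytr_s <- (ytr - yc) / ysd
      } else {
        code <- ifelse(y == levels(y)[2L], 1, -1)
        ytr <- code[tr]
        yc <- mean(ytr); ysd <- 1
        ytr_s <- ytr - yc
      }
      Ztr <- if (is.null(Z)) NULL else Z[tr, , drop = FALSE]
      G <- .constraint_basis(Xtr, Ztr)
      a_use <- min(n_components, length(tr) - 1L, ncol(Xtr))
      nip <- tryCatch(
        suppressWarnings(.nipals(Xtr %*% G, as.matrix(ytr_s), a_use)),
        error = function(e) NULL)
      if (is.null(nip)) {
        pred[te] <- yc          # degenerate fold: predict the training mean
      } else {
        pred[te] <- drop(Xte %*% (G %*% nip$B)) * ysd + yc
      }
      ref[te] <- yc
    }
    if (type == "regression") {
      press <- sum((y - pred)^2)
      tss <- sum((y - ref)^2)
      fold_mse <- c(fold_mse, vapply(seq_len(folds), function(f) {
        mean((y[fold == f] - pred[fold == f])^2)
      }, numeric(1L)))
      per_repeat[[r]] <- data.frame(repeat_id = r, q2 = 1 - press / tss,
                                    sdecv = sqrt(press / n))
    } else {
      lab <- factor(ifelse(pred - ref > 0, levels(y)[2L], levels(y)[1L]),
                    levels = levels(y))
      per_repeat[[r]] <- data.frame(repeat_id = r,
                                    mcc = mcc(confusion_matrix(y, lab, levels(y))))
    }
  }
  tab <- do.call(rbind, per_repeat)
  if (type == "regression") {
    list(q2 = mean(tab$q2), sdecv = mean(tab$sdecv), per_repeat = tab,
         mse = mean(fold_mse),
         mse_se = sd(fold_mse) / sqrt(length(fold_mse)))
  } else {
    list(mcc = mean(tab$mcc), per_repeat = tab)
  }
}

# assemble X / y / Z matrices from a dataset
.design_from <- function(ds, response = "pmi_hours",
                         constraints = "age_years", selected = NULL,
                         classes = NULL) {
  stopifnot(inherits(ds, "pmi_dataset"))
  X <- ds$concentrations
  if (!is.null(selected)) {
    missing <- setdiff(selected, colnames(X))
    if (length(missing)) stop("unknown metabolites: ", paste(missing, collapse = ", "))
    X <- X[, selected, drop = FALSE]
  }
  y <- if (!is.null(classes)) classes else ds$samples[[response]]
  Z <- if (is.null(constraints) || length(constraints) == 0L) NULL else {
    as.matrix(ds$samples[constraints])
  }
  list(X = X, y = y, Z = Z)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, samples are assigned to folds stratified by response
#' quantiles (regression) or class (classification); the full pipeline -
#' autoscaling, response scaling, constraint basis, PLS fit - is re-estimated
#' on the training folds and the held-out samples predicted. Per repeat,
#' `Q2 = 1 - PRESS/TSS` with TSS taken about the training-fold means composed
#' per fold (so predicting the training mean gives exactly Q2 = 0) and
#' `SDECV = sqrt(PRESS/n)`; the returned values are means over repeats. In
#' classification mode the per-repeat statistic is the MCC of the pooled
#' held-out predictions.
#'
#' @param ds a `pmi_dataset`.
#' @param n_components number of PLS components.
#' @param constraints metadata columns used as orthogonal constraints
#'   (default `"age_years"`); `NULL` for unconstrained.
#' @param selected optional metabolite subset.
#' @param response metadata column with the regression response.
#' @param classes optional two-level factor switching to classification mode.
#' @param folds,repeats CV geometry (defaults 5-fold, 20 repeats).
#' @param seed integer seed for the fold draws.
#' @return list with `q2`, `sdecv` (or `mcc`) and the `per_repeat` table.
#' @export
repeated_cv <- function(ds, n_components = 1L, constraints = "age_years",
                        selected = NULL, response = "pmi_hours",
                        classes = NULL, folds = 5L, repeats = 20L,
                        seed = NULL) {
  d <- .design_from(ds, response, constraints, selected, classes)
  type <- if (is.null(classes)) "regression" else "classification"
  if (type == "classification") d$y <- as.factor(d$y)
  with_seed(seed,
            .cv_engine(d$X, d$y, d$Z, n_components, folds, repeats, type))
}

# observed statistic used by the permutation test
.observed_stat <- function(X, y, Z, n_components, statistic, folds,
                           cv_repeats, type) {
  if (statistic == "Q2") {
    return(.cv_engine(X, y, Z, n_components, folds, cv_repeats, type)$q2)
  }
  if (statistic == "MCC" && type == "classification") {
    # cross-validated MCC: the randomisation gate of the classification
    # pipeline; training MCC would be inflated by predictor selection
    return(.cv_engine(X, y, Z, n_components, folds, cv_repeats, type)$mcc)
  }
  # R2 on the training data
  model <- ocpls_train(X, y, Z, n_components)
  fitted <- predict(model, X)
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

#' Response-permutation (randomisation) test
#'
#' Permutes the response (or class labels) across samples, keeping the
#' concentrations and constraints fixed, and recomputes the statistic
#' identically; `p = (1 + #{perm >= observed}) / (1 + n_perm)`, so p is never
#' 0. The model "passes" at `p < 0.05`.
#'
#' For `statistic = "Q2"` each evaluation runs a `cv_repeats`-repeat
#' `folds`-fold CV (default a single repeat: 1000 permutations of the full
#' 20-repeat CV would cost two orders of magnitude more for no calibration
#' gain).
#'
#' @inheritParams repeated_cv
#' @param statistic `"Q2"`, `"R2"` or `"MCC"`.
#' @param n_perm number of permutations (study setting: 1000).
#' @param cv_repeats CV repeats per evaluation when the statistic needs a CV.
#' @return list with `p_value`, `observed`, `permuted`, `statistic`,
#'   `passed` (p < 0.05).
#' @export
permutation_test <- function(ds, statistic = c("Q2", "R2", "MCC"),
                             n_components = 1L, constraints = "age_years",
                             selected = NULL, response = "pmi_hours",
                             classes = NULL, n_perm = 1000L, folds = 5L,
                             cv_repeats = 1L, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  d <- .design_from(ds, response, constraints, selected, classes)
  type <- if (is.null(classes)) "regression" else "classification"
  if (type == "classification") d$y <- as.factor(d$y)
  with_seed(seed, {
    observed <- .observed_stat(d$X, d$y, d$Z, n_components, statistic,
                               folds, cv_repeats, type)
    permuted <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(d$y)
      .observed_stat(d$X, yp, d$Z, n_components, statistic, folds,
                     cv_repeats, type)
    }, numeric(1L))
    p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
    list(p_value = p, observed = observed, permuted = permuted,
         statistic = statistic, passed = p < 0.05)
  })
}

#' Choose the number of PLS components
#'
#' Evaluates A = 1..`max_a` by repeated CV and keeps the A with the largest
#' mean Q2 (MCC in classification mode) among those passing the permutation
#' test at `alpha`; reports an explicit failure state when none passes.
#'
#' @inheritParams permutation_test
#' @param max_a largest component count tried.
#' @param repeats CV repeats for the Q2/MCC estimate itself.
#' @param alpha significance level of the randomisation test.
#' @return list with `n_components` (`NA` if none passed), `passed`, and the
#'   evaluation `table` (A, statistic, p-value).
#' @export
select_components <- function(ds, max_a = 3L, constraints = "age_years",
                              selected = NULL, response = "pmi_hours",
                              classes = NULL, folds = 5L, repeats = 20L,
                              n_perm = 1000L, cv_repeats = 1L, alpha = 0.05,
                              seed = NULL) {
  if (max_a < 1L) stop("max_a must be at least 1")
  type <- if (is.null(classes)) "regression" else "classification"
  stat_name <- if (type == "regression") "Q2" else "MCC"
  rows <- lapply(seq_len(max_a), function(a) {
    cv <- repeated_cv(ds, n_components = a, constraints = constraints,
                      selected = selected, response = response,
                      classes = classes, folds = folds, repeats = repeats,
                      seed = if (is.null(seed)) NULL else seed + a)
    stat <- if (type == "regression") cv$q2 else cv$mcc
    pt <- permutation_test(ds, statistic = stat_name, n_components = a,
                           constraints = constraints, selected = selected,
                           response = response, classes = classes,
                           n_perm = n_perm, folds = folds,
                           cv_repeats = cv_repeats,
                           seed = if (is.null(seed)) NULL else seed + 1000L + a)
    data.frame(n_components = a, statistic = stat, p_value = pt$p_value)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$p_value < alpha
  if (!any(ok)) {
    return(list(n_components = NA_integer_, passed = FALSE, table = tab))
  }
  best <- tab$n_components[ok][which.max(tab$statistic[ok])]
  list(n_components = best, passed = TRUE, table = tab)
}

#' Full fit diagnostics for a regression model
#'
#' Fits on the training samples, cross-validates, optionally predicts a test
#' set, and runs permutation tests for R2 and Q2. Mirrors the reporting
#' convention R2, Q2, SDEC, SDECV, SDEP.
#'
#' @inheritParams repeated_cv
#' @param test_ds optional held-out `pmi_dataset` for SDEP.
#' @param n_perm permutations for the randomisation tests (0 to skip).
#' @param cv_repeats CV repeats inside each permutation evaluation.
#' @return list of class `fit_diagnostics`.
#' @export
fit_diagnostics <- function(ds, n_components = 1L, constraints = "age_years",
                            selected = NULL, response = "pmi_hours",
                            test_ds = NULL, folds = 5L, repeats = 20L,
                            n_perm = 1000L, cv_repeats = 1L, seed = NULL) {
  d <- .design_from(ds, response, constraints, selected)
  model <- ocpls_train(d$X, d$y, d$Z, n_components)
  fitted <- predict(model, d$X)
  r2 <- 1 - sum((d$y - fitted)^2) / sum((d$y - mean(d$y))^2)
  sdec <- error_metrics(d$y, fitted, "SDEC")
  cv <- repeated_cv(ds, n_components, constraints, selected, response,
                    folds = folds, repeats = repeats, seed = seed)
  sdep <- NA_real_
  if (!is.null(test_ds)) {
    dt <- .design_from(test_ds, response, constraints, selected)
    sdep <- error_metrics(dt$y, predict(model, dt$X), "SDEP")
  }
  p_r2 <- p_q2 <- NA_real_
  if (n_perm > 0L) {
    p_r2 <- permutation_test(ds, "R2", n_components, constraints, selected,
                             response, n_perm = n_perm, folds = folds,
                             cv_repeats = cv_repeats,
                             seed = if (is.null(seed)) NULL else seed + 17L)$p_value
    p_q2 <- permutation_test(ds, "Q2", n_components, constraints, selected,
                             response, n_perm = n_perm, folds = folds,
                             cv_repeats = cv_repeats,
                             seed = if (is.null(seed)) NULL else seed + 31L)$p_value
  }
  structure(list(r2 = r2, q2 = cv$q2, sdec = sdec, sdecv = cv$sdecv,
                 sdep = sdep, p_r2 = p_r2, p_q2 = p_q2,
                 n_components = model$n_components, n_permutations = n_perm,
                 model = model),
            class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf(
    "R2 = %.3f (p = %s), Q2 = %.3f (p = %s)\nSDEC = %.1f h, SDECV = %.1f h, SDEP = %s h\n",
    x$r2, format(x$p_r2, digits = 3), x$q2, format(x$p_q2, digits = 3),
    x$sdec, x$sdecv,
    if (is.na(x$sdep)) "NA" else sprintf("%.1f", x$sdep)))
  invisible(x)
}
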