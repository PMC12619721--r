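# Stability selection: Binary Matrix Sampling subsets, per-subset VIP-ranked
# feature selection cross-validated by Q2, and a binomial null for "what a
# random selection would have achieved".

#' Binary Matrix Sampling masks
#'
#' Draws `n_subsets` independent Bernoulli(p) inclusion masks over both rows
#' (observations) and columns (predictors). Subsets with fewer than
#' `min_rows` rows or `min_cols` columns are re-drawn.
#'
#' @param n,k numbers of observations and predictors.
#' @param p inclusion probability (study setting 0.7).
#' @param n_subsets number of subsets (study setting 200).
#' @param min_rows,min_cols validity floor for a subset.
#' @param seed integer seed.
#' @return list of `n_subsets` lists with integer `rows` and `cols`.
#' @export
binary_matrix_sample <- function(n, k, p = 0.7, n_subsets = 200L,
                                 min_rows = 10L, min_cols = 2L, seed = NULL) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (n < min_rows) stop("cannot sample ", min_rows, " rows from ", n)
  with_seed(seed, {
    lapply(seq_len(n_subsets), function(s) {
      for (try in seq_len(1000L)) {
        rows <- which(runif(n) < p)
        cols <- which(runif(k) < p)
        if (length(rows) >= min_rows && length(cols) >= min_cols) {
          return(list(rows = rows, cols = cols))
        }
      }
      stop("could not draw a valid subset after 1000 attempts")
    })
  })
}

#' VIP-guided feature selection within one subset
#'
#' Fits the constrained model on the subset, ranks the sampled metabolites by
#' VIP, and evaluates nested candidate sets (top-m for m on a grid: every m
#' up to 25 columns, else 25 log-spaced sizes) by `folds`-fold CV Q2 on the
#' subset; returns the candidate set with maximal Q2, ties going to the
#' smaller set. When no candidate achieves Q2 > 0 the smallest evaluated set
#' is returned with attribute `no_positive_q2 = TRUE`.
#'
#' @param X raw concentration matrix of the subset (rows x sampled columns,
#'   with colnames).
#' @param y numeric response of the subset.
#' @param Z constraint matrix of the subset or `NULL`.
#' @param max_a maximum number of PLS components tried per candidate.
#' @param folds CV folds.
#' @return character vector of selected metabolite names, with attributes
#'   `q2` (best CV Q2) and `no_positive_q2`.
#' @export
select_in_subset <- function(X, y, Z = NULL, max_a = 2L, folds = 5L) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("subset too small to cross-validate (need >= 10 rows)")
  if (sd(y) == 0) {
    warning("constant response in subset; nothing selected")
    return(character(0L))
  }
  usable <- which(col_sds(X) > 0)
  if (length(usable) == 0L) {
    warning("no non-constant predictors in subset")
    return(character(0L))
  }
  Xu <- X[, usable, drop = FALSE]
  k <- ncol(Xu)
  a_rank <- min(max_a, nrow(Xu) - 1L, k)
  ranking <- tryCatch({
    model <- ocpls_train(Xu, y, Z, a_rank)
    order(-vip(model))
  }, error = function(e) {
    warning("subset model failed (", conditionMessage(e), "); nothing selected")
    NULL
  })
  if (is.null(ranking)) return(character(0L))
  grid <- if (k <= 25L) seq_len(k) else {
    sort(unique(round(exp(seq(log(1), log(k), length.out = 25L)))))
  }
  n_g <- length(grid)
  a_max <- min(max_a, nrow(Xu) - 1L)
  # one shared fold assignment: every candidate set is evaluated on the same
  # partition (paired comparison), and NIPALS components are nested so a
  # single fit per candidate yields every component count at once
  fold <- .make_folds(y, folds, "regression")
  press <- array(Inf, c(n_g, a_max, folds))
  tss_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    xs <- .scale_train(Xu[tr, , drop = FALSE])
    Xtr <- sweep(sweep(Xu[tr, , drop = FALSE], 2L, xs$center), 2L, xs$scale, "/")
    Xte <- sweep(sweep(Xu[te, , drop = FALSE], 2L, xs$center), 2L, xs$scale, "/")
    yc <- mean(y[tr]); ysd <- sd(y[tr]); if (ysd == 0) ysd <- 1
    ytr_s <- as.matrix((y[tr] - yc) / ysd)
    Ztr <- if (is.null(Z)) NULL else Z[tr, , drop = FALSE]
    tss_fold[f] <- sum((y[te] - yc)^2)
    for (i in seq_len(n_g)) {
      cols <- ranking[seq_len(grid[i])]
      fitd <- tryCatch({
        G <- .constraint_basis(Xtr[, cols, drop = FALSE], Ztr)
        suppressWarnings(.nipals(Xtr[, cols, drop = FALSE] %*% G, ytr_s,
                                 min(a_max, grid[i], ncol(G))))
      }, error = function(e) NULL)
      if (is.null(fitd)) next
      for (a in seq_len(fitd$n_components)) {
        Ba <- fitd$W[, 1:a, drop = FALSE] %*%
          solve(crossprod(fitd$P[, 1:a, drop = FALSE],
                          fitd$W[, 1:a, drop = FALSE])) %*%
          t(fitd$C[, 1:a, drop = FALSE])
        pred <- drop(Xte[, cols, drop = FALSE] %*% (G %*% Ba)) * ysd + yc
        press[i, a, f] <- sum((y[te] - pred)^2)
      }
    }
  }
  press_tot <- apply(press, c(1L, 2L), sum)          # candidates x components
  q2_mat <- 1 - press_tot / sum(tss_fold)
  a_best <- apply(q2_mat, 1L, which.max)
  q2s <- q2_mat[cbind(seq_len(n_g), a_best)]
  # CV Q2 is flat once every informative predictor is in, so the literal
  # argmax over-selects; keep the smallest candidate whose CV error is
  # within one standard error of the best (1-SE parsimony rule), realising
  # the "ties -> smaller set" intent on noisy estimates
  n_te <- as.vector(table(fold))
  mse_fold <- sweep(press[cbind(rep(seq_len(n_g), folds),
                                rep(a_best, folds),
                                rep(seq_len(folds), each = n_g))] |>
                      matrix(n_g, folds), 2L, n_te, "/")
  mses <- rowMeans(mse_fold)
  ses <- apply(mse_fold, 1L, sd) / sqrt(folds)
  best_i <- which.max(q2s)
  if (is.finite(mses[best_i]) && is.finite(ses[best_i])) {
    best_i <- which(mses <= mses[best_i] + ses[best_i])[1L]
  }
  out <- colnames(Xu)[ranking[seq_len(grid[best_i])]]
  attr(out, "q2") <- q2s[best_i]
  attr(out, "no_positive_q2") <- max(q2s, na.rm = TRUE) <= 0
  out
}

#' Stability selection of relevant predictors
#'
#' Runs [select_in_subset()] over Binary Matrix Sampling subsets and compares
#' each metabolite's selection frequency (normalised by the subsets in which
#' it was sampled at all) with what a random selection of the same per-subset
#' sizes would achieve. The default null is binomial with success probability
#' `mean(selected size / sampled size)` over subsets - fast, but only
#' approximate when sample-level chance correlations recur across
#' overlapping subsets. `null_method = "empirical"` instead reruns the whole
#' per-subset selection `n_null` times with the response permuted (same
#' masks), giving exactly calibrated per-metabolite permutation p-values at
#' `n_null` times the cost. A metabolite is selected when its one-sided
#' p-value falls below `alpha`; metabolites never sampled get `NA` and are
#' never selected.
#'
#' @param ds a `pmi_dataset` (training samples only - selection must not see
#'   the test set).
#' @param response metadata column with the response.
#' @param constraints metadata columns used as orthogonal constraints.
#' @param classes optional two-level factor; when given, selection runs on
#'   the centred -1/+1 class code.
#' @param alpha significance level (study setting 0.05).
#' @param n_subsets,sampling_p Binary Matrix Sampling parameters (200, 0.7).
#' @param max_a,folds per-subset model settings.
#' @param null_method `"binomial"` (default) or `"empirical"` (permutation).
#' @param n_null permutation-null replicates (39 resolves alpha = 0.05).
#' @param seed integer seed governing masks, folds and the empirical null.
#' @return a `selection_result`: data frame with per-metabolite `n_eligible`,
#'   `n_selected`, `frequency`, `p_value`, `selected`, plus attributes
#'   `null_frequency` and `selected_names`.
#' @export
stability_select <- function(ds, response = "pmi_hours",
                             constraints = "age_years", classes = NULL,
                             alpha = 0.05, n_subsets = 200L, sampling_p = 0.7,
                             max_a = 2L, folds = 5L,
                             null_method = c("binomial", "empirical"),
                             n_null = 39L, seed = NULL) {
  null_method <- match.arg(null_method)
  d <- .design_from(ds, response, constraints, classes = classes)
  y <- if (is.null(classes)) d$y else {
    cl <- as.factor(classes)
    ifelse(cl == levels(cl)[2L], 1, -1)
  }
  mets <- colnames(d$X)
  k <- length(mets)
  with_seed(seed, {
    masks <- binary_matrix_sample(nrow(d$X), k, p = sampling_p,
                                  n_subsets = n_subsets)
    n_eligible <- integer(k)
    names(n_eligible) <- mets
    for (m in masks) n_eligible[m$cols] <- n_eligible[m$cols] + 1L

    # one pass of per-subset selection over the fixed masks; a subset in
    # which no candidate cross-validates better than the mean (Q2 <= 0
    # throughout) carries no evidence and contributes an empty selection
    run_pass <- function(yy) {
      n_selected <- integer(k)
      names(n_selected) <- mets
      sel_frac <- numeric(n_subsets)
      for (s in seq_along(masks)) {
        m <- masks[[s]]
        picked <- suppressWarnings(select_in_subset(
          d$X[m$rows, m$cols, drop = FALSE], yy[m$rows],
          if (is.null(d$Z)) NULL else d$Z[m$rows, , drop = FALSE],
          max_a = max_a, folds = folds))
        if (isTRUE(attr(picked, "no_positive_q2"))) picked <- character(0L)
        n_selected[picked] <- n_selected[picked] + 1L
        sel_frac[s] <- length(picked) / length(m$cols)
      }
      list(n_selected = n_selected, qbar = mean(sel_frac))
    }

    obs <- run_pass(y)
    n_selected <- obs$n_selected
    qbar <- obs$qbar
    frequency <- ifelse(n_eligible > 0L, n_selected / n_eligible, NA_real_)
    if (null_method == "binomial") {
      p_value <- ifelse(n_eligible > 0L,
                        pbinom(n_selected - 1L, n_eligible, qbar,
                               lower.tail = FALSE),
                        NA_real_)
    } else {
      # permutation null: rerun the whole per-subset selection with the
      # response permuted, over the same masks; exchangeability makes the
      # resulting per-metabolite p-values exactly calibrated under the
      # global null (the binomial null is not, because sample-level chance
      # correlations recur across overlapping subsets)
      null_counts <- matrix(0L, n_null, k)
      for (r in seq_len(n_null)) {
        null_counts[r, ] <- run_pass(sample(y))$n_selected
      }
      p_value <- vapply(seq_len(k), function(j) {
        if (n_eligible[j] == 0L) return(NA_real_)
        (1 + sum(null_counts[, j] >= n_selected[j])) / (1 + n_null)
      }, numeric(1L))
    }
    selected <- !is.na(p_value) & p_value < alpha
    res <- data.frame(metabolite = mets, n_eligible = n_eligible,
                      n_selected = n_selected, frequency = frequency,
                      p_value = p_value, selected = selected,
                      row.names = NULL)
    attr(res, "null_frequency") <- qbar
    attr(res, "selected_names") <- mets[selected]
    class(res) <- c("selection_result", "data.frame")
    res
  })
}

#' Names of the metabolites retained by stability selection
#'
#' @param result a `selection_result`.
#' @return character vector.
#' @export
selected_metabolites <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  attr(result, "selected_names")
}

#' Export a selection result as CSV
#'
#' @param result a `selection_result`.
#' @param path output path.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  write.csv(as.data.frame(result), path, row.names = FALSE, quote = TRUE)
  invisible(result)
}
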