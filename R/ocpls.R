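# Constrained PLS core. The defining contract of oCPLS2 is that every score
# component is orthogonal to the constraint variables (Z' T = 0): weights are
# restricted to the null space of Z'X, so PLS is run in the admissible
# subspace and mapped back. With a vacuous constraint the basis is the
# identity and the code path is bitwise-identical to plain PLS2.

# NIPALS with X-deflation; X, Y centred/scaled N x K and N x M.
# Weight direction per component: dominant left singular vector of X'Y
# (exact; equals the normalised X'y for M = 1).
.nipals <- function(X, Y, n_components, warn = TRUE) {
  n <- nrow(X); k <- ncol(X); m <- ncol(Y)
  W <- matrix(0, k, n_components); P <- matrix(0, k, n_components)
  C <- matrix(0, m, n_components); Tm <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  Xd <- X
  a_done <- 0L
  for (a in seq_len(n_components)) {
    S <- crossprod(Xd, Y)                    # K x M
    if (m == 1L) {
      nrm <- sqrt(sum(S^2))
      if (nrm < 1e-12) break
      w <- S[, 1L] / nrm
    } else {
      sv <- svd(S, nu = 1L, nv = 0L)
      if (sv$d[1L] < 1e-12) break
      w <- sv$u[, 1L]
    }
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(Xd, t_a)) / tt
    c_a <- drop(crossprod(Y, t_a)) / tt
    W[, a] <- w; P[, a] <- p_a; C[, a] <- c_a; Tm[, a] <- t_a
    ssy[a] <- sum(c_a^2) * tt                # explained response SS
    Xd <- Xd - tcrossprod(t_a, p_a)
    a_done <- a
  }
  if (a_done < n_components) {
    if (warn) warning("predictor rank exhausted after ", a_done,
                      " of ", n_components, " components")
    idx <- seq_len(max(a_done, 1L))
    if (a_done == 0L) stop("no PLS component could be extracted (zero covariance)")
    W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
    C <- C[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
    ssy <- ssy[idx]
  }
  B <- W %*% solve(crossprod(P, W)) %*% t(C)
  list(W = W, P = P, C = C, T = Tm, B = B, ssy = ssy,
       n_components = ncol(W))
}

# orthonormal basis of the null space of Z'X (K-space); identity when the
# constraint is vacuous so that the unconstrained path is untouched
.constraint_basis <- function(X, Z) {
  k <- ncol(X)
  if (is.null(Z) || ncol(Z) == 0L) return(diag(k))
  Zc <- sweep(as.matrix(Z), 2L, colMeans(as.matrix(Z)))
  A <- crossprod(Zc, X)                       # C x K
  sv <- svd(A, nu = 0L, nv = k)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (rank == 0L) return(diag(k))
  if (rank >= k) stop("constraints exhaust predictor space (null space empty)")
  sv$v[, (rank + 1L):k, drop = FALSE]
}

.new_ocpls_model <- function(nip, G, constraint_names, x_scaling, y_scaling,
                             metabolite_names, type) {
  W_orig <- G %*% nip$W
  structure(list(n_components = nip$n_components,
                 weights = W_orig,
                 loadings = G %*% nip$P,
                 response_loadings = nip$C,
                 scores = nip$T,
                 coefficients = G %*% nip$B,   # K x M, autoscaled space
                 ssy = nip$ssy,
                 constraint_basis = G,
                 constraint_names = constraint_names,
                 x_scaling = x_scaling, y_scaling = y_scaling,
                 metabolite_names = metabolite_names,
                 type = type),
            class = "ocpls_model")
}

#' Fit an orthogonally constrained PLS2 regression
#'
#' PLS2 by NIPALS with the weight vectors restricted to the null space of
#' `Z'X`, which forces every score component to satisfy `Z'T = 0`: the
#' latent variables cannot carry variation correlated (in-sample) with the
#' constraint variables, here typically age. With `Z = NULL` the fit reduces
#' exactly to unconstrained PLS2.
#'
#' @param X centred/scaled predictor matrix (N x K).
#' @param Y centred/scaled response (N x M matrix or length-N vector).
#' @param Z constraint matrix (N x C) or `NULL`; centred internally.
#' @param n_components number of score components.
#' @param x_scaling,y_scaling optional scaling parameter lists
#'   (`list(center =, scale =)`) recorded in the model so [predict()] can
#'   accept raw inputs; when absent, identity scalings are stored.
#' @param constraint_names labels for the constraint columns.
#' @return an `ocpls_model`.
#' @export
fit_ocpls2 <- function(X, Y, Z = NULL, n_components = 1L,
                       x_scaling = NULL, y_scaling = NULL,
                       constraint_names = colnames(Z)) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  if (any(col_sds(Y) == 0)) stop("zero-variance response")
  if (n_components > min(nrow(X) - 1L, ncol(X))) {
    stop("n_components must not exceed min(N - 1, K)")
  }
  G <- .constraint_basis(X, Z)
  nip <- .nipals(X %*% G, Y, n_components)
  if (is.null(x_scaling)) x_scaling <- list(center = rep(0, ncol(X)),
                                            scale = rep(1, ncol(X)))
  if (is.null(y_scaling)) y_scaling <- list(center = rep(0, ncol(Y)),
                                            scale = rep(1, ncol(Y)))
  .new_ocpls_model(nip, G, constraint_names, x_scaling, y_scaling,
                   colnames(X), type = "regression")
}

#' Fit an unconstrained PLS2 regression
#'
#' Plain NIPALS PLS2; identical to [fit_ocpls2()] with `Z = NULL`.
#'
#' @inheritParams fit_ocpls2
#' @return an `ocpls_model`.
#' @export
fit_pls2 <- function(X, Y, n_components = 1L,
                     x_scaling = NULL, y_scaling = NULL) {
  fit_ocpls2(X, Y, Z = NULL, n_components = n_components,
             x_scaling = x_scaling, y_scaling = y_scaling,
             constraint_names = character())
}

#' Fit an age-constrained PLS classifier (oCPLS2C)
#'
#' Two-class PLS-DA with the orthogonal constraint of [fit_ocpls2()]. The
#' classes are coded -1 (first level, "low") / +1 (second level, "high"),
#' centred, and regressed as a single response; new samples are classified
#' by the sign of the predicted centred response, ties going to the first
#' level.
#'
#' @param X centred/scaled predictor matrix.
#' @param classes factor (or coercible) with exactly two levels, both
#'   present; level order fixes the -1/+1 coding.
#' @param Z constraint matrix or `NULL`.
#' @param n_components number of score components.
#' @param x_scaling optional stored X scaling, as in [fit_ocpls2()].
#' @return an `ocpls_model` of subclass `ocpls2c` carrying `class_levels`.
#' @export
fit_ocpls2c <- function(X, classes, Z = NULL, n_components = 1L,
                        x_scaling = NULL) {
  classes <- as.factor(classes)
  classes <- droplevels(classes)
  if (nlevels(classes) != 2L) {
    stop("classification needs exactly two classes, both present (got ",
         nlevels(classes), ")")
  }
  code <- ifelse(classes == levels(classes)[2L], 1, -1)
  y_scaling <- list(center = mean(code), scale = 1)
  model <- fit_ocpls2(X, code - mean(code), Z = Z, n_components = n_components,
                      x_scaling = x_scaling, y_scaling = y_scaling,
                      constraint_names = colnames(Z))
  model$type <- "classification"
  model$class_levels <- levels(classes)
  class(model) <- c("ocpls2c", "ocpls_model")
  model
}

#' Predict from a fitted (o)CPLS model
#'
#' Applies the scaling stored at fit time (never re-estimated), multiplies by
#' the regression coefficients, and inverts the response scaling.
#'
#' @param object an `ocpls_model`.
#' @param newdata raw predictor matrix or `pmi_dataset` with matching
#'   metabolite columns.
#' @param ... unused.
#' @return numeric matrix/vector of predictions in original response units.
#' @export
predict.ocpls_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "pmi_dataset")) {
    newdata$concentrations[, object$metabolite_names, drop = FALSE]
  } else as.matrix(newdata)
  if (ncol(X) != nrow(object$coefficients)) {
    stop("newdata has ", ncol(X), " columns; model was fitted on ",
         nrow(object$coefficients))
  }
  Xs <- sweep(sweep(X, 2L, object$x_scaling$center), 2L,
              object$x_scaling$scale, "/")
  Ys <- Xs %*% object$coefficients
  out <- sweep(sweep(Ys, 2L, object$y_scaling$scale, "*"), 2L,
               object$y_scaling$center, "+")
  if (ncol(out) == 1L) drop(out) else out
}

#' @rdname predict.ocpls_model
#' @param type `"class"` (default) for labels, `"response"` for the raw
#'   decision value (predicted centred class code).
#' @export
predict.ocpls2c <- function(object, newdata, type = c("class", "response"), ...) {
  type <- match.arg(type)
  raw <- NextMethod()
  centred <- raw - object$y_scaling$center
  if (type == "response") return(centred)
  factor(ifelse(centred > 0, object$class_levels[2L], object$class_levels[1L]),
         levels = object$class_levels)
}

#' @export
print.ocpls_model <- function(x, ...) {
  con <- if (ncol(x$constraint_basis) < nrow(x$constraint_basis)) {
    paste0("constrained (", paste(x$constraint_names, collapse = ", "), ")")
  } else "unconstrained"
  cat("<ocpls_model> ", x$type, ", ", x$n_components, " component(s), ",
      nrow(x$coefficients), " predictors, ", con, "\n", sep = "")
  invisible(x)
}

#' Variable Influence on Projection
#'
#' `VIP_j = sqrt(K * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)` with
#' `SSY_a = (c_a'c_a)(t_a't_a)` the response sum of squares explained by
#' component a, and the weights taken in the original predictor space. By
#' construction the squared VIPs average to 1 (`sum VIP^2 = K`).
#'
#' @param model a fitted `ocpls_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "ocpls_model"))
  if (sum(model$ssy) <= 0) stop("zero explained response sum of squares")
  W <- model$weights
  wn2 <- sweep(W^2, 2L, colSums(W^2), "/")
  v <- sqrt(nrow(W) * drop(wn2 %*% model$ssy) / sum(model$ssy))
  names(v) <- model$metabolite_names
  v
}

#' Train an age-constrained PLS model from raw data
#'
#' Convenience wrapper around the scaled-space fitters: autoscales the
#' predictors (and, for regression, the response), centres the constraint
#' columns, fits, and stores the scalings so [predict()] accepts raw
#' concentrations.
#'
#' @param X_raw raw concentration matrix (samples x metabolites).
#' @param y response: numeric PMI (regression) or two-level factor
#'   (classification).
#' @param Z_raw raw constraint matrix (e.g. the age column) or `NULL`.
#' @param n_components number of score components.
#' @return an `ocpls_model` (or `ocpls2c`).
#' @export
ocpls_train <- function(X_raw, y, Z_raw = NULL, n_components = 1L) {
  sm <- autoscale(X_raw)
  x_scaling <- list(center = sm$center, scale = sm$scale)
  if (is.numeric(y)) {
    y_scaling <- list(center = mean(y), scale = sd(y))
    if (y_scaling$scale == 0) stop("zero-variance response")
    fit_ocpls2(sm$values, (y - y_scaling$center) / y_scaling$scale,
               Z = Z_raw, n_components = n_components,
               x_scaling = x_scaling, y_scaling = y_scaling,
               constraint_names = colnames(Z_raw))
  } else {
    fit_ocpls2c(sm$values, y, Z = Z_raw, n_components = n_components,
                x_scaling = x_scaling)
  }
}

#' Serialise a fitted model to JSON
#'
#' Writes every matrix, scaling parameter and label of the model as a single
#' JSON document so a fit can be archived and replayed.
#'
#' @param model an `ocpls_model`.
#' @param path output path.
#' @export
write_ocpls_model <- function(model, path) {
  stopifnot(inherits(model, "ocpls_model"))
  obj <- unclass(model)
  obj$is_classifier <- inherits(model, "ocpls2c")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(model)
}

#' @rdname write_ocpls_model
#' @export
read_ocpls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  is_cls <- isTRUE(obj$is_classifier)
  obj$is_classifier <- NULL
  for (f in c("weights", "loadings", "response_loadings", "scores",
              "coefficients", "constraint_basis")) {
    obj[[f]] <- as.matrix(obj[[f]])
  }
  obj$x_scaling <- lapply(obj$x_scaling, as.numeric)
  obj$y_scaling <- lapply(obj$y_scaling, as.numeric)
  class(obj) <- if (is_cls) c("ocpls2c", "ocpls_model") else "ocpls_model"
  obj
}
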