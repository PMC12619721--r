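# Preprocessing: autoscaling, two-batch cosine similarity, PCA.

#' Autoscale a concentration matrix
#'
#' Column-wise centering to mean 0 and scaling to unit sample SD (n-1
#' denominator), the standard pretreatment for NMR concentration tables
#' before PLS. The fitted means/SDs are stored so that new samples can be
#' projected with [apply_scaling()] without re-estimation.
#'
#' @param x a `pmi_dataset` or a numeric matrix.
#' @return a `scaled_matrix`: list with `values`, `center`, `scale`,
#'   `metabolite_names`.
#' @export
autoscale <- function(x) {
  mat <- if (inherits(x, "pmi_dataset")) x$concentrations else as.matrix(x)
  if (nrow(mat) < 2L) stop("autoscaling needs at least 2 samples")
  mu <- colMeans(mat)
  sds <- col_sds(mat)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0L) {
    nm <- colnames(mat)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("constant column(s) cannot be autoscaled: ", paste(nm, collapse = ", "))
  }
  vals <- sweep(sweep(mat, 2L, mu), 2L, sds, "/")
  structure(list(values = vals, center = mu, scale = sds,
                 metabolite_names = colnames(mat)),
            class = "scaled_matrix")
}

#' Apply stored autoscaling parameters to new rows
#'
#' Uses the means and SDs estimated at fit time; never re-estimates on the
#' new data (required for honest test-set prediction).
#'
#' @param sm a `scaled_matrix` from [autoscale()].
#' @param new_rows numeric matrix with the same columns as the fitting data.
#' @return scaled numeric matrix.
#' @export
apply_scaling <- function(sm, new_rows) {
  stopifnot(inherits(sm, "scaled_matrix"))
  new_rows <- as.matrix(new_rows)
  if (ncol(new_rows) != length(sm$center)) {
    stop("column count mismatch: scaling fitted on ", length(sm$center),
         " metabolites, new data has ", ncol(new_rows))
  }
  sweep(sweep(new_rows, 2L, sm$center), 2L, sm$scale, "/")
}

#' Per-metabolite cosine similarity between two batches
#'
#' For each metabolite, the cosine of the angle between its raw concentration
#' vectors in the two batches, over the shared samples (rows aligned by
#' sample ID before computing). Computed on raw, not autoscaled, values:
#' cosine of mean-centred columns would collapse to Pearson r.
#'
#' @param batch1,batch2 `pmi_dataset`s over the same samples and metabolites.
#' @param threshold similarity above which a metabolite is flagged as
#'   "strong" (default 0.90).
#' @return data frame with `metabolite`, `cosine`, `strong`; zero-norm
#'   columns yield `NA` cosine and are never flagged.
#' @export
cosine_batch_similarity <- function(batch1, batch2, threshold = 0.90) {
  stopifnot(inherits(batch1, "pmi_dataset"), inherits(batch2, "pmi_dataset"))
  ids <- intersect(rownames(batch1$concentrations), rownames(batch2$concentrations))
  if (length(ids) == 0L) stop("batches share no sample IDs")
  mets <- colnames(batch1$concentrations)
  if (!setequal(mets, colnames(batch2$concentrations))) {
    stop("batches must quantify the same metabolite set")
  }
  a <- batch1$concentrations[ids, mets, drop = FALSE]
  b <- batch2$concentrations[ids, mets, drop = FALSE]
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2)) * sqrt(colSums(b^2))
  cosine <- ifelse(den > 0, num / den, NA_real_)
  data.frame(metabolite = mets, cosine = unname(cosine),
             strong = !is.na(cosine) & cosine > threshold)
}

#' Principal component analysis of a scaled matrix
#'
#' SVD-based PCA with a deterministic sign convention: within each loading
#' vector the element of largest magnitude is made positive. Explained
#' variance fractions are relative to the total variance of the input.
#'
#' @param sm a `scaled_matrix` (or any centred numeric matrix).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `loadings`
#'   (metabolites x components), `explained_variance_fraction`.
#' @export
pca <- function(sm, n_components) {
  x <- if (inherits(sm, "scaled_matrix")) sm$values else as.matrix(sm)
  n <- nrow(x); k <- ncol(x)
  if (n_components > min(n - 1L, k)) {
    stop("n_components must not exceed min(n - 1, n_metabolites)")
  }
  dec <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * dec$d[1L]
  rank <- sum(dec$d > tol)
  if (rank < n_components) {
    warning("matrix rank ", rank, " below requested ", n_components,
            " components; returning ", rank)
    n_components <- rank
  }
  idx <- seq_len(n_components)
  scores <- dec$u[, idx, drop = FALSE] %*% diag(dec$d[idx], n_components)
  loadings <- dec$v[, idx, drop = FALSE]
  for (j in idx) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- colnames(x)
  rownames(scores) <- rownames(x)
  list(scores = scores, loadings = loadings,
       explained_variance_fraction = (dec$d[idx]^2) / sum(dec$d^2))
}
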