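# Training/test extraction: PMI segmentation, per-segment PCA + Ward
# clustering, cluster-representative selection.

#' Segment samples by PMI
#'
#' Assigns samples to `n_segments` contiguous PMI intervals with
#' equal-frequency boundaries: samples are ordered by PMI (ties broken by
#' input order) and cut into chunks whose sizes differ by at most one, the
#' earlier segments taking the extra samples (65 samples in 4 segments ->
#' 17/16/16/16).
#'
#' @param records data frame of sample records.
#' @param n_segments number of PMI segments (>= 1).
#' @return integer vector of segment indices, parallel to `records`.
#' @export
segment_pmi <- function(records, n_segments) {
  n <- nrow(records)
  if (n_segments < 1L) stop("n_segments must be at least 1")
  if (n_segments > n / 2) {
    stop("n_segments = ", n_segments, " exceeds n/2 = ", n / 2)
  }
  while (n %/% n_segments < 2L && n_segments > 1L) {
    warning("reducing n_segments so every segment receives >= 2 samples")
    n_segments <- n_segments - 1L
  }
  sizes <- rep(n %/% n_segments, n_segments)
  extra <- n %% n_segments
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(records$pmi_hours, seq_len(n))
  seg <- integer(n)
  seg[ord] <- rep(seq_len(n_segments), times = sizes)
  seg
}

# score-space for clustering one segment: autoscale (dropping constant
# columns), then PCA components up to `cum_var` cumulative variance, capped
.segment_scores <- function(mat, cum_var = 0.80, max_pcs = 10L) {
  sds <- col_sds(mat)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) == 0L) {
    return(matrix(0, nrow(mat), 1L))  # all samples identical
  }
  sm <- autoscale(mat[, keep, drop = FALSE])
  full <- min(nrow(mat) - 1L, length(keep))
  pc <- suppressWarnings(pca(sm, full))
  cum <- cumsum(pc$explained_variance_fraction)
  a <- min(max(which(cum >= cum_var)[1L], 1L), max_pcs, ncol(pc$scores))
  if (is.na(a)) a <- ncol(pc$scores)
  pc$scores[, seq_len(a), drop = FALSE]
}

# representative of each cluster: sample with minimal Euclidean distance to
# the cluster mean in score space; ties -> smallest index
.cluster_representatives <- function(scores, cluster) {
  vapply(sort(unique(cluster)), function(cl) {
    members <- which(cluster == cl)
    centre <- colMeans(scores[members, , drop = FALSE])
    d <- sqrt(rowSums(sweep(scores[members, , drop = FALSE], 2L, centre)^2))
    members[which.min(d)]  # which.min takes the first (smallest index) on ties
  }, integer(1L))
}

#' Extract a training set by cluster representatives
#'
#' Within each PMI segment the concentrations are autoscaled, projected onto
#' principal components retaining >= 80% cumulative variance (capped at 10),
#' and clustered by Ward's method on Euclidean distances in score space. The
#' tree is cut at round(fraction x segment size) clusters (round half up) and
#' the sample closest to each cluster mean joins the training set; the rest
#' form the test set. The samples with the overall minimum and maximum PMI
#' are always swapped into the training set (within their own cluster) so the
#' test set never requires extrapolation.
#'
#' @param ds a `pmi_dataset`.
#' @param segments segment assignment from [segment_pmi()] (or `NULL` to
#'   compute with `n_segments`).
#' @param fraction target training fraction per segment (default 0.70).
#' @param training_size optional forced total training size; representatives
#'   are trimmed from (or runners-up added to) the segments with the most
#'   training (respectively test) samples until the total matches.
#' @param n_segments used when `segments` is `NULL` (default 4).
#' @param cum_var,max_pcs PCA dimensionality rule for the clustering space.
#' @return a `split_result`: list with `training_ids`, `test_ids`,
#'   `segments` (named integer vector).
#' @export
select_training <- function(ds, segments = NULL, fraction = 0.70,
                            training_size = NULL, n_segments = 4L,
                            cum_var = 0.80, max_pcs = 10L) {
  stopifnot(inherits(ds, "pmi_dataset"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (is.null(segments)) segments <- segment_pmi(ds$samples, n_segments)
  ids <- ds$samples$sample_id
  n <- length(ids)
  in_training <- logical(n)
  seg_scores <- vector("list", max(segments))

  for (s in sort(unique(segments))) {
    members <- which(segments == s)
    scores <- .segment_scores(ds$concentrations[members, , drop = FALSE],
                              cum_var, max_pcs)
    k <- max(1L, round_half_up(fraction * length(members)))
    k <- min(k, length(members))
    cl <- if (length(members) == 1L) 1L else
      cutree(hclust(dist(scores), method = "ward.D2"), k = k)
    reps <- .cluster_representatives(scores, cl)
    in_training[members[reps]] <- TRUE
    seg_scores[[s]] <- list(members = members, scores = scores, cluster = cl)
  }

  # guard extrapolation: global PMI extremes always train, swapped with the
  # representative of their own cluster so sizes are preserved
  for (idx in c(which.min(ds$samples$pmi_hours), which.max(ds$samples$pmi_hours))) {
    if (!in_training[idx]) {
      s <- segments[idx]
      info <- seg_scores[[s]]
      pos <- match(idx, info$members)
      mates <- info$members[info$cluster == info$cluster[pos]]
      rep_mate <- mates[in_training[mates]]
      in_training[rep_mate] <- FALSE
      in_training[idx] <- TRUE
    }
  }

  if (!is.null(training_size)) {
    in_training <- .force_training_size(in_training, segments, seg_scores,
                                        training_size)
  }

  structure(list(training_ids = ids[in_training],
                 test_ids = ids[!in_training],
                 segments = setNames(segments, ids)),
            class = "split_result")
}

# trim representatives from / add runners-up to segments until the training
# total matches `target`; deterministic (largest segment first, then the
# cluster whose candidate is closest to its mean)
.force_training_size <- function(in_training, segments, seg_scores, target) {
  dist_to_centre <- function(info, i) {
    pos <- match(i, info$members)
    mates <- which(info$cluster == info$cluster[pos])
    centre <- colMeans(info$scores[mates, , drop = FALSE])
    sqrt(sum((info$scores[pos, ] - centre)^2))
  }
  while (sum(in_training) > target) {
    seg_train <- tapply(in_training, segments, sum)
    s <- as.integer(names(which.max(seg_train)))
    info <- seg_scores[[s]]
    cand <- info$members[in_training[info$members]]
    # drop the representative farthest from its cluster centre
    d <- vapply(cand, function(i) dist_to_centre(info, i), numeric(1L))
    in_training[cand[which.max(d)]] <- FALSE
  }
  while (sum(in_training) < target) {
    seg_test <- tapply(!in_training, segments, sum)
    s <- as.integer(names(which.max(seg_test)))
    info <- seg_scores[[s]]
    cand <- info$members[!in_training[info$members]]
    if (length(cand) == 0L) stop("cannot reach requested training_size")
    d <- vapply(cand, function(i) dist_to_centre(info, i), numeric(1L))
    in_training[cand[which.min(d)]] <- TRUE
  }
  in_training
}

#' Serialise / replay a split
#'
#' `write_split()` stores a split as CSV (`sample_id,role,segment`);
#' `read_split()` reads such a file back into a `split_result`, so published
#' splits can be replayed exactly.
#'
#' @param split a `split_result`.
#' @param path CSV path.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  ids <- names(split$segments)
  df <- data.frame(sample_id = ids,
                   role = ifelse(ids %in% split$training_ids, "train", "test"),
                   segment = unname(split$segments))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(split)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- read.csv(path, colClasses = c(sample_id = "character"))
  structure(list(training_ids = df$sample_id[df$role == "train"],
                 test_ids = df$sample_id[df$role == "test"],
                 segments = setNames(as.integer(df$segment), df$sample_id)),
            class = "split_result")
}
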