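# Preprocessing: gene intersection, quantile normalization with a stored
# reference distribution, train/test splitting, and cluster-based
# cross-platform distribution transformation.

#' Restrict expression matrices to their common genes
#'
#' All matrices are subset to the lexicographically sorted intersection of
#' their gene ids so that rows align across datasets.
#'
#' @param matrices A list of genes x samples matrices (a single matrix is
#'   also accepted).
#' @return A list of matrices restricted to the shared genes, in the same
#'   (sorted) gene order.
#' @export
intersect_genes <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(matrices) < 1L) stop("need at least one matrix", call. = FALSE)
  lapply(matrices, check_expression_matrix)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0L) stop("empty gene intersection across matrices", call. = FALSE)
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

# Map one sample's values onto a sorted reference by within-sample rank;
# tied values share the average of the reference values at the tied
# midranks (fractional ranks interpolate between adjacent order statistics).
map_to_reference <- function(x, ref_sorted) {
  r <- rank(x, ties.method = "average")
  lo <- floor(r)
  hi <- ceiling(r)
  (ref_sorted[lo] + ref_sorted[hi]) / 2
}

#' Quantile-normalize an expression matrix
#'
#' Each sample's values are replaced by the mean-of-order-statistics
#' reference at that value's within-sample rank, forcing all samples onto a
#' single empirical distribution. The reference is returned so that later
#' samples (test or external sets) can be mapped onto the same distribution
#' with [apply_reference()] without information leaking from them into the
#' reference.
#'
#' @param expr Genes x samples matrix with at least 2 samples.
#' @return A list with `normalized` (the normalized matrix) and `reference`
#'   (sorted numeric vector of length `nrow(expr)`).
#' @export
quantile_normalize <- function(expr) {
  check_expression_matrix(expr, "expr")
  if (ncol(expr) < 2L)
    stop("quantile normalization needs >= 2 samples; use apply_reference() to map a single sample onto an existing reference",
         call. = FALSE)
  ref <- rowMeans(apply(expr, 2, sort))
  out <- apply(expr, 2, map_to_reference, ref_sorted = ref)
  dimnames(out) <- dimnames(expr)
  list(normalized = out, reference = ref)
}

#' Map samples onto a stored quantile-normalization reference
#'
#' @param expr Genes x samples matrix; `nrow(expr)` must equal the reference
#'   length.
#' @param reference Sorted reference distribution from
#'   [quantile_normalize()].
#' @return The normalized matrix on the reference distribution.
#' @export
apply_reference <- function(expr, reference) {
  check_expression_matrix(expr, "expr")
  if (length(reference) != nrow(expr))
    stop(sprintf("reference length (%d) does not match gene count (%d)",
                 length(reference), nrow(expr)), call. = FALSE)
  ref <- sort(reference)
  out <- apply(expr, 2, map_to_reference, ref_sorted = ref)
  dimnames(out) <- dimnames(expr)
  out
}

#' Split samples into training and test sets
#'
#' Deterministic under a fixed seed. With `stratify_by`, the split is drawn
#' within each stratum so every stratum's test share is within one sample of
#' `test_fraction`.
#'
#' @param metadata Data.frame with a `sample_id` column (>= 5 rows).
#' @param test_fraction Proportion of samples held out (default 0.2).
#' @param seed Integer seed.
#' @param stratify_by Optional metadata column name to stratify on.
#' @return A list with character vectors `train` and `test`.
#' @export
split_train_test <- function(metadata, test_fraction = 0.2, seed = 1L,
                             stratify_by = NULL) {
  if (!is.data.frame(metadata) || is.null(metadata$sample_id))
    stop("metadata must be a data.frame with a sample_id column", call. = FALSE)
  if (nrow(metadata) < 5L) stop("need at least 5 samples to split", call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  ids <- as.character(metadata$sample_id)
  with_seed(seed, {
    if (is.null(stratify_by)) {
      strata <- list(ids)
    } else {
      if (is.null(metadata[[stratify_by]]))
        stop(sprintf("unknown metadata field '%s'", stratify_by), call. = FALSE)
      strata <- split(ids, metadata[[stratify_by]])
    }
    test <- unlist(lapply(strata, function(s) {
      n_test <- max(1L, min(length(s) - 1L, round(length(s) * test_fraction)))
      sample(s, n_test)
    }), use.names = FALSE)
    list(train = setdiff(ids, test), test = test[order(match(test, ids))])
  })
}

#' Cross-platform distribution transformation
#'
#' Maps a target platform's expression values onto a reference platform's
#' scale. Genes are clustered by k-means on their standardized reference
#' profiles (default 6 clusters); within each cluster -- and within each
#' sample group when group labels are supplied, e.g. age bins -- the target
#' values are rank-mapped onto the empirical distribution of the reference
#' cluster's values. Clusters with fewer than 2 genes are merged into the
#' nearest cluster with a warning.
#'
#' @param target Genes x samples matrix to transform; its genes must be a
#'   subset of the reference's.
#' @param reference Genes x samples matrix defining the output scale.
#' @param n_clusters Number of gene clusters (default 6).
#' @param target_groups Optional per-sample group labels for `target`
#'   (length `ncol(target)`).
#' @param ref_groups Optional per-sample group labels for `reference`;
#'   required when `target_groups` is given.
#' @param seed Seed for the k-means initialization.
#' @return The transformed target matrix, on the reference scale.
#' @export
cross_platform_transform <- function(target, reference, n_clusters = 6L,
                                     target_groups = NULL, ref_groups = NULL,
                                     seed = 1L) {
  check_expression_matrix(target, "target")
  check_expression_matrix(reference, "reference")
  if (!all(rownames(target) %in% rownames(reference)))
    stop("target gene ids must be a subset of reference gene ids", call. = FALSE)
  if (n_clusters < 1L) stop("n_clusters must be >= 1", call. = FALSE)
  if (!is.null(target_groups) && is.null(ref_groups))
    stop("ref_groups must be supplied together with target_groups", call. = FALSE)
  if (!is.null(target_groups) && length(target_groups) != ncol(target))
    stop("target_groups must have one label per target sample", call. = FALSE)
  if (!is.null(ref_groups) && length(ref_groups) != ncol(reference))
    stop("ref_groups must have one label per reference sample", call. = FALSE)

  ref <- reference[rownames(target), , drop = FALSE]
  # Cluster genes on standardized reference profiles.
  prof <- t(scale(t(ref)))
  prof[!is.finite(prof)] <- 0
  k <- min(n_clusters, nrow(ref))
  cl <- if (k == 1L) {
    list(cluster = rep(1L, nrow(ref)), centers = matrix(colMeans(prof), 1))
  } else {
    with_seed(seed, stats::kmeans(prof, centers = k, nstart = 5, iter.max = 50))
  }
  membership <- cl$cluster
  # Merge singleton clusters into the nearest populated cluster.
  sizes <- table(membership)
  small <- as.integer(names(sizes)[sizes < 2])
  if (length(small) > 0 && length(sizes) > length(small)) {
    keep <- setdiff(unique(membership), small)
    for (s in small) {
      for (g in which(membership == s)) {
        d <- colSums((t(cl$centers[keep, , drop = FALSE]) - prof[g, ])^2)
        membership[g] <- keep[which.min(d)]
      }
    }
    warning(sprintf("%d cluster(s) with < 2 genes merged into nearest cluster",
                    length(small)), call. = FALSE)
  }

  if (is.null(target_groups)) {
    target_groups <- rep("all", ncol(target))
    ref_groups <- rep("all", ncol(ref))
  }
  target_groups <- as.character(target_groups)
  ref_groups <- as.character(ref_groups)

  out <- target
  for (c_id in unique(membership)) {
    genes <- which(membership == c_id)
    for (g in unique(target_groups)) {
      t_cols <- which(target_groups == g)
      r_cols <- which(ref_groups == g)
      if (length(r_cols) == 0L)
        stop(sprintf("no reference samples for group '%s'", g), call. = FALSE)
      ref_vals <- sort(as.vector(ref[genes, r_cols, drop = FALSE]))
      block <- as.vector(target[genes, t_cols, drop = FALSE])
      p <- (rank(block, ties.method = "average") - 0.5) / length(block)
      out[genes, t_cols] <- stats::quantile(ref_vals, probs = p, type = 5, names = FALSE)
    }
  }
  out
}
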