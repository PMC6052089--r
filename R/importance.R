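# Gene-importance rank sources: elastic-net coefficient rank, random-forest
# Gini (impurity) rank, DFS selection-weight rank, wrapper feature
# importance under permutation and directional fold-change perturbations,
# and the two-group |log2FC| rank. Each source emits one score and one rank
# per gene; ranks are a permutation of 1..n_genes with ties broken by gene
# id.

#' Specify a perturbation for wrapper feature importance
#'
#' @param mode `"permute"` (randomly permute the gene's values across
#'   samples) or `"fold_change"` (multiply the gene's linear-scale values by
#'   `2^f`; on the log2 scale this adds `f`).
#' @param f Log2 fold change, used in fold_change mode (the directional
#'   perturbations use +3 and -3).
#' @param seed Seed for permute mode.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(mode = c("permute", "fold_change"), f = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(f) || !is.finite(f)) stop_config("f", "must be finite")
  structure(list(mode = mode, f = f, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Convert importance scores to ranks
#'
#' Rank 1 is the most important (highest score); ties are broken by gene id
#' ascending so the ranking is a deterministic permutation of 1..n.
#'
#' @param scores Named numeric vector (names are gene ids).
#' @return Integer ranks, named and ordered like `scores`.
#' @export
scores_to_ranks <- function(scores) {
  if (is.null(names(scores))) stop("scores must be named by gene id", call. = FALSE)
  if (any(is.na(scores))) stop("missing scores", call. = FALSE)
  ord <- order(-scores, names(scores))
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  names(ranks) <- names(scores)
  ranks
}

importance_frame <- function(scores, method, flags = NULL) {
  ranks <- scores_to_ranks(scores)
  out <- data.frame(gene_id = names(scores), method = method,
                    score = as.numeric(scores), rank = as.integer(ranks),
                    stringsAsFactors = FALSE)
  if (!is.null(flags)) out$flag <- flags
  rownames(out) <- NULL
  out
}

#' Rank genes by absolute elastic-net coefficient
#'
#' @param model A fitted elastic-net `age_model`.
#' @return A data.frame (gene_id, method, score, rank), method `"ELNET"`.
#' @export
coef_rank <- function(model) {
  if (!inherits(model, "age_model_elastic_net"))
    stop("coef_rank needs a fitted elastic-net age model", call. = FALSE)
  scores <- abs(model$fit$weights)
  names(scores) <- model$genes
  importance_frame(scores, "ELNET")
}

#' Rank genes by random-forest impurity (Gini) importance
#'
#' Impurity importances are normalized to sum to one before ranking.
#'
#' @param model A fitted random-forest `age_model`.
#' @return A data.frame (gene_id, method, score, rank), method `"RF"`.
#' @export
gini_rank <- function(model) {
  if (!inherits(model, "age_model_random_forest"))
    stop("gini_rank needs a fitted random-forest age model", call. = FALSE)
  imp <- ranger::importance(model$fit$ranger)
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- model$genes
  importance_frame(imp, "RF")
}

#' Rank genes by DFS selection-layer weight, averaged over folds
#'
#' @param fold_models A list of fitted DFS `age_model`s (one per
#'   cross-validation fold) sharing the same gene order, or a `cv_result`
#'   from a DFS cross-validation.
#' @return A data.frame (gene_id, method, score, rank), method `"DFS"`.
#' @export
dfs_rank <- function(fold_models) {
  if (inherits(fold_models, "cv_result")) fold_models <- fold_models$models
  if (!all(vapply(fold_models, inherits, logical(1), "age_model_dfs_network")))
    stop("dfs_rank needs fitted DFS age models", call. = FALSE)
  genes <- fold_models[[1]]$genes
  for (m in fold_models)
    if (!identical(m$genes, genes))
      stop("fold models do not share a gene order", call. = FALSE)
  w <- rowMeans(vapply(fold_models, function(m) abs(m$fit$selection),
                       numeric(length(genes))))
  names(w) <- genes
  importance_frame(w, "DFS")
}

#' Perturb one gene's expression
#'
#' In permute mode the gene's values are randomly permuted across samples
#' (its value multiset is preserved); in fold_change mode the gene's
#' linear-scale values are multiplied by `2^f`, which on the log2 scale
#' stored here is addition of `f`.
#'
#' @param x Genes x samples log2 matrix.
#' @param gene_id Gene to perturb.
#' @param spec A [perturbation_spec()].
#' @return The perturbed matrix; all other genes untouched.
#' @export
perturb_expression <- function(x, gene_id, spec) {
  check_expression_matrix(x, "x")
  stopifnot(inherits(spec, "perturbation_spec"))
  if (!gene_id %in% rownames(x))
    stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
  if (spec$mode == "fold_change") {
    x[gene_id, ] <- x[gene_id, ] + spec$f
  } else {
    perm <- with_seed(spec$seed, sample.int(ncol(x)))
    x[gene_id, ] <- x[gene_id, perm]
  }
  x
}

fi_floor <- 1e-6

fi_from_r2 <- function(r2_base, r2_pert) {
  clamped <- r2_pert < fi_floor
  list(fi = mean(r2_base / pmax(r2_pert, fi_floor)), clamped = any(clamped))
}

r2_value <- function(y, pred) {
  1 - sum((pred - y)^2) / sum((y - mean(y))^2)
}

#' Wrapper feature importance of one gene
#'
#' For each cross-validation fold, the fold's model predicts its held-out
#' validation split before and after perturbing the gene; the importance is
#' the mean over folds of the ratio `R2(before) / R2(after)`. FI = 1 means
#' the perturbation did not change the fit; FI >> 1 marks an influential
#' gene. Perturbed R2 values below 1e-6 are clamped to keep the ratio
#' finite, and the result is flagged.
#'
#' @param cv A `cv_result` (the backbone is linear-kernel SVR by default in
#'   the pipeline).
#' @param x Genes x samples matrix the cross-validation was run on.
#' @param y Ages, in column order of `x`.
#' @param gene_id Gene to perturb.
#' @param spec A [perturbation_spec()].
#' @return The FI value, with attribute `clamped` (logical).
#' @export
wrapper_fi <- function(cv, x, y, gene_id, spec) {
  stopifnot(inherits(cv, "cv_result"))
  check_expression_matrix(x, "x")
  r2b <- r2p <- numeric(length(cv$models))
  for (f in seq_along(cv$models)) {
    ids <- cv$val_ids[[f]]
    xv <- x[, ids, drop = FALSE]
    yv <- y[match(ids, colnames(x))]
    base <- predict(cv$models[[f]], xv)
    pert <- predict(cv$models[[f]],
                    perturb_expression(xv, gene_id,
                                       fold_perturbation(spec, f, gene_id)))
    r2b[f] <- r2_value(yv, base)
    r2p[f] <- r2_value(yv, pert)
  }
  res <- fi_from_r2(r2b, r2p)
  structure(res$fi, clamped = res$clamped)
}

# Each gene draws one fixed permutation per fold, deterministically derived
# from the spec seed, the fold index and the gene id — so the exact linear
# fast path and the generic perturb-and-repredict path see identical
# perturbations.
fold_perturbation <- function(spec, fold, gene_id) {
  if (spec$mode == "permute")
    perturbation_spec("permute",
                      seed = derive_seed(spec$seed, sprintf("fold%d:%s", fold, gene_id)))
  else spec
}

#' Wrapper feature importance of every gene
#'
#' Vectorized version of [wrapper_fi()]. For models exposing a raw-scale
#' linear representation (elastic net, linear SVR), the perturbed
#' predictions are obtained exactly from the base predictions plus
#' `w_g * delta_g`, avoiding one re-prediction per gene; other families fall
#' back to perturb-and-repredict.
#'
#' @param cv A `cv_result`.
#' @param x,y Data the cross-validation was run on.
#' @param spec A [perturbation_spec()].
#' @param method_label Method name recorded in the output (e.g.
#'   `"SVM_PFI"`).
#' @return A data.frame (gene_id, method, score, rank, flag) where score is
#'   the FI value and flag marks clamped denominators.
#' @export
wrapper_importance <- function(cv, x, y, spec, method_label = "SVM_PFI") {
  stopifnot(inherits(cv, "cv_result"))
  check_expression_matrix(x, "x")
  genes <- rownames(x)
  p <- length(genes)
  k <- length(cv$models)
  ratio_sum <- numeric(p)
  clamped <- logical(p)
  for (f in seq_len(k)) {
    model <- cv$models[[f]]
    ids <- cv$val_ids[[f]]
    xv <- x[, ids, drop = FALSE]
    yv <- y[match(ids, colnames(x))]
    base <- predict(model, xv)
    r2b <- r2_value(yv, base)
    ss_tot <- sum((yv - mean(yv))^2)
    r <- base - yv
    if (!is.null(model$linear_weights)) {
      w <- model$linear_weights[genes]
      if (spec$mode == "fold_change") {
        ss_res <- sum(r^2) + 2 * w * spec$f * sum(r) + length(r) * (w * spec$f)^2
      } else {
        d <- xv * 0
        for (gi in seq_len(p)) {
          perm <- with_seed(derive_seed(spec$seed, sprintf("fold%d:%s", f, genes[gi])),
                            sample.int(ncol(xv)))
          d[gi, ] <- xv[gi, perm] - xv[gi, ]
        }
        ss_res <- sum(r^2) + 2 * w * as.numeric(d %*% r) + w^2 * rowSums(d^2)
      }
      r2p <- 1 - ss_res / ss_tot
    } else {
      r2p <- vapply(genes, function(g) {
        pert <- predict(model, perturb_expression(xv, g, fold_perturbation(spec, f)))
        r2_value(yv, pert)
      }, numeric(1))
    }
    clamped <- clamped | (r2p < fi_floor)
    ratio_sum <- ratio_sum + r2b / pmax(r2p, fi_floor)
  }
  fi <- ratio_sum / k
  names(fi) <- genes
  importance_frame(fi, method_label, flags = ifelse(clamped, "clamped", ""))
}

#' Rank genes by absolute two-group log2 fold change
#'
#' The per-gene log2FC is `mean(young) - mean(old)` (the old group is the
#' reference); genes are ranked by its absolute value.
#'
#' @param x Genes x samples log2 matrix.
#' @param young_ids,old_ids Sample ids of the two groups (both non-empty).
#' @return A data.frame (gene_id, method, score, rank), method `"DE"`.
#' @export
de_log2fc_rank <- function(x, young_ids, old_ids) {
  check_expression_matrix(x, "x")
  if (length(young_ids) == 0 || length(old_ids) == 0)
    stop("both age groups must be non-empty", call. = FALSE)
  if (!all(c(young_ids, old_ids) %in% colnames(x)))
    stop("group sample ids not all present in x", call. = FALSE)
  fc <- rowMeans(x[, young_ids, drop = FALSE]) - rowMeans(x[, old_ids, drop = FALSE])
  out <- importance_frame(abs(fc), "DE")
  out$log2fc <- as.numeric(fc)
  out
}
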