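# End-to-end orchestration: intersect -> normalize -> split -> fit and
# cross-validate the model families -> evaluate -> seven importance rank
# sources -> Borda biomarker panel. One global seed deterministically
# derives per-stage seeds so any stage can be reproduced in isolation.

default_model_specs <- function(seed) {
  families <- c("elastic_net", "svr_linear", "knn", "random_forest", "dfs_network")
  specs <- lapply(families, function(f)
    model_spec(f, seed = derive_seed(seed, paste0("model:", f))))
  names(specs) <- families
  specs
}

#' Model specifications sized for desk-scale cohorts
#'
#' Returns the five family specs with their tuned defaults, except that the
#' DFS network is scaled to the hundreds-of-samples, few-thousand-gene
#' cohorts this package's synthetic studies use: a 32/16/8 hidden stack
#' trained with Adam at 2e-3 for up to 60 epochs. At that problem size the
#' full 512/256/128 architecture with learning rate 1e-5 cannot complete
#' enough optimization steps to move its weights appreciably; the compact
#' configuration trains to convergence in seconds and makes the selection
#' layer informative.
#'
#' @param seed Integer seed from which each family's seed is derived.
#' @return A named list of [model_spec()]s for [age_clock()].
#' @export
desk_scale_models <- function(seed = 1L) {
  list(
    elastic_net = model_spec("elastic_net", seed = derive_seed(seed, "model:elastic_net")),
    svr_linear = model_spec("svr_linear", seed = derive_seed(seed, "model:svr_linear")),
    knn = model_spec("knn", seed = derive_seed(seed, "model:knn")),
    random_forest = model_spec("random_forest", seed = derive_seed(seed, "model:random_forest")),
    dfs_network = model_spec("dfs_network", hidden = c(32L, 16L, 8L), lr = 2e-3,
                             epochs = 60L, batch_size = 32L, patience = 15L,
                             seed = derive_seed(seed, "model:dfs_network"))
  )
}

config_hash <- function(x) {
  sprintf("%08x", derive_seed(0L, paste(deparse(x), collapse = "")))
}

#' Fit a transcriptomic aging clock and derive a biomarker panel
#'
#' Runs the full analysis on a gene-expression cohort: restricts to common
#' genes (for multi-platform input), splits samples 80/20, quantile
#' normalizes with the reference fit on the training split only, fits and
#' five-fold cross-validates the requested model families, evaluates on the
#' held-out test set (overall and sex-stratified), computes the seven
#' gene-importance rank sources (elastic-net coefficients, random-forest
#' Gini importance, DFS selection weights, wrapper FI under permutation and
#' log2 fold changes of +3 and -3 with the linear-SVR backbone, and the
#' young-vs-old |log2FC|), and aggregates them into a Borda-count biomarker
#' panel.
#'
#' @param expression Genes x samples log2 matrix, or a list of such
#'   matrices (one per platform; genes are intersected).
#' @param metadata Data.frame (or list of data.frames matching
#'   `expression`) with columns sample_id, age, sex; optional age_bin,
#'   platform.
#' @param models Named list of [model_spec()]s (default: all five families
#'   with their tuned defaults). The importance stage uses whichever of
#'   elastic_net / random_forest / dfs_network / svr_linear are present.
#' @param test_fraction Held-out share (default 0.2).
#' @param stratify_by Optional metadata column to stratify the split on.
#' @param k Cross-validation folds (default 5).
#' @param epsilon Tolerance for [epsilon_accuracy()] reporting (default 10
#'   years).
#' @param young_max,old_min Age cut-offs defining the differential
#'   expression groups: young = [16, `young_max`], old = (`old_min`, Inf)
#'   (defaults 30 and 60).
#' @param top_n Panel size to report (default 20; `NULL` keeps all genes).
#' @param seed Global seed; all stage seeds derive from it.
#' @param output_dir Optional directory; when given, metrics, panel and a
#'   JSON manifest are written there as TSV/JSON.
#' @return An object of class `age_clock`; see
#'   [print.age_clock()], [summary.age_clock()], [predict.age_clock()].
#' @export
age_clock <- function(expression, metadata, models = NULL, test_fraction = 0.2,
                      stratify_by = NULL, k = 5L, epsilon = 10,
                      young_max = 30, old_min = 60, top_n = 20L, seed = 1L,
                      output_dir = NULL) {
  if (is.list(expression) && !is.matrix(expression)) {
    expression <- intersect_genes(expression)
    expression <- do.call(cbind, expression)
    if (is.list(metadata) && !is.data.frame(metadata))
      metadata <- do.call(rbind, metadata)
  }
  check_expression_matrix(expression, "expression")
  if (!all(metadata$sample_id %in% colnames(expression)))
    stop("metadata sample ids not all present in expression", call. = FALSE)
  metadata <- metadata[match(colnames(expression), metadata$sample_id), ]
  if (any(!is.finite(metadata$age)))
    stop("all samples need a numeric age for training", call. = FALSE)
  if (is.null(models)) models <- default_model_specs(seed)

  split <- split_train_test(metadata, test_fraction = test_fraction,
                            seed = derive_seed(seed, "split"),
                            stratify_by = stratify_by)
  qn <- quantile_normalize(expression[, split$train, drop = FALSE])
  x_train <- qn$normalized
  x_test <- apply_reference(expression[, split$test, drop = FALSE], qn$reference)
  meta_train <- metadata[match(split$train, metadata$sample_id), ]
  meta_test <- metadata[match(split$test, metadata$sample_id), ]
  y_train <- meta_train$age
  y_test <- meta_test$age

  cv <- list(); fits <- list(); test_pred <- list()
  metrics_rows <- list()
  for (nm in names(models)) {
    spec <- models[[nm]]
    cv[[nm]] <- cross_validate(spec, x_train, y_train, k = k,
                               seed = derive_seed(seed, paste0("cv:", nm)))
    fits[[nm]] <- fit_age_model(spec, x_train, y_train)
    pred <- predict(fits[[nm]], x_test)
    test_pred[[nm]] <- age_predictions(split$test, y_test, pred,
                                       sex = if (!is.null(meta_test$sex))
                                         meta_test$sex else rep("unknown", length(y_test)))
    sm <- stratified_metrics(test_pred[[nm]], by = "sex", epsilon = epsilon)
    sm <- cbind(model = spec$family, sm)
    metrics_rows[[nm]] <- sm
  }
  metrics <- do.call(rbind, metrics_rows)
  rownames(metrics) <- NULL

  rank_sources <- list()
  if ("elastic_net" %in% names(fits))
    rank_sources$ELNET <- coef_rank(fits$elastic_net)
  if ("random_forest" %in% names(fits))
    rank_sources$RF <- gini_rank(fits$random_forest)
  if ("dfs_network" %in% names(cv))
    rank_sources$DFS <- dfs_rank(cv$dfs_network)
  if ("svr_linear" %in% names(cv)) {
    fi_seed <- derive_seed(seed, "wrapper_fi")
    rank_sources[["SVM_PFI"]] <-
      wrapper_importance(cv$svr_linear, x_train, y_train,
                         perturbation_spec("permute", seed = fi_seed), "SVM_PFI")
    rank_sources[["SVM_log2FC=3"]] <-
      wrapper_importance(cv$svr_linear, x_train, y_train,
                         perturbation_spec("fold_change", f = 3), "SVM_log2FC=3")
    rank_sources[["SVM_log2FC=-3"]] <-
      wrapper_importance(cv$svr_linear, x_train, y_train,
                         perturbation_spec("fold_change", f = -3), "SVM_log2FC=-3")
  }
  young <- meta_train$sample_id[y_train >= 16 & y_train <= young_max]
  old <- meta_train$sample_id[y_train > old_min]
  if (length(young) > 0 && length(old) > 0)
    rank_sources$DE <- de_log2fc_rank(x_train, young, old)

  panel <- NULL
  if (length(rank_sources) >= 1) {
    keep <- intersect(rank_source_names, names(rank_sources))
    panel <- borda_aggregate(rank_table(rank_sources[keep]))
    if (!is.null(top_n))
      panel <- build_biomarker_panel(panel, min(top_n, nrow(panel)),
                                     n_genes = nrow(expression))
  }

  obj <- structure(list(
    seed = seed, split = split, reference = qn$reference,
    train_matrix = x_train, train_metadata = meta_train,
    models = fits, cv = cv, test_predictions = test_pred,
    metrics = metrics, rank_sources = rank_sources, panel = panel,
    epsilon = epsilon, genes = rownames(expression),
    config_hash = config_hash(list(names(models), test_fraction, k, epsilon,
                                   young_max, old_min, top_n, seed))
  ), class = "age_clock")

  if (!is.null(output_dir)) write_run(obj, output_dir)
  obj
}

# Persist run artifacts: metrics TSV, panel TSV, JSON manifest.
write_run <- function(clock, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(clock$metrics, file.path(output_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(clock$panel))
    utils::write.table(as.data.frame(clock$panel), file.path(output_dir, "panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "transclock",
    version = as.character(utils::packageVersion("transclock")),
    seed = clock$seed, config_hash = clock$config_hash,
    n_genes = length(clock$genes),
    n_train = length(clock$split$train), n_test = length(clock$split$test),
    models = names(clock$models), rank_sources = names(clock$rank_sources)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.age_clock <- function(x, ...) {
  cat(sprintf("Transcriptomic aging clock: %d genes, %d train / %d test samples\n",
              length(x$genes), length(x$split$train), length(x$split$test)))
  overall <- x$metrics[x$metrics$stratum == "overall", ]
  for (i in seq_len(nrow(overall)))
    cat(sprintf("  %-14s r = %.3f  R2 = %.3f  MAE = %.2f  eps-acc(%g) = %.2f\n",
                overall$model[i], overall$r[i], overall$r_squared[i],
                overall$mae[i], x$epsilon, overall$epsilon_accuracy[i]))
  if (!is.null(x$panel))
    cat("  top genes:", paste(utils::head(x$panel$gene_id, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.age_clock <- function(object, ...) {
  structure(list(metrics = object$metrics, panel = object$panel,
                 n_genes = length(object$genes)), class = "summary.age_clock")
}

#' @export
print.summary.age_clock <- function(x, ...) {
  cat("Test-set metrics by model and sex stratum:\n")
  print.data.frame(x$metrics, digits = 3)
  if (!is.null(x$panel)) {
    cat("\nConsensus biomarker panel (Borda count):\n")
    print(x$panel)
  }
  invisible(x)
}

#' Predict ages for new samples with a fitted clock
#'
#' New samples are mapped onto the clock's quantile-normalization reference
#' before prediction, so raw log2 matrices can be passed directly.
#'
#' @param object An `age_clock`.
#' @param x Genes x samples log2 matrix over the clock's gene set.
#' @param model Which fitted family to predict with (default
#'   `"svr_linear"`).
#' @param normalize Map onto the training reference first (default TRUE).
#' @param ... Unused.
#' @return Named numeric vector of predicted ages.
#' @export
predict.age_clock <- function(object, x, model = "svr_linear", normalize = TRUE, ...) {
  if (!model %in% names(object$models))
    stop(sprintf("model '%s' was not fitted in this run", model), call. = FALSE)
  missing <- setdiff(object$genes, rownames(x))
  if (length(missing) > 0)
    stop(sprintf("x is missing %d clock gene(s)", length(missing)), call. = FALSE)
  x <- x[object$genes, , drop = FALSE]
  if (normalize) x <- apply_reference(x, object$reference)
  predict(object$models[[model]], x)
}

#' Predicted-versus-actual age plot for the held-out test set
#'
#' @param x An `age_clock`.
#' @param model Family to plot (default `"svr_linear"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.age_clock <- function(x, model = "svr_linear", ...) {
  p <- x$test_predictions[[model]]
  if (is.null(p)) stop(sprintf("model '%s' was not fitted", model), call. = FALSE)
  graphics::plot(p$age, p$predicted, xlab = "Chronological age (years)",
                 ylab = "Predicted age (years)",
                 main = sprintf("%s: r = %.2f, MAE = %.1f", model,
                                pearson_r(p), mae(p)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Validate a fitted clock on an external, bin-labelled cohort
#'
#' The external matrix is mapped onto the clock's training distribution by
#' cluster-based cross-platform transformation (grouped by age bin, 6 gene
#' clusters by default), then predicted, and age-bin separation is scored
#' by multiclass pairwise AUC, overall and by sex.
#'
#' @param clock An `age_clock`.
#' @param expression External genes x samples log2 matrix containing all
#'   clock genes.
#' @param metadata External metadata with sample_id, age_bin, and
#'   optionally sex (exact ages may be unknown).
#' @param model Family used for prediction (default `"svr_linear"`).
#' @param n_clusters Gene clusters for the cross-platform transform.
#' @param bin_origin Origin used to bin the training ages for the grouped
#'   transform (training ages below it are pooled into the first bin).
#' @return A list with `mauc`, `mauc_by_sex`, and `predictions` (an
#'   [age_predictions()] with bins).
#' @export
validate_external <- function(clock, expression, metadata, model = "svr_linear",
                              n_clusters = 6L, bin_origin = 20) {
  stopifnot(inherits(clock, "age_clock"))
  check_expression_matrix(expression, "expression")
  missing <- setdiff(clock$genes, rownames(expression))
  if (length(missing) > 0)
    stop(sprintf("external cohort is missing %d clock gene(s)", length(missing)),
         call. = FALSE)
  metadata <- metadata[match(colnames(expression), metadata$sample_id), ]
  if (is.null(metadata$age_bin) || any(is.na(metadata$age_bin)))
    stop("external metadata must provide an age_bin for every sample", call. = FALSE)
  if (length(unique(metadata$age_bin)) < 2)
    stop("need at least 2 occupied age bins for external validation", call. = FALSE)
  expression <- expression[clock$genes, , drop = FALSE]
  ref_bins <- as.character(bin_ages(pmax(clock$train_metadata$age, bin_origin),
                                    origin = bin_origin))
  transformed <- cross_platform_transform(
    expression, clock$train_matrix, n_clusters = n_clusters,
    target_groups = as.character(metadata$age_bin), ref_groups = ref_bins,
    seed = derive_seed(clock$seed, "distran"))
  pred <- predict(clock$models[[model]], transformed)
  p <- age_predictions(metadata$sample_id, rep(NA_real_, nrow(metadata)), pred,
                       sex = metadata$sex, age_bin = metadata$age_bin)
  mauc <- multiclass_auc(p)
  by_sex <- NULL
  if (!is.null(p$sex)) {
    by_sex <- vapply(sort(unique(p$sex)), function(s) {
      q <- p[p$sex == s, , drop = FALSE]
      if (length(unique(q$age_bin)) >= 2) multiclass_auc(q) else NA_real_
    }, numeric(1))
  }
  list(mauc = mauc, mauc_by_sex = by_sex, predictions = p)
}
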