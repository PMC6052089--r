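# The age-regression families: elastic net, linear-kernel SVR, weighted
# k-nearest neighbours, random forest, and the deep feature-selection
# network. One fitting front end returns a classed `age_model` object;
# family internals live behind it. Elastic net, SVR and the DFS network see
# per-gene z-scored inputs (scaling fit on the training set); tree and kNN
# families consume the normalized expression directly.

#' Specify an age-regression model
#'
#' Defaults pin each family to its tuned configuration: elastic net with
#' penalty 0.001 and L1 ratio 0.2; linear-kernel SVR with cost 0.01; kNN
#' with 5 inverse-distance-weighted neighbours; random forest with 700 trees
#' of depth at most 50; and the DFS network with hidden layers 512/256/128,
#' ELU activations, dropout 0.5, L1 + L2 penalties on the selection layer,
#' a Frobenius-norm penalty on dense weights, and Adam at learning rate
#' 1e-5.
#'
#' @param family One of `"elastic_net"`, `"svr_linear"`, `"knn"`,
#'   `"random_forest"`, `"dfs_network"`.
#' @param ... Family-specific hyperparameters overriding the defaults:
#'   elastic_net: `lambda`, `l1_ratio`; svr_linear: `cost`, `epsilon`;
#'   knn: `k`; random_forest: `n_trees`, `max_depth`; dfs_network:
#'   `hidden`, `dropout`, `l1`, `l2`, `frobenius`, `lr`, `epochs`,
#'   `batch_size`, `patience`, `validation_fraction`.
#' @param seed Integer seed used by stochastic families.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("elastic_net", "svr_linear", "knn",
                                  "random_forest", "dfs_network"),
                       ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    elastic_net = list(lambda = 0.001, l1_ratio = 0.2),
    svr_linear = list(cost = 0.01, epsilon = 0.1),
    knn = list(k = 5L),
    random_forest = list(n_trees = 700L, max_depth = 50L),
    dfs_network = list(hidden = c(512L, 256L, 128L), dropout = 0.5,
                       l1 = 1e-4, l2 = 1e-4, frobenius = 1e-4, lr = 1e-5,
                       epochs = 200L, batch_size = 32L, patience = 20L,
                       validation_fraction = 0.1)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0)
    stop_config(unknown[1], sprintf("not a hyperparameter of family '%s'", family))
  params <- utils::modifyList(defaults, override)
  if (family == "knn" && (params$k < 1))
    stop_config("k", "must be a positive integer")
  if (family == "elastic_net" && (params$lambda < 0 || params$l1_ratio < 0 ||
                                  params$l1_ratio > 1))
    stop_config("lambda/l1_ratio", "lambda >= 0 and l1_ratio in [0, 1] required")
  if (family == "svr_linear" && params$cost <= 0)
    stop_config("cost", "must be > 0")
  if (family == "random_forest" && (params$n_trees < 1 || params$max_depth < 1))
    stop_config("n_trees/max_depth", "must be positive integers")
  if (family == "dfs_network" && (any(params$hidden < 1) || params$dropout < 0 ||
                                  params$dropout >= 1 || params$lr <= 0))
    stop_config("hidden/dropout/lr", "hidden sizes >= 1, dropout in [0, 1), lr > 0 required")
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

standardize_fit <- function(xt) {
  mu <- colMeans(xt)
  sigma <- apply(xt, 2, stats::sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  list(mu = mu, sigma = sigma)
}

standardize_apply <- function(xt, sc) {
  sweep(sweep(xt, 2, sc$mu, "-"), 2, sc$sigma, "/")
}

#' Fit an age-regression model
#'
#' @param spec A [model_spec()].
#' @param x Genes x samples log2 expression matrix.
#' @param y Ages in years, one per sample (in column order of `x`).
#' @return An object of class `age_model` (and `age_model_<family>`), with
#'   [predict.age_model()], [print.age_model()], [coef.age_model()] and
#'   [residuals.age_model()] methods as the family admits.
#' @export
fit_age_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  check_expression_matrix(x, "x")
  if (length(y) != ncol(x))
    stop("length(y) must equal the number of samples in x", call. = FALSE)
  if (any(!is.finite(y))) stop("ages must be finite", call. = FALSE)
  if (spec$family == "knn" && spec$params$k > ncol(x))
    stop(sprintf("knn with k = %d needs at least that many training samples (got %d)",
                 spec$params$k, ncol(x)), call. = FALSE)
  xt <- t(x)  # samples x genes
  scaled_family <- spec$family %in% c("elastic_net", "svr_linear", "dfs_network")
  scaling <- if (scaled_family) standardize_fit(xt) else NULL
  xs <- if (scaled_family) standardize_apply(xt, scaling) else xt
  fit <- switch(spec$family,
    elastic_net = fit_elastic_net(xs, y, spec),
    svr_linear = fit_svr_linear(xs, y, spec),
    knn = list(train_x = xs, train_y = y),
    random_forest = fit_random_forest(xs, y, spec),
    dfs_network = fit_dfs_family(xs, y, spec)
  )
  obj <- list(spec = spec, genes = rownames(x), scaling = scaling, fit = fit,
              train_ages = y)
  # Raw-scale linear representation, when the family admits one; used by the
  # exact fast path of wrapper feature importance.
  if (spec$family %in% c("elastic_net", "svr_linear")) {
    w_std <- fit$weights
    obj$linear_weights <- w_std / scaling$sigma
    obj$linear_intercept <- fit$intercept - sum(w_std * scaling$mu / scaling$sigma)
    names(obj$linear_weights) <- rownames(x)
  }
  class(obj) <- c(paste0("age_model_", spec$family), "age_model")
  obj
}

# Elastic net minimizing 1/(2n)||y - Xw||^2 + a*r*||w||_1 + a*(1-r)/2*||w||^2
# (the convention in which the tuned lambda/l1_ratio are stated). glmnet
# standardizes y internally, which leaves its effective L1 penalty at
# lambda*alpha but divides the effective L2 penalty by sd(y); the requested
# (a, r) are converted to the glmnet (lambda, alpha) solving the same
# problem:  lambda*alpha = a*r,  lambda*(1-alpha)/sd(y) = a*(1-r).
fit_elastic_net <- function(xs, y, spec) {
  a <- spec$params$lambda
  r <- spec$params$l1_ratio
  sdy <- sqrt(mean((y - mean(y))^2))
  if (sdy == 0)  # degenerate constant target: the penalized optimum is w = 0
    return(list(glmnet = NULL, weights = numeric(ncol(xs)), intercept = mean(y)))
  if (a == 0) {
    g_alpha <- 0; g_lambda <- 0
  } else if (r >= 1) {
    g_alpha <- 1; g_lambda <- a
  } else {
    t_ratio <- r / ((1 - r) * sdy)
    g_alpha <- t_ratio / (1 + t_ratio)
    g_lambda <- a * (1 - r) * sdy / (1 - g_alpha)
  }
  fit <- glmnet::glmnet(xs, y, alpha = g_alpha, lambda = g_lambda,
                        standardize = FALSE, thresh = 1e-10)
  beta <- as.numeric(fit$beta[, 1])
  list(glmnet = fit, weights = beta, intercept = as.numeric(fit$a0[1]))
}

fit_svr_linear <- function(xs, y, spec) {
  if (stats::sd(y) == 0)  # constant target leaves no support vectors
    return(list(svm = NULL, weights = numeric(ncol(xs)), intercept = y[1]))
  fit <- e1071::svm(xs, y, type = "eps-regression", kernel = "linear",
                    cost = spec$params$cost, epsilon = spec$params$epsilon,
                    scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  list(svm = fit, weights = w, intercept = -fit$rho)
}

fit_random_forest <- function(xs, y, spec) {
  df <- as.data.frame(xs)
  colnames(df) <- paste0("g", seq_len(ncol(xs)))
  fit <- ranger::ranger(x = df, y = y, num.trees = spec$params$n_trees,
                        max.depth = spec$params$max_depth,
                        importance = "impurity", seed = spec$seed,
                        num.threads = 1)
  list(ranger = fit)
}

fit_dfs_family <- function(xs, y, spec) {
  p <- spec$params
  net <- build_dfs_network(ncol(xs), hidden = p$hidden, dropout = p$dropout,
                           l1 = p$l1, l2 = p$l2, frobenius = p$frobenius,
                           lr = p$lr, seed = spec$seed)
  train_dfs(net, xs, y, epochs = p$epochs, batch_size = p$batch_size,
            patience = p$patience, validation_fraction = p$validation_fraction,
            seed = spec$seed)
}

#' Predict ages for new samples
#'
#' @param object A fitted `age_model`.
#' @param x Genes x samples matrix over the model's training gene set (gene
#'   order may differ; missing genes raise an error naming them).
#' @param ... Unused.
#' @return A named numeric vector of predicted ages, one per sample.
#' @export
predict.age_model <- function(object, x, ...) {
  check_expression_matrix(x, "x")
  missing <- setdiff(object$genes, rownames(x))
  if (length(missing) > 0)
    stop(sprintf("x is missing %d model gene(s): %s%s", length(missing),
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""), call. = FALSE)
  x <- x[object$genes, , drop = FALSE]
  xt <- t(x)
  if (!is.null(object$scaling)) xt <- standardize_apply(xt, object$scaling)
  pred <- switch(object$spec$family,
    elastic_net = as.numeric(xt %*% object$fit$weights) + object$fit$intercept,
    svr_linear = as.numeric(xt %*% object$fit$weights) + object$fit$intercept,
    knn = knn_predict(object$fit$train_x, object$fit$train_y, xt, object$spec$params$k),
    random_forest = {
      df <- as.data.frame(xt)
      colnames(df) <- paste0("g", seq_len(ncol(xt)))
      stats::predict(object$fit$ranger, data = df, num.threads = 1)$predictions
    },
    dfs_network = predict_dfs(object$fit, xt)
  )
  names(pred) <- colnames(x)
  pred
}

# Inverse-distance-weighted k-nearest-neighbour regression (Euclidean).
# Exact-distance-zero neighbours take over with equal weights, so k = 1
# prediction on a training point returns its own age.
knn_predict <- function(train_x, train_y, new_x, k) {
  t_sq <- rowSums(train_x^2)
  apply(new_x, 1, function(q) {
    d2 <- pmax(t_sq - 2 * as.numeric(train_x %*% q) + sum(q^2), 0)
    nn <- order(d2)[seq_len(k)]
    d <- sqrt(d2[nn])
    if (any(d == 0)) return(mean(train_y[nn][d == 0]))
    w <- 1 / d
    sum(w * train_y[nn]) / sum(w)
  })
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("Age-regression model (%s), %d genes\n", x$spec$family,
              length(x$genes)))
  pstr <- paste(names(x$spec$params),
                vapply(x$spec$params, function(v) paste(format(v), collapse = "/"),
                       character(1)),
                sep = " = ", collapse = ", ")
  cat("  hyperparameters:", pstr, "\n")
  invisible(x)
}

#' Linear coefficients of an age model
#'
#' Available for the linear families (elastic net and linear-kernel SVR);
#' coefficients are reported on the raw log2-expression scale.
#'
#' @param object A fitted `age_model`.
#' @param ... Unused.
#' @return Named numeric vector of per-gene coefficients, with an
#'   `"(Intercept)"` entry first.
#' @export
coef.age_model <- function(object, ...) {
  if (is.null(object$linear_weights))
    stop(sprintf("family '%s' has no linear coefficients", object$spec$family),
         call. = FALSE)
  c("(Intercept)" = object$linear_intercept, object$linear_weights)
}

#' Five-fold cross-validation of an age model
#'
#' Samples are partitioned into `k` near-equal folds; each fold's model is
#' trained on the other folds and predicts the held-out fold, so every
#' sample receives exactly one out-of-fold prediction. The per-fold models
#' and held-out sample ids are retained for feature-importance analysis.
#'
#' @param spec A [model_spec()].
#' @param x Genes x samples matrix.
#' @param y Ages, one per sample.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return An object of class `cv_result`: `fold_assignments` (named
#'   integer vector), `models` (list of k fitted models), `oof`
#'   ([age_predictions()] over all samples), `fold_metrics` (per-fold MAE
#'   and R-squared), `val_ids` (list of held-out sample ids per fold).
#' @export
cross_validate <- function(spec, x, y, k = 5L, seed = 1L) {
  check_expression_matrix(x, "x")
  n <- ncol(x)
  if (k > n) stop(sprintf("k = %d exceeds the sample count %d", k, n), call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  names(folds) <- colnames(x)
  models <- vector("list", k)
  val_ids <- vector("list", k)
  oof <- numeric(n)
  fold_metrics <- data.frame(fold = seq_len(k), mae = NA_real_, r_squared = NA_real_)
  for (f in seq_len(k)) {
    hold <- folds == f
    models[[f]] <- fit_age_model(spec, x[, !hold, drop = FALSE], y[!hold])
    pred <- predict(models[[f]], x[, hold, drop = FALSE])
    oof[hold] <- pred
    val_ids[[f]] <- colnames(x)[hold]
    ap <- age_predictions(colnames(x)[hold], y[hold], pred)
    fold_metrics$mae[f] <- mae(ap)
    fold_metrics$r_squared[f] <- if (sum(hold) >= 2 && stats::sd(y[hold]) > 0)
      r_squared(ap) else NA_real_
  }
  structure(list(spec = spec, fold_assignments = folds, models = models,
                 oof = age_predictions(colnames(x), y, oof),
                 fold_metrics = fold_metrics, val_ids = val_ids),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of family '%s'\n",
              length(x$models), x$spec$family))
  cat(sprintf("  out-of-fold MAE %.2f years, mean per-fold MAE %.2f\n",
              mae(x$oof), mean(x$fold_metrics$mae)))
  invisible(x)
}

#' Grid search over hyperparameters by out-of-fold MAE
#'
#' Each grid point is evaluated by [cross_validate()]; the point with the
#' lowest mean per-fold MAE wins, ties broken by declaration order.
#'
#' @param spec_template A [model_spec()] providing the family and any fixed
#'   parameters.
#' @param grid A non-empty list of named hyperparameter lists, in
#'   declaration order.
#' @param x,y Training data as in [fit_age_model()].
#' @param k Folds (default 5).
#' @param seed Fold-assignment seed (shared across grid points).
#' @return A list with `best_spec`, `best_index`, and `results` (data.frame
#'   of grid point vs mean out-of-fold MAE).
#' @export
grid_search <- function(spec_template, grid, x, y, k = 5L, seed = 1L) {
  stopifnot(inherits(spec_template, "model_spec"))
  if (length(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  scores <- numeric(length(grid))
  specs <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    params <- utils::modifyList(spec_template$params, grid[[i]])
    specs[[i]] <- do.call(model_spec,
                          c(list(family = spec_template$family, seed = spec_template$seed),
                            params))
    cv <- cross_validate(specs[[i]], x, y, k = k, seed = seed)
    scores[i] <- mean(cv$fold_metrics$mae)
  }
  best <- which.min(scores)  # which.min takes the first minimum: declaration-order tie-break
  list(best_spec = specs[[best]], best_index = best,
       results = data.frame(grid_point = seq_along(grid), mean_oof_mae = scores))
}

#' @export
residuals.age_model <- function(object, x, y, ...) {
  predict(object, x) - y
}
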