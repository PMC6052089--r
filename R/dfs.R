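# Deep feature-selection (DFS) network: a feed-forward age regressor whose
# first layer is elementwise -- one weight per input gene, no mixing -- so
# the selection weights double as gene importances. Implemented directly on
# base-R matrix operations: ELU activations, inverted dropout, Adam, L1 + L2
# penalties on the selection layer and a Frobenius-norm penalty on the dense
# weights. Targets are z-scored internally and mapped back at prediction
# time.

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

#' Build an untrained deep feature-selection network
#'
#' Architecture: an elementwise selection layer (one weight per gene),
#' then dense ELU layers of the given sizes, then a single linear output
#' unit. Dense weights use He-style Gaussian initialization; selection
#' weights start at 1 (pass-through).
#'
#' @param n_genes Number of input genes.
#' @param hidden Integer vector of hidden-layer sizes (default 512, 256,
#'   128).
#' @param dropout Dropout rate on hidden activations during training.
#' @param l1,l2 Penalty coefficients on the selection layer.
#' @param frobenius Squared-norm penalty coefficient on dense weights.
#' @param lr Adam learning rate (default 1e-5).
#' @param seed Seed for weight initialization.
#' @return An object of class `dfs_network` with a `selection` weight
#'   vector of length `n_genes`.
#' @export
build_dfs_network <- function(n_genes, hidden = c(512L, 256L, 128L),
                              dropout = 0.5, l1 = 1e-4, l2 = 1e-4,
                              frobenius = 1e-4, lr = 1e-5, seed = 1L) {
  if (n_genes < 1) stop_config("n_genes", "must be >= 1")
  if (any(hidden < 1)) stop_config("hidden", "layer sizes must be >= 1")
  sizes <- c(n_genes, hidden, 1L)
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                    sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    structure(list(selection = rep(1, n_genes), W = W, b = b, sizes = sizes,
                   dropout = dropout, l1 = l1, l2 = l2, frobenius = frobenius,
                   lr = lr, trained = FALSE, y_center = 0, y_scale = 1),
              class = "dfs_network")
  })
}

dfs_forward <- function(net, x, drop_masks = NULL) {
  z <- sweep(x, 2, net$selection, "*")
  acts <- list(z)
  n_dense <- length(net$W)
  for (l in seq_len(n_dense - 1L)) {
    pre <- sweep(acts[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    a <- elu(pre)
    if (!is.null(drop_masks)) a <- a * drop_masks[[l]]
    acts[[l + 1L]] <- a
  }
  out <- as.numeric(acts[[n_dense]] %*% net$W[[n_dense]]) + net$b[[n_dense]]
  list(acts = acts, out = out)
}

#' Train a DFS network with Adam and early stopping
#'
#' Minimizes mean squared error plus the configured penalties by minibatch
#' Adam. A fraction of the training samples is held out as a validation
#' split; training stops when validation MAE has not improved for
#' `patience` epochs, and the best-validation weights are restored.
#'
#' @param net An untrained [build_dfs_network()].
#' @param x Samples x genes matrix (typically z-scored).
#' @param y Ages.
#' @param epochs Maximum epochs (default 200).
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs.
#' @param validation_fraction Fraction held out for early stopping (0
#'   disables early stopping).
#' @param seed Seed for shuffling, dropout and the validation split.
#' @return The trained `dfs_network`.
#' @export
train_dfs <- function(net, x, y, epochs = 200L, batch_size = 32L,
                      patience = 20L, validation_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(net, "dfs_network"))
  n <- nrow(x)
  net$y_center <- mean(y)
  net$y_scale <- if (stats::sd(y) > 0) stats::sd(y) else 1
  yz <- (y - net$y_center) / net$y_scale

  n_dense <- length(net$W)
  # Adam state for selection, W, b.
  ms <- list(s = numeric(length(net$selection)),
             W = lapply(net$W, function(w) w * 0), b = lapply(net$b, function(v) v * 0))
  vs <- ms
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0

  with_seed(seed, {
    use_val <- validation_fraction > 0 && floor(n * validation_fraction) >= 1
    if (use_val) {
      val_idx <- sample.int(n, max(1L, floor(n * validation_fraction)))
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      tr_idx <- seq_len(n)
    }
    best <- list(err = Inf, selection = net$selection, W = net$W, b = net$b)
    wait <- 0L
    for (ep in seq_len(epochs)) {
      order_ep <- sample(tr_idx)
      for (start in seq(1, length(order_ep), by = batch_size)) {
        idx <- order_ep[start:min(start + batch_size - 1L, length(order_ep))]
        xb <- x[idx, , drop = FALSE]
        yb <- yz[idx]
        m <- length(idx)
        drop_masks <- NULL
        if (net$dropout > 0) {
          drop_masks <- lapply(seq_len(n_dense - 1L), function(l)
            matrix(stats::rbinom(m * net$sizes[l + 1L], 1, 1 - net$dropout),
                   m, net$sizes[l + 1L]) / (1 - net$dropout))
        }
        fwd <- dfs_forward(net, xb, drop_masks)
        delta_out <- 2 * (fwd$out - yb) / m

        gW <- vector("list", n_dense); gb <- vector("list", n_dense)
        # Output layer.
        gW[[n_dense]] <- crossprod(fwd$acts[[n_dense]], delta_out) +
          2 * net$frobenius * net$W[[n_dense]]
        gb[[n_dense]] <- sum(delta_out)
        delta <- tcrossprod(matrix(delta_out, ncol = 1), net$W[[n_dense]])
        # Hidden layers, back to front.
        for (l in rev(seq_len(n_dense - 1L))) {
          a <- fwd$acts[[l + 1L]]
          if (!is.null(drop_masks)) {
            delta <- delta * drop_masks[[l]]
            a_pre_drop <- a / ifelse(drop_masks[[l]] == 0, 1, drop_masks[[l]])
            delta <- delta * elu_grad(NULL, a_pre_drop)
          } else {
            delta <- delta * elu_grad(NULL, a)
          }
          gW[[l]] <- crossprod(fwd$acts[[l]], delta) + 2 * net$frobenius * net$W[[l]]
          gb[[l]] <- colSums(delta)
          delta <- delta %*% t(net$W[[l]])
        }
        gs <- colSums(delta * xb) + net$l1 * sign(net$selection) +
          2 * net$l2 * net$selection

        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        ms$s <- beta1 * ms$s + (1 - beta1) * gs
        vs$s <- beta2 * vs$s + (1 - beta2) * gs^2
        net$selection <- net$selection -
          net$lr * (ms$s / corr1) / (sqrt(vs$s / corr2) + eps)
        for (l in seq_len(n_dense)) {
          ms$W[[l]] <- beta1 * ms$W[[l]] + (1 - beta1) * gW[[l]]
          vs$W[[l]] <- beta2 * vs$W[[l]] + (1 - beta2) * gW[[l]]^2
          net$W[[l]] <- net$W[[l]] -
            net$lr * (ms$W[[l]] / corr1) / (sqrt(vs$W[[l]] / corr2) + eps)
          ms$b[[l]] <- beta1 * ms$b[[l]] + (1 - beta1) * gb[[l]]
          vs$b[[l]] <- beta2 * vs$b[[l]] + (1 - beta2) * gb[[l]]^2
          net$b[[l]] <- net$b[[l]] -
            net$lr * (ms$b[[l]] / corr1) / (sqrt(vs$b[[l]] / corr2) + eps)
        }
      }
      if (use_val) {
        val_pred <- dfs_forward(net, x[val_idx, , drop = FALSE])$out
        val_err <- mean(abs(val_pred - yz[val_idx]))
        if (val_err < best$err - 1e-9) {
          best <- list(err = val_err, selection = net$selection, W = net$W, b = net$b)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    }
    if (use_val && is.finite(best$err)) {
      net$selection <- best$selection; net$W <- best$W; net$b <- best$b
    }
  })
  net$trained <- TRUE
  net
}

# ELU gradient from the activation value (a = elu(z)): 1 where a > 0, a + 1
# otherwise. The first argument is unused and kept for call-site symmetry.
elu_grad <- function(z, a) ifelse(a > 0, 1, a + 1)

#' Predict with a trained DFS network
#'
#' @param net A trained `dfs_network`.
#' @param x Samples x genes matrix on the training scale.
#' @return Numeric predicted ages.
#' @export
predict_dfs <- function(net, x) {
  if (!isTRUE(net$trained)) stop("network is not trained", call. = FALSE)
  dfs_forward(net, x)$out * net$y_scale + net$y_center
}
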