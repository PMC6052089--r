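# Shared fixtures: small expression matrices, planted cohorts, and
# brute-force metric oracles used to cross-check the vectorized
# implementations.

named_matrix <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

random_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  named_matrix(rnorm(n_genes * n_samples, 8, 2), n_genes, n_samples)
}

# A cohort with exactly one age-informative gene (G001); all other genes are
# pure noise around a constant baseline.
single_causal_cohort <- function(n = 300, p = 200, slope = 0.03, noise = 0.3,
                                 null_sd = 0.5, seed = 1) {
  set.seed(seed)
  age <- runif(n, 19, 89)
  x <- named_matrix(rnorm(p * n, 0, null_sd), p, n) + runif(p, 4, 12)
  x[1, ] <- 8 + slope * (age - 54) + rnorm(n, 0, noise)
  list(x = x, age = age, causal = rownames(x)[1])
}

# DFS settings sized for the small cohorts used in tests: a compact net
# trained long enough (and fast enough) to actually fit them.
tiny_dfs_spec <- function(seed = 1, ...) {
  model_spec("dfs_network", hidden = c(32L, 16L, 8L), lr = 2e-3, epochs = 120L,
             batch_size = 16L, patience = 30L, seed = seed, ...)
}

# --- brute-force metric oracles -------------------------------------------

oracle_pearson <- function(y, yhat) {
  cy <- y - mean(y); cyh <- yhat - mean(yhat)
  sum(cy * cyh) / sqrt(sum(cy^2) * sum(cyh^2))
}

oracle_r2 <- function(y, yhat) 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)

oracle_mae <- function(y, yhat) sum(abs(yhat - y)) / length(y)

oracle_eps <- function(y, yhat, eps) {
  hits <- 0
  for (i in seq_along(y))
    if (yhat[i] >= y[i] - eps && yhat[i] <= y[i] + eps) hits <- hits + 1
  hits / length(y)
}

# Exhaustive pair counting over all unordered bin pairs (higher bin
# positive); ties count 1/2.
oracle_mauc <- function(bins, pred) {
  lv <- unique(bins)
  lv <- lv[order(suppressWarnings(as.numeric(sub("^([0-9.]+).*$", "\\1", lv))))]
  total <- 0; n_pairs <- 0
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    lo <- pred[bins == lv[i]]; hi <- pred[bins == lv[j]]
    wins <- 0
    for (a in hi) for (b in lo)
      wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
    total <- total + wins / (length(hi) * length(lo))
    n_pairs <- n_pairs + 1
  }
  total / n_pairs
}
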