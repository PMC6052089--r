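test_that("scores map to ranks with gene-id tie-breaking", {
  s <- c(G2 = 3, G1 = 1, G3 = 2)
  expect_equal(unname(scores_to_ranks(s)), c(1L, 3L, 2L))
  tied <- c(B = 1, A = 1, C = 1)
  expect_equal(scores_to_ranks(tied), c(B = 2L, A = 1L, C = 3L))
  # absolute-value ordering of coefficients (0.5, -2.0, 0.0)
  expect_equal(unname(scores_to_ranks(c(A = 0.5, B = 2.0, C = 0.0))), c(2L, 1L, 3L))
  expect_error(scores_to_ranks(c(A = 1, B = NA)), "missing")
  # any score vector yields a permutation of 1..n
  set.seed(1)
  for (i in 1:20) {
    r <- scores_to_ranks(setNames(sample(rnorm(8), 8, replace = TRUE),
                                  paste0("G", 1:8)))
    expect_setequal(r, 1:8)
  }
})

test_that("elastic-net coefficient rank finds a planted causal gene", {
  hits <- 0
  for (s in 1:20) {
    d <- single_causal_cohort(n = 120, p = 50, slope = 0.04, noise = 0.25, seed = s)
    m <- fit_age_model(model_spec("elastic_net", seed = s), d$x, d$age)
    cr <- coef_rank(m)
    hits <- hits + (cr$gene_id[cr$rank == 1] == d$causal)
  }
  expect_gte(hits / 20, 0.95)
  expect_error(coef_rank(list()), "elastic-net")
})

test_that("Gini importances normalize to one and split across duplicated genes", {
  d <- single_causal_cohort(n = 150, p = 30, slope = 0.05, noise = 0.2, seed = 3)
  m <- fit_age_model(model_spec("random_forest", n_trees = 300, seed = 3), d$x, d$age)
  gr <- gini_rank(m)
  expect_equal(sum(gr$score), 1, tolerance = 1e-9)
  expect_equal(gr$gene_id[gr$rank == 1], d$causal)

  # duplicate the causal gene: the two copies share its importance
  x2 <- rbind(d$x, dup = d$x[d$causal, ])
  rownames(x2)[nrow(x2)] <- "G_dup"
  m2 <- fit_age_model(model_spec("random_forest", n_trees = 300, seed = 3), x2, d$age)
  g2 <- gini_rank(m2)
  single_share <- gr$score[gr$gene_id == d$causal]
  combined <- sum(g2$score[g2$gene_id %in% c(d$causal, "G_dup")])
  expect_gt(combined, 0.5 * single_share)
  expect_lt(abs(combined - single_share), 0.5 * single_share)
  # neither copy alone should carry the full single-copy importance
  expect_lt(max(g2$score[g2$gene_id %in% c(d$causal, "G_dup")]), single_share)
})

test_that("DFS selection ranks average over folds as stated", {
  d <- single_causal_cohort(n = 60, p = 12, seed = 5)
  m <- fit_age_model(tiny_dfs_spec(seed = 5, epochs = 15), d$x, d$age)
  fold_models <- list(m, m, m, m, m)
  dr <- dfs_rank(fold_models)
  expect_equal(dr$score, unname(abs(m$fit$selection)))

  # one fold with all-zero weights scales the average by 4/5
  mz <- m
  mz$fit$selection <- m$fit$selection * 0
  dr2 <- dfs_rank(list(m, m, m, m, mz))
  expect_equal(dr2$score, unname(abs(m$fit$selection)) * 4 / 5)

  m_bad <- m; m_bad$genes <- rev(m$genes)
  expect_error(dfs_rank(list(m, m_bad, m, m, m)), "gene order")
})

test_that("perturbation adds f on the log2 scale and permutes multisets", {
  x <- named_matrix(log2(c(1, 2, 4, 8)), 2, 2)
  up <- perturb_expression(x, "G001", perturbation_spec("fold_change", f = 3))
  # x' = x * 2^3 on the linear scale
  expect_equal(2^up["G001", ], 8 * 2^x["G001", ])
  expect_equal(up["G002", ], x["G002", ])

  same <- perturb_expression(x, "G001", perturbation_spec("fold_change", f = 0))
  expect_identical(same, x)

  y <- random_matrix(10, 50, seed = 7)
  perm <- perturb_expression(y, "G004", perturbation_spec("permute", seed = 9))
  expect_equal(as.numeric(sort(perm["G004", ])), as.numeric(sort(y["G004", ])))
  expect_equal(perm[-4, ], y[-4, ])
  expect_error(perturb_expression(y, "nope", perturbation_spec("permute")), "unknown gene")
})

test_that("wrapper FI is exactly 1 for a zero-weight gene under fold change", {
  d <- single_causal_cohort(n = 120, p = 40, slope = 0.05, noise = 0.2, seed = 11)
  # elastic net with real L1 gives exact zero coefficients on null genes
  cv <- cross_validate(model_spec("elastic_net", lambda = 5, l1_ratio = 0.9),
                       d$x, d$age, seed = 11)
  w_all <- vapply(cv$models, function(m) abs(m$fit$weights), numeric(40))
  zero_genes <- cv$models[[1]]$genes[rowSums(w_all) == 0]
  expect_gt(length(zero_genes), 0)
  fi <- wrapper_fi(cv, d$x, d$age, zero_genes[1],
                   perturbation_spec("fold_change", f = 3))
  expect_identical(as.numeric(fi), 1)
  expect_false(attr(fi, "clamped"))
})

test_that("wrapper FI separates a single causal gene from nulls", {
  d <- single_causal_cohort(seed = 21)
  cv <- cross_validate(model_spec("svr_linear"), d$x, d$age, seed = 21)
  fi <- wrapper_importance(cv, d$x, d$age, perturbation_spec("permute", seed = 21))
  causal_fi <- fi$score[fi$gene_id == d$causal]
  null_fi <- fi$score[fi$gene_id != d$causal]
  expect_gt(causal_fi, 10)
  expect_lt(abs(median(null_fi) - 1), 0.1)
  expect_equal(fi$rank[fi$gene_id == d$causal], 1L)
})

test_that("the linear fast path agrees with generic perturb-and-repredict", {
  d <- single_causal_cohort(n = 80, p = 25, seed = 31)
  cv <- cross_validate(model_spec("svr_linear"), d$x, d$age, seed = 31)
  for (spec in list(perturbation_spec("fold_change", f = 3),
                    perturbation_spec("fold_change", f = -3),
                    perturbation_spec("permute", seed = 5))) {
    fast <- wrapper_importance(cv, d$x, d$age, spec)
    for (g in rownames(d$x)[c(1, 7, 20)]) {
      slow <- wrapper_fi(cv, d$x, d$age, g, spec)
      expect_equal(fast$score[fast$gene_id == g], as.numeric(slow),
                   tolerance = 1e-8)
    }
  }
})

test_that("directional fold changes differ for a saturating response", {
  # G001 enters the predictor through a ceiling at 6 log2 units: raising it
  # by f = +3 saturates its contribution while lowering it by f = -3 keeps
  # it in the linear regime, so the two directional FIs must differ. G002
  # is the main linear driver, keeping both perturbed fits informative
  # (neither denominator clamps).
  set.seed(41)
  x <- named_matrix(0, 2, 100)
  x[1, ] <- rnorm(100, 6, 1)
  x[2, ] <- rnorm(100, 0, 2)
  fake_model <- structure(list(genes = rownames(x)), class = "saturating_model")
  registerS3method("predict", "saturating_model",
                   function(object, newdata, ...)
                     50 + 5 * newdata[2, ] + pmin(newdata[1, ], 6))
  age <- 50 + 5 * x[2, ] + pmin(x[1, ], 6) + rnorm(100, 0, 0.5)
  cv <- structure(list(models = list(fake_model), val_ids = list(colnames(x))),
                  class = "cv_result")
  up <- wrapper_fi(cv, x, age, "G001", perturbation_spec("fold_change", f = 3))
  down <- wrapper_fi(cv, x, age, "G001", perturbation_spec("fold_change", f = -3))
  expect_false(attr(up, "clamped"))
  expect_false(attr(down, "clamped"))
  expect_gt(abs(as.numeric(up) - as.numeric(down)), 0.01)
})

test_that("log2 fold-change ranking uses young minus old with old as reference", {
  x <- named_matrix(0, 3, 6)
  x[1, ] <- c(6, 6, 6, 4.5, 4.5, 4.5)   # young mean 6.0, old mean 4.5
  x[2, ] <- c(5, 5, 5, 5, 5, 5)          # equal means
  x[3, ] <- c(4, 4, 4, 4.8, 4.8, 4.8)
  young <- colnames(x)[1:3]; old <- colnames(x)[4:6]
  de <- de_log2fc_rank(x, young, old)
  expect_equal(de$log2fc[de$gene_id == "G001"], 1.5)
  expect_equal(de$rank[de$gene_id == "G002"], 3L)

  swapped <- de_log2fc_rank(x, old, young)
  expect_equal(swapped$log2fc, -de$log2fc)
  expect_equal(swapped$rank, de$rank)
  expect_error(de_log2fc_rank(x, character(0), old), "non-empty")
})

test_that("every rank source separates planted signal genes from nulls", {
  sources_win <- matrix(FALSE, 10, 7,
                        dimnames = list(NULL, c("ELNET", "RF", "DFS", "SVM_PFI",
                                                "SVM_log2FC=3", "SVM_log2FC=-3", "DE")))
  for (s in 1:10) {
    cfg <- cohort_config(n_samples = 150, n_genes = 60, n_signal_genes = 8,
                         effect_size_range = c(0.3, 0.4), seed = s)
    coh <- generate_cohort(cfg)
    x <- coh$expression; age <- coh$metadata$age
    sig <- coh$truth$signal_genes
    beats <- function(df) median(df$rank[df$gene_id %in% sig]) <
      median(df$rank[!df$gene_id %in% sig])

    en <- fit_age_model(model_spec("elastic_net", seed = s), x, age)
    rf <- fit_age_model(model_spec("random_forest", n_trees = 200, seed = s), x, age)
    cv_svr <- cross_validate(model_spec("svr_linear", seed = s), x, age, seed = s)
    cv_dfs <- cross_validate(tiny_dfs_spec(seed = s), x, age, seed = s)
    young <- coh$metadata$sample_id[age <= 30]
    old <- coh$metadata$sample_id[age > 60]

    sources_win[s, "ELNET"] <- beats(coef_rank(en))
    sources_win[s, "RF"] <- beats(gini_rank(rf))
    sources_win[s, "DFS"] <- beats(dfs_rank(cv_dfs))
    sources_win[s, "SVM_PFI"] <- beats(wrapper_importance(
      cv_svr, x, age, perturbation_spec("permute", seed = s)))
    sources_win[s, "SVM_log2FC=3"] <- beats(wrapper_importance(
      cv_svr, x, age, perturbation_spec("fold_change", f = 3), "SVM_log2FC=3"))
    sources_win[s, "SVM_log2FC=-3"] <- beats(wrapper_importance(
      cv_svr, x, age, perturbation_spec("fold_change", f = -3), "SVM_log2FC=-3"))
    sources_win[s, "DE"] <- beats(de_log2fc_rank(x, young, old))
  }
  for (src in colnames(sources_win))
    expect_gte(sum(sources_win[, src]), 8)
})
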