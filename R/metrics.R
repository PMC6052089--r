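# Evaluation metrics for age prediction: Pearson r, coefficient of
# determination, mean absolute error, epsilon-accuracy, and multiclass
# pairwise AUC for cohorts whose ages are only known as bins.

#' Bundle true and predicted ages for a sample set
#'
#' @param sample_id Character sample ids.
#' @param age True ages in years (may be NA when only a bin is known).
#' @param predicted Predicted ages in years.
#' @param sex Optional sex labels.
#' @param age_bin Optional age-bin labels (factor or character).
#' @return A data.frame of class `age_predictions`.
#' @export
age_predictions <- function(sample_id, age, predicted, sex = NULL, age_bin = NULL) {
  n <- length(sample_id)
  if (length(age) != n || length(predicted) != n)
    stop("sample_id, age and predicted must have equal lengths", call. = FALSE)
  if (any(!is.finite(predicted)))
    stop("predicted ages must be finite", call. = FALSE)
  df <- data.frame(sample_id = as.character(sample_id), age = as.numeric(age),
                   predicted = as.numeric(predicted), stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- as.character(sex)
  if (!is.null(age_bin)) df$age_bin <- as.character(age_bin)
  class(df) <- c("age_predictions", "data.frame")
  df
}

#' Pearson correlation between predicted and true age
#'
#' @param p An [age_predictions()] object.
#' @return Product-moment correlation in [-1, 1].
#' @export
pearson_r <- function(p) {
  if (nrow(p) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(p$age) == 0 || stats::sd(p$predicted) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(p$age, p$predicted)
}

#' Coefficient of determination
#'
#' `1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`; can be negative when the
#' predictor does worse than the mean.
#'
#' @param p An [age_predictions()] object.
#' @return R-squared.
#' @export
r_squared <- function(p) {
  if (nrow(p) < 2L) stop("need at least 2 samples", call. = FALSE)
  ss_tot <- sum((p$age - mean(p$age))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant true ages", call. = FALSE)
  1 - sum((p$predicted - p$age)^2) / ss_tot
}

#' Mean absolute error in years
#'
#' @param p An [age_predictions()] object.
#' @return Mean of `|predicted - age|`.
#' @export
mae <- function(p) {
  if (nrow(p) < 1L) stop("need at least 1 sample", call. = FALSE)
  mean(abs(p$predicted - p$age))
}

#' Epsilon-accuracy
#'
#' Fraction of samples whose prediction falls within `epsilon` years of the
#' true age; the interval is closed at both ends, so an exact boundary hit
#' counts as correct.
#'
#' @param p An [age_predictions()] object.
#' @param epsilon Tolerance in years (default 10).
#' @return Proportion in [0, 1].
#' @export
epsilon_accuracy <- function(p, epsilon = 10) {
  if (nrow(p) < 1L) stop("need at least 1 sample", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  mean(abs(p$predicted - p$age) <= epsilon)
}

# Two-class AUC of a continuous score: P(score_pos > score_neg) + 0.5 ties,
# computed via the rank-sum (Mann-Whitney) identity.
pairwise_auc <- function(score_pos, score_neg) {
  n1 <- length(score_pos)
  n2 <- length(score_neg)
  r <- rank(c(score_pos, score_neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Multiclass pairwise AUC of age-bin separation
#'
#' Unweighted mean over all unordered pairs of occupied age bins of the
#' two-class AUC of the continuous age prediction separating the pair, with
#' the older bin treated as positive. Tied predictions contribute 1/2.
#' Invariant under strictly monotone transforms of the predictions.
#'
#' @param p An [age_predictions()] object carrying `age_bin` labels.
#' @param weighted If TRUE, average bin pairs weighted by `n_i * n_j`
#'   instead of uniformly.
#' @return mAUC in [0, 1].
#' @export
multiclass_auc <- function(p, weighted = FALSE) {
  if (is.null(p$age_bin)) stop("age_bin labels required for multiclass AUC", call. = FALSE)
  bins <- unique(as.character(p$age_bin))
  # Order bins by their leading numeric age when labels look like "20-29",
  # falling back to lexicographic order otherwise.
  lead <- suppressWarnings(as.numeric(sub("^([0-9.]+).*$", "\\1", bins)))
  bins <- if (all(is.finite(lead))) bins[order(lead)] else sort(bins)
  if (length(bins) < 2L) stop("need at least 2 occupied age bins", call. = FALSE)
  pairs <- utils::combn(bins, 2, simplify = FALSE)
  aucs <- vapply(pairs, function(pr) {
    lo <- p$predicted[p$age_bin == pr[1]]
    hi <- p$predicted[p$age_bin == pr[2]]
    pairwise_auc(hi, lo)
  }, numeric(1))
  if (weighted) {
    w <- vapply(pairs, function(pr)
      sum(p$age_bin == pr[1]) * sum(p$age_bin == pr[2]), numeric(1))
    sum(aucs * w) / sum(w)
  } else {
    mean(aucs)
  }
}

#' Metrics stratified by a metadata field
#'
#' Computes r, R-squared, MAE and epsilon-accuracy within each stratum plus
#' pooled over all samples. Strata with fewer than 2 samples report NA for r
#' and R-squared.
#'
#' @param p An [age_predictions()] object.
#' @param by Name of a column of `p` to stratify on (e.g. `"sex"`).
#' @param epsilon Tolerance for [epsilon_accuracy()].
#' @return A data.frame with one row per stratum plus an `"overall"` row.
#' @export
stratified_metrics <- function(p, by = "sex", epsilon = 10) {
  if (is.null(p[[by]])) stop(sprintf("unknown field '%s'", by), call. = FALSE)
  one <- function(q, label) {
    data.frame(
      stratum = label, n = nrow(q),
      r = if (nrow(q) >= 2 && stats::sd(q$age) > 0 && stats::sd(q$predicted) > 0)
        pearson_r(q) else NA_real_,
      r_squared = if (nrow(q) >= 2 && stats::sd(q$age) > 0) r_squared(q) else NA_real_,
      mae = mae(q), epsilon_accuracy = epsilon_accuracy(q, epsilon),
      stringsAsFactors = FALSE
    )
  }
  labs <- sort(unique(as.character(p[[by]])))
  rows <- lapply(labs, function(l) one(p[p[[by]] == l, , drop = FALSE], l))
  out <- rbind(one(p, "overall"), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
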