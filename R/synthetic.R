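# Synthetic multi-platform expression cohorts with planted age signal.
#
# The generator works directly on the log2 scale: every gene gets a constant
# baseline, and a minority of "signal" genes additionally drift linearly with
# donor age. Gaussian noise is added with a sex-dependent standard deviation,
# and platforms apply independent per-gene affine distortions. Ground truth
# (which genes carry signal, and their slopes) is returned alongside the data
# so downstream ranking stages can be scored against it.

#' Configuration for a synthetic expression cohort
#'
#' @param n_samples Number of samples to generate.
#' @param n_genes Total number of genes.
#' @param n_signal_genes Number of genes whose expected expression changes
#'   linearly with age (0 for a pure-null cohort).
#' @param age_range Length-2 numeric, years; ages are drawn uniformly on this
#'   interval (default 19 to 89).
#' @param effect_size_range Length-2 numeric: the magnitude of the age slope
#'   of signal genes, in log2 units per decade. Each signal gene draws its
#'   magnitude uniformly from this interval and a random sign. The default
#'   0.1--0.4 log2/decade spans subtle to strong age drifts relative to the
#'   default noise level.
#' @param noise_sd Additive Gaussian noise standard deviation, log2 units.
#' @param sex_noise_ratio Multiplier applied to the noise sd of female
#'   samples (default 0.8, i.e. female profiles are slightly less noisy).
#' @param n_platforms Number of simulated assay platforms.
#' @param batch_scale_sd Standard deviation of the per-platform, per-gene
#'   multiplicative batch effect around 1.
#' @param batch_shift_sd Standard deviation of the per-platform, per-gene
#'   additive batch effect, log2 units.
#' @param seed Integer seed; identical configs with identical seeds produce
#'   bit-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300L, n_genes = 1000L, n_signal_genes = 50L,
                          age_range = c(19, 89), effect_size_range = c(0.1, 0.4),
                          noise_sd = 0.5, sex_noise_ratio = 0.8, n_platforms = 1L,
                          batch_scale_sd = 0.05, batch_shift_sd = 0.3, seed = 1L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    stop_config("n_samples", "must be a positive integer")
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop_config("n_genes", "must be a positive integer")
  if (!is.numeric(n_signal_genes) || length(n_signal_genes) != 1L ||
      n_signal_genes < 0 || n_signal_genes > n_genes)
    stop_config("n_signal_genes", "must be an integer in [0, n_genes]")
  if (length(age_range) != 2L || !is.numeric(age_range) || age_range[1] >= age_range[2])
    stop_config("age_range", "must be an increasing pair of years")
  if (length(effect_size_range) != 2L || any(effect_size_range < 0) ||
      effect_size_range[1] > effect_size_range[2])
    stop_config("effect_size_range", "must be a non-decreasing pair of non-negative slopes")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_config("noise_sd", "must be > 0")
  if (!is.numeric(sex_noise_ratio) || sex_noise_ratio <= 0)
    stop_config("sex_noise_ratio", "must be > 0")
  if (!is.numeric(n_platforms) || n_platforms < 1)
    stop_config("n_platforms", "must be a positive integer")
  if (batch_scale_sd < 0) stop_config("batch_scale_sd", "must be >= 0")
  if (batch_shift_sd < 0) stop_config("batch_shift_sd", "must be >= 0")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_signal_genes = as.integer(n_signal_genes), age_range = as.numeric(age_range),
    effect_size_range = as.numeric(effect_size_range), noise_sd = noise_sd,
    sex_noise_ratio = sex_noise_ratio, n_platforms = as.integer(n_platforms),
    batch_scale_sd = batch_scale_sd, batch_shift_sd = batch_shift_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a single-platform synthetic cohort
#'
#' Ages are drawn uniformly on `config$age_range`. Signal genes follow
#' `baseline + slope * (age - midpoint)`; null genes sit at their baseline.
#' Additive Gaussian noise uses `noise_sd`, scaled by `sex_noise_ratio` for
#' female samples.
#'
#' @param config A [cohort_config()].
#' @return A list with components `expression` (genes x samples log2 matrix),
#'   `metadata` (data.frame: sample_id, age, age_bin, sex, platform) and
#'   `truth` (list: `signal_genes`, `slope_per_gene` in log2 units per year
#'   for every gene, `sex_effect`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    p <- config$n_genes
    n <- config$n_samples
    gene_ids <- sprintf("G%05d", seq_len(p))
    sample_ids <- sprintf("S%05d", seq_len(n))
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- sample(c("female", "male"), n, replace = TRUE)
    baseline <- stats::runif(p, 4, 12)
    slope <- numeric(p)
    signal_idx <- integer(0)
    if (config$n_signal_genes > 0) {
      signal_idx <- sort(sample.int(p, config$n_signal_genes))
      mag <- stats::runif(config$n_signal_genes,
                          config$effect_size_range[1], config$effect_size_range[2]) / 10
      slope[signal_idx] <- mag * sample(c(-1, 1), config$n_signal_genes, replace = TRUE)
    }
    mid <- mean(config$age_range)
    mu <- outer(baseline, rep(1, n)) + outer(slope, age - mid)
    sd_sample <- config$noise_sd * ifelse(sex == "female", config$sex_noise_ratio, 1)
    noise <- matrix(stats::rnorm(p * n), p, n) * rep(sd_sample, each = p)
    expr <- mu + noise
    dimnames(expr) <- list(gene_ids, sample_ids)
    bins <- rep(NA_character_, n)
    ok <- age >= 20
    bins[ok] <- as.character(bin_ages(age[ok]))
    meta <- data.frame(sample_id = sample_ids, age = age, age_bin = bins,
                       sex = sex, platform = "P1", stringsAsFactors = FALSE)
    names(slope) <- gene_ids
    list(expression = expr, metadata = meta,
         truth = list(signal_genes = gene_ids[signal_idx],
                      slope_per_gene = slope,
                      sex_effect = sprintf("female noise sd x %g", config$sex_noise_ratio)))
  })
}

#' Generate a multi-platform synthetic cohort
#'
#' Samples are split across `n_platforms` platforms; each platform applies an
#' independent per-gene affine transform `scale * x + shift` to the shared
#' biological signal, with `scale ~ N(1, batch_scale_sd)` and
#' `shift ~ N(0, batch_shift_sd)`.
#'
#' @param config A [cohort_config()] with `n_platforms >= 2`.
#' @return A list with `platforms` (a list of `list(expression, metadata)`
#'   per platform) and `truth` as in [generate_cohort()].
#' @export
generate_multiplatform <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_platforms < 1) stop_config("n_platforms", "must be >= 1")
  if (config$n_platforms < 2)
    stop_config("n_platforms", "multi-platform generation needs >= 2 platforms")
  base <- generate_cohort(config)
  with_seed(derive_seed(config$seed, "platform_effects"), {
    n <- config$n_samples
    p <- config$n_genes
    k <- config$n_platforms
    assign_platform <- sample(rep_len(seq_len(k), n))
    out <- vector("list", k)
    for (j in seq_len(k)) {
      idx <- which(assign_platform == j)
      scale <- 1 + stats::rnorm(p, 0, config$batch_scale_sd)
      shift <- stats::rnorm(p, 0, config$batch_shift_sd)
      expr_j <- base$expression[, idx, drop = FALSE] * scale + shift
      meta_j <- base$metadata[idx, , drop = FALSE]
      meta_j$platform <- sprintf("P%d", j)
      rownames(meta_j) <- NULL
      out[[j]] <- list(expression = expr_j, metadata = meta_j)
    }
    list(platforms = out, truth = base$truth)
  })
}

#' Bin continuous ages into half-open fixed-width bins
#'
#' Bins are `[origin + k*width, origin + (k+1)*width)`, labelled e.g.
#' `"20-29"`. The defaults give decade bins starting at 20, the convention
#' used for donor ages released only as coarse bins.
#'
#' @param ages Numeric ages in years.
#' @param bin_width Bin width in years (> 0).
#' @param origin Lower edge of the first bin.
#' @return A factor of bin labels with levels in increasing age order.
#' @export
bin_ages <- function(ages, bin_width = 10, origin = 20) {
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (any(!is.finite(ages))) stop("ages must be finite", call. = FALSE)
  if (any(ages < origin))
    stop(sprintf("age below bin origin %g: %g", origin, min(ages)), call. = FALSE)
  k <- floor((ages - origin) / bin_width)
  lab <- function(k) sprintf("%g-%g", origin + k * bin_width, origin + (k + 1) * bin_width - 1)
  factor(lab(k), levels = lab(seq(0, max(k))))
}

#' Write an expression matrix as gene-by-sample TSV
#'
#' First column holds gene ids (header `gene_id`), remaining columns are
#' samples.
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param path Output file path.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression_matrix(expr, "expr")
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample TSV expression matrix
#'
#' @param path File written by [write_expression_tsv()] (first column gene
#'   ids, header row of sample ids).
#' @return A genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  check_expression_matrix(m, basename(path))
  m
}

#' Write sample metadata as TSV
#'
#' @param metadata A data.frame with columns sample_id, age, age_bin, sex,
#'   platform.
#' @param path Output file path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix in GCT 1.2 format
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param path Output file path.
#' @param description Optional per-gene description column (defaults to
#'   gene ids).
#' @export
write_gct <- function(expr, path, description = NULL) {
  check_expression_matrix(expr, "expr")
  if (is.null(description)) description <- rownames(expr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(nrow(expr), ncol(expr), sep = "\t"), con)
  df <- data.frame(Name = rownames(expr), Description = description, expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
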