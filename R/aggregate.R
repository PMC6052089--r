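# Borda-count consensus of the seven importance rank sources into a final
# biomarker panel. The implemented rule is rank-sum ascending: a gene's
# Borda score is the sum of its per-method ranks, and the gene with the
# lowest sum wins — which orders candidates identically to classical Borda
# points (n - rank, highest total wins).

rank_source_names <- c("RF", "ELNET", "SVM_PFI", "SVM_log2FC=3",
                       "SVM_log2FC=-3", "DFS", "DE")

#' Assemble a gene x method rank table
#'
#' @param ranks A numeric matrix (genes x methods) of positive integer
#'   ranks with gene ids as rownames and method names as colnames, or a
#'   list of importance data.frames as returned by the rank sources (each
#'   with columns gene_id, method, rank).
#' @param require_permutation If TRUE (default), validate that every method
#'   column is a permutation of 1..n_genes.
#' @return A validated integer matrix of class `rank_table`.
#' @export
rank_table <- function(ranks, require_permutation = TRUE) {
  if (is.list(ranks) && !is.data.frame(ranks) && !is.matrix(ranks)) {
    genes <- ranks[[1]]$gene_id
    m <- vapply(ranks, function(df) {
      if (!all(c("gene_id", "method", "rank") %in% names(df)))
        stop("each rank source needs gene_id, method and rank columns", call. = FALSE)
      df$rank[match(genes, df$gene_id)]
    }, numeric(length(genes)))
    colnames(m) <- vapply(ranks, function(df) df$method[1], character(1))
    rownames(m) <- genes
    ranks <- m
  }
  if (!is.matrix(ranks) || is.null(rownames(ranks)) || is.null(colnames(ranks)))
    stop("ranks must be a genes x methods matrix with dimnames", call. = FALSE)
  if (any(is.na(ranks))) stop("rank table has missing cells", call. = FALSE)
  storage.mode(ranks) <- "integer"
  if (require_permutation) {
    n <- nrow(ranks)
    for (m_name in colnames(ranks)) {
      if (!identical(sort(unname(ranks[, m_name])), seq_len(n)))
        stop(sprintf("method '%s' is not a permutation of 1..%d", m_name, n),
             call. = FALSE)
    }
  }
  structure(ranks, class = c("rank_table", class(ranks)))
}

#' Borda-count aggregation of per-method ranks
#'
#' Sums each gene's ranks across methods and orders genes by ascending sum.
#' Ties in the Borda score are broken by gene id ascending and flagged.
#'
#' @param table A [rank_table()] (or a matrix acceptable to it).
#' @param weights Optional per-method weights (default uniform).
#' @return An object of class `biomarker_panel`: a data.frame with gene_id,
#'   the per-method component ranks, `borda_score`, `final_rank`, and a
#'   `tied` flag.
#' @export
borda_aggregate <- function(table, weights = NULL) {
  if (!inherits(table, "rank_table")) table <- rank_table(table)
  if (is.null(weights)) weights <- rep(1, ncol(table))
  if (length(weights) != ncol(table))
    stop("one weight per method required", call. = FALSE)
  score <- as.numeric(table %*% weights)
  ord <- order(score, rownames(table))
  out <- data.frame(gene_id = rownames(table)[ord],
                    as.data.frame(unclass(table))[ord, , drop = FALSE],
                    borda_score = score[ord],
                    final_rank = seq_along(score),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$tied <- duplicated(out$borda_score) | duplicated(out$borda_score, fromLast = TRUE)
  rownames(out) <- NULL
  class(out) <- c("biomarker_panel", "data.frame")
  out
}

#' Truncate a biomarker panel to its top genes
#'
#' Keeps the `top_n` best-ranked genes with all component ranks, and
#' reports each gene's worst component rank as a fraction of the total gene
#' count (a panel drawn from a well-behaved consensus stays within the top
#' quartile on every component).
#'
#' @param panel A `biomarker_panel` from [borda_aggregate()].
#' @param top_n Number of genes to keep.
#' @param n_genes Total number of genes the component ranks refer to
#'   (default: number of rows of `panel`).
#' @return The truncated panel with an extra `worst_component_fraction`
#'   column.
#' @export
build_biomarker_panel <- function(panel, top_n, n_genes = nrow(panel)) {
  stopifnot(inherits(panel, "biomarker_panel"))
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  if (top_n > nrow(panel)) stop("top_n exceeds the number of genes", call. = FALSE)
  out <- panel[seq_len(top_n), , drop = FALSE]
  comp <- setdiff(colnames(out), c("gene_id", "borda_score", "final_rank", "tied",
                                   "worst_component_fraction"))
  out$worst_component_fraction <-
    as.numeric(apply(out[, comp, drop = FALSE], 1, max)) / n_genes
  class(out) <- c("biomarker_panel", "data.frame")
  out
}

#' @export
print.biomarker_panel <- function(x, n = 10L, ...) {
  cat(sprintf("Biomarker panel: %d genes, %d rank sources\n", nrow(x),
              length(setdiff(colnames(x), c("gene_id", "borda_score", "final_rank",
                                            "tied", "worst_component_fraction")))))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more genes\n", nrow(x) - n))
  invisible(x)
}

#' Published 20-gene muscle-aging biomarker panel ranks
#'
#' Loads the component ranks (seven importance methods) and final consensus
#' ranks of a published 20-gene skeletal-muscle aging biomarker panel,
#' shipped with the package as a plain-text fixture. The component ranks
#' refer to a background of 7,682 genes.
#'
#' @return A data.frame with columns gene, the seven method ranks, and
#'   final_rank.
#' @export
muscle_panel_ranks <- function() {
  path <- system.file("extdata", "muscle_panel_ranks.tsv", package = "transclock",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
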