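# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Derive a stage-specific seed from a global seed
#'
#' One global seed deterministically yields independent per-stage seeds, so
#' individual pipeline stages can be rerun in isolation and still reproduce
#' the full run. The stage name is hashed by summing character codes with a
#' multiplicative mix, folded into the 31-bit signed-integer range.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed, always in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Validate the genes x samples expression matrix contract.
check_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric genes x samples matrix", arg), call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("'%s' must carry gene ids as rownames and sample ids as colnames", arg),
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(sprintf("duplicate gene ids in '%s'", arg), call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop(sprintf("duplicate sample ids in '%s'", arg), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in '%s'", arg), call. = FALSE)
  invisible(x)
}
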