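# Internal helpers shared across modules.

#' Evaluate an expression with a locally seeded RNG
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded generators never perturb the global
#' random stream.
#'
#' @param seed integer scalar, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() wrapper that skips the call in the message
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a samples-by-miRNAs expression matrix
#'
#' @param x numeric matrix, samples in rows, miRNAs in columns; must have
#'   unique row and column names, strictly positive finite values and at
#'   least `min_samples` rows.
#' @noRd
check_expression <- function(x, min_samples = 3L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expression data must be a numeric matrix (samples x miRNAs)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("expression matrix needs sample ids as rownames and miRNA ids as colnames")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    abort("sample and miRNA ids must be unique")
  }
  if (nrow(x) < min_samples) {
    abort(sprintf("at least %d samples are required, got %d", min_samples, nrow(x)))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("expression matrix contains missing or non-finite values")
  }
  if (any(x <= 0)) {
    abort("expression values must be strictly positive (2^-dCt scale)")
  }
  invisible(x)
}
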