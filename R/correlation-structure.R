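# Latent correlation structures for the Gaussian-copula generator.
#
# Dependence is specified on the latent Gaussian (log) scale.  Pearson
# correlation of the raw 2^-dCt values is attenuated relative to the latent
# r for high-CV log-normal marginals; see the methods vignette.

#' Construct a latent correlation structure
#'
#' @param ids ordered character vector of miRNA ids.
#' @param matrix symmetric correlation matrix in `[-1, 1]` with unit
#'   diagonal, one row/column per id; defaults to the identity
#'   (independence).
#' @return A `corr_structure`: the matrix with ids as dimnames.
#' @export
correlation_structure <- function(ids, matrix = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) abort("miRNA ids must be unique")
  p <- length(ids)
  if (is.null(matrix)) matrix <- diag(p)
  if (!is.matrix(matrix) || nrow(matrix) != p || ncol(matrix) != p) {
    abort("correlation matrix dimensions must match the ids")
  }
  if (max(abs(matrix - t(matrix))) > 1e-12) abort("correlation matrix must be symmetric")
  if (any(abs(diag(matrix) - 1) > 1e-12)) abort("correlation matrix diagonal must be 1")
  if (any(matrix < -1 - 1e-12) || any(matrix > 1 + 1e-12)) {
    abort("correlation entries must lie in [-1, 1]")
  }
  matrix <- (matrix + t(matrix)) / 2
  dimnames(matrix) <- list(ids, ids)
  structure(ensure_psd(matrix), class = "corr_structure")
}

#' Block-structured latent correlation
#'
#' Builds a correlation structure in which ids inside each listed block are
#' pairwise correlated at `within_r`, ids in different listed blocks at
#' `between_r`, and unlisted ids are independent of everything.
#'
#' @param ids all miRNA ids (column order of the generator output).
#' @param blocks list of character vectors, each a subset of `ids`.
#' @param within_r,between_r latent correlations in `[-1, 1]`.
#' @return A `corr_structure`.
#' @export
block_correlation <- function(ids, blocks, within_r = 0.9, between_r = 0) {
  ids <- as.character(ids)
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  blocks <- lapply(blocks, as.character)
  unknown <- setdiff(unlist(blocks), ids)
  if (length(unknown)) abort("unknown ids in blocks: ", paste(unknown, collapse = ", "))
  for (i in seq_along(blocks)) {
    bi <- blocks[[i]]
    m[bi, bi] <- within_r
    for (j in seq_along(blocks)) {
      if (i != j) m[bi, blocks[[j]]] <- between_r
    }
  }
  diag(m) <- 1
  correlation_structure(ids, m)
}

#' Latent correlation structure emulating the sepsis study
#'
#' The 11 miRNAs of the S and C groups (see [mirna_groups()]) form one
#' correlated block — in the control network the S-S, S-C and C-C edges all
#' exist, so within-group and cross-group latent correlations are set to the
#' same `r` — while the remaining miRNAs (including the two viral ones,
#' isolated in every printed network) are independent.
#'
#' @param r latent correlation of the connected block.
#' @param ids miRNA ids; defaults to the 16 bundled ones.
#' @return A `corr_structure`.
#' @export
study_correlation <- function(r = 0.95, ids = group_profiles("control")$mirna) {
  g <- mirna_groups()
  block_correlation(ids, list(c(g$S, g$C)), within_r = r)
}

#' Decorrelate a set of sponged miRNAs
#'
#' Emulates the sponging perturbation: every latent correlation with at
#' least one endpoint in `sponged_ids` is shrunk towards zero, to
#' `sign(r) * min(|r|, residual_r)`; entries among non-sponged ids are
#' untouched.  If the perturbed matrix is no longer positive semi-definite
#' it is repaired by eigenvalue clipping (with a message).  Applying the
#' same injection twice is idempotent.
#'
#' @param corr a `corr_structure`.
#' @param sponged_ids ids losing their connectivity.
#' @param residual_r remaining absolute correlation, in `[0, 1)`.
#' @return A `corr_structure`.
#' @export
inject_sponge <- function(corr, sponged_ids, residual_r = 0) {
  stopifnot(inherits(corr, "corr_structure"))
  if (!is.numeric(residual_r) || length(residual_r) != 1L ||
      residual_r < 0 || residual_r >= 1) {
    abort("residual_r must be a single value in [0, 1)")
  }
  sponged_ids <- as.character(sponged_ids)
  ids <- rownames(corr)
  unknown <- setdiff(sponged_ids, ids)
  if (length(unknown)) abort("unknown sponged ids: ", paste(unknown, collapse = ", "))
  if (!length(sponged_ids)) return(corr)

  m <- unclass(corr)
  touched <- outer(ids %in% sponged_ids, ids %in% sponged_ids, `|`)
  diag(touched) <- FALSE
  block <- m[touched]
  nonzero <- abs(block) > 0
  if (any(nonzero) && residual_r >= min(abs(block[nonzero]))) {
    warning("residual_r is not below every affected |r|; some entries are unchanged")
  }
  m[touched] <- sign(m[touched]) * pmin(abs(m[touched]), residual_r)
  correlation_structure(ids, m)
}

# Clip negative eigenvalues to zero and renormalize the diagonal to 1.
# A perturbed block structure can leave the indefinite cone slightly; the
# repair is logged via message() so runs that needed it are identifiable.
ensure_psd <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) return(m)
  message(sprintf(
    "correlation matrix repaired to PSD (smallest eigenvalue %.3g clipped to 0)",
    min(e$values)))
  vals <- pmax(e$values, 0)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  dimnames(r) <- dimnames(m)
  (r + t(r)) / 2
}
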