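# Gaussian-copula generator for synthetic expression matrices.

#' Generate a synthetic expression matrix
#'
#' Draws correlated standard normals with the latent correlation structure
#' `corr` (Cholesky transform, with an eigen fallback for singular
#' structures) and maps each column through `exp(mu + sigma * z)`, where
#' `(mu, sigma)` come from [lognormal_params()] applied to the profile's
#' per-miRNA mean and SD.  Marginals therefore reproduce the profile
#' moments exactly in expectation, and dependence is exactly `corr` on the
#' log scale.
#'
#' @param profile a `group_profile` (see [group_profiles()]).
#' @param corr a `corr_structure` covering exactly the profile's miRNA ids,
#'   or `NULL` for independence.
#' @param n_samples number of rows to draw (>= 3, the minimum downstream
#'   correlation needs).
#' @param seed integer seed; identical arguments give an identical matrix.
#' @return Numeric matrix, samples in rows (`S001`, `S002`, ...), miRNAs in
#'   columns, strictly positive values on the 2^-dCt scale.
#' @examples
#' x <- generate_expression(group_profiles("control"), n_samples = 10, seed = 1)
#' dim(x)
#' @export
generate_expression <- function(profile, corr = NULL, n_samples, seed = NULL) {
  validate_group_profile(profile)
  ids <- profile$mirna
  if (is.null(corr)) corr <- correlation_structure(ids)
  stopifnot(inherits(corr, "corr_structure"))
  if (!identical(as.character(rownames(corr)), as.character(ids))) {
    abort("correlation structure ids must match the profile's miRNA ids (same order)")
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L) abort("n_samples must be at least 3")

  par <- lognormal_params(profile$mean, profile$sd)
  p <- length(ids)
  l <- tryCatch(chol(unclass(corr)), error = function(e) NULL)
  z <- with_seed(seed, matrix(stats::rnorm(n_samples * p), n_samples, p))
  if (is.null(l)) {
    # exactly singular structure (e.g. residual_r = 0 after a full sponge
    # would still be fine, but r = 1 blocks are not): use the symmetric
    # eigen square root instead of Cholesky
    e <- eigen(unclass(corr), symmetric = TRUE)
    l <- t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
  }
  z <- z %*% l
  x <- exp(sweep(z, 2L, par$sigma, `*`) + matrix(par$mu, n_samples, p, byrow = TRUE))
  dimnames(x) <- list(sprintf("S%03d", seq_len(n_samples)), ids)
  x
}

#' Generate data for one patient group
#'
#' Convenience wrapper around [generate_expression()] using the bundled
#' profile and, by default, the printed cohort size of the group.
#'
#' @param group one of `"sepsis"`, `"control"`, `"pre_surgery"`,
#'   `"post_surgery"`.
#' @param n_samples sample size; defaults to the group's cohort size.
#' @param corr latent correlation structure (`NULL` = independence).
#' @param seed integer seed.
#' @export
generate_group_data <- function(group, n_samples = NULL, corr = NULL, seed = NULL) {
  prof <- group_profiles(group)
  n <- n_samples %||% unname(group_sizes()[attr(prof, "group")])
  generate_expression(prof, corr = corr, n_samples = n, seed = seed)
}

#' Generate a four-group dataset emulating the study design
#'
#' Control and post-surgery data carry the intact latent structure of
#' [study_correlation()]; sepsis and pre-surgery data carry the same
#' structure after [inject_sponge()] of the S group.  This reproduces the
#' direction of the printed findings — a connectivity collapse of the S
#' group in sepsis and a pre-to-post edge increase — and is the stated
#' world of the package's end-to-end tests.
#'
#' @param r latent correlation of the connected S+C block.
#' @param sponge_residual residual latent correlation left to the sponged
#'   S-group miRNAs.
#' @param n_samples optional named vector overriding [group_sizes()].
#' @param seed integer seed; per-group seeds are derived from it.
#' @return Named list of four expression matrices.
#' @export
generate_study_data <- function(r = 0.95, sponge_residual = 0.1,
                                n_samples = NULL, seed = 1L) {
  sizes <- group_sizes()
  if (!is.null(n_samples)) {
    n_samples <- unlist(n_samples)
    sizes[names(n_samples)] <- n_samples
  }
  intact <- study_correlation(r)
  sponged <- inject_sponge(intact, mirna_groups()$S, sponge_residual)
  structure_of <- list(sepsis = sponged, control = intact,
                       pre_surgery = sponged, post_surgery = intact)
  out <- lapply(seq_along(structure_of), function(i) {
    g <- names(structure_of)[i]
    generate_group_data(g, n_samples = sizes[[g]], corr = structure_of[[i]],
                        seed = as.integer(seed) + i - 1L)
  })
  names(out) <- names(structure_of)
  out
}
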