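# Correlation-coefficient network: pairwise Pearson r, edge at +0.8.

#' Pairwise Pearson correlation matrix of miRNA profiles
#'
#' Standard product-moment correlation between every pair of miRNA columns
#' across samples.  Constant columns have an undefined correlation; these
#' are reported as 0 with a warning so degenerate synthetic inputs still
#' yield a (sparse) network.
#'
#' @param data samples-by-miRNAs expression matrix (>= 3 samples).
#' @param scale `"raw"` correlates the 2^-dCt values as presented,
#'   `"log"` correlates their natural logs — the latent scale of the
#'   copula generator, where dependence is not attenuated by the skew of
#'   the log-normal marginals.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(data, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  check_expression(data)
  if (scale == "log") data <- log(data)
  sds <- apply(data, 2L, stats::sd)
  constant <- sds == 0
  r <- suppressWarnings(stats::cor(data))
  if (any(constant)) {
    warning("constant expression for ",
            paste(colnames(data)[constant], collapse = ", "),
            "; undefined correlations set to 0")
    r[constant, ] <- 0
    r[, constant] <- 0
  }
  diag(r) <- 1
  r
}

#' Threshold a correlation matrix into a network
#'
#' An edge joins two miRNAs when their correlation reaches the threshold:
#' `r >= threshold` in `positive_only` mode (the default — the published
#' threshold is written "+0.8" and no negative-correlation edge is shown),
#' `|r| >= threshold` in `absolute` mode.  All nodes are retained even if
#' isolated.
#'
#' @param corr symmetric correlation matrix with named dimensions.
#' @param threshold edge threshold in (0, 1); ties at exactly the
#'   threshold count as edges.
#' @param mode `"positive_only"` or `"absolute"`.
#' @return A `mirna_network` (method `"correlation"`) whose edges carry
#'   the correlation as attribute `r`.
#' @export
threshold_network <- function(corr, threshold = 0.8,
                              mode = c("positive_only", "absolute")) {
  mode <- match.arg(mode)
  if (!is.matrix(corr) || nrow(corr) != ncol(corr) || is.null(rownames(corr))) {
    abort("corr must be a square matrix with miRNA ids as dimnames")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must be a single value in (0, 1)")
  }
  ids <- rownames(corr)
  v <- if (mode == "absolute") abs(corr) else corr
  hit <- which(upper.tri(v) & v >= threshold, arr.ind = TRUE)
  edges <- cbind(ids[hit[, 1L]], ids[hit[, 2L]])
  attrs <- if (nrow(hit)) data.frame(r = corr[hit]) else NULL
  mirna_network(ids, edges, attrs, method = "correlation")
}

#' Build the correlation-method network from expression data
#'
#' One-shot composition of [pearson_matrix()] and [threshold_network()].
#'
#' @inheritParams pearson_matrix
#' @inheritParams threshold_network
#' @export
correlation_network <- function(data, threshold = 0.8,
                                mode = c("positive_only", "absolute"),
                                scale = c("raw", "log")) {
  threshold_network(pearson_matrix(data, scale = match.arg(scale)),
                    threshold = threshold, mode = match.arg(mode))
}
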