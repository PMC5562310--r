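# Hierarchical-cluster network: cut the miRNA dendrogram into k clusters,
# connect all within-cluster pairs, grade edges by cophenetic distance.

#' Agglomerative clustering of miRNA expression profiles
#'
#' The miRNAs are the clustered objects and the samples the feature
#' dimension.  Defaults follow the SPSS hierarchical-cluster defaults the
#' published analysis relied on: between-groups (UPGMA) average linkage on
#' squared Euclidean distances.  Because the 16 bundled miRNAs span seven
#' orders of magnitude in abundance, each miRNA profile is z-scored by
#' default; otherwise the most abundant miRNA dominates every distance.
#'
#' @param data samples-by-miRNAs expression matrix (>= 3 samples,
#'   >= 2 miRNAs).
#' @param metric `"squared_euclidean"` (default), `"euclidean"` or
#'   `"correlation_distance"` (1 - Pearson r between profiles).
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @param standardize z-score each miRNA profile before computing
#'   distances (default `TRUE`).
#' @return An `hclust` tree with the pairwise distance matrix attached as
#'   attribute `"dist"` and the configuration as attribute `"config"`.
#' @export
hierarchical_cluster <- function(data,
                                 metric = c("squared_euclidean", "euclidean",
                                            "correlation_distance"),
                                 linkage = c("average", "complete", "ward"),
                                 standardize = TRUE) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  check_expression(data)
  if (ncol(data) < 2L) abort("at least 2 miRNAs are required")

  profiles <- t(data) # rows = miRNAs = clustered objects
  if (standardize) {
    mu <- rowMeans(profiles)
    sdv <- apply(profiles, 1L, stats::sd)
    profiles <- (profiles - mu) / ifelse(sdv > 0, sdv, 1)
  }
  if (metric == "correlation_distance") {
    sdv <- apply(profiles, 1L, stats::sd)
    if (any(sdv == 0)) {
      abort("correlation distance undefined for zero-variance profile(s): ",
            paste(rownames(profiles)[sdv == 0], collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(t(profiles)))
  } else {
    d <- stats::dist(profiles, method = "euclidean")
    if (metric == "squared_euclidean") d <- d^2
  }
  tree <- stats::hclust(d, method = switch(linkage,
                                           average = "average",
                                           complete = "complete",
                                           ward = "ward.D"))
  attr(tree, "dist") <- d
  attr(tree, "config") <- list(metric = metric, linkage = linkage,
                               standardize = standardize)
  tree
}

#' Cut a dendrogram into k clusters
#'
#' @param tree an `hclust` tree.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return Named integer vector of cluster memberships.
#' @export
cut_to_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  k <- as.integer(k)
  if (length(k) != 1L || k < 1L || k > n) {
    abort(sprintf("k must lie in [1, %d]", n))
  }
  stats::cutree(tree, k = k)
}

#' Build the cluster-method network from a partition
#'
#' Every within-cluster pair of miRNAs is connected.  Each edge carries the
#' distance between its endpoints — by default the cophenetic distance (the
#' merge height at which the two leaves first join), optionally the raw
#' pairwise dissimilarity — and a connection-strength bin in 1..6.  The six
#' bins are delimited by five increasing edges; distances beyond the last
#' edge fall in bin 6.  When `bin_edges` is `NULL` the five sextile cut
#' points of this network's own edge distances are used and recorded in the
#' result (attribute `"bin_edges"`), so comparisons can re-apply the same
#' bins to another network.
#'
#' @param tree an `hclust` tree from [hierarchical_cluster()].
#' @param partition cluster membership vector from [cut_to_clusters()].
#' @param bin_edges five increasing non-negative distance thresholds, or
#'   `NULL` to derive them from the edge distances.
#' @param distance `"cophenetic"` (default) or `"raw"` pairwise
#'   dissimilarity.
#' @return A `mirna_network` (method `"cluster"`) with edge attributes
#'   `distance` and `strength_bin`.
#' @export
cluster_network <- function(tree, partition, bin_edges = NULL,
                            distance = c("cophenetic", "raw")) {
  distance <- match.arg(distance)
  stopifnot(inherits(tree, "hclust"))
  ids <- tree$labels
  if (!all(ids %in% names(partition))) {
    abort("partition must cover every leaf of the tree")
  }
  dmat <- as.matrix(if (distance == "cophenetic") stats::cophenetic(tree)
                    else attr(tree, "dist"))
  dmat <- dmat[ids, ids]

  pairs <- which(upper.tri(dmat) &
                   outer(partition[ids], partition[ids], `==`),
                 arr.ind = TRUE)
  if (!nrow(pairs)) {
    net <- mirna_network(ids, method = "cluster")
    attr(net, "bin_edges") <- bin_edges
    return(net)
  }
  dists <- dmat[pairs]
  if (is.null(bin_edges)) {
    bin_edges <- unname(stats::quantile(dists, probs = seq_len(5L) / 6))
  }
  if (length(bin_edges) != 5L || is.unsorted(bin_edges, strictly = FALSE)) {
    abort("bin_edges must be five non-decreasing distance thresholds")
  }
  bins <- findInterval(dists, bin_edges) + 1L
  net <- mirna_network(
    ids,
    cbind(ids[pairs[, 1L]], ids[pairs[, 2L]]),
    data.frame(distance = dists, strength_bin = bins),
    method = "cluster"
  )
  attr(net, "bin_edges") <- bin_edges
  net
}

#' Total inter-node distance of a network
#'
#' Sum of the `distance` edge attribute over all edges — the published
#' summary of connection strength for the cluster method (e.g. a control
#' total of 1595 against a sepsis total of 7370).
#'
#' @param net a `mirna_network`; an empty network totals 0.
#' @export
total_distance <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  if (!nrow(net$edges)) return(0)
  if (is.null(net$edge_attrs$distance)) {
    abort("network edges carry no distance attribute")
  }
  sum(net$edge_attrs$distance)
}

#' Build the cluster-method network from expression data
#'
#' Composes [hierarchical_cluster()], [cut_to_clusters()] and
#' [cluster_network()] with the published choice of four clusters.
#'
#' @inheritParams hierarchical_cluster
#' @inheritParams cluster_network
#' @param k number of clusters (default 4).
#' @export
build_cluster_network <- function(data, k = 4L,
                                  metric = c("squared_euclidean", "euclidean",
                                             "correlation_distance"),
                                  linkage = c("average", "complete", "ward"),
                                  standardize = TRUE, bin_edges = NULL,
                                  distance = c("cophenetic", "raw")) {
  tree <- hierarchical_cluster(data, metric = match.arg(metric),
                               linkage = match.arg(linkage),
                               standardize = standardize)
  cluster_network(tree, cut_to_clusters(tree, k), bin_edges = bin_edges,
                  distance = match.arg(distance))
}
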