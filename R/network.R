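# The common undirected network container shared by all three builders.

#' Construct a miRNA network
#'
#' Undirected graph over a fixed node set.  Edges are stored canonically
#' (lexicographically ordered pairs, no self loops, no duplicates) so that
#' set operations between networks are well defined; isolated nodes are
#' first-class citizens — the central observation of the analysis is node
#' isolation, so no operation or serialization may drop degree-0 nodes.
#'
#' @param nodes character vector of miRNA ids.
#' @param edges two-column character matrix (or data frame) of endpoint
#'   pairs; may be empty.
#' @param edge_attrs optional data frame of per-edge attributes, one row
#'   per row of `edges` (e.g. `r`, `distance`, `strength_bin`, `direction`).
#' @param method one of `"correlation"`, `"cluster"`, `"bayes"` (or
#'   another label for ad-hoc graphs).
#' @return An object of class `mirna_network` with elements `nodes`,
#'   `edges`, `edge_attrs`, `method`.
#' @export
mirna_network <- function(nodes, edges = NULL, edge_attrs = NULL,
                          method = "custom") {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("network nodes must be unique")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), 0L, 2L)
    edge_attrs <- if (is.null(edge_attrs)) NULL else edge_attrs[0L, , drop = FALSE]
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) abort("edges must have two columns")
  }
  if (nrow(edges)) {
    bad <- setdiff(c(edges), nodes)
    if (length(bad)) abort("edge endpoints not in node set: ", paste(bad, collapse = ", "))
    if (any(edges[, 1L] == edges[, 2L])) abort("self loops are not allowed")
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    edges <- cbind(a, b, deparse.level = 0)
    if (!is.null(edge_attrs)) {
      edge_attrs <- as.data.frame(edge_attrs)
      if (nrow(edge_attrs) != nrow(edges)) {
        abort("edge_attrs must have one row per edge")
      }
    }
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      edges <- edges[keep, , drop = FALSE]
      if (!is.null(edge_attrs)) edge_attrs <- edge_attrs[keep, , drop = FALSE]
      key <- key[keep]
    }
    o <- order(edges[, 1L], edges[, 2L])
    edges <- edges[o, , drop = FALSE]
    if (!is.null(edge_attrs)) {
      edge_attrs <- edge_attrs[o, , drop = FALSE]
      rownames(edge_attrs) <- NULL
    }
  }
  structure(
    list(nodes = nodes, edges = edges, edge_attrs = edge_attrs, method = method),
    class = "mirna_network"
  )
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("<mirna_network: %s method, %d nodes, %d edges, %d isolated>\n",
              x$method, length(x$nodes), nrow(x$edges),
              sum(network_degree(x) == 0L)))
  invisible(x)
}

#' Number of edges of a network
#' @param net a `mirna_network`.
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  nrow(net$edges)
}

#' Per-node degree of a network
#'
#' @param net a `mirna_network`.
#' @return Named integer vector over all nodes (isolated nodes report 0).
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

# canonical "a|b" edge keys, used for set algebra between networks
edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  paste(net$edges[, 1L], net$edges[, 2L], sep = "|")
}

# mirna_network -> igraph, keeping isolated nodes and edge attributes
as_igraph <- function(net) {
  stopifnot(inherits(net, "mirna_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, as.vector(t(net$edges)))
    if (!is.null(net$edge_attrs)) {
      for (nm in names(net$edge_attrs)) {
        g <- igraph::set_edge_attr(g, nm, value = net$edge_attrs[[nm]])
      }
    }
  }
  igraph::set_graph_attr(g, "method", net$method)
}
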