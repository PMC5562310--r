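# File formats: expression TSV/CSV, edge-list TSV, GraphML, JSON reports.
# Isolated nodes are always serialized — the analysis' key observation is
# node isolation, so formats that drop degree-0 nodes are forbidden here.

#' Write an expression matrix to TSV/CSV
#'
#' First column `sample_id`, one column per miRNA, header row mandatory.
#' Values are written with 12 significant digits and round-trip losslessly
#' at that precision.
#'
#' @param x samples-by-miRNAs expression matrix.
#' @param path output path; a `.csv` extension selects comma separation,
#'   anything else tab.
#' @export
write_expression <- function(x, path) {
  check_expression(x, min_samples = 1L)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(x),
                   apply(x, 2L, function(v) formatC(v, digits = 12, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param path TSV or CSV file with a `sample_id` first column.
#' @return Numeric samples-by-miRNAs matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort("no such expression file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id") {
    abort(path, ": first column must be 'sample_id'")
  }
  x <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(x)) abort(path, ": non-numeric expression values")
  rownames(x) <- df$sample_id
  check_expression(x, min_samples = 1L)
  x
}

#' Write a network as an edge-list TSV
#'
#' Columns `node_a`, `node_b` plus any edge attributes.  The full node set
#' and the method label are stored in `#` header comments so isolated
#' nodes survive the round trip.
#'
#' @param net a `mirna_network`.
#' @param path output path.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "mirna_network"))
  df <- data.frame(node_a = net$edges[, 1L], node_b = net$edges[, 2L],
                   stringsAsFactors = FALSE)
  if (!is.null(net$edge_attrs)) df <- cbind(df, net$edge_attrs)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 12, format = "g"))
  body <- c(paste(names(df), collapse = "\t"),
            if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(c(paste0("# method: ", net$method),
               paste0("# nodes: ", paste(net$nodes, collapse = "\t")),
               body), path)
  invisible(path)
}

#' Read a network written by [write_network_tsv()]
#'
#' @param path edge-list TSV with `# method:` and `# nodes:` header
#'   comments.
#' @return A `mirna_network`.
#' @export
read_network_tsv <- function(path) {
  if (!file.exists(path)) abort("no such network file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  method <- sub("^# method: ", "", grep("^# method: ", hdr, value = TRUE))
  nodes_line <- sub("^# nodes: ", "", grep("^# nodes: ", hdr, value = TRUE))
  if (!length(method) || !length(nodes_line)) {
    abort(path, ": missing '# method:' or '# nodes:' header")
  }
  nodes <- strsplit(nodes_line, "\t", fixed = TRUE)[[1L]]
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  attrs <- if (ncol(df) > 2L) df[, -(1:2), drop = FALSE] else NULL
  mirna_network(nodes, as.matrix(df[, 1:2]), attrs, method = method)
}

#' Write a network as GraphML
#'
#' Isolated nodes and edge attributes are preserved; node ids are stored
#' in the `name` vertex attribute.
#'
#' @param net a `mirna_network`.
#' @param path output path.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network written by [write_network_graphml()]
#'
#' @param path GraphML file.
#' @return A `mirna_network`.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) abort("no such network file: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  attrs <- if (length(ea) && nrow(el)) as.data.frame(ea) else NULL
  method <- igraph::graph_attr(g, "method") %||% "custom"
  mirna_network(nodes, el, attrs, method = method)
}

#' Serialize a comparison report (or any report list) as JSON
#'
#' @param report a `comparison_report` or plain list.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  for (nm in intersect(c("kept", "lost", "gained"), names(out))) {
    m <- out[[nm]]
    out[[nm]] <- if (nrow(m)) apply(m, 1L, paste, collapse = "|") else character(0)
  }
  out$c_group <- as.vector(out$c_group)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export an edge-difference view as three-colour GraphML
#'
#' One graph over the union node set whose edges carry a `status`
#' attribute (`kept`, `lost`, `gained`) — the differential-network figure
#' of the analysis as a file.
#'
#' @param net_a,net_b `mirna_network` objects.
#' @param path output path.
#' @export
write_edge_diff_graphml <- function(net_a, net_b, path) {
  d <- edge_diff(net_a, net_b)
  edges <- rbind(d$kept, d$lost, d$gained)
  status <- rep(c("kept", "lost", "gained"),
                c(nrow(d$kept), nrow(d$lost), nrow(d$gained)))
  net <- mirna_network(union(net_a$nodes, net_b$nodes), edges,
                       if (length(status)) data.frame(status = status) else NULL,
                       method = "diff")
  write_network_graphml(net, path)
}
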