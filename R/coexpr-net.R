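#' All-pairs Pearson correlation of gene expression profiles
#'
#' Correlations are computed over pairwise-complete samples; a pair with
#' fewer than `min_overlap` shared non-missing samples, or involving a
#' zero-variance gene, gets `NA`.  The diagonal is 1 for genes with
#' defined variance.
#'
#' @param x an `expression_matrix`.
#' @param min_overlap minimum shared non-missing samples per pair
#'   (default 3).
#' @return A symmetric genes x genes correlation matrix in \[-1, 1\].
#' @export
pcc_matrix <- function(x, min_overlap = 3L) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  suppressWarnings(cc <- stats::cor(t(v), use = "pairwise.complete.obs",
                                    method = "pearson"))
  obs <- !is.na(v)
  overlap <- obs %*% t(obs)
  cc[overlap < min_overlap] <- NA_real_
  zero_var <- apply(v, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) < 2L || stats::sd(r) == 0
  })
  if (any(zero_var)) {
    message(sum(zero_var), " zero-variance gene(s) excluded from ",
            "correlation: ",
            paste(utils::head(rownames(v)[zero_var], 5L), collapse = ", "),
            if (sum(zero_var) > 5L) ", ...")
    cc[zero_var, ] <- NA_real_
    cc[, zero_var] <- NA_real_
  }
  diag(cc)[!zero_var] <- 1
  cc
}

#' Build the thresholded co-expression network
#'
#' An edge joins genes i and j iff PCC(i, j) > `threshold`, strictly:
#' positive correlations above the cutoff are co-expression associations.
#' Nodes are the genes incident to at least one edge; correlation-isolated
#' genes are excluded from the network.  Edge weights carry the PCC.
#'
#' @param pcc symmetric correlation matrix from [pcc_matrix()].
#' @param threshold correlation cutoff in \[-1, 1); default 0.90.
#' @param provenance label stored on the graph (`"inferred"` by default).
#' @return An undirected [igraph::igraph] with edge attribute `weight` and
#'   graph attribute `provenance`.
#' @export
build_network <- function(pcc, threshold = 0.90, provenance = "inferred") {
  if (!(threshold >= -1 && threshold < 1)) {
    stop("threshold must lie in [-1, 1)")
  }
  if (is.null(rownames(pcc))) stop("correlation matrix needs gene ids")
  keep <- which(upper.tri(pcc) & !is.na(pcc) & pcc > threshold,
                arr.ind = TRUE)
  edges <- data.frame(from = rownames(pcc)[keep[, 1L]],
                      to = colnames(pcc)[keep[, 2L]],
                      weight = pcc[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::set_graph_attr(g, "provenance", provenance)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Summary statistics of a co-expression network
#'
#' The primary summaries are those of an undirected graph: node and edge
#' counts, average connectivity (mean degree, 2E/N) and maximum degree.
#' Optionally the edge set is also read under an ordered-pair convention
#' (each undirected edge oriented from the lexicographically smaller to
#' the larger gene id), yielding out-/in-degree maxima and a per-node mean
#' of outgoing edges; these directed readings are reported clearly
#' labelled, since a co-expression graph has no intrinsic direction.
#'
#' @param net an igraph network from [build_network()] or derived from it.
#' @param directed_convention also compute the lexicographic ordered-pair
#'   statistics (default `FALSE`).
#' @return A one-row `data.frame`: `provenance`, `n_nodes`, `n_edges`,
#'   `connectivity_avg`, `connectivity_max`, plus `degree_avg_directed`,
#'   `outdegree_max`, `indegree_max` when requested.
#' @export
network_stats <- function(net, directed_convention = FALSE) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  e <- igraph::ecount(net)
  deg <- igraph::degree(net)
  out <- data.frame(
    provenance = igraph::graph_attr(net, "provenance") %||% NA_character_,
    n_nodes = n, n_edges = e,
    connectivity_avg = 2 * e / n,
    connectivity_max = max(deg),
    stringsAsFactors = FALSE)
  if (directed_convention) {
    el <- igraph::as_edgelist(net)
    src <- pmin(el[, 1L], el[, 2L])
    dst <- pmax(el[, 1L], el[, 2L])
    outdeg <- table(factor(src, levels = igraph::V(net)$name))
    indeg <- table(factor(dst, levels = igraph::V(net)$name))
    out$degree_avg_directed <- e / n
    out$outdegree_max <- max(outdeg)
    out$indegree_max <- max(indeg)
  }
  out
}

#' Mean degree from node and edge counts
#'
#' The average connectivity of an undirected graph is 2E/N; this desk-scale
#' identity lets published node/edge counts be checked against published
#' connectivity columns without the underlying data.
#'
#' @param n_nodes,n_edges nonnegative counts.
#' @return 2 * n_edges / n_nodes.
#' @export
mean_degree <- function(n_nodes, n_edges) {
  if (any(n_nodes <= 0)) stop("n_nodes must be positive")
  2 * n_edges / n_nodes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a network as an edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `pcc`; rows sorted lexicographically for
#' byte-reproducible output.
#'
#' @param net an igraph network with `weight` edge attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(gene_a = pmin(el[, 1L], el[, 2L]),
                   gene_b = pmax(el[, 1L], el[, 2L]),
                   pcc = igraph::E(net)$weight, stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in SIF format
#'
#' Simple interaction format: `gene_a  coexp  gene_b`, one edge per line,
#' plus bare lines for isolated nodes (none are produced by
#' [build_network()], but induced subgraphs may contain them).
#'
#' @inheritParams write_edge_list
#' @param relation interaction type string (default `"coexp"`).
#' @export
write_sif <- function(net, path, relation = "coexp") {
  el <- igraph::as_edgelist(net)
  lines <- character(0)
  if (nrow(el)) {
    a <- pmin(el[, 1L], el[, 2L])
    b <- pmax(el[, 1L], el[, 2L])
    ord <- order(a, b)
    lines <- paste(a[ord], relation, b[ord], sep = "\t")
  }
  lonely <- setdiff(igraph::V(net)$name, unique(c(el)))
  writeLines(c(lines, sort(lonely)), path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Thin wrapper over [igraph::write_graph()] for interoperability with
#' Cytoscape-style viewers.
#'
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
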