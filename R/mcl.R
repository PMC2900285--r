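#' Markov Clustering (MCL) of a weighted network
#'
#' From-scratch implementation of the MCL graph clustering algorithm on
#' sparse matrices.  The weighted adjacency matrix (PCC edge weights by
#' default) is given self-loops, column-normalized to a stochastic flow
#' matrix, and then iterated through alternating *expansion* (matrix
#' power, default squaring) and *inflation* (elementwise power followed by
#' column renormalization).  Entries below `prune_threshold` are dropped
#' after each inflation to keep the matrix sparse, and iteration stops
#' when the largest entrywise change falls below `tol` or after
#' `max_iter` rounds.  Inflation controls cluster granularity; the mussel
#' atlas analysis uses 3.0.
#'
#' Clusters are read off the limit matrix as attractor systems: nodes with
#' positive diagonal mass are attractors, attractors connected through the
#' nonzero structure of the limit matrix form one system, and every other
#' node joins the system receiving most of its flow (ties broken towards
#' the system with the lexicographically smallest member, so the
#' clustering is deterministic).
#'
#' @param net an undirected igraph network with `weight` edge attribute.
#' @param inflation inflation exponent (> 1); default 3.0.
#' @param expansion expansion power (integer >= 2); default 2.
#' @param prune_threshold entries below this are zeroed after inflation;
#'   default 1e-5.
#' @param max_iter iteration cap; default 100.
#' @param tol convergence tolerance on the max entrywise change;
#'   default 1e-6.
#' @param use_weights use PCC edge weights (default) or binary adjacency.
#' @param self_loops `"max"` (per-node self-loop equal to the maximum
#'   incident edge weight, standard MCL practice) or `"one"`.
#' @return A `cluster_set`: list with `clusters` (list of character
#'   vectors, ordered by decreasing size), `sizes`, `retained` (all `NA`
#'   until [filter_clusters()]), `converged`, `iterations`, `params`.
#' @export
mcl <- function(net, inflation = 3.0, expansion = 2L,
                prune_threshold = 1e-5, max_iter = 100L, tol = 1e-6,
                use_weights = TRUE, self_loops = c("max", "one")) {
  self_loops <- match.arg(self_loops)
  if (inflation <= 1) stop("inflation must exceed 1")
  if (expansion < 2L) stop("expansion must be >= 2")
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  nodes <- igraph::V(net)$name
  a <- igraph::as_adjacency_matrix(net, attr = if (use_weights) "weight",
                                   sparse = TRUE)
  a <- methods::as(a, "CsparseMatrix")
  if (any(a@x < 0)) stop("negative edge weights are not supported")
  loop <- switch(self_loops,
                 max = {
                   m <- apply(a, 2L, max)
                   m[m == 0] <- 1
                   m
                 },
                 one = rep(1, n))
  Matrix::diag(a) <- loop
  m <- normalize_columns(a)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    m_new <- m
    for (i in seq_len(expansion - 1L)) m_new <- m_new %*% m
    m_new <- inflate_columns(m_new, inflation)
    m_new <- Matrix::drop0(m_new * (abs(m_new) >= prune_threshold))
    m_new <- normalize_columns(m_new)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current clustering")
  }
  clusters <- read_attractor_systems(as.matrix(m), nodes)
  new_cluster_set(clusters,
                  params = list(inflation = inflation,
                                expansion = expansion,
                                prune_threshold = prune_threshold,
                                max_iter = max_iter, tol = tol,
                                use_weights = use_weights,
                                self_loops = self_loops),
                  converged = converged, iterations = iter)
}

# column-normalize a sparse nonnegative matrix to stochastic columns;
# an all-zero column gets mass 1 on its diagonal
normalize_columns <- function(m) {
  cs <- Matrix::colSums(m)
  dead <- which(cs == 0)
  if (length(dead)) {
    m[cbind(dead, dead)] <- 1
    cs[dead] <- 1
  }
  m %*% Matrix::Diagonal(x = 1 / cs)
}

# elementwise power on the nonzero entries
inflate_columns <- function(m, r) {
  m <- methods::as(m, "CsparseMatrix")
  m@x <- m@x^r
  normalize_columns(m)
}

# interpret a (near-)limit stochastic matrix as disjoint clusters
read_attractor_systems <- function(m, nodes, eps = 1e-8) {
  n <- length(nodes)
  attract <- which(diag(m) > eps)
  if (!length(attract)) attract <- seq_len(n)   # degenerate guard
  # attractor systems: components of the symmetrized nonzero structure
  # restricted to attractor nodes (label propagation to a fixed point)
  sub <- (abs(m[attract, attract, drop = FALSE]) > eps)
  sub <- sub | t(sub)
  diag(sub) <- TRUE
  system_of <- seq_along(attract)
  repeat {
    nxt <- vapply(seq_along(attract),
                  function(i) min(system_of[sub[i, ]]), integer(1))
    if (identical(nxt, system_of)) break
    system_of <- nxt
  }
  system_of <- match(system_of, sort(unique(system_of)))
  n_sys <- max(system_of)
  # lexicographically smallest member per system, for tie-breaking
  heads <- vapply(seq_len(n_sys), function(s) {
    min(nodes[attract[system_of == s]])
  }, character(1))
  assign <- integer(n)
  assign[attract] <- system_of
  rest <- setdiff(seq_len(n), attract)
  for (j in rest) {
    mass <- vapply(seq_len(n_sys), function(s) {
      sum(m[attract[system_of == s], j])
    }, numeric(1))
    best <- which(mass == max(mass))
    if (max(mass) <= eps) {
      # no flow towards any attractor: isolated singleton
      assign[j] <- NA_integer_
    } else {
      assign[j] <- best[order(heads[best])][1L]
    }
  }
  clusters <- lapply(seq_len(n_sys), function(s) {
    sort(nodes[which(assign == s)])
  })
  orphans <- which(is.na(assign))
  clusters <- c(clusters, lapply(orphans, function(j) nodes[j]))
  clusters[lengths(clusters) > 0]
}

new_cluster_set <- function(clusters, params, converged, iterations) {
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, `[`, character(1), 1L))
  clusters <- clusters[ord]
  structure(list(clusters = clusters, sizes = lengths(clusters),
                 retained = rep(NA, length(clusters)),
                 converged = converged, iterations = iterations,
                 params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d nodes (sizes %s)\n",
              length(x$clusters), sum(x$sizes),
              paste(utils::head(x$sizes, 10L), collapse = ", ")))
  if (!all(is.na(x$retained))) {
    cat(sprintf("retained: %d\n", sum(x$retained, na.rm = TRUE)))
  }
  invisible(x)
}

#' Flag clusters above a minimum size
#'
#' A cluster is retained iff its size strictly exceeds `min_size`; the
#' atlas analysis keeps clusters with more than 10 genes.
#'
#' @param cs a `cluster_set` from [mcl()].
#' @param min_size size threshold (default 10), strict.
#' @return The `cluster_set` with its `retained` flags set.
#' @export
filter_clusters <- function(cs, min_size = 10L) {
  stopifnot(inherits(cs, "cluster_set"))
  cs$retained <- cs$sizes > min_size
  cs$params$min_size <- min_size
  cs
}

#' Restrict a network to its retained MCL clusters
#'
#' The clustered network is the induced subgraph of the inferred network
#' on the union of retained-cluster nodes: every original edge between two
#' retained nodes is kept, including edges running between clusters.
#'
#' @param net the network the clusters were computed from.
#' @param cs a `cluster_set` with `retained` flags (see
#'   [filter_clusters()]).
#' @return An igraph network with provenance `"clustered"`.
#' @export
clustered_network <- function(net, cs) {
  stopifnot(inherits(cs, "cluster_set"))
  if (all(is.na(cs$retained))) {
    stop("run filter_clusters() before clustered_network()")
  }
  keep <- unique(unlist(cs$clusters[which(cs$retained)]))
  if (!length(keep)) stop("no retained clusters; clustered network empty")
  g <- igraph::induced_subgraph(net, keep)
  igraph::set_graph_attr(g, "provenance", "clustered")
}

#' Write cluster membership as TSV
#'
#' Columns `gene_id`, `cluster`, `cluster_size`, `retained`; clusters are
#' numbered in decreasing size order.
#'
#' @param cs a `cluster_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cs, path) {
  df <- data.frame(
    gene_id = unlist(cs$clusters),
    cluster = rep(seq_along(cs$clusters), cs$sizes),
    cluster_size = rep(cs$sizes, cs$sizes),
    retained = rep(cs$retained, cs$sizes),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
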