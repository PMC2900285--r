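# small in-code fixtures shared across test files

toy_expr <- function(values, tissues = NULL, scale = "log2") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(tissues)) {
    tissues <- rep(paste0("t", seq_len(max(2, ncol(values) %/% 2))),
                   length.out = ncol(values))
    tissues <- sort(tissues)
  }
  d <- sample_design(tissues)
  colnames(values) <- d$sample_id
  expression_matrix(values, d, scale = scale)
}

# four tissues x two replicates, n genes of pure noise
null_expr <- function(n_genes, sd = 1) {
  d <- mussel_design()
  v <- matrix(rnorm(n_genes * 8, sd = sd), nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              d$sample_id))
  expression_matrix(v, d, scale = "log2")
}

write_series_matrix_fixture <- function(path, ids, values, sample_ids) {
  header <- c("!Series_title\t\"toy two-channel series\"",
              "!Series_geo_accession\t\"GSE0000\"",
              paste(c("!Sample_title", sprintf("\"%s\"", sample_ids)),
                    collapse = "\t"))
  tab <- c(paste(c("ID_REF", sample_ids), collapse = "\t"),
           vapply(seq_along(ids), function(i) {
             paste(c(sprintf("\"%s\"", ids[i]),
                     format(values[i, ], trim = TRUE)), collapse = "\t")
           }, character(1)))
  writeLines(c(header, "!series_matrix_table_begin", tab,
               "!series_matrix_table_end"), path)
  path
}

# Erdos-Renyi-style random weighted graph for MCL cross-checks
random_weighted_graph <- function(n, p_edge = 0.25) {
  nodes <- sprintf("n%02d", seq_len(n))
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) {
        w <- runif(1, 0.5, 1)
        adj[i, j] <- w
        adj[j, i] <- w
      }
    }
  }
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE)
}
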