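make_clique_pair <- function() {
  nodes <- c(paste0("a", 1:5), paste0("b", 1:5))
  adj <- matrix(0, 10, 10, dimnames = list(nodes, nodes))
  adj[1:5, 1:5] <- 0.95
  adj[6:10, 6:10] <- 0.95
  diag(adj) <- 0
  graph_from_adj(adj)
}

test_that("disconnected cliques are returned as separate clusters", {
  cs <- mcl(make_clique_pair())
  expect_true(cs$converged)
  expect_identical(canon_partition(cs$clusters),
                   list(sort(paste0("a", 1:5)), sort(paste0("b", 1:5))))
})

test_that("a single self-looped node is one singleton cluster", {
  g <- igraph::make_graph(c("x", "x"), directed = FALSE)
  igraph::E(g)$weight <- 1
  cs <- mcl(g)
  expect_identical(cs$clusters, list("x"))
})

test_that("sparse MCL equals the independent dense implementation on random graphs", {
  set.seed(61)
  for (k in 1:20) {
    n <- sample(5:30, 1)
    adj <- random_weighted_graph(n, p_edge = runif(1, 0.15, 0.5))
    g <- graph_from_adj(adj)
    if (igraph::ecount(g) == 0) next
    inflation <- sample(c(2, 3, 4), 1)
    cs <- mcl(g, inflation = inflation)
    # the igraph vertex order may drop isolated nodes; restrict the
    # oracle adjacency to the graph's nodes in its own order
    keep <- igraph::V(g)$name
    oracle <- mcl_dense_oracle(adj[keep, keep, drop = FALSE], inflation)
    expect_identical(canon_partition(cs$clusters),
                     canon_partition(oracle),
                     info = sprintf("graph %d (n=%d, inflation=%g)",
                                    k, n, inflation))
  }
})

test_that("clustering is equivariant under node relabeling", {
  set.seed(62)
  adj <- random_weighted_graph(15, 0.3)
  g <- graph_from_adj(adj)
  cs <- mcl(g)
  perm <- sample(rownames(adj))
  adj2 <- adj[perm, perm]
  cs2 <- mcl(graph_from_adj(adj2))
  expect_identical(canon_partition(cs$clusters),
                   canon_partition(cs2$clusters))
})

test_that("MCL recovers noiseless planted modules exactly", {
  sim <- generate_dataset(synth_params(n_genes = 60, n_de_genes = 0,
                                       n_modules = 3, module_size = 8,
                                       module_corr = 1, noise_sd = 0,
                                       seed = 63))
  cc <- suppressMessages(pcc_matrix(sim$expr))
  net <- build_network(cc, 0.90)
  truth <- split(names(sim$truth$module_assignments),
                 sim$truth$module_assignments)
  # network components are the planted cliques
  comp <- igraph::components(net)
  expect_identical(canon_partition(split(names(comp$membership),
                                         comp$membership)),
                   canon_partition(truth))
  cs <- mcl(net)
  expect_identical(canon_partition(cs$clusters), canon_partition(truth))
})

test_that("cluster retention uses a strict size threshold", {
  clusters <- list(paste0("a", 1:3), paste0("b", 1:10), paste0("c", 1:11))
  cs <- structure(list(clusters = clusters, sizes = lengths(clusters),
                       retained = rep(NA, 3), converged = TRUE,
                       iterations = 1L, params = list()),
                  class = "cluster_set")
  cs <- filter_clusters(cs, min_size = 10)
  expect_identical(cs$retained, c(FALSE, FALSE, TRUE))
  cs1 <- filter_clusters(cs, min_size = 0)
  expect_true(all(cs1$retained))
  singletons <- structure(list(clusters = list("a", "b"), sizes = c(1L, 1L),
                               retained = c(NA, NA), converged = TRUE,
                               iterations = 1L, params = list()),
                          class = "cluster_set")
  expect_false(any(filter_clusters(singletons, 10)$retained))
})

test_that("planted modules above the size cutoff are all retained", {
  sim <- generate_dataset(synth_params(n_genes = 120, n_de_genes = 0,
                                       n_modules = 3, module_size = 15,
                                       module_corr = 0.98, noise_sd = 0.3,
                                       seed = 64))
  cc <- suppressMessages(pcc_matrix(sim$expr))
  net <- build_network(cc, 0.90)
  cs <- filter_clusters(mcl(net), 10)
  retained_nodes <- unlist(cs$clusters[cs$retained])
  truth <- split(names(sim$truth$module_assignments),
                 sim$truth$module_assignments)
  for (m in truth) {
    hit <- vapply(which(cs$retained),
                  function(i) length(intersect(cs$clusters[[i]],
                                               m)) >= 14,
                  logical(1))
    expect_true(any(hit))
  }
})

test_that("the clustered network is the induced subgraph on retained nodes", {
  # two retained clusters joined by one inter-cluster edge: the edge stays
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4), "z")
  adj <- matrix(0, 9, 9, dimnames = list(nodes, nodes))
  adj[1:4, 1:4] <- 0.95
  adj[5:8, 5:8] <- 0.95
  diag(adj) <- 0
  adj["a1", "b1"] <- adj["b1", "a1"] <- 0.91   # bridge
  adj["z", "a1"] <- adj["a1", "z"] <- 0.92     # hangs off a small cluster
  g <- graph_from_adj(adj)
  cs <- mcl(g)
  cs <- filter_clusters(cs, min_size = 3)
  cn <- clustered_network(g, cs)
  expect_true(igraph::are_adjacent(cn, "a1", "b1"))
  kept <- igraph::V(cn)$name
  expected_edges <- sum(adj[kept, kept][upper.tri(adj[kept, kept])] > 0)
  expect_identical(as.integer(igraph::ecount(cn)),
                   as.integer(expected_edges))
  # edges of the clustered network are a subset of the source network
  el <- igraph::as_edgelist(cn)
  for (i in seq_len(nrow(el))) {
    expect_true(igraph::are_adjacent(g, el[i, 1], el[i, 2]))
  }
})

test_that("one all-covering retained cluster reproduces the input network", {
  g <- make_clique_pair()
  cs <- structure(list(clusters = list(igraph::V(g)$name),
                       sizes = igraph::vcount(g), retained = NA,
                       converged = TRUE, iterations = 0L, params = list()),
                  class = "cluster_set")
  cs <- filter_clusters(cs, 1)
  cn <- clustered_network(g, cs)
  expect_identical(igraph::vcount(cn), igraph::vcount(g))
  expect_identical(igraph::ecount(cn), igraph::ecount(g))
  cs$retained <- FALSE
  expect_error(clustered_network(g, cs), "no retained")
})

test_that("cluster membership table covers each node exactly once", {
  set.seed(65)
  g <- graph_from_adj(random_weighted_graph(20, 0.3))
  cs <- filter_clusters(mcl(g), 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(cs, path)
  tab <- read.delim(path)
  expect_setequal(tab$gene_id, igraph::V(g)$name)
  expect_false(anyDuplicated(tab$gene_id) > 0)
})
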