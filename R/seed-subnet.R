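#' Extract the 1-hop neighborhood of seed genes
#'
#' Given seed clones (e.g. the heat shock protein clones of the mussel
#' atlas), returns the subnetwork on the seeds plus all their direct
#' co-expression neighbors: the induced subgraph of `net` on that node
#' set, so neighbor-neighbor edges are kept too.  Seeds absent from the
#' network are reported with a warning, never silently dropped; if no
#' seed is present the call errors listing them all.
#'
#' @param net an igraph co-expression network.
#' @param seeds character vector of seed gene ids.
#' @param order neighborhood hop depth (default 1).
#' @param provenance label for the subnetwork (default `"hsp"`).
#' @return An igraph network.
#' @export
seed_neighborhood <- function(net, seeds, order = 1L, provenance = "hsp") {
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, igraph::V(net)$name)
  absent <- setdiff(seeds, present)
  if (!length(present)) {
    stop("no seed present in network; missing: ",
         paste(absent, collapse = ", "))
  }
  if (length(absent)) {
    warning("seed(s) absent from network: ", paste(absent, collapse = ", "))
  }
  nb <- igraph::ego(net, order = order, nodes = present)
  nodes <- unique(c(present, unlist(lapply(nb, names))))
  if (length(nodes) == length(present) &&
      sum(igraph::degree(net, present)) == 0) {
    warning("seed(s) have no neighbors; returning seeds only")
  }
  g <- igraph::induced_subgraph(net, nodes)
  igraph::set_graph_attr(g, "provenance", provenance)
}

#' Rank a seed's direct neighbors
#'
#' Neighbors sorted by descending co-expression weight (or degree), ties
#' broken by gene id so the ordering is deterministic; used to report a
#' seed's closest co-expression partners.
#'
#' @param net an igraph network with `weight` edge attribute.
#' @param seed a single gene id present in `net`.
#' @param by `"weight"` (PCC of the seed-neighbor edge, default) or
#'   `"degree"` (the neighbor's degree in `net`).
#' @return A `data.frame` with columns `neighbor` and `weight` (or
#'   `degree`), in rank order.
#' @export
rank_neighbors <- function(net, seed, by = c("weight", "degree")) {
  by <- match.arg(by)
  if (!seed %in% igraph::V(net)$name) {
    stop("seed not in network: ", seed)
  }
  inc <- igraph::incident(net, seed)
  if (!length(inc)) {
    return(data.frame(neighbor = character(0),
                      value = numeric(0))[, c(1, 2)] |>
             stats::setNames(c("neighbor", by)))
  }
  ends <- igraph::ends(net, inc)
  neighbor <- ifelse(ends[, 1L] == seed, ends[, 2L], ends[, 1L])
  value <- switch(by,
                  weight = igraph::E(net)$weight[as.integer(inc)],
                  degree = as.numeric(igraph::degree(net, neighbor)))
  ord <- order(-value, neighbor)
  stats::setNames(data.frame(neighbor = neighbor[ord], value = value[ord],
                             stringsAsFactors = FALSE),
                  c("neighbor", by))
}

#' Overlap between a DE gene set and a network's nodes
#'
#' Exact integer intersection counts, used to report how many
#' differentially expressed genes survive into a derived network.
#'
#' @param de_set character vector of DE gene ids.
#' @param net an igraph network.
#' @return A list: `n_overlap`, `frac_of_de` (overlap / |de_set|),
#'   `frac_of_net` (overlap / network nodes).  Fractions are `NA` for
#'   empty denominators.
#' @export
de_overlap <- function(de_set, net) {
  de_set <- unique(as.character(de_set))
  nodes <- igraph::V(net)$name
  n <- length(intersect(de_set, nodes))
  list(n_overlap = n,
       frac_of_de = if (length(de_set)) n / length(de_set) else NA_real_,
       frac_of_net = if (length(nodes)) n / length(nodes) else NA_real_)
}

#' Read a seed table
#'
#' Two-column TSV mapping clone ids to gene labels (header `clone_id`,
#' `label`); how Hsp annotations enter real-data runs.
#'
#' @param path TSV path.
#' @return A `data.frame` with columns `clone_id`, `label`.
#' @export
read_seed_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("clone_id", "label") %in% colnames(tab))) {
    stop("seed table needs columns 'clone_id' and 'label'")
  }
  tab[, c("clone_id", "label")]
}
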