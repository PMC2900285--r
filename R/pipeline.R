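#' Configuration for a full pipeline run
#'
#' Bundles every tunable of the load -> normalize -> ANOVA -> correlation
#' network -> MCL -> seed subnetwork pipeline.  Defaults are the published
#' parameters of the mussel tissue-atlas analysis: DE filter at raw
#' p < 0.05, co-expression edges at PCC > 0.90, MCL inflation 3.0,
#' clusters kept above 10 genes.
#'
#' @param expr an [expression_matrix()], or `NULL` if `matrix_path` is
#'   given.
#' @param matrix_path TSV expression table (read with
#'   [read_expression_table()]) used when `expr` is `NULL`.
#' @param design a [sample_design()]; default [mussel_design()].
#' @param scale scale of the input values (`"ratio"` triggers
#'   [normalize_log2()]).
#' @param alpha ANOVA p-value cutoff.
#' @param pcc_threshold correlation cutoff for edges.
#' @param inflation MCL inflation.
#' @param min_cluster_size strict lower bound on retained cluster sizes.
#' @param seeds character vector of seed gene ids, a seed-table TSV path
#'   (see [read_seed_table()]), or `NULL` to skip the seed subnetwork.
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the input came from
#'   [generate_dataset()]).
#' @param reference_counts optional named numeric vector of external
#'   reference counts (e.g. published values) to diff against; names among
#'   `de_genes`, `inferred_nodes`, `inferred_edges`, `clustered_nodes`,
#'   `clustered_edges`, `hsp_nodes`, `hsp_edges`, `de_in_clustered`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr = NULL, matrix_path = NULL,
                            design = mussel_design(),
                            scale = c("log2", "ratio"),
                            alpha = 0.05, pcc_threshold = 0.90,
                            inflation = 3.0, min_cluster_size = 10L,
                            seeds = NULL, out_dir = tempfile("musselnet_"),
                            seed = 1L, reference_counts = NULL) {
  scale <- match.arg(scale)
  if (is.null(expr) && is.null(matrix_path)) {
    stop("provide either 'expr' or 'matrix_path'")
  }
  structure(list(expr = expr, matrix_path = matrix_path, design = design,
                 scale = scale, alpha = alpha,
                 pcc_threshold = pcc_threshold, inflation = inflation,
                 min_cluster_size = as.integer(min_cluster_size),
                 seeds = seeds, out_dir = out_dir, seed = as.integer(seed),
                 reference_counts = reference_counts),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `design`
#' may be given as a list with `tissues` and `replicates`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  design <- if (!is.null(y$design)) {
    sample_design(rep(y$design$tissues, each = y$design$replicates))
  } else {
    mussel_design()
  }
  pipeline_config(
    matrix_path = y$matrix_path, design = design,
    scale = y$scale %||% "log2",
    alpha = y$alpha %||% 0.05,
    pcc_threshold = y$pcc_threshold %||% 0.90,
    inflation = y$inflation %||% 3.0,
    min_cluster_size = y$min_cluster_size %||% 10L,
    seeds = y$seeds, out_dir = y$out_dir %||% tempfile("musselnet_"),
    seed = y$seed %||% 1L)
}

#' Run the full co-expression pipeline
#'
#' Executes load -> normalize -> per-gene ANOVA -> PCC network -> MCL ->
#' clustered network -> seed subnetwork -> overlap statistics, logging
#' gene/edge counts at every stage boundary so runs can be diffed against
#' published counts.  All outputs (TSV tables, edge lists, manifest JSON)
#' are written under `cfg$out_dir`; a failure at any stage aborts with
#' the stage name and removes partial outputs.  Reruns with the same
#' configuration produce byte-identical tables.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return The run manifest, invisibly: parameters, per-stage counts,
#'   network statistics rows, output paths, input checksums, and (when
#'   `reference_counts` was supplied) per-stage diffs.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(cfg$out_dir, name)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    stage <- "load"
    expr <- cfg$expr
    checksum <- NULL
    if (is.null(expr)) {
      expr <- read_expression_table(cfg$matrix_path, cfg$design,
                                    scale = cfg$scale)
      checksum <- unname(tools::md5sum(cfg$matrix_path))
    }
    say(sprintf("load: %d genes x %d samples (scale %s)",
                nrow(expr$values), ncol(expr$values), expr$scale))

    stage <- "normalize"
    if (expr$scale == "ratio") expr <- normalize_log2(expr)

    stage <- "differential_expression"
    de_res <- anova_per_gene(expr)
    de_set <- sort(filter_de(de_res, alpha = cfg$alpha))
    say(sprintf("ANOVA: %d / %d genes at p < %g", length(de_set),
                nrow(de_res), cfg$alpha))
    utils::write.table(de_res, out("de_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(de_set, out("de_genes.txt"))

    stage <- "correlation_network"
    cc <- pcc_matrix(expr)
    inferred <- build_network(cc, threshold = cfg$pcc_threshold)
    say(sprintf("inferred network: %d nodes, %d edges (PCC > %g)",
                igraph::vcount(inferred), igraph::ecount(inferred),
                cfg$pcc_threshold))
    write_edge_list(inferred, out("inferred_edges.tsv"))

    stage <- "mcl"
    cs <- mcl(inferred, inflation = cfg$inflation)
    cs <- filter_clusters(cs, min_size = cfg$min_cluster_size)
    say(sprintf("MCL: %d clusters, %d retained (> %d genes)",
                length(cs$clusters), sum(cs$retained),
                cfg$min_cluster_size))
    write_cluster_table(cs, out("clusters.tsv"))
    clustered <- clustered_network(inferred, cs)
    say(sprintf("clustered network: %d nodes, %d edges",
                igraph::vcount(clustered), igraph::ecount(clustered)))
    write_edge_list(clustered, out("clustered_edges.tsv"))

    stage <- "seed_subnetwork"
    hsp <- NULL
    seeds <- cfg$seeds
    if (is.character(seeds) && length(seeds) == 1L && file.exists(seeds)) {
      seeds <- read_seed_table(seeds)$clone_id
    }
    if (!is.null(seeds)) {
      hsp <- seed_neighborhood(clustered, seeds)
      say(sprintf("seed subnetwork: %d nodes, %d edges",
                  igraph::vcount(hsp), igraph::ecount(hsp)))
      write_edge_list(hsp, out("hsp_edges.tsv"))
    }

    stage <- "statistics"
    stats_tab <- network_stats(inferred, directed_convention = TRUE)
    stats_tab <- rbind(stats_tab,
                       network_stats(clustered, directed_convention = TRUE))
    if (!is.null(hsp)) {
      stats_tab <- rbind(stats_tab,
                         network_stats(hsp, directed_convention = TRUE))
    }
    utils::write.table(stats_tab, out("network_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ov <- de_overlap(de_set, clustered)

    counts <- c(de_genes = length(de_set),
                inferred_nodes = igraph::vcount(inferred),
                inferred_edges = igraph::ecount(inferred),
                clustered_nodes = igraph::vcount(clustered),
                clustered_edges = igraph::ecount(clustered),
                hsp_nodes = if (!is.null(hsp)) igraph::vcount(hsp) else NA,
                hsp_edges = if (!is.null(hsp)) igraph::ecount(hsp) else NA,
                de_in_clustered = ov$n_overlap)
    counts <- vapply(counts, as.integer, integer(1))

    diffs <- NULL
    if (!is.null(cfg$reference_counts)) {
      ref <- cfg$reference_counts
      common <- intersect(names(ref), names(counts))
      diffs <- data.frame(stage = common,
                          observed = unname(counts[common]),
                          reference = unname(ref[common]),
                          diff = unname(counts[common] - ref[common]),
                          stringsAsFactors = FALSE)
      utils::write.table(diffs, out("reference_diffs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      for (i in seq_len(nrow(diffs))) {
        say(sprintf("diff vs reference: %s observed %d, reference %d (%+d)",
                    diffs$stage[i], as.integer(diffs$observed[i]),
                    as.integer(diffs$reference[i]),
                    as.integer(diffs$diff[i])))
      }
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("musselnet")),
      parameters = list(alpha = cfg$alpha,
                        pcc_threshold = cfg$pcc_threshold,
                        inflation = cfg$inflation,
                        min_cluster_size = cfg$min_cluster_size,
                        scale = cfg$scale, seed = cfg$seed),
      input_checksum_md5 = checksum,
      counts = as.list(counts[!is.na(counts)]),
      de_overlap = ov,
      mcl = list(converged = cs$converged, iterations = cs$iterations),
      network_stats = stats_tab,
      reference_diffs = diffs,
      outputs = basename(written))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = on_fail)
}
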