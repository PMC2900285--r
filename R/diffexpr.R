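#' Per-gene one-way ANOVA across tissues
#'
#' Fits the standard fixed-effects one-way ANOVA to every gene's log2
#' profile, treating replicates as independent observations: F =
#' MS_between / MS_within with df_between = n_tissues - 1 and df_within =
#' n_samples - n_tissues.  The computation is vectorized over genes via
#' group sums of squares; it is numerically identical to fitting each gene
#' with `aov`/`oneway.test` but scales to thousands of genes.
#'
#' Conventions for degenerate genes: if the within-group sum of squares is
#' zero but the between-group one is positive, F is `Inf` and p is 0 (exact
#' separation); if both are zero (a flat gene) F and p are `NA` and the
#' gene can never enter the DE set.  A gene whose missing values leave some
#' tissue without observations also gets `NA`.
#'
#' @param x an `expression_matrix` on scale `"log2"` with >= 2 tissues.
#' @return A `data.frame` with one row per gene: `gene_id`, `F`, `p`,
#'   `df_between`, `df_within`, and one `mean_<tissue>` column per tissue.
#' @export
anova_per_gene <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale != "log2") {
    stop("ANOVA expects log2-scale data; run normalize_log2() first")
  }
  tissue <- factor(x$design$tissue, levels = unique(x$design$tissue))
  k <- nlevels(tissue)
  if (k < 2L) stop("need at least two tissues")
  v <- x$values
  obs <- !is.na(v)
  v0 <- v
  v0[!obs] <- 0

  # indicator matrix samples x tissues
  ind <- stats::model.matrix(~ tissue - 1)
  grp_n <- obs %*% ind                      # genes x tissues counts
  grp_sum <- v0 %*% ind
  n_tot <- rowSums(grp_n)
  grp_mean <- grp_sum / grp_n               # NaN where a tissue is empty
  grand_sum <- rowSums(grp_sum)
  grand_mean <- grand_sum / n_tot

  ss_total <- rowSums(v0^2 * obs) - n_tot * grand_mean^2
  ss_between <- rowSums(grp_sum^2 / grp_n) - n_tot * grand_mean^2
  ss_within <- ss_total - ss_between
  # guard tiny negatives from cancellation
  ss_between <- pmax(ss_between, 0)
  ss_within <- pmax(ss_within, 0)

  df_between <- k - 1L
  df_within <- n_tot - k
  defined <- rowSums(grp_n == 0) == 0 & df_within >= 1

  Fstat <- rep(NA_real_, nrow(v))
  pval <- rep(NA_real_, nrow(v))
  msb <- ss_between / df_between
  msw <- ss_within / df_within
  ok <- defined & msw > 0
  Fstat[ok] <- msb[ok] / msw[ok]
  pval[ok] <- stats::pf(Fstat[ok], df_between, df_within[ok],
                        lower.tail = FALSE)
  sep <- defined & msw == 0 & msb > 0       # exact separation
  Fstat[sep] <- Inf
  pval[sep] <- 0
  # both zero: flat gene, stays NA

  out <- data.frame(gene_id = rownames(v), F = Fstat, p = pval,
                    df_between = df_between, df_within = df_within,
                    stringsAsFactors = FALSE)
  colnames(grp_mean) <- paste0("mean_", levels(tissue))
  cbind(out, as.data.frame(grp_mean))
}

#' Select differentially expressed genes by p-value cutoff
#'
#' The study design filters at a raw per-gene p-value below `alpha` with no
#' multiple-testing correction; a Benjamini-Hochberg option is available
#' but off by default to match that convention.
#'
#' @param results output of [anova_per_gene()].
#' @param alpha significance cutoff in \[0, 1\]; default 0.05 (0 selects
#'   nothing, since the comparison is strict).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Character vector of DE gene ids (genes with defined p < alpha).
#' @export
filter_de <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must lie in [0, 1]")
  p <- results$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  results$gene_id[!is.na(p) & p < alpha]
}

#' Two-way unsupervised hierarchical clustering of a matrix
#'
#' Agglomerative clustering of genes (rows) and samples (columns) under
#' Euclidean distance, as used for DE-gene heatmaps.  Genes with any
#' missing value are dropped with a message (Euclidean distance is
#' undefined for them).
#'
#' @param x an `expression_matrix` (typically restricted to DE genes).
#' @param linkage agglomeration method passed to [stats::hclust()];
#'   default `"average"`.
#' @return A list: `gene_hclust`, `sample_hclust` (hclust trees),
#'   `gene_order`, `sample_order` (leaf orderings as labels).
#' @export
hierarchical_two_way <- function(x, linkage = "average") {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  drop <- rowSums(is.na(v)) > 0
  if (any(drop)) {
    message("dropping ", sum(drop), " gene(s) with missing values")
    v <- v[!drop, , drop = FALSE]
  }
  if (nrow(v) < 2L || ncol(v) < 2L) {
    stop("need at least two genes and two samples after filtering")
  }
  gh <- stats::hclust(stats::dist(v, method = "euclidean"), method = linkage)
  sh <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                      method = linkage)
  list(gene_hclust = gh, sample_hclust = sh,
       gene_order = rownames(v)[gh$order],
       sample_order = colnames(v)[sh$order])
}

#' Principal component analysis of the samples
#'
#' PCA of samples in gene space on gene-centered, unscaled log2 data; used
#' to confirm inter-replicate reproducibility and tissue separation.
#' Genes with missing values are dropped first.
#'
#' @param x an `expression_matrix`.
#' @param n_components number of leading components to return (default 3,
#'   capped at the matrix rank).
#' @return A list: `scores` (samples x components), `explained_variance`
#'   (proportion per returned component), `sdev` (all component standard
#'   deviations).
#' @export
pca_samples <- function(x, n_components = 3L) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  v <- v[rowSums(is.na(v)) == 0, , drop = FALSE]
  if (ncol(v) < 3L) stop("need at least three samples")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  if (k < n_components) {
    message("rank-deficient input: returning ", k, " component(s)")
  }
  var_all <- pc$sdev^2
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = var_all[seq_len(k)] / sum(var_all),
       sdev = pc$sdev)
}
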