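#' Parameters for the synthetic expression generator
#'
#' Defaults emulate the four-tissue, two-replicate mussel atlas: 3840 cDNA
#' clones over 8 arrays on the log2 ratio scale.  Planted structure comes in
#' two flavours: tissue-specific differentially expressed (DE) genes, whose
#' mean in one designated tissue is shifted by `de_effect` log2 units, and
#' co-expression modules, whose members share a latent tissue profile so
#' that the expected pairwise Pearson correlation within a module is
#' approximately `module_corr`.  Remaining genes are i.i.d. Gaussian noise.
#'
#' @param n_genes total number of genes (default 3840).
#' @param tissues tissue labels (default the four atlas tissues).
#' @param replicates replicates per tissue (default 2).
#' @param n_de_genes number of planted tissue-specific DE genes.
#' @param de_effect shift of the affected tissue's mean, log2 units.
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per module.
#' @param module_corr target expected within-module Pearson correlation,
#'   in (0, 1]; 1 means exact copies of the latent profile.
#' @param noise_sd standard deviation of gene-level Gaussian noise on the
#'   log2 scale (0 allowed: noiseless data for exact-recovery checks).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_genes = 3840L,
                         tissues = c("gills", "gonads", "foot",
                                     "digestive_gland"),
                         replicates = 2L,
                         n_de_genes = 400L,
                         de_effect = 2,
                         n_modules = 8L,
                         module_size = 15L,
                         module_corr = 0.95,
                         noise_sd = 0.5,
                         seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), tissues = as.character(tissues),
            replicates = as.integer(replicates),
            n_de_genes = as.integer(n_de_genes), de_effect = de_effect,
            n_modules = as.integer(n_modules),
            module_size = as.integer(module_size),
            module_corr = module_corr, noise_sd = noise_sd,
            seed = as.integer(seed))
  if (p$n_genes < 1L || p$replicates < 1L || length(p$tissues) < 1L) {
    stop("n_genes, replicates and tissues must be positive")
  }
  if (p$module_corr <= 0 || p$module_corr > 1) {
    stop("module_corr must lie in (0, 1]")
  }
  if (p$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (p$n_de_genes + p$n_modules * p$module_size > p$n_genes) {
    stop("infeasible parameters: n_de_genes + n_modules * module_size ",
         "exceeds n_genes")
  }
  class(p) <- "synth_params"
  p
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' Gene ids are `g0001`, `g0002`, ...; the first `n_de_genes` are the DE
#' genes, the next `n_modules * module_size` the module genes, the rest
#' background noise.  Module members are built as a shared latent
#' per-tissue profile (standard normal per tissue, replicated across
#' arrays; profiles of distinct modules are rejection-sampled to pairwise
#' |PCC| <= 0.85 so planted modules stay separable at a 0.90 edge
#' threshold) plus independent Gaussian gene noise whose variance is
#' calibrated so the expected within-module correlation equals
#' `module_corr`; with `module_corr = 1` members are exact copies of the
#' profile.  DE genes are noise plus a `de_effect` shift in one
#' round-robin-assigned tissue.
#'
#' @param params a [synth_params()] list.
#' @return A list with elements `expr` (an [expression_matrix()] on scale
#'   `"log2"`) and `truth`, itself a list: `de_gene_ids` (character),
#'   `tissue_of_effect` (named character, DE genes only),
#'   `module_assignments` (named integer, module genes only).
#' @examples
#' sim <- generate_dataset(synth_params(n_genes = 100, n_de_genes = 10,
#'                                      n_modules = 2, module_size = 5,
#'                                      seed = 7))
#' dim(sim$expr)
#' @export
generate_dataset <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  design <- sample_design(rep(p$tissues, each = p$replicates))
  n_samp <- nrow(design)
  ids <- sprintf("g%0*d", max(4L, nchar(p$n_genes)), seq_len(p$n_genes))

  values <- matrix(stats::rnorm(p$n_genes * n_samp, sd = p$noise_sd),
                   nrow = p$n_genes, ncol = n_samp,
                   dimnames = list(ids, design$sample_id))

  # planted tissue-specific DE genes: round-robin tissue assignment
  de_ids <- character(0)
  tissue_of_effect <- character(0)
  if (p$n_de_genes > 0L) {
    de_ids <- ids[seq_len(p$n_de_genes)]
    tissue_of_effect <- p$tissues[(seq_len(p$n_de_genes) - 1L) %%
                                    length(p$tissues) + 1L]
    names(tissue_of_effect) <- de_ids
    for (i in seq_len(p$n_de_genes)) {
      cols <- design$tissue == tissue_of_effect[i]
      values[i, cols] <- values[i, cols] + p$de_effect
    }
  }

  # planted co-expression modules: shared per-tissue latent profile
  module_assignments <- integer(0)
  if (p$n_modules > 0L && p$module_size > 0L) {
    first <- p$n_de_genes + 1L
    mod_ids <- ids[first:(first + p$n_modules * p$module_size - 1L)]
    module_assignments <- rep(seq_len(p$n_modules), each = p$module_size)
    names(module_assignments) <- mod_ids
    profiles <- list()
    for (m in seq_len(p$n_modules)) {
      # rejection-sample tissue profiles so distinct modules stay mutually
      # separable at a 0.90 correlation threshold (pairwise |PCC| <= 0.85);
      # with few tissues two random profiles can otherwise collide by chance
      for (try in seq_len(1000L)) {
        profile_t <- stats::rnorm(length(p$tissues))
        ok <- all(vapply(profiles, function(q) {
          abs(stats::cor(profile_t, q)) <= 0.85
        }, logical(1)))
        if (ok) break
      }
      profiles[[m]] <- profile_t
      profile <- profile_t[match(design$tissue, p$tissues)]
      # calibrate gene noise against the realized profile variance so the
      # expected within-module sample PCC tracks module_corr
      v_p <- stats::var(profile)
      if (v_p < 1e-12) v_p <- 1
      sigma_g <- sqrt(v_p * (1 - p$module_corr) / p$module_corr)
      members <- mod_ids[module_assignments == m]
      eps <- matrix(stats::rnorm(length(members) * n_samp, sd = sigma_g),
                    nrow = length(members))
      values[members, ] <- rep(profile, each = length(members)) + eps
    }
  }

  expr <- expression_matrix(values, design, scale = "log2")
  truth <- list(de_gene_ids = de_ids,
                tissue_of_effect = tissue_of_effect,
                module_assignments = module_assignments)
  list(expr = expr, truth = truth)
}

#' Write generator ground truth as TSV
#'
#' One row per gene carrying planted structure: columns `gene_id`, `role`
#' (`de` or `module`), `tissue_of_effect`, `module`.
#'
#' @param truth the `truth` element of [generate_dataset()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  de <- data.frame(gene_id = truth$de_gene_ids, role = "de",
                   tissue_of_effect = unname(truth$tissue_of_effect),
                   module = NA_integer_, stringsAsFactors = FALSE)
  mod <- data.frame(gene_id = names(truth$module_assignments),
                    role = "module", tissue_of_effect = NA_character_,
                    module = unname(truth$module_assignments),
                    stringsAsFactors = FALSE)
  utils::write.table(rbind(de, mod), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
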