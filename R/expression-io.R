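#' Sample design for a multi-tissue microarray experiment
#'
#' Describes which tissue and replicate each array column belongs to.  The
#' mussel tissue atlas this package was written around profiles four tissues
#' (gills, gonads, foot, digestive gland) with two biological replicates
#' each, but any k >= 1 replicates over >= 1 tissues are accepted.
#'
#' @param tissue character vector, one tissue label per sample.
#' @param replicate integer vector of replicate indices (>= 1), recycled
#'   within tissue if missing: samples of each tissue are numbered 1, 2, ...
#'   in order of appearance.
#' @param sample_id character vector of unique sample identifiers; default
#'   `"<tissue>_<replicate>"`.
#' @return A `data.frame` with columns `sample_id`, `tissue`, `replicate`,
#'   of class `sample_design`.
#' @examples
#' sample_design(rep(c("gills", "foot"), each = 2))
#' @export
sample_design <- function(tissue, replicate = NULL, sample_id = NULL) {
  tissue <- as.character(tissue)
  if (length(tissue) < 1L) stop("design needs at least one sample")
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(tissue), tissue, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  if (any(replicate < 1L)) stop("replicate indices must be >= 1")
  if (length(replicate) != length(tissue)) {
    stop("'tissue' and 'replicate' lengths differ")
  }
  if (is.null(sample_id)) sample_id <- paste(tissue, replicate, sep = "_")
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  out <- data.frame(sample_id = sample_id, tissue = tissue,
                    replicate = replicate, stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' Default design of the four-tissue mussel atlas
#'
#' Four tissues (gills, gonads, foot, digestive_gland), two replicates each:
#' eight samples in all.
#'
#' @param replicates replicates per tissue (default 2).
#' @return A [sample_design()] data frame with `4 * replicates` rows.
#' @export
mussel_design <- function(replicates = 2L) {
  tissues <- c("gills", "gonads", "foot", "digestive_gland")
  sample_design(rep(tissues, each = replicates))
}

#' Construct an expression matrix with its design
#'
#' The central data container: a genes x samples numeric matrix plus the
#' sample design and a scale flag (`"ratio"` for test/reference intensity
#' ratios, `"log2"` after [normalize_log2()]).  Missing values are `NA`,
#' never silent zeros.
#'
#' @param values numeric matrix, genes in rows.  Row names are gene ids
#'   (unique); column names must match `design$sample_id`.
#' @param design a [sample_design()].
#' @param scale `"ratio"` or `"log2"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `design`, `scale`.
#' @export
expression_matrix <- function(values, design, scale = c("ratio", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("'values' must have gene ids as row names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) stop("duplicated gene ids: ", paste(dup, collapse = ", "))
  if (ncol(values) != nrow(design)) {
    stop("matrix has ", ncol(values), " columns but design describes ",
         nrow(design), " samples")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- design$sample_id
  } else if (!all(design$sample_id %in% colnames(values))) {
    missing <- setdiff(design$sample_id, colnames(values))
    stop("samples in design missing from matrix: ",
         paste(missing, collapse = ", "))
  } else {
    values <- values[, design$sample_id, drop = FALSE]
  }
  structure(list(values = values, design = design, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (scale = %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("tissues: %s\n",
              paste(unique(x$design$tissue), collapse = ", ")))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("missing values: %d\n", n_na))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return Character vector of gene ids in row order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Read a genes x samples expression table from TSV
#'
#' Plain tab-separated dialect: first column gene id, header row of sample
#' ids; `NA`, `.` or empty cells are missing.  Non-numeric cells are flagged
#' missing with a warning rather than silently coerced.
#'
#' @param path TSV file path.
#' @param design a [sample_design()]; every `sample_id` must appear in the
#'   file header (extra file columns are dropped).
#' @param scale scale the file stores; default `"ratio"`.
#' @return An [expression_matrix()] with file row order preserved.
#' @export
read_expression_table <- function(path, design, scale = c("ratio", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ".", ""))
  if (ncol(tab) < 2L) stop("expected gene-id column plus sample columns")
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated gene ids: ", paste(dup, collapse = ", "))
  missing <- setdiff(design$sample_id, colnames(tab)[-1L])
  if (length(missing)) {
    stop("samples in design missing from file: ",
         paste(missing, collapse = ", "))
  }
  raw <- as.matrix(tab[, design$sample_id, drop = FALSE])
  suppressWarnings(values <- matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = list(ids, design$sample_id)))
  bad <- !is.na(raw) & is.na(values)
  if (any(bad)) {
    warning(sum(bad), " non-numeric cell(s) flagged missing")
  }
  expression_matrix(values, design, scale = scale)
}

#' Read the data table of a GEO series-matrix file
#'
#' Parses the `!series_matrix_table_begin` ... `!series_matrix_table_end`
#' block of a GEO series-matrix text file (the deposit format of expression
#' series such as GSE2176).  Values are taken as deposited; whether they are
#' intensity ratios or already log2 is declared by the caller via `scale`.
#'
#' @inheritParams read_expression_table
#' @export
read_series_matrix <- function(path, design, scale = c("ratio", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop("no series-matrix table block found in ", path)
  }
  block <- lines[(beg + 1L):(end - 1L)]
  tmp <- textConnection(block)
  on.exit(close(tmp))
  tab <- utils::read.delim(tmp, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", "null", ""), quote = "\"")
  # GEO quotes the ID_REF values
  ids <- gsub('^"|"$', "", tab[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated gene ids: ", paste(dup, collapse = ", "))
  missing <- setdiff(design$sample_id, colnames(tab)[-1L])
  if (length(missing)) {
    stop("samples in design missing from file: ",
         paste(missing, collapse = ", "))
  }
  raw <- as.matrix(tab[, design$sample_id, drop = FALSE])
  suppressWarnings(values <- matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = list(ids, design$sample_id)))
  expression_matrix(values, design, scale = scale)
}

#' Combine separate test/reference channel matrices into ratios
#'
#' For deposits storing the two channels separately per sample, the analysis
#' ratio is test signal / reference signal, elementwise.
#'
#' @param test,reference numeric matrices of identical dimension and
#'   dimnames (genes x samples).
#' @param design a [sample_design()].
#' @return An [expression_matrix()] on scale `"ratio"`.
#' @export
ratio_from_channels <- function(test, reference, design) {
  if (!identical(dim(test), dim(reference))) {
    stop("channel matrices differ in dimension")
  }
  if (!identical(rownames(test), rownames(reference))) {
    stop("channel matrices differ in gene order")
  }
  if (any(reference <= 0, na.rm = TRUE)) {
    stop("nonpositive reference signal; cannot form ratios")
  }
  expression_matrix(test / reference, design, scale = "ratio")
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: first column `gene_id`, one column
#' per sample, `NA` for missing.
#'
#' @param x an `expression_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  tab <- data.frame(gene_id = gene_ids(x), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform an intensity-ratio matrix
#'
#' The analysis scale throughout the pipeline is the binary logarithm of the
#' normalized test/reference intensity ratio.  Missing values stay missing;
#' nonpositive ratios are an error naming the offending gene and sample.
#'
#' @param raw an `expression_matrix` on scale `"ratio"` with all present
#'   values > 0.
#' @return The same matrix on scale `"log2"`.
#' @export
normalize_log2 <- function(raw) {
  stopifnot(inherits(raw, "expression_matrix"))
  if (raw$scale != "ratio") stop("input is already on scale '", raw$scale, "'")
  bad <- which(!is.na(raw$values) & raw$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("nonpositive ratio at gene ", rownames(raw$values)[bad[1, 1]],
         ", sample ", colnames(raw$values)[bad[1, 2]],
         if (nrow(bad) > 1) sprintf(" (and %d more)", nrow(bad) - 1L))
  }
  out <- raw
  out$values <- log2(raw$values)
  out$scale <- "log2"
  out
}
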