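#' Build a position weight matrix from base counts
#'
#' Counts per position are converted to frequencies with a pseudocount
#' spread by the background distribution, then to log2-odds scores
#' against that background:
#' `score(b, i) = log2( (count(b, i) + pseudocount * bg(b)) /
#' (N_i + pseudocount) / bg(b) )`.
#' A window's score is the sum over positions; consensus-matching windows
#' score highest.  The default pseudocount of 0.8 and uniform background
#' follow common JASPAR practice.
#'
#' @param counts 4 x W numeric matrix with rownames A, C, G, T.
#' @param name motif name.
#' @param pseudocount total pseudocount per position (default 0.8).
#' @param background named base frequencies summing to 1
#'   (default uniform).
#' @return A `pwm` object: list with `name`, `counts`, `log_odds`,
#'   `pseudocount`, `background`, `width`.
#' @export
pwm <- function(counts, name = "motif", pseudocount = 0.8,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  bases <- c("A", "C", "G", "T")
  if (!all(bases %in% rownames(counts))) {
    stop("counts must have rows A, C, G, T")
  }
  counts <- counts[bases, , drop = FALSE]
  if (ncol(counts) < 1L) stop("matrix width must be >= 1")
  if (any(counts < 0)) stop("negative counts")
  background <- background[bases]
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  totals <- colSums(counts)
  freq <- sweep(counts + pseudocount * background, 2L,
                totals + pseudocount, "/")
  lo <- log2(freq / background)
  if (any(!is.finite(lo))) stop("non-finite log-odds; increase pseudocount")
  structure(list(name = name, counts = counts, log_odds = lo,
                 pseudocount = pseudocount, background = background,
                 width = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, max score %.3f, consensus %s\n",
              x$name, x$width, max_score(x), consensus(x)))
  invisible(x)
}

#' Read a JASPAR-style count matrix
#'
#' Accepts the classic JASPAR flat format: a `>identifier name` header
#' followed by four rows, either bare numbers or the bracketed
#' `A  [ 4 19 0 ]` form, in A/C/G/T order (row labels honoured when
#' present).
#'
#' @param path file path.
#' @inheritParams pwm
#' @return A `pwm` object.
#' @export
read_jaspar <- function(path, pseudocount = 0.8,
                        background = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- "motif"
  if (startsWith(lines[1L], ">")) {
    name <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("expected four matrix rows")
  rows <- lapply(lines[1:4], function(l) {
    lab <- NA_character_
    if (grepl("^[ACGTacgt]\\b", l)) {
      lab <- toupper(substr(l, 1L, 1L))
      l <- sub("^[ACGTacgt]", "", l)
    }
    l <- gsub("\\[|\\]", " ", l)
    vals <- as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    list(label = lab, values = vals)
  })
  labs <- vapply(rows, `[[`, character(1), "label")
  if (all(!is.na(labs))) {
    ord <- match(c("A", "C", "G", "T"), labs)
    if (anyNA(ord)) stop("matrix rows must be labelled A, C, G, T")
    rows <- rows[ord]
  }
  w <- unique(lengths(lapply(rows, `[[`, "values")))
  if (length(w) != 1L) stop("matrix rows differ in width")
  counts <- do.call(rbind, lapply(rows, `[[`, "values"))
  rownames(counts) <- c("A", "C", "G", "T")
  pwm(counts, name = name, pseudocount = pseudocount,
      background = background)
}

#' Consensus sequence of a PWM
#' @param x a `pwm`.
#' @return Character string of the per-position best-scoring bases.
#' @export
consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(rownames(x$log_odds)[apply(x$log_odds, 2L, which.max)],
        collapse = "")
}

#' Maximum attainable PWM score
#' @param x a `pwm`.
#' @return The score of the consensus window.
#' @export
max_score <- function(x) {
  stopifnot(inherits(x, "pwm"))
  sum(apply(x$log_odds, 2L, max))
}

#' Reverse-complement a PWM
#' @param x a `pwm`.
#' @return The `pwm` scoring the reverse complement of the motif.
#' @export
reverse_complement_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  counts <- x$counts[c("T", "G", "C", "A"), rev(seq_len(x$width)),
                     drop = FALSE]
  rownames(counts) <- c("A", "C", "G", "T")
  pwm(counts, name = paste0(x$name, "_rc"), pseudocount = x$pseudocount,
      background = x$background)
}

#' Scan a sequence for PWM matches above a score cutoff
#'
#' Every window of motif width is scored on the plus strand and, when
#' `both_strands`, against the reverse-complemented motif; windows
#' scoring at or above `cutoff` are reported.  Minus-strand hits are
#' reported at plus-strand coordinates of the window.  Coordinates are
#' 0-based, half-open.  Windows containing bases outside A/C/G/T
#' (e.g. N) are skipped.
#'
#' @param seq a character string, `Biostrings::DNAString`, or a named
#'   single-element character vector; `seq_id` defaults to its name.
#' @param x a `pwm`.
#' @param cutoff minimum reported log2-odds score.
#' @param both_strands scan the minus strand too (default `TRUE`).
#' @param seq_id identifier used in the output.
#' @return A `data.frame`: `seq_id`, `start`, `end`, `strand`, `score`,
#'   `match` (plus-strand subsequence), sorted by position then strand.
#' @export
pwm_scan <- function(seq, x, cutoff, both_strands = TRUE,
                     seq_id = NULL) {
  stopifnot(inherits(x, "pwm"))
  if (is.null(seq_id)) {
    seq_id <- if (!is.null(names(seq))) names(seq)[1L] else "seq"
  }
  s <- toupper(as.character(seq)[1L])
  n <- nchar(s)
  w <- x$width
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), match = character(0),
                      stringsAsFactors = FALSE)
  if (w > n) {
    warning("motif wider than sequence; no windows to scan")
    return(empty)
  }
  chars <- strsplit(s, "")[[1L]]
  idx <- match(chars, c("A", "C", "G", "T"))       # NA for N etc.
  starts <- seq_len(n - w + 1L)
  offsets <- 0:(w - 1L)
  score_with <- function(lo) {
    vapply(starts, function(p) {
      b <- idx[p + offsets]
      if (anyNA(b)) return(NA_real_)
      sum(lo[cbind(b, seq_len(w))])
    }, numeric(1))
  }
  plus <- score_with(x$log_odds)
  hits <- data.frame(seq_id = seq_id, start = starts - 1L,
                     end = starts - 1L + w, strand = "+",
                     score = plus, stringsAsFactors = FALSE)
  if (both_strands) {
    minus <- score_with(reverse_complement_pwm(x)$log_odds)
    hits <- rbind(hits,
                  data.frame(seq_id = seq_id, start = starts - 1L,
                             end = starts - 1L + w, strand = "-",
                             score = minus, stringsAsFactors = FALSE))
  }
  hits <- hits[!is.na(hits$score) & hits$score >= cutoff, , drop = FALSE]
  hits$match <- substring(s, hits$start + 1L, hits$end)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan every record of a FASTA file
#'
#' @param path FASTA file.
#' @inheritParams pwm_scan
#' @return Row-bound [pwm_scan()] hits over all records.
#' @export
pwm_scan_fasta <- function(path, x, cutoff, both_strands = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  do.call(rbind, lapply(seq_along(seqs), function(i) {
    pwm_scan(as.character(seqs[[i]]), x, cutoff,
             both_strands = both_strands, seq_id = names(seqs)[i])
  }))
}

#' Write scan hits as BED6
#'
#' Scores are scaled to the BED 0-1000 range relative to the motif's
#' maximum attainable score (negative scores clamp to 0).
#'
#' @param hits output of [pwm_scan()].
#' @param x the `pwm` used for the scan.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, x, path) {
  ms <- max_score(x)
  score <- pmin(1000L, pmax(0L, as.integer(round(
    1000 * pmax(hits$score, 0) / max(ms, .Machine$double.eps)))))
  bed <- data.frame(hits$seq_id, hits$start, hits$end, x$name, score,
                    hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Optimal Smith-Waterman local alignment with affine gaps
#'
#' Finds the best-scoring local alignment of two DNA sequences under
#' `match`/`mismatch` substitution scores and affine gap penalties (a gap
#' of length L costs `gap_open + L * gap_extend`), and reports the
#' percent identity over alignment columns — the statistic used to call
#' sequence-element similarity (e.g. a LINE-like repeat 69% identical
#' over 181 aligned nucleotides).  The dynamic programming is delegated
#' to `Biostrings::pairwiseAlignment(type = "local")`.
#'
#' Aligning against the reverse complement of `b` is an explicit option,
#' never implicit.
#'
#' @param a,b DNA sequences (character or `DNAString`).
#' @param match match score (> 0); default 2.
#' @param mismatch mismatch score; default -1.
#' @param gap_open gap opening penalty (>= 0); default 5.
#' @param gap_extend per-base gap extension penalty (> 0); default 2.
#' @param revcomp_b align `a` against the reverse complement of `b`.
#' @return A list of class `local_alignment`: `score`, `a_aligned`,
#'   `b_aligned` (gapped strings), `a_start`, `a_end`, `b_start`,
#'   `b_end` (1-based inclusive on the input sequences), `matches`,
#'   `length` (alignment columns), `pident` (0-100).  All-mismatch
#'   inputs yield the empty alignment with score 0.
#' @export
local_align <- function(a, b, match = 2, mismatch = -1, gap_open = 5,
                        gap_extend = 2, revcomp_b = FALSE) {
  a <- Biostrings::DNAString(toupper(as.character(a)))
  b <- Biostrings::DNAString(toupper(as.character(b)))
  if (length(a) == 0L || length(b) == 0L) stop("empty sequence")
  if (revcomp_b) b <- Biostrings::reverseComplement(b)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  score <- Biostrings::score(aln)
  if (score <= 0) {
    return(structure(list(score = 0, a_aligned = "", b_aligned = "",
                          a_start = NA_integer_, a_end = NA_integer_,
                          b_start = NA_integer_, b_end = NA_integer_,
                          matches = 0L, length = 0L, pident = NA_real_),
                     class = "local_alignment"))
  }
  len <- Biostrings::nchar(aln)
  matches <- Biostrings::nmatch(aln)
  pat <- Biostrings::alignedPattern(aln)
  sub <- Biostrings::alignedSubject(aln)
  structure(list(
    score = score,
    a_aligned = as.character(pat[[1L]]),
    b_aligned = as.character(sub[[1L]]),
    a_start = Biostrings::start(Biostrings::pattern(aln)),
    a_end = Biostrings::end(Biostrings::pattern(aln)),
    b_start = Biostrings::start(Biostrings::subject(aln)),
    b_end = Biostrings::end(Biostrings::subject(aln)),
    matches = matches, length = len,
    pident = 100 * matches / len),
    class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  if (x$length == 0L) {
    cat("local_alignment: empty (score 0)\n")
  } else {
    cat(sprintf(
      "local_alignment: score %.1f, %d/%d identical (%.1f%%) over %d columns\n",
      x$score, x$matches, x$length, x$pident, x$length))
    cat(" a:", x$a_aligned, "\n b:", x$b_aligned, "\n")
  }
  invisible(x)
}
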