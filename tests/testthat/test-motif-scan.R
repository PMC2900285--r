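toy_pwm <- function() {
  counts <- matrix(c(8, 0, 1, 1,
                     0, 9, 0, 1,
                     1, 0, 8, 1,
                     0, 1, 0, 9), nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm(counts, name = "toy")
}

test_that("PWM construction validates inputs and yields finite log-odds", {
  p <- toy_pwm()
  expect_identical(p$width, 4L)
  expect_true(all(is.finite(p$log_odds)))
  expect_identical(consensus(p), "ACGT")
  bad <- matrix(1, 3, 2, dimnames = list(c("A", "C", "G"), NULL))
  expect_error(pwm(bad), "A, C, G, T")
  expect_error(pwm(toy_pwm()$counts, background = c(A = 1, C = 0, G = 0.2,
                                                    T = 0.2)),
               "sum to 1")
})

test_that("the consensus window scores the maximum and is found once", {
  p <- toy_pwm()
  hits <- pwm_scan("TTTACGTTTT", p, cutoff = max_score(p) - 1e-9,
                   both_strands = FALSE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 3L)
  expect_identical(hits$end, 7L)
  expect_identical(hits$match, "ACGT")
  expect_equal(hits$score, max_score(p), tolerance = 1e-12)
})

test_that("minus-strand hits mirror plus-strand hits of the reverse complement", {
  p <- toy_pwm()
  set.seed(81)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
             collapse = "")
  both <- pwm_scan(s, p, cutoff = 1)
  minus <- both[both$strand == "-", ]
  rc_hits <- pwm_scan(s, reverse_complement_pwm(p), cutoff = 1,
                      both_strands = FALSE)
  expect_identical(minus$start, rc_hits$start)
  expect_equal(minus$score, rc_hits$score, tolerance = 1e-12)
})

test_that("scan hits equal exhaustive per-window scoring on both strands", {
  p <- toy_pwm()
  set.seed(82)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 80, replace = TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
             collapse = "")
  cutoff <- -2
  hits <- pwm_scan(s, p, cutoff = cutoff)
  w <- p$width
  rc <- reverse_complement_pwm(p)
  expected <- list()
  for (start0 in 0:(nchar(s) - w)) {
    win <- substr(s, start0 + 1, start0 + w)
    for (strand in c("+", "-")) {
      lo <- if (strand == "+") p$log_odds else rc$log_odds
      sc <- pwm_window_score_oracle(win, lo)
      if (!is.na(sc) && sc >= cutoff) {
        expected[[length(expected) + 1]] <-
          data.frame(start = start0, strand = strand, score = sc)
      }
    }
  }
  expected <- do.call(rbind, expected)
  expected <- expected[order(expected$start, expected$strand), ]
  expect_identical(hits$start, expected$start)
  expect_identical(hits$strand, expected$strand)
  expect_equal(hits$score, expected$score, tolerance = 1e-12)
})

test_that("hit count is monotone non-increasing in the cutoff", {
  p <- toy_pwm()
  set.seed(83)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  cuts <- c(-5, -2, 0, 2, 4)
  n <- vapply(cuts, function(ct) nrow(pwm_scan(s, p, ct)), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("motifs wider than the sequence warn and return no hits", {
  p <- toy_pwm()
  expect_warning(hits <- pwm_scan("AC", p, cutoff = 0), "wider")
  expect_identical(nrow(hits), 0L)
})

test_that("JASPAR matrices parse in bracketed and bare forms", {
  bracketed <- withr::local_tempfile(lines = c(
    ">MA0106.1 TP53",
    "A  [ 2  0 10  1 ]",
    "C  [ 4 12  0  1 ]",
    "G  [ 5  0  1 11 ]",
    "T  [ 1  0  1  0 ]"))
  p <- read_jaspar(bracketed)
  expect_identical(p$name, "MA0106.1 TP53")
  expect_identical(p$width, 4L)
  expect_identical(unname(p$counts["C", 2]), 12)

  bare <- withr::local_tempfile(lines = c(">m", "1 2", "3 4", "5 6",
                                          "7 8"))
  p2 <- read_jaspar(bare)
  expect_identical(unname(p2$counts["T", 1]), 7)
})

test_that("BED output scales scores into 0-1000", {
  p <- toy_pwm()
  hits <- pwm_scan("TTTACGTTTT", p, cutoff = 0)
  path <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, p, path)
  bed <- read.delim(path, header = FALSE)
  expect_identical(ncol(bed), 6L)
  expect_true(all(bed$V5 >= 0 & bed$V5 <= 1000))
})

test_that("FASTA scanning reports per-record hits", {
  fa <- withr::local_tempfile(lines = c(">r1", "TTTACGTTTT",
                                        ">r2", "ACGTACGT"))
  hits <- pwm_scan_fasta(fa, toy_pwm(), cutoff = 4, both_strands = FALSE)
  expect_setequal(unique(hits$seq_id), c("r1", "r2"))
  expect_identical(sum(hits$seq_id == "r2"), 2L)
})

test_that("identical sequences align at 100% identity over full length", {
  s <- "ACGTGCTAGCTAGGATCCAGTTGCAACGTT"
  aln <- local_align(s, s)
  expect_equal(aln$pident, 100)
  expect_identical(aln$length, nchar(s))
  expect_identical(aln$matches, nchar(s))
  expect_equal(aln$score, 2 * nchar(s))
})

test_that("all-mismatch inputs give the empty alignment with score 0", {
  aln <- local_align("AAAAAA", "CCCCCC")
  expect_identical(aln$score, 0)
  expect_identical(aln$length, 0L)
  expect_true(is.na(aln$pident))
})

test_that("reverse-complement alignment is explicit, never implicit", {
  a <- "AAAAAAAAAACCCCCCCCCC"   # deliberately non-palindromic
  b_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  direct <- local_align(a, b_rc)
  flipped <- local_align(a, b_rc, revcomp_b = TRUE)
  expect_equal(flipped$pident, 100)
  expect_lt(direct$score, flipped$score)
})

test_that("alignment scores equal the independent Gotoh oracle on random 40-mers", {
  set.seed(84)
  for (k in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    aln <- local_align(a, b, match = 2, mismatch = -1, gap_open = 5,
                       gap_extend = 2)
    expect_equal(aln$score, sw_score_oracle(a, b), tolerance = 1e-9,
                 info = paste("pair", k))
    # score is symmetric in the sequence order
    expect_equal(local_align(b, a)$score, aln$score, tolerance = 1e-9)
  }
})

test_that("percent identity reflects planted divergence", {
  set.seed(85)
  base <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  mut <- base
  pos <- sample(100, 30)
  for (i in pos) {
    mut[i] <- sample(setdiff(c("A", "C", "G", "T"), base[i]), 1)
  }
  aln <- local_align(paste(base, collapse = ""),
                     paste(mut, collapse = ""))
  expect_lt(aln$pident, 100)
  expect_gt(aln$pident, 55)
  expect_true(aln$pident >= 0 && aln$pident <= 100)
})
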