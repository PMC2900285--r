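# Independent brute-force oracles, deliberately written with plain loops
# and base R so they share no code path with the package implementation.

# Pearson correlation from first principles over complete pairs
pcc_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# textbook one-way ANOVA F from group sums of squares
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  lev <- unique(groups)
  n <- length(values)
  k <- length(lev)
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in lev) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  list(F = f, p = p)
}

# dense from-first-principles MCL on base-R matrices: same update rules,
# fully separate code path from the package's sparse implementation
mcl_dense_oracle <- function(adj, inflation, expansion = 2,
                             prune = 1e-5, max_iter = 100, tol = 1e-6) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  # self loops: max incident weight (1 for isolated nodes)
  for (i in seq_len(n)) {
    m <- max(adj[i, ])
    adj[i, i] <- if (m > 0) m else 1
  }
  norm_cols <- function(m) {
    for (j in seq_len(n)) {
      s <- sum(m[, j])
      if (s == 0) {
        m[j, j] <- 1
        s <- 1
      }
      m[, j] <- m[, j] / s
    }
    m
  }
  m <- norm_cols(adj)
  for (it in seq_len(max_iter)) {
    m2 <- m
    for (e in seq_len(expansion - 1)) m2 <- m2 %*% m
    m2 <- m2^inflation
    m2 <- norm_cols(m2)
    m2[m2 < prune] <- 0
    m2 <- norm_cols(m2)
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) break
  }
  # attractors and attractor systems by hand (BFS on the symmetrized
  # nonzero structure restricted to attractor nodes)
  eps <- 1e-8
  attract <- which(diag(m) > eps)
  link <- (m[attract, attract, drop = FALSE] > eps)
  link <- link | t(link)
  sys <- rep(0L, length(attract))
  cur <- 0L
  for (s in seq_along(attract)) {
    if (sys[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    sys[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(link[v, ] & sys == 0L)
      sys[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  heads <- vapply(seq_len(cur), function(s) min(nodes[attract[sys == s]]),
                  character(1))
  assign <- rep(NA_integer_, n)
  assign[attract] <- sys
  for (j in setdiff(seq_len(n), attract)) {
    mass <- vapply(seq_len(cur),
                   function(s) sum(m[attract[sys == s], j]), numeric(1))
    if (max(mass) <= eps) next
    best <- which(mass == max(mass))
    assign[j] <- best[order(heads[best])][1]
  }
  parts <- lapply(seq_len(cur), function(s) sort(nodes[which(assign == s)]))
  orphans <- which(is.na(assign))
  c(parts, lapply(orphans, function(j) nodes[j]))
}

# canonical form of a partition for comparison
canon_partition <- function(clusters) {
  cl <- lapply(clusters, function(x) unname(sort(x)))
  unname(cl[order(vapply(cl, `[`, character(1), 1))])
}

# per-window PWM scoring, one window at a time
pwm_window_score_oracle <- function(window, log_odds) {
  chars <- strsplit(window, "")[[1]]
  total <- 0
  for (i in seq_along(chars)) {
    r <- match(chars[i], c("A", "C", "G", "T"))
    if (is.na(r)) return(NA_real_)
    total <- total + unname(log_odds[r, i])
  }
  total
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Smith-Waterman with affine gaps (Gotoh), score only; a gap of length L
# costs gap_open + L * gap_extend, matching the convention of local_align()
sw_score_oracle <- function(a, b, match = 2, mismatch = -1,
                            gap_open = 5, gap_extend = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in a (move along b)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in b (move along a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}
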