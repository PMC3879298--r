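# Independent brute-force oracles: explicit dictionaries and per-word loops,
# sharing no code with the package implementations.

naive_revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Dictionary k-mer counter: loops over every window of every read (and of its
# reverse complement), skipping windows that contain N.
naive_count <- function(reads, k, both_strands = TRUE) {
  seqs <- reads
  if (both_strands) seqs <- c(seqs, vapply(reads, naive_revcomp, ""))
  words <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in 1:(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (!grepl("N", w, fixed = TRUE)) words <- c(words, w)
    }
  }
  as.numeric(table(factor(words, levels = kmer_words(k))))
}

base_idx <- function(v) sum((match(v, c("A", "C", "G", "T")) - 1L) *
                              4^((length(v) - 1):0)) + 1L

# Chain-rule word probability evaluated per word from the model tables.
naive_word_prob <- function(m, word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  r <- m$order
  tr <- m$transitions
  tr[is.na(tr)] <- 0
  p <- if (r == 0) 1 else m$initial[base_idx(ch[1:r])]
  for (i in seq_len(length(ch) - r)) {
    ctx <- if (r == 0) 1L else base_idx(ch[i:(i + r - 1)])
    p <- p * tr[ctx, base_idx(ch[i + r])]
  }
  as.numeric(p)
}

# Naive per-word summations for the eight measures.
naive_d2 <- function(x, y) {
  num <- sx <- sy <- 0
  for (w in seq_along(x)) {
    num <- num + x[w] * y[w]
    sx <- sx + x[w]^2
    sy <- sy + y[w]^2
  }
  (1 - num / (sqrt(sx) * sqrt(sy))) / 2
}

naive_d2s <- function(xt, yt) {
  D <- A <- B <- 0
  for (w in seq_along(xt)) {
    if (xt[w] == 0 && yt[w] == 0) next
    r <- sqrt(xt[w]^2 + yt[w]^2)
    D <- D + xt[w] * yt[w] / r
    A <- A + xt[w]^2 / r
    B <- B + yt[w]^2 / r
  }
  (1 - D / sqrt(A * B)) / 2
}

naive_d2star <- function(xt, yt, ex, ey) {
  D <- A <- B <- 0
  for (w in seq_along(xt)) {
    if (ex[w] > 0 && ey[w] > 0) D <- D + xt[w] * yt[w] / sqrt(ex[w] * ey[w])
    if (ex[w] > 0) A <- A + xt[w]^2 / ex[w]
    if (ey[w] > 0) B <- B + yt[w]^2 / ey[w]
  }
  (1 - D / sqrt(A * B)) / 2
}

naive_lp <- function(fx, fy, variant) {
  acc <- 0
  for (w in seq_along(fx)) {
    d <- abs(fx[w] - fy[w])
    acc <- switch(variant,
                  manhattan = acc + d,
                  euclidean = acc + d^2,
                  chebyshev = max(acc, d))
  }
  if (variant == "euclidean") sqrt(acc) else acc
}

# Composition vector from frequencies of the three signature sizes.
naive_cvtree_comp <- function(reads, k) {
  fk <- naive_count(reads, k) / sum(naive_count(reads, k))
  f1 <- naive_count(reads, k - 1) / sum(naive_count(reads, k - 1))
  f2 <- naive_count(reads, k - 2) / sum(naive_count(reads, k - 2))
  wk <- kmer_words(k)
  a <- numeric(length(wk))
  for (i in seq_along(wk)) {
    w <- wk[i]
    pre <- f1[base_idx(strsplit(substr(w, 1, k - 1), "")[[1]])]
    suf <- f1[base_idx(strsplit(substr(w, 2, k), "")[[1]])]
    mid <- f2[base_idx(strsplit(substr(w, 2, k - 1), "")[[1]])]
    f0 <- if (mid > 0) pre * suf / mid else 0
    a[i] <- if (f0 > 0) (fk[i] - f0) / f0 else 0
  }
  a
}

naive_s2_half <- function(f, p, n) {
  acc <- 0
  for (w in seq_along(f)) {
    if (f[w] == 0) next
    pw <- if (p[w] > 0) p[w] else 1 / (10 * n)
    acc <- acc + f[w] * log(f[w] / pw)
  }
  acc
}

# Spearman via the explicit mid-rank Pearson formula.
naive_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
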