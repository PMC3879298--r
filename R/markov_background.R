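# Per-sample Markov background models (orders 0-3): word probabilities and
# expected counts used to center the d2S / d2* / S2 statistics, plus the
# CVTree (k-2)-order expected frequency.

#' Fit an order-r Markov background model to a read set
#'
#' The initial distribution is the observed r-tuple frequency vector and each
#' transition row is the observed distribution of the next base given the
#' preceding r-tuple (estimated from (r+1)-tuple counts).  By default counts
#' come from both strands, matching [count_ktuples()], so model expectations
#' share the signature's reverse-complement symmetry.  Contexts never
#' observed are marked `NA`; a word probability that would need such a
#' context is 0 and is floored downstream (see [expected_counts()]).
#'
#' @param rs A [read_set()].
#' @param order Markov order r, an integer 0-3.
#' @param both_strands Estimate from both strands (default `TRUE`).
#' @return An object of class `markov_model` with fields `sample_id`,
#'   `order`, `initial` (length `4^r`, sums to 1), `transitions`
#'   (`4^r x 4` matrix, observed rows sum to 1) and `source_counts`.
#' @export
fit_markov <- function(rs, order, both_strands = TRUE) {
  stopifnot(inherits(rs, "read_set"))
  r <- as.integer(order)
  if (r < 0 || r > 3) {
    stop_metasig("Markov order must be an integer in 0..3", "metasig_parameter_error")
  }
  ext_sig <- tryCatch(count_ktuples(rs, r + 1L, both_strands = both_strands),
    metasig_degenerate_sample_error = function(e) {
      stop_metasig(sprintf("sample '%s' has no (r+1) = %d-tuple; cannot fit order-%d model",
                           rs$sample_id, r + 1L, r), "metasig_degenerate_sample_error")
    })
  ctx_sig <- if (r > 0) count_ktuples(rs, r, both_strands = both_strands) else NULL
  markov_from_signatures(ext_sig, ctx_sig)
}

#' Assemble a Markov model from precomputed signatures
#'
#' Builds the order-(k-1) model whose transition rows come from the
#' (r+1)-tuple signature and whose initial distribution comes from the
#' r-tuple signature, so models can be constructed from reused count files
#' without re-reading the sequence data.  [fit_markov()] is this applied to
#' freshly counted signatures.
#'
#' @param sig_ext Signature at `r + 1` (defines the order `r`).
#' @param sig_ctx Signature at `r` from the same reads (required for
#'   `r >= 1`).
#' @return A `markov_model`.
#' @export
markov_from_signatures <- function(sig_ext, sig_ctx = NULL) {
  r <- sig_ext$k - 1L
  ext <- matrix(sig_ext$counts, ncol = 4L, byrow = TRUE)  # rows: r-tuple context
  ctx_tot <- rowSums(ext)
  transitions <- ext / ifelse(ctx_tot > 0, ctx_tot, NA_real_)
  if (r == 0) {
    initial <- 1
    ctx_counts <- sum(ext)
  } else {
    if (is.null(sig_ctx) || sig_ctx$k != r) {
      stop_metasig("order >= 1 needs the r-tuple context signature",
                   "metasig_parameter_error")
    }
    ctx_counts <- sig_ctx$counts
    initial <- ctx_counts / sum(ctx_counts)
  }
  structure(
    list(sample_id = sig_ext$sample_id, order = r, initial = initial,
         transitions = transitions,
         source_counts = list(context = ctx_counts, extended = sig_ext$counts)),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> sample '%s': order %d, %d/%d contexts observed\n",
              x$sample_id, x$order, sum(!is.na(x$transitions[, 1])),
              nrow(x$transitions)))
  invisible(x)
}

check_model_k <- function(m, k) {
  if (k < m$order + 1) {
    stop_metasig(sprintf(
      "order-%d centering is undefined for k = %d (needs k >= r+1); combination is NA",
      m$order, k), "metasig_na_error")
  }
}

#' Markov probabilities of all 4^k words
#'
#' Chain factorisation `p(w) = p(w1..wr) * prod p(w_{i+r} | w_i..w_{i+r-1})`,
#' evaluated for every word at once in lexicographic index order.  When every
#' context was observed the probabilities sum to 1.
#'
#' @param m A [fit_markov()] model.
#' @param k Word size, must satisfy `k >= order + 1`.
#' @return Numeric vector of length `4^k` (unobserved-context words get 0).
#' @export
word_probabilities <- function(m, k) {
  stopifnot(inherits(m, "markov_model"))
  k <- as.integer(k)
  check_model_k(m, k)
  check_k_cap(k)
  r <- m$order
  tr <- m$transitions
  tr[is.na(tr)] <- 0
  p <- as.numeric(m$initial)       # length 4^r (scalar 1 for r = 0)
  for (j in seq_len(k - r) + r - 1L) {   # current word length j, extend to j+1
    ctx <- if (r == 0) rep(1L, 4^j) else (seq_len(4^j) - 1L) %% 4^r + 1L
    p <- rep(p, each = 4L) * as.vector(t(tr)[, ctx, drop = FALSE])
  }
  p
}

#' Markov probability of single words
#'
#' @param m A [fit_markov()] model.
#' @param word Character vector of k-tuples over `{A,C,G,T}` (all of one
#'   length `k >= order + 1`).
#' @return Numeric vector of probabilities `p_w`.
#' @export
word_probability <- function(m, word) {
  stopifnot(inherits(m, "markov_model"))
  k <- unique(nchar(word))
  if (length(k) != 1) {
    stop_metasig("all words must have the same length", "metasig_parameter_error")
  }
  check_model_k(m, k)
  if (any(grepl("[^ACGT]", word))) {
    stop_metasig("words must be over {A,C,G,T}", "metasig_alphabet_error")
  }
  r <- m$order
  tr <- m$transitions
  tr[is.na(tr)] <- 0
  vapply(strsplit(word, "", fixed = TRUE), function(ch) {
    b <- match(ch, DNA_BASES) - 1L
    p <- if (r == 0) 1 else {
      m$initial[sum(b[seq_len(r)] * 4^((r - 1):0)) + 1L]
    }
    for (i in seq_len(k - r)) {
      ctx <- if (r == 0) 1L else sum(b[i:(i + r - 1L)] * 4^((r - 1):0)) + 1L
      p <- p * tr[ctx, b[i + r] + 1L]
    }
    as.numeric(p)
  }, numeric(1))
}

# Floor rule: a word with positive observed count but zero model probability
# gets p = 1/(10 n) so that expectation-standardised statistics stay finite.
floor_probabilities <- function(p, observed, n) {
  bad <- observed > 0 & p <= 0
  if (any(bad)) {
    p[bad] <- 1 / (10 * n)
    warning(sprintf("%d word(s) with positive count had zero model probability; floored at 1/(10n)",
                    sum(bad)), call. = FALSE)
  }
  p
}

#' Expected k-tuple counts under a background model
#'
#' Elementwise `n * p_w`.  If `observed` counts are supplied, zero
#' probabilities at words with positive observed count are floored at
#' `1/(10 n)` so downstream standardisations stay finite.
#'
#' @param m A [fit_markov()] model.
#' @param k Word size (`k >= order + 1`).
#' @param n Total tuple count of the signature being centered.
#' @param observed Optional observed count vector (length `4^k`) that
#'   triggers the zero-probability floor.
#' @return Numeric vector of length `4^k` summing to `n` (up to unobserved
#'   contexts).
#' @export
expected_counts <- function(m, k, n, observed = NULL) {
  if (n <= 0) stop_metasig("n must be positive", "metasig_parameter_error")
  p <- word_probabilities(m, k)
  if (!is.null(observed)) p <- floor_probabilities(p, observed, n)
  n * p
}

#' CVTree expected frequency under the (k-2)-order chain
#'
#' `f0(w) = f(w1..w_{k-1}) * f(w2..w_k) / f(w2..w_{k-1})`, each `f` being the
#' relative frequency from its own signature; 0 by convention when the middle
#' (k-2)-word frequency is 0.  This is the maximal-order background used by
#' the composition-vector (CVTree) measure, hence it needs `k >= 3`.
#'
#' @param sig_k,sig_km1,sig_km2 Signatures at k, k-1 and k-2 built from the
#'   same read set.
#' @param words Optional character vector of k-words; default all `4^k`.
#' @return Numeric vector of expected frequencies.
#' @export
cvtree_expected_frequency <- function(sig_k, sig_km1, sig_km2, words = NULL) {
  k <- sig_k$k
  if (k < 3) {
    stop_metasig("the (k-2)-order expectation needs k >= 3; combination is NA",
                 "metasig_na_error")
  }
  stopifnot(sig_km1$k == k - 1L, sig_km2$k == k - 2L)
  f1 <- to_frequencies(sig_km1)
  f2 <- to_frequencies(sig_km2)
  idx <- if (is.null(words)) 0:(4^k - 1) else word_index(words)
  prefix <- idx %/% 4L
  suffix <- idx %% 4^(k - 1)
  middle <- suffix %/% 4L
  denom <- f2[middle + 1]
  out <- ifelse(denom > 0, f1[prefix + 1] * f1[suffix + 1] / denom, 0)
  as.numeric(out)
}

#' Write / read a word-probability file
#'
#' Text format with headers `#sample=`, `#k=`, `#markov_order=` and
#' `WORD<TAB>PROBABILITY` rows (nonzero words, lexicographic order), so
#' probability files can be reused like count files.
#'
#' @param m A [fit_markov()] model.
#' @param k Word size to tabulate.
#' @param path File path.
#' @return `write_probabilities`: `path` invisibly; `read_probabilities`: a
#'   list with `sample_id`, `k`, `order` and the dense `probabilities`
#'   vector.
#' @export
write_probabilities <- function(m, k, path) {
  p <- word_probabilities(m, k)
  nz <- which(p > 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#sample=%s", m$sample_id),
    sprintf("#k=%d", as.integer(k)),
    sprintf("#markov_order=%d", m$order),
    sprintf("%s\t%.17g", kmer_words(k)[nz], p[nz])
  ), con)
  invisible(path)
}

#' @rdname write_probabilities
#' @export
read_probabilities <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_field <- function(key) {
    row <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (length(row) != 1) {
      stop_metasig(sprintf("probability file %s lacks header '#%s='", path, key),
                   "metasig_format_error")
    }
    sub(sprintf("^#%s=", key), "", row)
  }
  k <- as.integer(get_field("k"))
  parts <- strsplit(body, "\t", fixed = TRUE)
  words <- vapply(parts, `[[`, "", 1L)
  if (any(nchar(words) != k)) {
    stop_metasig(sprintf("word length inconsistent with k=%d in %s", k, path),
                 "metasig_format_error")
  }
  p <- numeric(4^k)
  p[word_index(words) + 1] <- as.numeric(vapply(parts, `[[`, "", 2L))
  list(sample_id = get_field("sample"), k = k,
       order = as.integer(get_field("markov_order")), probabilities = p)
}
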