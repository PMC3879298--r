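# Internal helpers: seed scoping, word indexing, error classes.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic stream of repetition seeds derived from a master seed, so any
# single repetition can be re-run in isolation.  Kept below 2^31 - 1.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(2147483646L, n))
}

stop_metasig <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "metasig_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

DNA_BASES <- c("A", "C", "G", "T")

#' All k-tuples over {A,C,G,T} in lexicographic order
#'
#' Lexicographic with A < C < G < T and the leftmost base most significant;
#' this is the index order used by every count and probability vector in the
#' package (and by [Biostrings::oligonucleotideFrequency()]).
#'
#' @param k Tuple size (positive integer).
#' @return Character vector of length `4^k`.
#' @export
#' @examples
#' kmer_words(2)[1:5]
kmer_words <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  Biostrings::mkAllStrings(DNA_BASES, k)
}

# 0-based lexicographic index of each word in `words` (A=0, C=1, G=2, T=3,
# leftmost most significant).  Words containing other letters map to NA.
word_index <- function(words) {
  k <- nchar(words[1L])
  mat <- matrix(match(unlist(strsplit(words, "", fixed = TRUE)), DNA_BASES) - 1L,
                nrow = k)
  idx <- as.numeric(4^((k - 1L):0) %*% mat)
  idx
}

check_k_cap <- function(k, allow_large = FALSE) {
  if (k > 12 && !allow_large) {
    stop_metasig(sprintf(
      "k = %d would need a 4^%d-entry vector (~%.1f GB); pass allow_large = TRUE to override",
      k, k, 8 * 4^k / 1e9), "metasig_parameter_error")
  }
  invisible(k)
}
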