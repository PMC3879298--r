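# k-tuple sequence signatures: 4^k count vectors over both strands.

#' Reverse complement of nucleotide sequences
#'
#' Vectorised over a character vector; `N` is its own complement.  Applying
#' the operation twice returns the input.
#'
#' @param seq Character vector over the alphabet `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) {
    stop_metasig("sequences must be over {A,C,G,T,N}", "metasig_alphabet_error")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Build the k-tuple signature of a read set
#'
#' Counts every length-`k` window of every read *and of its reverse
#' complement* (the strand of an unaligned read is unknown, so both strands
#' contribute).  Windows containing `N` match no word and are skipped.  The
#' resulting vector of length `4^k` is indexed lexicographically
#' (A < C < G < T, leftmost base most significant, see [kmer_words()]).
#'
#' @param rs A [read_set()].
#' @param k Tuple size (1-12 by default; the memory cost is `8 * 4^k` bytes).
#' @param both_strands Count the reverse complement as well (default `TRUE`).
#' @param allow_large Permit `k > 12`.
#' @return An object of class `ktuple_signature` with fields `sample_id`,
#'   `k`, `counts` (numeric, length `4^k`), `n` (total count) and
#'   `complement_included`.
#' @export
#' @examples
#' sig <- count_ktuples(read_set("ACGT", "toy"), k = 2)
#' setNames(sig$counts, kmer_words(2))[sig$counts > 0]
count_ktuples <- function(rs, k, both_strands = TRUE, allow_large = FALSE) {
  stopifnot(inherits(rs, "read_set"), k >= 1)
  k <- as.integer(k)
  check_k_cap(k, allow_large)
  if (max(nchar(rs$reads)) < k) {
    stop_metasig(sprintf("no read of length >= k = %d in sample '%s'",
                         k, rs$sample_id), "metasig_degenerate_sample_error")
  }
  # Joining reads on "N" and counting the single string is equivalent to
  # counting per read (windows containing N match no word, which removes
  # exactly the cross-read windows) and is much faster for many short reads.
  joined <- Biostrings::DNAString(paste(rs$reads, collapse = "N"))
  counts <- as.numeric(Biostrings::oligonucleotideFrequency(joined, width = k))
  if (both_strands) {
    counts <- counts + as.numeric(Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(joined), width = k))
  }
  n <- sum(counts)
  if (n == 0) {
    stop_metasig(sprintf(
      "all k = %d windows in sample '%s' contain N; no tuple counted",
      k, rs$sample_id), "metasig_degenerate_sample_error")
  }
  new_signature(rs$sample_id, k, counts, both_strands)
}

new_signature <- function(sample_id, k, counts, both_strands) {
  structure(
    list(sample_id = sample_id, k = as.integer(k), counts = counts,
         n = sum(counts), complement_included = isTRUE(both_strands)),
    class = "ktuple_signature"
  )
}

#' @export
print.ktuple_signature <- function(x, ...) {
  cat(sprintf("<ktuple_signature> sample '%s': k = %d, n = %.0f, %d/%d words observed%s\n",
              x$sample_id, x$k, x$n, sum(x$counts > 0), length(x$counts),
              if (x$complement_included) ", both strands" else ""))
  invisible(x)
}

#' Relative k-tuple frequencies of a signature
#'
#' @param sig A [count_ktuples()] signature with `n > 0`.
#' @return Numeric vector `counts / n`, summing to 1.
#' @export
to_frequencies <- function(sig) {
  stopifnot(inherits(sig, "ktuple_signature"))
  if (sig$n <= 0) {
    stop_metasig("signature has zero total count", "metasig_degenerate_sample_error")
  }
  sig$counts / sig$n
}

#' Write / read a signature file
#'
#' Plain-text format with header lines `#sample=`, `#k=`, `#n=`,
#' `#complement=`, `#order=lexicographic_ACGT`, followed by
#' `WORD<TAB>COUNT` rows for the nonzero words in lexicographic order, so
#' count files can be reused across runs without recounting reads.
#'
#' @param sig A `ktuple_signature`.
#' @param path File path.
#' @return `write_signature`: `path` invisibly; `read_signature`: the
#'   reconstructed `ktuple_signature` (zeros restored for unlisted words).
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "ktuple_signature"))
  nz <- which(sig$counts > 0)
  words <- kmer_words(sig$k)[nz]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#sample=%s", sig$sample_id),
    sprintf("#k=%d", sig$k),
    sprintf("#n=%.0f", sig$n),
    sprintf("#complement=%s",
            if (sig$complement_included) "both_strands" else "single_strand"),
    "#order=lexicographic_ACGT",
    sprintf("%s\t%.0f", words, sig$counts[nz])
  ), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_field <- function(key) {
    row <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (length(row) != 1) {
      stop_metasig(sprintf("signature file %s lacks header '#%s='", path, key),
                   "metasig_format_error")
    }
    sub(sprintf("^#%s=", key), "", row)
  }
  k <- as.integer(get_field("k"))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop_metasig(sprintf("malformed WORD\\tCOUNT row in %s", path),
                 "metasig_format_error")
  }
  words <- vapply(parts, `[[`, "", 1L)
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (any(nchar(words) != k) || any(grepl("[^ACGT]", words))) {
    stop_metasig(sprintf(
      "word(s) inconsistent with header k=%d in %s", k, path),
      "metasig_format_error")
  }
  counts <- numeric(4^k)
  counts[word_index(words) + 1] <- vals
  sig <- new_signature(get_field("sample"), k, counts,
                       get_field("complement") == "both_strands")
  n_hdr <- as.numeric(get_field("n"))
  if (abs(n_hdr - sig$n) > 0.5) {
    stop_metasig(sprintf("header n=%.0f disagrees with summed counts %.0f in %s",
                         n_hdr, sig$n, path), "metasig_format_error")
  }
  sig
}
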