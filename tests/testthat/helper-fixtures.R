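# Programmatic fixtures shared across test files.

random_read_set <- function(n_reads, len, seed, id = paste0("s", seed),
                            probs = c(0.25, 0.25, 0.25, 0.25), with_n = FALSE) {
  metasig:::with_seed(seed, {
    alphabet <- c("A", "C", "G", "T")
    p <- probs
    if (with_n) {
      alphabet <- c(alphabet, "N")
      p <- c(probs * 0.95, 0.05)
    }
    chars <- sample(alphabet, n_reads * len, replace = TRUE, prob = p)
    reads <- apply(matrix(chars, n_reads, len), 1, paste, collapse = "")
    read_set(reads, id)
  })
}

# Read set with an order-0 source of random base composition (uniform on the
# simplex), the configuration used for the range-bound checks.
dirichlet_read_set <- function(n_reads, len, seed, id = paste0("d", seed)) {
  metasig:::with_seed(seed, {
    probs <- stats::rgamma(4, 1)
    probs <- probs / sum(probs)
    chars <- sample(c("A", "C", "G", "T"), n_reads * len, replace = TRUE,
                    prob = probs)
    read_set(apply(matrix(chars, n_reads, len), 1, paste, collapse = ""), id)
  })
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
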