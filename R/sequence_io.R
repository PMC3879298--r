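# Reading, writing and subsampling read sets.

#' Construct a read set
#'
#' A `read_set` is a named collection of nucleotide reads from one sample.
#' Sequences are upper-cased and any character outside `{A,C,G,T,N}` is
#' replaced by `N` (with a warning reporting how many characters were mapped),
#' so one canonical alphabet flows through the whole pipeline.
#'
#' @param reads Character vector of nucleotide sequences (non-empty strings).
#' @param sample_id Text label for the sample.
#' @param provenance Named list of free-text metadata (source file, sampling
#'   rate, seed, ...).
#' @return An object of class `read_set` with fields `sample_id`, `reads`
#'   and `provenance`.
#' @export
#' @examples
#' rs <- read_set(c("acgt", "TTTT"), "toy")
#' rs$reads
read_set <- function(reads, sample_id, provenance = list()) {
  if (length(reads) == 0) {
    stop_metasig("read set is empty", "metasig_empty_input_error")
  }
  reads <- toupper(as.character(reads))
  if (any(!nzchar(reads))) {
    stop_metasig("read set contains empty sequences", "metasig_empty_input_error")
  }
  n_bad <- sum(nchar(reads)) - sum(nchar(gsub("[^ACGTN]", "", reads)))
  if (n_bad > 0) {
    reads <- gsub("[^ACGTN]", "N", reads)
    warning(sprintf("%d non-ACGTN character(s) mapped to N in sample '%s'",
                    n_bad, sample_id), call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), reads = reads,
         provenance = provenance),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> sample '%s': %d reads, %.0f bases (lengths %d-%d)\n",
              x$sample_id, length(x$reads), sum(nchar(x$reads)),
              min(nchar(x$reads)), max(nchar(x$reads))))
  invisible(x)
}

#' Total base count of a read set
#' @param rs A [read_set()].
#' @return Sum of read lengths.
#' @export
n_bases <- function(rs) sum(nchar(rs$reads))

infer_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("fa", "fasta", "fna")) return("fasta")
  if (ext %in% c("fq", "fastq")) return("fastq")
  stop_metasig(sprintf("cannot infer sequence format from suffix '.%s' (%s)",
                       ext, path), "metasig_format_error")
}

#' Read a FASTA or FASTQ file into a read set
#'
#' Records are returned in file order; sequences are upper-cased and
#' non-ACGTN characters are mapped to `N` with a warning.  With
#' `format = "auto"` the format is inferred from the file suffix
#' (`.fa`/`.fasta`/`.fna` for FASTA, `.fq`/`.fastq` for FASTQ).
#'
#' @param path Path to the sequence file.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.
#' @param sample_id Sample label; defaults to the file name without suffix.
#' @return A [read_set()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_metasig(sprintf("file not found: %s", path), "metasig_io_error")
  }
  if (format == "auto") format <- infer_format(path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) {
      stop_metasig(sprintf("failed to parse %s as %s: %s",
                           path, format, conditionMessage(e)),
                   "metasig_format_error")
    }
  )
  if (length(seqs) == 0) {
    stop_metasig(sprintf("no sequence records in %s", path),
                 "metasig_empty_input_error")
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  rs <- read_set(as.character(seqs), sample_id,
                 provenance = list(source = path, format = format))
  names(rs$reads) <- names(seqs)
  rs
}

#' Write a read set to FASTA or FASTQ
#'
#' FASTQ output carries placeholder qualities (`I`, Sanger offset 33) because
#' the pipeline never uses quality scores.  Round-trips with
#' [read_sequences()]: reads and their order are preserved.
#'
#' @param rs A [read_set()].
#' @param path Output path.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(rs, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- infer_format(path)
  if (length(rs$reads) == 0) {
    stop_metasig("refusing to write an empty read set", "metasig_empty_input_error")
  }
  seqs <- Biostrings::DNAStringSet(rs$reads)
  ids <- names(rs$reads)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- sprintf("%s_read%d", rs$sample_id, seq_along(rs$reads))
  }
  names(seqs) <- ids
  ok <- tryCatch({
    if (format == "fasta") {
      Biostrings::writeXStringSet(seqs, path, format = "fasta")
    } else {
      quals <- Biostrings::BStringSet(strrep("I", nchar(rs$reads)))
      Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
    }
    TRUE
  }, error = function(e) {
    stop_metasig(sprintf("failed to write %s: %s", path, conditionMessage(e)),
                 "metasig_io_error")
  })
  invisible(path)
}

#' Subsample a read set without replacement
#'
#' Draws `round(rate * N)` reads uniformly without replacement (emulating a
#' reduced sequencing depth), deterministically for a fixed seed.  The
#' retained reads keep their original file order.
#'
#' @param rs A [read_set()].
#' @param rate Sampling fraction in (0, 1].
#' @param seed Integer seed making the draw reproducible.
#' @return A [read_set()] whose provenance records `rate` and `seed`.
#' @export
subsample_reads <- function(rs, rate, seed) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0 || rate > 1) {
    stop_metasig("rate must be a single number in (0, 1]", "metasig_parameter_error")
  }
  n <- length(rs$reads)
  m <- round(rate * n)
  if (m == 0) {
    stop_metasig(sprintf(
      "subsample of %d reads at rate %g is empty; raise the rate", n, rate),
      "metasig_degenerate_sample_error")
  }
  keep <- if (m == n) seq_len(n) else sort(with_seed(seed, sample.int(n, m)))
  out <- rs
  out$reads <- rs$reads[keep]
  out$provenance <- modifyList(rs$provenance,
                               list(subsample_rate = rate, subsample_seed = seed))
  out
}
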