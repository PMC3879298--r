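# End-to-end orchestration: count -> probabilities -> dissimilarity ->
# cluster / ordinate -> evaluate, with on-disk artifact reuse.

#' Build a validated pipeline configuration
#'
#' @param inputs Either a list of [read_set()] objects or a character
#'   vector of FASTA/FASTQ paths.
#' @param out_dir Output directory (created if missing).
#' @param measures Subset of `"d2"`, `"d2s"`, `"d2star"`, `"ma"`, `"eu"`,
#'   `"ch"`, `"hao"`, `"s2"`.
#' @param k Tuple sizes to run (each in 2-12).
#' @param orders Markov orders to run (each in 0-3; ignored by measures
#'   without a background model).
#' @param seed Master seed for any randomised step.
#' @param reference_tree Optional `phylo`, Newick string or Newick file
#'   path; when given, every clustering is scored against it.
#' @param covariate Optional numeric vector (sample order) or two-column
#'   `sample<TAB>value` file; when given, PCoA GOF and |SRCC| are reported.
#' @param both_strands Count both strands (default `TRUE`).
#' @param s2_cross Cross pairing for S2 (see [s2()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs, out_dir, measures = "d2s", k = 6,
                            orders = 0, seed = 1, reference_tree = NULL,
                            covariate = NULL, both_strands = TRUE,
                            s2_cross = TRUE) {
  measures <- vapply(measures, match.arg, "", choices = MEASURES)
  if (any(k < 2 | k > 12)) {
    stop_metasig("tuple sizes must lie in 2..12", "metasig_config_error")
  }
  if (any(orders < 0 | orders > 3)) {
    stop_metasig("Markov orders must lie in 0..3", "metasig_config_error")
  }
  if (is.character(inputs)) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) {
      stop_metasig(paste("input file(s) not found:", paste(missing, collapse = ", ")),
                   "metasig_config_error")
    }
  } else if (!all(vapply(inputs, inherits, TRUE, "read_set"))) {
    stop_metasig("inputs must be file paths or read_set objects",
                 "metasig_config_error")
  }
  structure(list(inputs = inputs, out_dir = out_dir,
                 measures = unname(measures), k = as.integer(k),
                 orders = as.integer(orders), seed = seed,
                 reference_tree = reference_tree, covariate = covariate,
                 both_strands = both_strands, s2_cross = s2_cross),
            class = "pipeline_config")
}

load_reference_tree <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "phylo")) return(x)
  if (file.exists(x)) return(from_newick(paste(readLines(x), collapse = "")))
  from_newick(x)
}

load_covariate <- function(x, labels) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) {
    if (length(x) != length(labels)) {
      stop_metasig("covariate length must match the number of samples",
                   "metasig_config_error")
    }
    return(x)
  }
  tab <- utils::read.table(x, header = FALSE, sep = "\t",
                           col.names = c("sample", "value"))
  val <- setNames(tab$value, tab$sample)[labels]
  if (anyNA(val)) {
    stop_metasig("covariate file is missing some sample ids",
                 "metasig_config_error")
  }
  unname(val)
}

# Internal: dissimilarity matrix from per-sample artifacts prepared by the
# pipeline cache (signatures at the needed k values and word-probability
# vectors), mirroring pairwise_matrix().
combo_matrix <- function(samples, measure, k, order, get_sig, get_probs,
                         s2_cross = TRUE) {
  labels <- unname(vapply(samples, function(s) s$sample_id, ""))
  ns <- length(samples)
  mat <- matrix(0, ns, ns, dimnames = list(labels, labels))
  if (!is_valid_combination(measure, k, order)) {
    mat[] <- NA_real_
    return(new_dissim_matrix(mat, measure, k, order, valid = FALSE))
  }
  sigs <- lapply(labels, get_sig, k = k)
  art <- switch(
    measure,
    d2 = sigs,
    ma = , eu = , ch = lapply(sigs, to_frequencies),
    d2s = , d2star = lapply(seq_len(ns), function(i) {
      p <- floor_probabilities(get_probs(labels[i], k, order),
                               sigs[[i]]$counts, sigs[[i]]$n)
      ex <- sigs[[i]]$n * p
      structure(list(sample_id = labels[i], k = k, order = order,
                     centered = sigs[[i]]$counts - ex, expectations = ex,
                     n = sigs[[i]]$n),
                class = "centered_signature")
    }),
    hao = lapply(seq_len(ns), function(i) {
      cvtree_composition(sigs[[i]], get_sig(labels[i], k - 1L),
                         get_sig(labels[i], k - 2L))
    }),
    s2 = lapply(seq_len(ns), function(i) {
      list(f = to_frequencies(sigs[[i]]), n = sigs[[i]]$n,
           p = get_probs(labels[i], k, order))
    }))
  pair_fun <- switch(
    measure,
    d2 = function(a, b) d2(a, b),
    d2s = function(a, b) d2s(a, b),
    d2star = function(a, b) d2star(a, b),
    ma = function(a, b) lp_distance(a, b, "manhattan"),
    eu = function(a, b) lp_distance(a, b, "euclidean"),
    ch = function(a, b) lp_distance(a, b, "chebyshev"),
    hao = function(a, b) cos_dissim(a, b),
    s2 = function(a, b) {
      if (s2_cross) rel_entropy(a$f, b$p, b$n) + rel_entropy(b$f, a$p, a$n)
      else rel_entropy(a$f, a$p, a$n) + rel_entropy(b$f, b$p, b$n)
    })
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      mat[i, j] <- mat[j, i] <- pair_fun(art[[i]], art[[j]])
    }
  }
  new_dissim_matrix(mat, measure, k, order, valid = TRUE)
}

#' Run the full analysis pipeline
#'
#' For every requested (measure, k, order) combination: builds (or reuses
#' from `out_dir`) signature and word-probability files, writes the
#' dissimilarity matrix and the UPGMA tree, and, when configured, the
#' symmetric-difference score against a reference tree and the PCoA
#' GOF/|SRCC| gradient report.  Signature and probability files already on
#' disk are read back instead of recomputed (a cache hit is logged with
#' `message()`), so reruns are cheap and any combination can be added
#' later.  An invalid combination yields an `NA` matrix and never aborts
#' the others.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `manifest` (data frame of artifacts), `scores`
#'   (symmetric differences, if a reference tree was given), `gradient`
#'   (GOF/|SRCC| rows, if a covariate was given) and `matrices` (the
#'   `dissim_matrix` objects, named `measure.k<k>.m<order>`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (d in file.path(cfg$out_dir, c("signatures", "matrices", "trees", "reports"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  samples <- if (is.character(cfg$inputs)) {
    lapply(cfg$inputs, read_sequences)
  } else cfg$inputs
  labels <- vapply(samples, function(s) s$sample_id, "")
  if (anyDuplicated(labels)) {
    stop_metasig("duplicate sample ids in inputs", "metasig_label_error")
  }
  names(samples) <- labels
  reference <- load_reference_tree(cfg$reference_tree)
  covariate <- load_covariate(cfg$covariate, labels)

  sig_mem <- new.env(parent = emptyenv())
  get_sig <- function(id, k) {
    key <- sprintf("%s|%d", id, k)
    if (!is.null(sig_mem[[key]])) return(sig_mem[[key]])
    path <- file.path(cfg$out_dir, "signatures", sprintf("%s.k%d.cnt", id, k))
    sig <- if (file.exists(path)) {
      message("cache hit: ", path)
      read_signature(path)
    } else {
      s <- count_ktuples(samples[[id]], k, both_strands = cfg$both_strands)
      write_signature(s, path)
      s
    }
    sig_mem[[key]] <- sig
    sig
  }
  prob_mem <- new.env(parent = emptyenv())
  get_probs <- function(id, k, order) {
    key <- sprintf("%s|%d|%d", id, k, order)
    if (!is.null(prob_mem[[key]])) return(prob_mem[[key]])
    path <- file.path(cfg$out_dir, "signatures",
                      sprintf("%s.k%d.m%d.prob", id, k, order))
    p <- if (file.exists(path)) {
      message("cache hit: ", path)
      read_probabilities(path)$probabilities
    } else {
      m <- markov_from_signatures(get_sig(id, order + 1L),
                                  if (order > 0) get_sig(id, order))
      write_probabilities(m, k, path)
      word_probabilities(m, k)
    }
    prob_mem[[key]] <- p
    p
  }

  uses_order <- function(measure) measure %in% c("d2s", "d2star", "s2")
  combos <- unique(do.call(rbind, lapply(cfg$measures, function(me) {
    if (uses_order(me)) {
      expand.grid(measure = me, k = cfg$k, order = cfg$orders,
                  stringsAsFactors = FALSE)
    } else {
      expand.grid(measure = me, k = cfg$k, order = 0L, stringsAsFactors = FALSE)
    }
  })))

  manifest <- list()
  scores <- list()
  gradient <- list()
  matrices <- list()
  for (i in seq_len(nrow(combos))) {
    me <- combos$measure[i]
    k <- combos$k[i]
    ord <- combos$order[i]
    tag <- if (uses_order(me)) sprintf("%s.k%d.m%d", me, k, ord)
           else sprintf("%s.k%d", me, k)
    res <- tryCatch({
      dm <- combo_matrix(samples, me, k, ord, get_sig, get_probs, cfg$s2_cross)
      mpath <- file.path(cfg$out_dir, "matrices", paste0(tag, ".tsv"))
      write_dissimilarity(dm, mpath)
      manifest[[length(manifest) + 1]] <- data.frame(
        type = "matrix", measure = me, k = k, order = ord,
        valid = attr(dm, "valid"), path = mpath)
      matrices[[tag]] <- dm
      if (attr(dm, "valid")) {
        tree <- upgma(dm)
        tpath <- file.path(cfg$out_dir, "trees", paste0(tag, ".nwk"))
        writeLines(to_newick(tree), tpath)
        manifest[[length(manifest) + 1]] <- data.frame(
          type = "tree", measure = me, k = k, order = ord,
          valid = TRUE, path = tpath)
        if (!is.null(reference)) {
          scores[[length(scores) + 1]] <- data.frame(
            measure = me, k = k, order = ord,
            symmetric_difference = symmetric_difference(reference, tree))
        }
        if (!is.null(covariate)) {
          gr <- gradient_report(dm, covariate)
          gradient[[length(gradient) + 1]] <- data.frame(
            measure = me, k = k, order = ord, gof = gr$gof, srcc = gr$srcc)
        }
      }
      TRUE
    }, metasig_error = function(e) {
      warning(sprintf("combination %s failed: %s", tag, conditionMessage(e)),
              call. = FALSE)
      manifest[[length(manifest) + 1]] <- data.frame(
        type = "failed", measure = me, k = k, order = ord,
        valid = FALSE, path = NA_character_)
      FALSE
    })
  }
  scores_df <- if (length(scores)) do.call(rbind, scores) else NULL
  gradient_df <- if (length(gradient)) do.call(rbind, gradient) else NULL
  if (!is.null(scores_df)) {
    utils::write.table(scores_df,
                       file.path(cfg$out_dir, "reports", "treedist.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(gradient_df)) {
    utils::write.table(gradient_df,
                       file.path(cfg$out_dir, "reports", "gradient.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(manifest = do.call(rbind, manifest), scores = scores_df,
       gradient = gradient_df, matrices = matrices)
}

#' Subsampling experiment against a reference tree
#'
#' For each sampling rate and repetition, subsamples every read set,
#' recomputes the dissimilarity matrix and UPGMA tree per measure, and
#' scores the tree against the reference; reports the mean symmetric
#' difference per (measure, rate).  Repetition seeds are derived
#' deterministically from the master seed, so any repetition can be re-run
#' in isolation; repetitions whose subsample is too shallow to count any
#' tuple are recorded as missing.
#'
#' @param samples List of [read_set()] objects.
#' @param reference Reference `phylo` tree (or Newick string/path).
#' @param rates Sampling rates in (0, 1].
#' @param reps Repetitions per rate.
#' @param measures Measures to evaluate.
#' @param k Tuple size.
#' @param order Markov order for model-based measures.
#' @param seed Master seed.
#' @param mode Symmetric-difference mode, see [symmetric_difference()].
#' @param both_strands Count both strands.
#' @return Data frame with columns `measure`, `rate`, `mean_symdiff`,
#'   `n_reps_ok`.
#' @export
subsample_experiment <- function(samples, reference, rates, reps,
                                 measures = "d2s", k = 6, order = 0, seed = 1,
                                 mode = "clusters", both_strands = TRUE) {
  reference <- load_reference_tree(reference)
  out <- list()
  for (rate in rates) {
    rep_seeds <- derive_seeds(seed, reps)
    score_mat <- matrix(NA_real_, reps, length(measures),
                        dimnames = list(NULL, measures))
    for (rep_i in seq_len(reps)) {
      sub <- tryCatch({
        ss <- derive_seeds(rep_seeds[rep_i], length(samples))
        lapply(seq_along(samples), function(j) {
          subsample_reads(samples[[j]], rate, seed = ss[j])
        })
      }, metasig_degenerate_sample_error = function(e) NULL)
      if (is.null(sub)) next
      for (me in measures) {
        score_mat[rep_i, me] <- tryCatch({
          dm <- pairwise_matrix(sub, me, k, order, both_strands = both_strands)
          symmetric_difference(reference, upgma(dm), mode = mode)
        }, metasig_error = function(e) NA_real_)
      }
    }
    out[[length(out) + 1]] <- data.frame(
      measure = measures, rate = rate,
      mean_symdiff = colMeans(score_mat, na.rm = TRUE),
      n_reps_ok = colSums(!is.na(score_mat)), row.names = NULL)
  }
  do.call(rbind, out)
}
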