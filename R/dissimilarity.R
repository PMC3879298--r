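# The eight dissimilarity measures between k-tuple signatures, and labelled
# pairwise matrices over sample panels.

MEASURES <- c("d2", "d2s", "d2star", "ma", "eu", "ch", "hao", "s2")

# (1 - cosine)/2 with a tiny-negative clamp from floating-point roundoff.
cos_dissim <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop_metasig("zero-norm vector in cosine-type dissimilarity",
                 "metasig_degenerate_sample_error")
  }
  val <- (1 - sum(x * y) / (nx * ny)) / 2
  max(val, 0)
}

sig_counts <- function(x) {
  if (inherits(x, "ktuple_signature")) x$counts else as.numeric(x)
}

#' Center a signature under a Markov background model
#'
#' Produces the centralised counts `X~_w = X_w - n * p_w` used by the d2S and
#' d2* statistics, with the zero-probability floor applied to the
#' expectations (see [expected_counts()]).
#'
#' @param sig A [count_ktuples()] signature.
#' @param model A [fit_markov()] model of the same sample (`k >= order + 1`).
#' @return An object of class `centered_signature` with fields `sample_id`,
#'   `k`, `order`, `centered`, `expectations`, `n`.
#' @export
center_signature <- function(sig, model) {
  stopifnot(inherits(sig, "ktuple_signature"), inherits(model, "markov_model"))
  ex <- expected_counts(model, sig$k, sig$n, observed = sig$counts)
  structure(
    list(sample_id = sig$sample_id, k = sig$k, order = model$order,
         centered = sig$counts - ex, expectations = ex, n = sig$n),
    class = "centered_signature"
  )
}

#' The d2 dissimilarity (uncentered)
#'
#' `(1 - cos(X, Y)) / 2` on the raw k-tuple count vectors; ranges over
#' `[0, 0.5]` because counts are nonnegative, and is 0 iff the vectors are
#' proportional.
#'
#' @param sigX,sigY Signatures at the same `k` (or plain numeric count
#'   vectors of equal length).
#' @return Dissimilarity in `[0, 0.5]`.
#' @export
d2 <- function(sigX, sigY) {
  x <- sig_counts(sigX)
  y <- sig_counts(sigY)
  if (length(x) != length(y)) {
    stop_metasig("signatures have different k", "metasig_shape_error")
  }
  cos_dissim(x, y)
}

#' The d2S dissimilarity (self-standardised, centered)
#'
#' With centralised counts `X~, Y~`, computes
#' `D = sum X~ Y~ / sqrt(X~^2 + Y~^2)`, `A = sum X~^2 / sqrt(X~^2 + Y~^2)`,
#' `B = sum Y~^2 / sqrt(X~^2 + Y~^2)` (words with `X~ = Y~ = 0` are 0/0 terms
#' and are skipped) and returns `(1 - D / sqrt(A B)) / 2`, which lies in
#' `[0, 1]`.
#'
#' @param csX,csY [center_signature()] results at the same `k` and order (or
#'   plain numeric centered vectors).
#' @return Dissimilarity in `[0, 1]`.
#' @export
d2s <- function(csX, csY) {
  x <- if (inherits(csX, "centered_signature")) csX$centered else as.numeric(csX)
  y <- if (inherits(csY, "centered_signature")) csY$centered else as.numeric(csY)
  if (length(x) != length(y)) {
    stop_metasig("centered signatures have different k", "metasig_shape_error")
  }
  keep <- !(x == 0 & y == 0)
  x <- x[keep]
  y <- y[keep]
  r <- sqrt(x^2 + y^2)
  a <- sum(x^2 / r)
  b <- sum(y^2 / r)
  if (a == 0 || b == 0) {
    stop_metasig("all-zero centered vector in d2s", "metasig_degenerate_sample_error")
  }
  val <- (1 - sum(x * y / r) / sqrt(a * b)) / 2
  max(val, 0)
}

#' The d2* dissimilarity (expectation-standardised, centered)
#'
#' With centralised counts and expectations `E = n p_w`, computes
#' `D* = sum X~ Y~ / sqrt(E_X E_Y)`, `A* = sum X~^2 / E_X`,
#' `B* = sum Y~^2 / E_Y` and returns `(1 - D* / sqrt(A* B*)) / 2`; the
#' Cauchy-Schwarz inequality keeps the value in `[0, 1]`.
#'
#' @param csX,csY [center_signature()] results at the same `k` and order.
#' @return Dissimilarity in `[0, 1]`.
#' @export
d2star <- function(csX, csY) {
  if (length(csX$centered) != length(csY$centered)) {
    stop_metasig("centered signatures have different k", "metasig_shape_error")
  }
  ex <- csX$expectations
  ey <- csY$expectations
  x <- csX$centered
  y <- csY$centered
  # a word with zero expectation has zero observed count (the floor rule
  # guarantees it), so its centered value is 0 and the term vanishes
  okx <- ex > 0
  oky <- ey > 0
  both <- okx & oky
  dstar <- sum(x[both] * y[both] / sqrt(ex[both] * ey[both]))
  astar <- sum(x[okx]^2 / ex[okx])
  bstar <- sum(y[oky]^2 / ey[oky])
  if (astar == 0 || bstar == 0) {
    stop_metasig("all-zero centered vector in d2star", "metasig_degenerate_sample_error")
  }
  val <- (1 - dstar / sqrt(astar * bstar)) / 2
  max(val, 0)
}

#' L-type distances between frequency vectors
#'
#' Manhattan `sum |x - y|`, Euclidean `sqrt(sum (x - y)^2)` and Chebyshev
#' `max |x - y|` on relative k-tuple frequency vectors (frequencies rather
#' than raw counts, so samples of very different depth are comparable).
#'
#' @param freqX,freqY Frequency vectors of equal length (see
#'   [to_frequencies()]), or signatures which are converted.
#' @param variant One of `"manhattan"`, `"euclidean"`, `"chebyshev"`.
#' @return Nonnegative distance.
#' @export
lp_distance <- function(freqX, freqY, variant = c("manhattan", "euclidean", "chebyshev")) {
  variant <- match.arg(variant)
  x <- if (inherits(freqX, "ktuple_signature")) to_frequencies(freqX) else as.numeric(freqX)
  y <- if (inherits(freqY, "ktuple_signature")) to_frequencies(freqY) else as.numeric(freqY)
  if (length(x) != length(y)) {
    stop_metasig("frequency vectors have different length", "metasig_shape_error")
  }
  d <- x - y
  switch(variant,
         manhattan = sum(abs(d)),
         euclidean = sqrt(sum(d^2)),
         chebyshev = max(abs(d)))
}

#' CVTree composition vector of a sample
#'
#' Per word, `a_w = (f(w) - f0(w)) / f0(w)` where `f0` is the
#' (k-2)-order expected frequency ([cvtree_expected_frequency()]); words
#' with `f0(w) = 0` contribute 0.
#'
#' @param sig_k,sig_km1,sig_km2 Signatures at k, k-1, k-2 from one read set.
#' @return Numeric vector of length `4^k`.
#' @export
cvtree_composition <- function(sig_k, sig_km1, sig_km2) {
  f0 <- cvtree_expected_frequency(sig_k, sig_km1, sig_km2)
  f <- to_frequencies(sig_k)
  ifelse(f0 > 0, (f - f0) / f0, 0)
}

#' The CVTree (Hao) dissimilarity
#'
#' `(1 - cos(a_X, a_Y)) / 2` on the two samples' composition vectors;
#' components can be negative so the value ranges over `[0, 1]`.  Defined
#' only for `k >= 3`.
#'
#' @param sigsX,sigsY Lists of three signatures (k, k-1, k-2) for each
#'   sample, e.g. `list(count_ktuples(rs, 6), count_ktuples(rs, 5),
#'   count_ktuples(rs, 4))`.
#' @return Dissimilarity in `[0, 1]`.
#' @export
hao <- function(sigsX, sigsY) {
  aX <- cvtree_composition(sigsX[[1]], sigsX[[2]], sigsX[[3]])
  aY <- cvtree_composition(sigsY[[1]], sigsY[[2]], sigsY[[3]])
  cos_dissim(aX, aY)
}

# One-sided relative entropy sum F_i ln(F_i / P_i), with 0 ln(0/p) := 0 and
# the zero-probability floor applied against the observed frequencies.
rel_entropy <- function(f, p, n) {
  p <- floor_probabilities(p, f, n)
  i <- f > 0
  sum(f[i] * log(f[i] / p[i]))
}

#' The S2 relative-entropy dissimilarity
#'
#' `S2 = sum F_X ln(F_X / P) + sum F_Y ln(F_Y / Q)` with natural logs, where
#' `F_X`, `F_Y` are observed k-tuple frequencies and `P`, `Q` are order-r
#' Markov word probabilities.  By default the cross form is used (`P` from
#' sample Y's model against `F_X`, and `Q` from X's model against `F_Y`);
#' `cross = FALSE` scores each sample against its own background instead.
#'
#' @param sigX,sigY Signatures at the same `k`.
#' @param mX,mY [fit_markov()] models of X and Y (`k >= order + 1`).
#' @param cross Use the cross pairing (default `TRUE`).
#' @return Nonnegative dissimilarity.
#' @export
s2 <- function(sigX, sigY, mX, mY, cross = TRUE) {
  stopifnot(sigX$k == sigY$k)
  check_model_k(mX, sigX$k)
  check_model_k(mY, sigX$k)
  fx <- to_frequencies(sigX)
  fy <- to_frequencies(sigY)
  px <- word_probabilities(mX, sigX$k)
  py <- word_probabilities(mY, sigX$k)
  if (cross) {
    rel_entropy(fx, py, sigY$n) + rel_entropy(fy, px, sigX$n)
  } else {
    rel_entropy(fx, px, sigX$n) + rel_entropy(fy, py, sigY$n)
  }
}

#' Is a (measure, k, order) combination defined?
#'
#' Measures centered by an order-r Markov model (d2S, d2*, S2) need
#' `k >= r + 1`; the CVTree measure needs `k >= 3` (its background is the
#' (k-2)-order chain); d2 and the L-type distances are always defined.
#' Invalid combinations are reported as `NA`, never as errors, mirroring how
#' such cells are tabulated.
#'
#' @param measure One of `r toString(MEASURES)`.
#' @param k Tuple size.
#' @param order Markov order (ignored by d2, ma, eu, ch, hao).
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_combination <- function(measure, k, order = 0) {
  measure <- match.arg(measure, MEASURES)
  switch(measure,
         d2s = , d2star = , s2 = k >= order + 1,
         hao = k >= 3,
         TRUE)
}

#' Pairwise dissimilarity matrix over a sample panel
#'
#' Computes all per-sample artifacts once (signatures, background models,
#' centered vectors or composition vectors as the measure requires) and
#' fills a labelled symmetric zero-diagonal matrix.  An invalid
#' (measure, k, order) combination yields a matrix of `NA` flagged with
#' `attr(, "valid") = FALSE` rather than an error.
#'
#' @param samples List of [read_set()] objects with unique sample ids.
#' @param measure One of `"d2"`, `"d2s"`, `"d2star"`, `"ma"`, `"eu"`,
#'   `"ch"`, `"hao"`, `"s2"`.
#' @param k Tuple size.
#' @param order Markov order 0-3 (used by d2s, d2star, s2).
#' @param both_strands Count both strands (default `TRUE`).
#' @param s2_cross Cross pairing for S2 (see [s2()]).
#' @return A `dissim_matrix`: a symmetric numeric matrix with sample-id
#'   dimnames and attributes `measure`, `k`, `order`, `valid`.
#' @export
pairwise_matrix <- function(samples, measure, k, order = 0,
                            both_strands = TRUE, s2_cross = TRUE) {
  measure <- match.arg(measure, MEASURES)
  labels <- vapply(samples, function(s) s$sample_id, "")
  if (length(samples) < 2) {
    stop_metasig("need at least two samples", "metasig_parameter_error")
  }
  if (anyDuplicated(labels)) {
    stop_metasig("duplicate sample ids in panel", "metasig_label_error")
  }
  ns <- length(samples)
  mat <- matrix(0, ns, ns, dimnames = list(labels, labels))
  if (!is_valid_combination(measure, k, order)) {
    mat[] <- NA_real_
    return(new_dissim_matrix(mat, measure, k, order, valid = FALSE))
  }

  sigs <- lapply(samples, count_ktuples, k = k, both_strands = both_strands)
  art <- switch(
    measure,
    d2 = sigs,
    ma = , eu = , ch = lapply(sigs, to_frequencies),
    d2s = , d2star = {
      mods <- lapply(samples, fit_markov, order = order, both_strands = both_strands)
      Map(center_signature, sigs, mods)
    },
    hao = lapply(samples, function(s) {
      cvtree_composition(count_ktuples(s, k, both_strands = both_strands),
                         count_ktuples(s, k - 1L, both_strands = both_strands),
                         count_ktuples(s, k - 2L, both_strands = both_strands))
    }),
    s2 = {
      mods <- lapply(samples, fit_markov, order = order, both_strands = both_strands)
      Map(function(sg, m) list(f = to_frequencies(sg), n = sg$n,
                               p = word_probabilities(m, k)),
          sigs, mods)
    })

  pair_fun <- switch(
    measure,
    d2 = function(i, j) d2(art[[i]], art[[j]]),
    d2s = function(i, j) d2s(art[[i]], art[[j]]),
    d2star = function(i, j) d2star(art[[i]], art[[j]]),
    ma = function(i, j) lp_distance(art[[i]], art[[j]], "manhattan"),
    eu = function(i, j) lp_distance(art[[i]], art[[j]], "euclidean"),
    ch = function(i, j) lp_distance(art[[i]], art[[j]], "chebyshev"),
    hao = function(i, j) cos_dissim(art[[i]], art[[j]]),
    s2 = function(i, j) {
      a <- art[[i]]; b <- art[[j]]
      if (s2_cross) {
        rel_entropy(a$f, b$p, b$n) + rel_entropy(b$f, a$p, a$n)
      } else {
        rel_entropy(a$f, a$p, a$n) + rel_entropy(b$f, b$p, b$n)
      }
    })

  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      mat[i, j] <- mat[j, i] <- pair_fun(i, j)
    }
  }
  new_dissim_matrix(mat, measure, k, order, valid = TRUE)
}

new_dissim_matrix <- function(mat, measure, k, order, valid) {
  structure(mat, class = c("dissim_matrix", "matrix"),
            measure = measure, k = as.integer(k),
            order = if (measure %in% c("d2s", "d2star", "s2")) as.integer(order) else NA_integer_,
            valid = valid)
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("<dissim_matrix> %s, k = %d%s, %d samples%s\n",
              attr(x, "measure"), attr(x, "k"),
              if (!is.na(attr(x, "order"))) sprintf(", order %d", attr(x, "order")) else "",
              nrow(x), if (!attr(x, "valid")) " [invalid combination: NA]" else ""))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Write / read a dissimilarity matrix as TSV
#'
#' Comment headers `#measure=`, `#k=`, `#order=`, `#valid=`, then a header
#' row of sample ids, a first column of sample ids, and the full square
#' symmetric body.
#'
#' @param dm A [pairwise_matrix()] result.
#' @param path File path.
#' @return `write_dissimilarity`: `path` invisibly; `read_dissimilarity`:
#'   the reconstructed `dissim_matrix`.
#' @export
write_dissimilarity <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#measure=%s", attr(dm, "measure")),
               sprintf("#k=%d", attr(dm, "k")),
               sprintf("#order=%s", ifelse(is.na(attr(dm, "order")), "none", attr(dm, "order"))),
               sprintf("#valid=%s", attr(dm, "valid")),
               paste(c("sample", colnames(dm)), collapse = "\t")), con)
  body <- cbind(rownames(dm), format(unclass(dm), digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_field <- function(key) sub(sprintf("^#%s=", key), "",
                                 grep(sprintf("^#%s=", key), hdr, value = TRUE)[1])
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  labels <- vapply(rows, `[[`, "", 1L)
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cols))))
  dimnames(mat) <- list(labels, cols)
  ord <- get_field("order")
  new_dissim_matrix(mat, get_field("measure"), as.integer(get_field("k")),
                    if (ord == "none") NA else as.integer(ord),
                    valid = get_field("valid") == "TRUE")
}
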