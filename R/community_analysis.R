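# Downstream evaluation: UPGMA clustering, symmetric-difference tree
# comparison, principal coordinates analysis with goodness of fit, and
# Spearman gradient correlation.

#' UPGMA hierarchical clustering of a dissimilarity matrix
#'
#' Average linkage: the distance between two clusters is the mean of all
#' cross-pair dissimilarities; at each step the closest pair merges at
#' height = distance / 2, yielding an ultrametric rooted tree.  Ties are
#' broken deterministically by the lexicographically lowest pair of
#' original labels (each cluster is keyed by its smallest member label,
#' byte order).
#'
#' @param dm A [pairwise_matrix()] result or plain symmetric matrix with
#'   dimnames; no `NA` allowed.
#' @return An [ape::read.tree()] `phylo` object with branch lengths (leaf
#'   heights 0, node heights = merge distance / 2).
#' @export
upgma <- function(dm) {
  if (inherits(dm, "dissim_matrix") && !attr(dm, "valid")) {
    stop_metasig("cannot cluster an invalid (NA) dissimilarity matrix",
                 "metasig_invalid_input_error")
  }
  m <- unclass(as.matrix(dm))
  if (nrow(m) < 2 || anyNA(m) || max(abs(m - t(m))) > 1e-12) {
    stop_metasig("need a symmetric NA-free matrix with >= 2 samples",
                 "metasig_invalid_input_error")
  }
  labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("S%d", seq_len(nrow(m)))
  frag <- labels
  height <- numeric(length(frag))
  size <- rep(1L, length(frag))
  minlab <- labels
  D <- (m + t(m)) / 2
  diag(D) <- Inf
  while (length(frag) > 1) {
    dmin <- min(D[upper.tri(D)])
    cand <- which(D == dmin & upper.tri(D), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      key1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
      key2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
      cand <- cand[order(key1, key2, method = "radix")[1], , drop = FALSE]
    }
    i <- cand[1, 1]
    j <- cand[1, 2]
    if (minlab[j] < minlab[i]) {  # smaller-labelled child printed first
      tmp <- i; i <- j; j <- tmp
    }
    h <- dmin / 2
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], h - height[i],
                       frag[j], h - height[j])
    newd <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_along(frag), c(i, j))
    newd <- newd[keep]
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd),
               c(newd, Inf))
    dimnames(D) <- NULL
    frag <- c(frag[keep], newfrag)
    height <- c(height[keep], h)
    size <- c(size[keep], size[i] + size[j])
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
  }
  ape::read.tree(text = paste0(frag, ";"))
}

#' Newick serialisation of trees
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; round-trips
#' preserve topology, labels and branch lengths, and multifurcations and
#' trees without branch lengths (typical for reference cluster trees) are
#' accepted.
#'
#' @param tree A `phylo` tree.
#' @param text A Newick string.
#' @return `to_newick`: a Newick string; `from_newick`: a `phylo` object.
#' @export
to_newick <- function(tree) {
  ape::write.tree(tree)
}

#' @rdname to_newick
#' @export
from_newick <- function(text) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop_metasig(sprintf("malformed Newick string: %s",
                         substr(text, 1, 60)), "metasig_parse_error")
  }
  tr
}

#' Nontrivial clusters of a rooted tree
#'
#' Each internal node is the set of its descendant leaves; singletons and
#' the full leaf set are excluded.  Clusters are returned as canonical
#' `|`-joined sorted label strings.
#'
#' @param tree A `phylo` tree.
#' @return Character vector of cluster keys.
#' @export
tree_clusters <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sizes <- lengths(pp)
  keep <- sizes > 1 & sizes < length(labs)
  unique(vapply(pp[keep], function(i) paste(sort(labs[i], method = "radix"),
                                            collapse = "|"), ""))
}

tree_splits <- function(tree) {
  labs <- sort(tree$tip.label, method = "radix")
  ref <- labs[1]
  pp <- ape::prop.part(tree)
  pl <- attr(pp, "labels")
  n <- length(pl)
  keys <- vapply(pp, function(i) {
    side <- pl[i]
    if (ref %in% side) side <- setdiff(pl, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side, method = "radix"), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Symmetric difference between two trees
#'
#' With `mode = "clusters"` (the default) each rooted tree is reduced to
#' the set of its nontrivial clusters (see [tree_clusters()]) and the count
#' of clusters present in exactly one tree is returned.  With
#' `mode = "splits"` the same count is taken over nontrivial unrooted
#' bipartitions (the Robinson-Foulds distance).  Branch lengths are
#' ignored; both trees must carry identical leaf labels.
#'
#' @param t1,t2 `phylo` trees on the same leaves.
#' @param mode `"clusters"` or `"splits"`.
#' @return Nonnegative integer.
#' @export
symmetric_difference <- function(t1, t2, mode = c("clusters", "splits")) {
  mode <- match.arg(mode)
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    stop_metasig("trees have different leaf-label sets", "metasig_label_error")
  }
  f <- if (mode == "clusters") tree_clusters else tree_splits
  a <- f(t1)
  b <- f(t2)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Recovery of planted clusters by an estimated tree
#'
#' One-sided variant of [symmetric_difference()]: counts how many of the
#' reference tree's nontrivial clusters are absent from the estimated tree.
#' A strictly binary clustering of a panel whose truth contains polytomies
#' (e.g. exchangeable replicates within planted groups) always carries
#' extra clusters, so the two-sided score has a positive floor; recovery is
#' perfect precisely when `n_missing == 0`, i.e. every planted cluster
#' appears as a clade.
#'
#' @param reference `phylo` tree with the planted clusters.
#' @param tree Estimated `phylo` tree on the same leaves.
#' @return List with `n_reference`, `n_recovered`, `n_missing`.
#' @export
cluster_recovery <- function(reference, tree) {
  if (!setequal(reference$tip.label, tree$tip.label)) {
    stop_metasig("trees have different leaf-label sets", "metasig_label_error")
  }
  ref <- tree_clusters(reference)
  est <- tree_clusters(tree)
  list(n_reference = length(ref),
       n_recovered = length(intersect(ref, est)),
       n_missing = length(setdiff(ref, est)))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers `-1/2 D^2`, eigendecomposes, and scales the eigenvectors
#' of positive eigenvalues by the square roots of the eigenvalues.
#' Negative eigenvalues (from non-Euclidean dissimilarities) are reported,
#' not corrected.  The goodness of fit of the first axis is
#' `lambda_1 / sum(max(lambda_i, 0))` by default, or
#' `lambda_1 / sum(|lambda_i|)` with `gof = "absolute"`.
#'
#' @param dm Symmetric dissimilarity matrix (no `NA`).
#' @param gof Denominator convention, `"positive"` or `"absolute"`.
#' @return An object of class `pcoa_result`: `eigenvalues` (descending),
#'   `coordinates` (samples x positive axes, rownames = labels), `gof`.
#' @export
pcoa <- function(dm, gof = c("positive", "absolute")) {
  gof <- match.arg(gof)
  if (inherits(dm, "dissim_matrix") && !attr(dm, "valid")) {
    stop_metasig("cannot ordinate an invalid (NA) dissimilarity matrix",
                 "metasig_invalid_input_error")
  }
  m <- unclass(as.matrix(dm))
  if (anyNA(m) || nrow(m) < 2) {
    stop_metasig("need an NA-free matrix with >= 2 samples",
                 "metasig_invalid_input_error")
  }
  if (all(m == 0)) {
    stop_metasig("all-zero dissimilarity matrix", "metasig_degenerate_sample_error")
  }
  n <- nrow(m)
  d2m <- m^2
  cen <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * cen %*% d2m %*% cen
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  tol <- 1e-9 * max(abs(ev))
  pos <- which(ev > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  rownames(coords) <- rownames(m)
  colnames(coords) <- sprintf("Axis%d", seq_along(pos))
  gof1 <- ev[1] / if (gof == "positive") sum(pmax(ev, 0)) else sum(abs(ev))
  structure(list(eigenvalues = ev, coordinates = coords, gof = gof1),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d positive axes, GOF(axis 1) = %.4f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$gof))
  invisible(x)
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (ties get the mean rank); +/-1 exactly
#' for perfectly monotone tie-free relationships.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_metasig("need two equal-length vectors of length >= 3",
                 "metasig_parameter_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_metasig("correlation undefined for a constant vector",
                 "metasig_undefined_correlation_error")
  }
  stats::cor(x, y, method = "spearman")
}

#' Gradient recovery report
#'
#' Runs [pcoa()] and correlates the first principal coordinate with a
#' per-sample numeric covariate (e.g. collection depth).  The absolute
#' Spearman correlation is reported because the orientation of a PCoA axis
#' is arbitrary.
#'
#' @param dm Dissimilarity matrix.
#' @param covariate Numeric vector, one value per sample (matrix row order).
#' @param gof GOF denominator convention, see [pcoa()].
#' @return List with `gof`, `srcc` (absolute Spearman of axis 1 vs the
#'   covariate) and the full `ordination`.
#' @export
gradient_report <- function(dm, covariate, gof = "positive") {
  m <- as.matrix(dm)
  if (length(covariate) != nrow(m)) {
    stop_metasig("covariate length must match the number of samples",
                 "metasig_parameter_error")
  }
  ord <- pcoa(dm, gof = gof)
  list(gof = ord$gof,
       srcc = abs(spearman(ord$coordinates[, 1], covariate)),
       ordination = ord)
}
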