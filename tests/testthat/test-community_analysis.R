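# UPGMA, tree comparison, PCoA and gradient correlation.

toy_matrix <- function(vals, labels) {
  n <- length(labels)
  m <- matrix(vals, n, n, dimnames = list(labels, labels))
  m
}

test_that("UPGMA merges by average linkage at height = distance / 2", {
  m <- toy_matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), c("A", "B", "C"))
  tr <- upgma(m)
  ht <- sort(unname(ape::branching.times(tr)))
  expect_equal(ht, c(1, 4))
  expect_equal(symmetric_difference(tr, from_newick("((A,B),C);")), 0)

  # 4-sample block structure: planted pairs merge first
  m4 <- matrix(9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m4[1, 2] <- m4[2, 1] <- 1
  m4[3, 4] <- m4[4, 3] <- 1
  diag(m4) <- 0
  t4 <- upgma(m4)
  expect_equal(symmetric_difference(t4, from_newick("((a,b),(c,d));")), 0)
  expect_equal(sort(unname(ape::branching.times(t4))), c(0.5, 0.5, 4.5))
})

test_that("UPGMA trees are ultrametric and label-order invariant up to ties", {
  set.seed(10)
  n <- 8
  d <- as.matrix(stats::dist(matrix(rnorm(n * 3), n)))
  dimnames(d) <- list(letters[1:n], letters[1:n])
  tr <- upgma(d)
  depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
  expect_lt(diff(range(depths)), 1e-9)

  perm <- sample(n)
  tr2 <- upgma(d[perm, perm])
  expect_equal(symmetric_difference(tr, tr2), 0)

  # exact ties resolve deterministically via the lexicographic pair rule
  tie <- toy_matrix(rep(1, 16), letters[1:4])
  diag(tie) <- 0
  expect_identical(to_newick(upgma(tie)), to_newick(upgma(tie[4:1, 4:1])))
})

test_that("UPGMA agrees with average-linkage hclust on tie-free matrices", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  n <- 10
  d <- as.matrix(stats::dist(matrix(rnorm(n * 4), n)))
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  mine <- upgma(d)
  ref <- phangorn::upgma(stats::as.dist(d))
  expect_equal(phangorn::RF.dist(mine, ref), 0)
  expect_equal(max(ape::node.depth.edgelength(mine)[1:n]),
               max(ape::node.depth.edgelength(ref)[1:n]), tolerance = 1e-9)
})

test_that("Newick round-trips preserve topology, heights and polytomies", {
  tr <- upgma(toy_matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), c("A", "B", "C")))
  back <- from_newick(to_newick(tr))
  expect_equal(sort(unname(ape::branching.times(back))), c(1, 4))
  expect_equal(symmetric_difference(tr, back), 0)

  poly <- from_newick("((A,B,C),D);")
  expect_equal(tree_clusters(poly), paste(c("A", "B", "C"), collapse = "|"))
  expect_silent(from_newick("((A,B),(C,D));"))  # no branch lengths
  expect_error(from_newick("((A,B),C"), class = "metasig_parse_error")
})

test_that("symmetric difference counts clusters present in exactly one tree", {
  t1 <- from_newick("((A,B),(C,D));")
  t2 <- from_newick("((A,C),(B,D));")
  t3 <- from_newick("(((A,B),C),D);")
  expect_equal(symmetric_difference(t1, t1), 0)
  expect_equal(symmetric_difference(t1, t2), 4)
  expect_equal(symmetric_difference(t1, t3), 2)
  expect_error(symmetric_difference(t1, from_newick("((A,B),(C,E));")),
               class = "metasig_label_error")
})

test_that("splits mode matches Robinson-Foulds on random binary trees", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    set.seed(seed)
    t1 <- ape::rtree(8)
    t2 <- ape::rtree(8)
    expect_equal(symmetric_difference(t1, t2, mode = "splits"),
                 phangorn::RF.dist(t1, t2, check.labels = TRUE))
  }
})

test_that("symmetric difference is a metric on trees with fixed leaves", {
  set.seed(7)
  trees <- lapply(1:6, function(i) ape::rtree(5))
  for (mode in c("clusters", "splits")) {
    d <- outer(seq_along(trees), seq_along(trees),
               Vectorize(function(i, j) symmetric_difference(trees[[i]], trees[[j]],
                                                             mode = mode)))
    expect_true(all(diag(d) == 0))
    expect_identical(d, t(d))
    for (i in 1:6) for (j in 1:6) for (l in 1:6) {
      expect_lte(d[i, j], d[i, l] + d[l, j])
    }
  }
})

test_that("cluster recovery counts planted clusters missing from a binary tree", {
  planted <- from_newick("((A,B,C),(D,E,F));")
  good <- from_newick("(((A,B),C),((D,E),F));")
  bad <- from_newick("(((A,B),D),((C,E),F));")
  expect_equal(cluster_recovery(planted, good)$n_missing, 0)
  expect_equal(cluster_recovery(planted, good)$n_recovered, 2)
  expect_gt(cluster_recovery(planted, bad)$n_missing, 0)
  # the two-sided score can never reach 0 against a finer binary tree
  expect_gt(symmetric_difference(planted, good), 0)
})

test_that("PCoA reproduces Euclidean configurations exactly", {
  pts <- c(0, 3, 5)
  D <- abs(outer(pts, pts, "-"))
  dimnames(D) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(D)
  expect_equal(ord$gof, 1, tolerance = 1e-9)
  gaps <- abs(diff(sort(ord$coordinates[, 1])))
  expect_equal(sort(unname(gaps)), c(2, 3), tolerance = 1e-9)

  # a 3-D Euclidean configuration: distances rebuilt from coordinates
  set.seed(11)
  X <- matrix(rnorm(7 * 3), 7)
  D3 <- as.matrix(stats::dist(X))
  ord3 <- pcoa(D3)
  rebuilt <- as.matrix(stats::dist(ord3$coordinates))
  expect_lt(max(abs(rebuilt - D3)), 1e-9)
  expect_true(all(diff(ord3$eigenvalues) <= 1e-9))
})

test_that("PCoA matches classical-scaling references and handles duplicates", {
  set.seed(12)
  X <- matrix(rnorm(6 * 2), 6)
  D <- as.matrix(stats::dist(X))
  ord <- pcoa(D)
  cs <- stats::cmdscale(D, k = 2, eig = TRUE)
  expect_equal(ord$eigenvalues[1:2], cs$eig[1:2], tolerance = 1e-9)
  expect_equal(abs(ord$coordinates[, 1]), abs(cs$points[, 1]), tolerance = 1e-9,
               ignore_attr = TRUE)
  ap <- ape::pcoa(D)
  expect_equal(ord$gof, ap$values$Relative_eig[1], tolerance = 1e-9)

  Ddup <- rbind(cbind(D, D[, 1]), c(D[1, ], 0))
  dimnames(Ddup) <- list(c(paste0("s", 1:6), "dup"), c(paste0("s", 1:6), "dup"))
  od <- pcoa(Ddup)
  expect_equal(od$coordinates["s1", ], od$coordinates["dup", ], tolerance = 1e-9)

  expect_error(pcoa(matrix(0, 3, 3)), class = "metasig_degenerate_sample_error")
})

test_that("Spearman correlation handles monotone, tied and constant inputs", {
  x <- c(1.2, 3.4, 3.5, 8, 12)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, -x^3), -1)
  expect_equal(spearman(1:4, c(1, 1, 2, 2)), 0.8944272, tolerance = 1e-7)
  expect_equal(spearman(1:4, c(1, 1, 2, 2)), naive_spearman(1:4, c(1, 1, 2, 2)),
               tolerance = 1e-12)
  expect_error(spearman(1:4, rep(2, 4)),
               class = "metasig_undefined_correlation_error")
  expect_error(spearman(1:2, 1:2), class = "metasig_parameter_error")
})

test_that("gradient reports recover a covariate that is the geometry", {
  cov <- c(25, 75, 125, 500, 350, 10)
  D <- abs(outer(cov, cov, "-"))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  gr <- gradient_report(D, cov)
  expect_equal(gr$srcc, 1, tolerance = 1e-9)
  expect_equal(gr$gof, 1, tolerance = 1e-9)

  perm <- c(3, 1, 4, 6, 2, 5)
  gr2 <- gradient_report(D, cov[perm])
  expect_lt(gr2$srcc, 1)
  expect_error(gradient_report(D, cov[1:3]), class = "metasig_parameter_error")
})
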