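# The eight dissimilarity measures and pairwise matrices.

centered_toy <- function(xt, ex) {
  structure(list(sample_id = "toy", k = 1, order = 0, centered = xt,
                 expectations = ex, n = sum(ex)),
            class = "centered_signature")
}

test_that("hand-computed toy values are exact", {
  expect_equal(d2(c(3, 4), c(4, 3)), (1 - 24 / 25) / 2)
  expect_equal(d2(c(1, 0, 0), c(0, 1, 0)), 0.5)
  expect_equal(d2(c(2, 4), c(1, 2)), 0)

  expect_equal(d2s(c(1, -1), c(-1, 1)), 1)
  expect_equal(d2s(c(2, -1, 3), c(2, -1, 3)), 0)

  expect_equal(d2star(centered_toy(c(1, -1), c(1, 1)),
                      centered_toy(c(-1, 1), c(1, 1))), 1)
  expect_equal(d2star(centered_toy(c(1, -2), c(2, 3)),
                      centered_toy(c(1, -2), c(2, 3))), 0)

  expect_equal(lp_distance(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5), "manhattan"), 2)
  expect_equal(lp_distance(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5), "euclidean"), 1)
  expect_equal(lp_distance(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5), "chebyshev"), 0.5)
  expect_equal(lp_distance(c(0.2, 0.8), c(0.2, 0.8), "manhattan"), 0)

  # one-sided relative-entropy term: F=(1,0) against P=(1/2,1/2)
  expect_equal(metasig:::rel_entropy(c(1, 0), c(0.5, 0.5), n = 10), log(2))
})

test_that("identical samples have zero dissimilarity under every measure", {
  rs <- random_read_set(60, 50, 21)
  sig <- count_ktuples(rs, 3)
  m <- fit_markov(rs, 0)
  cs <- center_signature(sig, m)
  expect_equal(d2(sig, sig), 0)
  expect_equal(d2s(cs, cs), 0)
  expect_equal(d2star(cs, cs), 0)
  sigs3 <- list(count_ktuples(rs, 3), count_ktuples(rs, 2), count_ktuples(rs, 1))
  expect_equal(hao(sigs3, sigs3), 0)
  # S2 of a sample against itself in the self form is its own relative
  # entropy twice, not zero; but two identical samples give a symmetric score
  expect_equal(s2(sig, sig, m, m), s2(sig, sig, m, m, cross = FALSE))
})

test_that("every measure matches its naive per-word summation oracle", {
  for (seed in c(2, 7)) {
    rsX <- random_read_set(30, 40, seed, probs = c(0.35, 0.25, 0.2, 0.2))
    rsY <- random_read_set(30, 40, seed + 50, probs = c(0.2, 0.2, 0.25, 0.35))
    for (k in 2:5) {
      sigX <- count_ktuples(rsX, k)
      sigY <- count_ktuples(rsY, k)
      expect_equal(d2(sigX, sigY), naive_d2(sigX$counts, sigY$counts),
                   tolerance = 1e-10)
      expect_equal(lp_distance(sigX, sigY, "manhattan"),
                   naive_lp(to_frequencies(sigX), to_frequencies(sigY), "manhattan"),
                   tolerance = 1e-10)
      expect_equal(lp_distance(sigX, sigY, "euclidean"),
                   naive_lp(to_frequencies(sigX), to_frequencies(sigY), "euclidean"),
                   tolerance = 1e-10)
      expect_equal(lp_distance(sigX, sigY, "chebyshev"),
                   naive_lp(to_frequencies(sigX), to_frequencies(sigY), "chebyshev"),
                   tolerance = 1e-10)
      for (r in 0:1) {
        mX <- fit_markov(rsX, r)
        mY <- fit_markov(rsY, r)
        csX <- center_signature(sigX, mX)
        csY <- center_signature(sigY, mY)
        expect_equal(d2s(csX, csY), naive_d2s(csX$centered, csY$centered),
                     tolerance = 1e-10)
        expect_equal(d2star(csX, csY),
                     naive_d2star(csX$centered, csY$centered,
                                  csX$expectations, csY$expectations),
                     tolerance = 1e-10)
        expect_equal(s2(sigX, sigY, mX, mY),
                     naive_s2_half(to_frequencies(sigX),
                                   word_probabilities(mY, k), sigY$n) +
                     naive_s2_half(to_frequencies(sigY),
                                   word_probabilities(mX, k), sigX$n),
                     tolerance = 1e-10)
      }
      if (k >= 3) {
        sigsX <- lapply(k - 0:2, count_ktuples, rs = rsX)
        sigsY <- lapply(k - 0:2, count_ktuples, rs = rsY)
        expect_equal(hao(sigsX, sigsY),
                     metasig:::cos_dissim(naive_cvtree_comp(rsX$reads, k),
                                          naive_cvtree_comp(rsY$reads, k)),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("measure ranges and norm orderings hold on fuzzed pairs", {
  for (seed in 1:15) {
    rsX <- dirichlet_read_set(40, 60, seed)
    rsY <- dirichlet_read_set(40, 60, seed + 1000)
    k <- 3
    sigX <- count_ktuples(rsX, k)
    sigY <- count_ktuples(rsY, k)
    mX <- fit_markov(rsX, 0)
    mY <- fit_markov(rsY, 0)
    csX <- center_signature(sigX, mX)
    csY <- center_signature(sigY, mY)
    v_d2s <- d2s(csX, csY)
    v_d2star <- d2star(csX, csY)
    expect_true(v_d2s >= 0 && v_d2s <= 1)
    expect_true(v_d2star >= 0 && v_d2star <= 1)
    expect_true(d2(sigX, sigY) <= 0.5)
    expect_gte(s2(sigX, sigY, mX, mY), 0)
    h <- hao(lapply(k - 0:2, count_ktuples, rs = rsX),
             lapply(k - 0:2, count_ktuples, rs = rsY))
    expect_true(h >= 0 && h <= 1)
    fx <- to_frequencies(sigX)
    fy <- to_frequencies(sigY)
    expect_lte(lp_distance(fx, fy, "chebyshev"), lp_distance(fx, fy, "euclidean"))
    expect_lte(lp_distance(fx, fy, "euclidean"), lp_distance(fx, fy, "manhattan"))
  }
})

test_that("pairwise matrices are symmetric, zero-diagonal and labelled", {
  samples <- lapply(1:4, function(i) random_read_set(40, 50, i, id = paste0("s", i)))
  for (me in c("d2", "d2s", "ma", "hao", "s2")) {
    dm <- pairwise_matrix(samples, me, k = 3, order = 0)
    expect_identical(unclass(dm), t(unclass(dm)))
    expect_equal(unname(diag(dm)), rep(0, 4))
    expect_true(all(dm >= 0))
    expect_identical(rownames(dm), paste0("s", 1:4))
    expect_true(attr(dm, "valid"))
  }
  # three copies of one sample: all off-diagonal entries 0
  trio <- lapply(1:3, function(i) read_set(samples[[1]]$reads, paste0("c", i)))
  dmt <- pairwise_matrix(trio, "d2s", 3, 0)
  expect_equal(max(abs(dmt)), 0)
  expect_error(pairwise_matrix(list(samples[[1]], samples[[1]]), "d2", 3),
               class = "metasig_label_error")
})

test_that("invalid (measure, k, order) combinations yield flagged NA matrices", {
  samples <- lapply(1:3, function(i) random_read_set(20, 30, i, id = paste0("s", i)))
  dm <- pairwise_matrix(samples, "d2s", k = 2, order = 2)
  expect_true(all(is.na(dm)))
  expect_false(attr(dm, "valid"))
  expect_false(is_valid_combination("d2s", 2, 2))
  expect_false(is_valid_combination("d2s", 3, 3))
  expect_false(is_valid_combination("hao", 2))
  expect_true(is_valid_combination("hao", 3))
  expect_true(is_valid_combination("d2s", 3, 2))
  expect_true(is_valid_combination("d2", 2, 3))
  dmh <- pairwise_matrix(samples, "hao", k = 2)
  expect_true(all(is.na(dmh)) && !attr(dmh, "valid"))
})

test_that("measures are invariant to strand flips and read order", {
  samples <- lapply(1:3, function(i) random_read_set(40, 40, i + 30, id = paste0("s", i)))
  for (me in c("d2", "d2s", "eu", "hao", "s2")) {
    dm <- pairwise_matrix(samples, me, k = 3, order = 0)
    flipped <- samples
    flipped[[2]] <- read_set(reverse_complement(samples[[2]]$reads), "s2")
    expect_equal(unclass(pairwise_matrix(flipped, me, 3, 0)), unclass(dm),
                 tolerance = 1e-12, info = me)
    shuffled <- samples
    shuffled[[1]] <- read_set(rev(samples[[1]]$reads), "s1")
    expect_identical(unclass(pairwise_matrix(shuffled, me, 3, 0)), unclass(dm))
  }
})

test_that("matrix files round-trip with their metadata", {
  samples <- lapply(1:3, function(i) random_read_set(30, 40, i, id = paste0("s", i)))
  dm <- pairwise_matrix(samples, "d2s", 4, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dissimilarity(dm, path)
  back <- read_dissimilarity(path)
  expect_equal(unclass(back), unclass(dm), tolerance = 1e-15)
  expect_identical(attr(back, "measure"), "d2s")
  expect_identical(attr(back, "k"), 4L)
  expect_identical(attr(back, "order"), 1L)
})

test_that("same-source pairs stay closer than different-source pairs at 10% depth", {
  pools <- make_source_pools(2, seed = 5)
  wins <- 0L
  n_trials <- 20L
  for (i in seq_len(n_trials)) {
    a1 <- sample_reads(pools[[1]], 1500, seed = 3 * i, sample_id = "a1")
    a2 <- sample_reads(pools[[1]], 1500, seed = 3 * i + 1, sample_id = "a2")
    b1 <- sample_reads(pools[[2]], 1500, seed = 3 * i + 2, sample_id = "b1")
    sub <- lapply(list(a1, a2, b1), subsample_reads, rate = 0.1, seed = i)
    dm <- pairwise_matrix(sub, "d2s", 6, 0)
    if (dm["a1", "a2"] < dm["a1", "b1"]) wins <- wins + 1L
  }
  expect_gte(wins, n_trials - 1L)
})
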