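# Synthetic communities: Markov-chain source pools with planted group
# structure, expression-weighted read sampling, mixture gradients, and a
# simple homogeneous sequencing-error injector.  Every generator is
# seed-deterministic so the whole pipeline is testable without external data.

rdirichlet1 <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# Simulate n sequences of length len from an order-r chain with transition
# table tr (4^r x 4, rows sum to 1); the first r bases are uniform.
simulate_chain <- function(n, len, tr, r) {
  stopifnot(len > r)
  cum <- t(apply(tr, 1, cumsum))
  out <- matrix(0L, n, len)
  if (r == 0) {
    ctx <- rep(1L, n)
    start <- 1L
  } else {
    ctx0 <- sample.int(4^r, n, replace = TRUE) - 1L
    for (p in seq_len(r)) {
      out[, p] <- (ctx0 %/% 4^(r - p)) %% 4L
    }
    ctx <- ctx0 + 1L
    start <- r + 1L
  }
  for (p in start:len) {
    u <- stats::runif(n)
    b <- as.integer(rowSums(cum[ctx, , drop = FALSE] < u))
    out[, p] <- b
    ctx <- if (r == 0) ctx else (((ctx - 1L) * 4L + b) %% 4^r) + 1L
  }
  apply(matrix(DNA_BASES[out + 1L], n, len), 1, paste, collapse = "")
}

#' Generate diverged source pools
#'
#' Builds a shared base transition table (rows drawn from a Dirichlet) and
#' perturbs it per pool by mixing with an independent random table at
#' weight `divergence`; each pool then regenerates its transcripts from its
#' own chain and receives independent Dirichlet expression weights.
#' Divergence therefore acts on sequence composition while the weights act
#' on expression abundance, the two axes along which real
#' metatranscriptomes differ.
#'
#' @param n_pools Number of pools (>= 2).
#' @param n_genes Transcripts per pool.
#' @param gene_len Transcript length in bases.
#' @param order Markov order of the generating chain (0-3).
#' @param divergence Mixing weight `delta` in `[0, 0.5]`; 0 makes all pools
#'   share one table.
#' @param seed Integer seed; same seed, same pools.
#' @param concentration Dirichlet concentration for transition rows.
#' @return List of `source_pool` objects (fields `pool_id`, `transcripts`,
#'   `expression_weights`, `order`, `transition`, `divergence`,
#'   `generator_seed`).
#' @export
make_source_pools <- function(n_pools, n_genes = 20, gene_len = 1000,
                              order = 1, divergence = 0.3, seed = 1,
                              concentration = 5) {
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.5) {
    stop_metasig("divergence must be in [0, 0.5]", "metasig_parameter_error")
  }
  if (n_pools < 2) {
    stop_metasig("need at least 2 pools", "metasig_parameter_error")
  }
  r <- as.integer(order)
  with_seed(seed, {
    base_tr <- rdirichlet1(4^r, rep(concentration, 4))
    lapply(seq_len(n_pools), function(p) {
      rand_tr <- rdirichlet1(4^r, rep(concentration, 4))
      tr <- (1 - divergence) * base_tr + divergence * rand_tr
      structure(
        list(pool_id = sprintf("pool%d", p),
             transcripts = simulate_chain(n_genes, gene_len, tr, r),
             expression_weights = as.numeric(rdirichlet1(1, rep(1, n_genes))),
             order = r, transition = tr, divergence = divergence,
             generator_seed = seed),
        class = "source_pool")
    })
  })
}

#' Sample reads from a source pool
#'
#' Each read picks a transcript with probability equal to its expression
#' weight, a read length from `Normal(len_mean, len_sd)` (fixed length when
#' `len_sd = 0`) truncated to `[min_len, transcript length]`, and a uniform
#' start position.  Transcripts shorter than `min_len` are skipped with a
#' warning.
#'
#' @param pool A [make_source_pools()] pool.
#' @param n_reads Number of reads (>= 1).
#' @param len_mean,len_sd Read-length distribution (e.g. 76/0 emulates
#'   fixed-length short reads; 198/92 emulates variable-length
#'   pyrosequencing reads).
#' @param seed Integer seed.
#' @param sample_id Label of the resulting read set.
#' @param min_len Minimum read length.
#' @return A [read_set()].
#' @export
sample_reads <- function(pool, n_reads, len_mean = 150, len_sd = 0, seed = 1,
                         sample_id = pool$pool_id, min_len = 20) {
  stopifnot(inherits(pool, "source_pool"), n_reads >= 1)
  tlen <- nchar(pool$transcripts)
  usable <- tlen >= min_len
  if (!any(usable)) {
    stop_metasig("every transcript is shorter than min_len",
                 "metasig_degenerate_sample_error")
  }
  if (!all(usable)) {
    warning(sprintf("%d transcript(s) shorter than min_len skipped", sum(!usable)),
            call. = FALSE)
  }
  w <- pool$expression_weights * usable
  w <- w / sum(w)
  with_seed(seed, {
    tid <- sample.int(length(pool$transcripts), n_reads, replace = TRUE, prob = w)
    lens <- if (len_sd == 0) rep(round(len_mean), n_reads) else
      round(stats::rnorm(n_reads, len_mean, len_sd))
    lens <- pmax(pmin(lens, tlen[tid]), min_len)
    start <- 1L + floor(stats::runif(n_reads) * (tlen[tid] - lens + 1))
    read_set(substring(pool$transcripts[tid], start, start + lens - 1),
             sample_id,
             provenance = list(pool = pool$pool_id, seed = seed,
                               len_mean = len_mean, len_sd = len_sd))
  })
}

#' Generate a mixture-gradient sample panel
#'
#' A sample at mixture level `t` draws each read from `poolB` with
#' probability `t` and from `poolA` otherwise; `reps` replicate samples are
#' generated per level.  This emulates a panel of communities collected
#' along an environmental gradient (e.g. several collection depths with two
#' samples per depth).
#'
#' @param poolA,poolB Two [make_source_pools()] pools.
#' @param levels Mixture fractions in `[0, 1]` (>= 3 levels).
#' @param reps Replicates per level.
#' @param n_reads Reads per sample.
#' @param len_mean,len_sd Read-length parameters, see [sample_reads()].
#' @param seed Master seed.
#' @return List with `samples` (read sets, `length(levels) * reps` of
#'   them), `covariate` (the level of each sample) and `levels`.
#' @export
make_gradient_panel <- function(poolA, poolB, levels = c(0, 1/3, 2/3, 1),
                                reps = 2, n_reads = 2000, len_mean = 150,
                                len_sd = 0, seed = 1) {
  if (length(levels) < 3 || any(levels < 0 | levels > 1)) {
    stop_metasig("need >= 3 mixture levels in [0, 1]", "metasig_parameter_error")
  }
  grid <- expand.grid(rep = seq_len(reps), level = seq_along(levels))
  seeds <- derive_seeds(seed, nrow(grid) * 3L)
  samples <- lapply(seq_len(nrow(grid)), function(i) {
    t <- levels[grid$level[i]]
    sid <- sprintf("L%d_r%d", grid$level[i], grid$rep[i])
    nB <- with_seed(seeds[3 * i - 2], stats::rbinom(1, n_reads, t))
    reads <- character(0)
    if (nB < n_reads) {
      reads <- c(reads, sample_reads(poolA, n_reads - nB, len_mean, len_sd,
                                     seed = seeds[3 * i - 1], sample_id = sid)$reads)
    }
    if (nB > 0) {
      reads <- c(reads, sample_reads(poolB, nB, len_mean, len_sd,
                                     seed = seeds[3 * i], sample_id = sid)$reads)
    }
    read_set(reads, sid, provenance = list(level = t, seed = seed))
  })
  list(samples = samples,
       covariate = levels[grid$level],
       levels = levels)
}

#' Inject substitution and indel sequencing errors
#'
#' A simplified homogeneous error model: per base, independently, with
#' probability `sub_rate` the base is replaced by a uniformly chosen
#' different base; with probability `indel_rate / 2` a uniform base is
#' inserted after it; with probability `indel_rate / 2` it is deleted.
#' Insertions and deletions balance, so the expected read length is
#' unchanged.  Defaults mirror pyrosequencing-style error loads (1% indel,
#' 0.1% substitution).
#'
#' @param rs A [read_set()].
#' @param indel_rate,sub_rate Per-base rates in `[0, 0.1]`.
#' @param seed Integer seed.
#' @return A [read_set()] with the same number of reads (reads erased to
#'   zero length by deletion are dropped with a warning).
#' @export
inject_errors <- function(rs, indel_rate = 0.01, sub_rate = 0.001, seed = 1) {
  if (indel_rate < 0 || indel_rate > 0.1 || sub_rate < 0 || sub_rate > 0.1) {
    stop_metasig("error rates must be in [0, 0.1]", "metasig_parameter_error")
  }
  if (indel_rate == 0 && sub_rate == 0) return(rs)
  with_seed(seed, {
    raw_bases <- charToRaw("ACGT")
    v <- charToRaw(paste(rs$reads, collapse = ""))
    lens <- nchar(rs$reads)
    L <- length(v)
    sub_mask <- stats::runif(L) < sub_rate & v != charToRaw("N")
    if (any(sub_mask)) {
      m <- match(v[sub_mask], raw_bases)
      shift <- sample.int(3L, sum(sub_mask), replace = TRUE)
      v[sub_mask] <- raw_bases[((m - 1L + shift) %% 4L) + 1L]
    }
    u <- stats::runif(L)
    ins <- u < indel_rate / 2
    del <- u >= indel_rate / 2 & u < indel_rate
    cnt <- 1L + ins - del
    out <- rep.int(v, cnt)
    if (any(ins)) {
      at <- cumsum(cnt)[ins]   # position of the duplicated slot
      out[at] <- raw_bases[sample.int(4L, sum(ins), replace = TRUE)]
    }
    new_ends <- cumsum(cnt)[cumsum(lens)]
    new_starts <- c(1, new_ends[-length(new_ends)] + 1)
    reads <- substring(rawToChar(out), new_starts, new_ends)
    empty <- !nzchar(reads)
    if (any(empty)) {
      warning(sprintf("%d read(s) fully deleted by error injection", sum(empty)),
              call. = FALSE)
      reads <- reads[!empty]
    }
    res <- read_set(unname(reads), rs$sample_id,
                    provenance = modifyList(rs$provenance,
                                            list(indel_rate = indel_rate,
                                                 sub_rate = sub_rate,
                                                 error_seed = seed)))
    res
  })
}

#' Generate a panel with planted group structure
#'
#' Builds `n_groups` diverged source pools, samples `samples_per_group`
#' replicate read sets from each, and emits the planted reference tree: a
#' star of groups, each group a polytomy of its samples (so the reference
#' carries exactly `n_groups` nontrivial clusters).
#'
#' @param n_groups Number of planted groups.
#' @param samples_per_group Replicate samples per group.
#' @param n_reads Reads per sample.
#' @param len_mean,len_sd Read-length parameters.
#' @param n_genes,gene_len,order,divergence Pool parameters, see
#'   [make_source_pools()].
#' @param seed Master seed.
#' @return List with `samples` (read sets named `g<i>_s<j>`), `reference`
#'   (`phylo` planted tree), `groups` (group id per sample) and `pools`.
#' @export
make_group_panel <- function(n_groups = 4, samples_per_group = 5,
                             n_reads = 2000, len_mean = 150, len_sd = 0,
                             n_genes = 20, gene_len = 1000, order = 1,
                             divergence = 0.3, seed = 1) {
  if (n_groups * samples_per_group < 4) {
    stop_metasig("need at least 4 samples in total", "metasig_parameter_error")
  }
  seeds <- derive_seeds(seed, 1L + n_groups * samples_per_group)
  pools <- make_source_pools(n_groups, n_genes = n_genes, gene_len = gene_len,
                             order = order, divergence = divergence,
                             seed = seeds[1])
  grid <- expand.grid(s = seq_len(samples_per_group), g = seq_len(n_groups))
  samples <- lapply(seq_len(nrow(grid)), function(i) {
    sid <- sprintf("g%d_s%d", grid$g[i], grid$s[i])
    sample_reads(pools[[grid$g[i]]], n_reads, len_mean, len_sd,
                 seed = seeds[1 + i], sample_id = sid)
  })
  ids <- vapply(samples, function(s) s$sample_id, "")
  newick <- paste0("(", paste(vapply(seq_len(n_groups), function(g) {
    paste0("(", paste(ids[grid$g == g], collapse = ","), ")")
  }, ""), collapse = ","), ");")
  list(samples = samples, reference = from_newick(newick),
       groups = grid$g, pools = pools)
}
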