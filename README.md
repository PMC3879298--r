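# metasig

Alignment-free comparison of metagenomic and metatranscriptomic
sequencing samples from their k-tuple (k-mer) sequence signatures.

Shotgun community sequencing — and metatranscriptomic sequencing in
particular — produces millions of short reads per sample from organisms
that are largely absent from reference databases, so comparing samples by
alignment is often impossible or wasteful. `metasig` implements the
alignment-free alternative for ecologists and bioinformaticians who need a
beta-diversity analysis straight from the reads: each sample is summarised
by the vector of occurrence counts of all 4^k nucleotide words of length k
(counted on both strands, since read orientation is unknown), samples are
compared with dissimilarity measures defined on those vectors, and the
resulting matrices are fed to standard community-analysis tools (UPGMA
clustering, principal coordinates analysis, gradient correlation).

## The measures

Let `X_w`, `Y_w` be the counts of word `w` in samples X and Y, `n` the
total count of a sample, and `p_w` the probability of `w` under an order-r
Markov background model fitted to that sample (r = 0–3). With centralised
counts `X̃_w = X_w − n·p_w`:

* **d2** — `(1 − cos(X, Y))/2` on the raw count vectors; range [0, 0.5].
* **d2S** — `(1 − D/√(A·B))/2` with
  `D = Σ X̃_w Ỹ_w / √(X̃_w² + Ỹ_w²)`,
  `A = Σ X̃_w² / √(X̃_w² + Ỹ_w²)`,
  `B = Σ Ỹ_w² / √(X̃_w² + Ỹ_w²)`; range [0, 1].
* **d2\*** — `(1 − D*/√(A*·B*))/2` with
  `D* = Σ X̃_w Ỹ_w / √(E_X E_Y)`, `A* = Σ X̃_w²/E_X`,
  `B* = Σ Ỹ_w²/E_Y`, `E = n·p_w`; range [0, 1].
* **Ma / Eu / Ch** — Manhattan, Euclidean and Chebyshev distances on the
  relative frequency vectors.
* **Hao (CVTree)** — `(1 − cos(a_X, a_Y))/2` on composition vectors
  `a_w = (f(w) − f0(w))/f0(w)`, where `f0` is the expected frequency under
  the (k−2)-order Markov chain,
  `f0(w) = f(w₁..w_{k−1})·f(w₂..w_k)/f(w₂..w_{k−1})`.
* **S2** — the relative-entropy measure
  `Σ F_X ln(F_X/P) + Σ F_Y ln(F_Y/Q)` pairing each sample's observed
  frequencies with the partner's Markov word probabilities.

Measures needing an order-r background are defined only for `k ≥ r + 1`
(Hao only for `k ≥ 3`); invalid combinations are reported as NA, never
silently as zeros.

The package also ships a synthetic community generator (Markov source
pools with planted group structure, expression-weighted transcript
sampling, mixture gradients, and an indel/substitution error injector), so
the entire pipeline — including depth-subsampling and error-robustness
protocols — runs and is testable without downloading any data.

## Worked example

Simulate nine samples from three diverged source communities, compare them
with d2S at k = 6 under an order-0 background, cluster, and score against
the planted truth:

```r
library(metasig)

panel <- make_group_panel(n_groups = 3, samples_per_group = 3,
                          n_reads = 1000, len_mean = 150,
                          divergence = 0.3, seed = 42)
dm <- pairwise_matrix(panel$samples, "d2s", k = 6, order = 0)
dm["g1_s1", c("g1_s2", "g2_s1")]
#>      g1_s2      g2_s1
#> 0.02748961 0.28107140
```

Within-group dissimilarities (~0.03) sit an order of magnitude below
between-group ones (~0.27): the planted structure is visible directly in
the matrix. Clustering recovers every planted group as a clade:

```r
tree <- upgma(dm)
cluster_recovery(panel$reference, tree)
#> $n_reference 3   $n_recovered 3   $n_missing 0
symmetric_difference(panel$reference, tree)
#> [1] 4
```

(The two-sided symmetric difference is 4, not 0, because the binary UPGMA
tree necessarily resolves finer than the planted star-of-groups reference;
`cluster_recovery()` is the statistic that is 0 exactly at perfect group
recovery.)

A mixture gradient between two source pools is recovered on the first
principal coordinate:

```r
pools <- make_source_pools(2, divergence = 0.3, seed = 7)
gp <- make_gradient_panel(pools[[1]], pools[[2]],
                          levels = c(0, 1/3, 2/3, 1), reps = 2,
                          n_reads = 2000, seed = 8)
gradient_report(pairwise_matrix(gp$samples, "d2s", 6, 0), gp$covariate)
#> GOF = 0.981, |SRCC| = 0.9759
```

0.9759 is the largest |SRCC| attainable for eight samples tied two-per-level
on four gradient levels, i.e. a perfectly ordered first axis.

A thin command-line front end over the same functions is installed at
`system.file("cli", "metasig", package = "metasig")` with subcommands
`count`, `prob`, `dist`, `cluster`, `treedist`, `ordinate`, `sample`,
`simulate` and `run`.

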