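---
title: "Alignment-free sample comparison with metasig: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free sample comparison with metasig: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasig)
```

## The model

`metasig` compares sequencing samples without alignment. A sample's
summary statistic is its *k-tuple signature*: the vector of occurrence
counts of all $4^k$ words of length $k$ over $\{A,C,G,T\}$ across all
reads. Because the originating strand of a shotgun read is unknown, every
read contributes the windows of both itself and its reverse complement;
the resulting vector is exactly invariant under the reverse-complement
permutation of word indices, and all downstream measures are therefore
strand-invariant. Windows containing `N` match no word and are skipped
entirely; at ingestion every character outside `{A,C,G,T,N}` is mapped to
`N` so that one canonical alphabet flows through the pipeline.

Raw counts confound composition with sequencing depth and with the
background word usage of the community, so the signature is interpreted
relative to a *background model*: an order-$r$ Markov chain ($r = 0$–$3$)
fitted per sample from its own strand-augmented counts. The chain gives
every word a probability
$p_w = p(w_1..w_r)\prod_i p(w_{i+r}\mid w_i..w_{i+r-1})$ and hence an
expected count $n\,p_w$, where $n$ is the sample's total tuple count.
Fitting each sample against its own background (rather than a pooled one)
follows the per-sample expectation terms in the centered statistics: the
question each centered measure asks is whether two samples deviate from
their *own* backgrounds in a correlated way.

The eight dissimilarity measures, their formulas and their validity rules
are listed in the README; the cosine-type statistics are normalised as
$(1-\cos)/2$ so that d2 ranges over $[0, 0.5]$ (nonnegative vectors) and
d2S, d2\* and Hao over $[0, 1]$ (centered components may be negative —
d2S/d2\* reach 1 by Cauchy–Schwarz, and the toy pair
$\tilde X = (1,-1), \tilde Y = (-1,1)$ attains it exactly).

## Parameters that matter

* **Tuple size `k`** (integer, default 6 in the examples). Small $k$
  yields dense, low-variance but weakly informative signatures; large $k$
  costs $8 \cdot 4^k$ bytes per vector and becomes sparse at modest
  depth. Requests above $k = 12$ are refused unless `allow_large = TRUE`,
  because memory grows geometrically.
* **Markov order `r`** (0–3, default 0). Higher orders absorb more local
  sequence structure into the background, sharpening the centered
  statistics but needing $4^{r+1}$ well-estimated transition cells; an
  order-$r$ centering is undefined for $k < r+1$ and such combinations
  are reported as `NA` by `pairwise_matrix()` and the pipeline rather
  than raising errors, so parameter sweeps degrade gracefully.
* **Subsampling `rate`** (fraction of reads, without replacement,
  `round(rate * N)` reads). Emulates a lower sequencing depth; without
  replacement is the right model because a shallower run observes each
  molecule at most as often as the deep run did.
* **Error rates** for the injector: per-base substitution probability and
  a combined indel probability split evenly between insertion-after and
  deletion, defaults 0.001 and 0.01 — a pyrosequencing-style error load
  where indels dominate substitutions by an order of magnitude.

## Numerical choices

* **Zero-probability floor.** A word observed in the counts but assigned
  probability 0 by the background (an unobserved transition context)
  would make the d2\* and S2 denominators blow up. Such probabilities are
  floored at $1/(10n)$ — below the smallest meaningful empirical
  frequency $1/n$ — with a warning. The alternative (pseudocounts on all
  cells) would perturb every probability; the floor touches only the
  pathological ones.
* **0/0 terms.** d2S skips words with $\tilde X_w = \tilde Y_w = 0$ (the
  term is 0/0 and contributes nothing to $D$, $A$ or $B$); the Hao
  composition sets $a_w = 0$ where the $(k-2)$-order expectation is 0; S2
  uses the convention $0 \ln(0/p) = 0$ and natural logarithms.
* **Determinism.** All summations run in fixed word-index order
  (lexicographic, $A<C<G<T$, leftmost base most significant — the order
  is recorded in every signature file header so dialects are detectable);
  matrices are stored at full double precision; every random step takes
  an explicit integer seed, and repetition seeds are derived from a
  master seed by a fixed scheme so any single repetition can be re-run in
  isolation.
* **UPGMA ties.** Average-linkage merging is deterministic under exact
  distance ties: candidate pairs are keyed by the lexicographically
  smallest original label in each cluster and the lowest pair wins.
  Merge heights are half the cluster distance, making leaf-to-root depths
  equal (ultrametric) by construction.
* **PCoA.** Classical scaling ($-\frac12$ double-centered squared
  dissimilarities, symmetric eigendecomposition); coordinates are
  returned for positive eigenvalues only, and negative eigenvalues are
  reported, not corrected. The first-axis goodness of fit divides by the
  sum of positive eigenvalues by default; `gof = "absolute"` selects the
  $\sum|\lambda_i|$ convention, since reported GOF values in the
  literature do not always state which was used.
* **Gradient correlation** uses $|SRCC|$ because the orientation of a
  principal coordinate is arbitrary.

## Open design decisions

* **"Complement" is implemented as reverse complement**, the biological
  convention for reading the opposite strand. For the symmetric count
  vector the literal (unreversed) complement would give identical
  signatures, so the choice is observationally equivalent downstream.
* **S2 pairing.** Whether each sample's observed frequencies are scored
  against its own or the partner's Markov probabilities is ambiguous in
  the measure's usual statement. The cross form (partner's probabilities)
  is the default — it is the form under which identical samples score the
  minimum — and the self form is available via `cross = FALSE`.
* **L-type distances operate on relative frequencies,** not raw counts:
  community samples differ in read totals by orders of magnitude, and
  raw-count Manhattan/Euclidean/Chebyshev distances would largely measure
  library size.
* **Tree comparison.** The symmetric difference defaults to rooted
  clusters (each internal node read as its set of descendant leaves,
  singletons and the full set excluded), which respects the order of
  hierarchical clustering; `mode = "splits"` gives the unrooted
  Robinson–Foulds variant for compatibility with external tools. Both
  ignore branch lengths and accept multifurcations.
* **Recovery scoring against polytomous references.** A planted reference
  that is a star of groups has exactly $G$ nontrivial clusters, while a
  binary clustering of $n$ samples has $n-2$; their two-sided symmetric
  difference therefore has a floor of $n-2-G$ even at perfect recovery.
  `cluster_recovery()` reports the one-sided count of planted clusters
  missing from the estimated tree, the statistic that is 0 exactly when
  every planted group forms a clade; the two-sided score remains the
  right tool for *comparing* two scores on the same reference (e.g.
  before/after error injection).
* **Duplicate reads are kept.** Deduplication would conflate expression
  abundance with sequence diversity, and abundance is signal here.

## What the synthetic generator emulates — and what it does not

`make_source_pools()` creates $G$ communities as order-$r$ Markov chains:
a shared base transition table (rows Dirichlet-distributed,
concentration 5, so compositions are realistic rather than extreme) is
mixed per pool with an independent random table at weight
$\delta \in [0, 0.5]$, and each pool regenerates its own transcripts and
draws independent Dirichlet expression weights. Divergence $\delta$ thus
perturbs *sequence composition* while the weights perturb *expression
abundance* — the two axes along which real metatranscriptomes differ.
`sample_reads()` draws reads transcript-proportionally to expression,
with uniform start positions and Normal (optionally fixed) lengths;
`make_gradient_panel()` mixes two pools read-by-read at given fractions;
`inject_errors()` applies a homogeneous per-base error model.

The defaults used throughout the test suite are the study conditions:
4 groups x 5 samples at 2,000 reads x 150 bp with $\delta = 0.3$ for
group-structure experiments (100 seeds, scored at full depth and at 10%
subsampled depth); 4 mixture levels x 2 replicates at 2,000 reads for
gradient experiments; 1% indel + 0.1% substitution for error-robustness
experiments (100 seeds); and 200 pairs of 500 reads x 100 bp order-0
sources for the range-bound checks. These sizes keep a full run of the
suite within tens of minutes on one CPU while leaving the planted effects
far from the decision boundaries.

What the generator does **not** emulate: homopolymer/flow-cycle error
structure of real pyrosequencers (the injector is homogeneous per base),
quality scores, paired-end layouts, chimeras, contamination, or the
phylogenetic correlation structure of real communities (pools diverge
independently from one base chain). Passing tests therefore demonstrate
that the statistics, the clustering and the protocols behave as specified
on data with planted truth — not that any particular real dataset will
cluster perfectly.

## Known limitations

* Memory is the binding constraint for large $k$: a single $k = 12$
  signature is ~134 MB; no sparse representation is attempted because the
  centered statistics are dense by construction.
* Markov orders above 3 and smoothed/interpolated background models are
  out of scope.
* The p-values sometimes attached to symmetric-difference scores in the
  literature have no generally described procedure and are not computed.
* FASTQ qualities are parsed and ignored; no quality filtering or
  trimming is performed.

## A compact end-to-end run

```{r example, eval = FALSE}
panel <- make_group_panel(n_groups = 4, samples_per_group = 5,
                          n_reads = 2000, len_mean = 150, seed = 1)
dm <- pairwise_matrix(panel$samples, "d2s", k = 6, order = 0)
tree <- upgma(dm)
cluster_recovery(panel$reference, tree)$n_missing  # 0 at perfect recovery

sub <- lapply(panel$samples, subsample_reads, rate = 0.1, seed = 99)
cluster_recovery(panel$reference,
                 upgma(pairwise_matrix(sub, "d2s", 6, 0)))$n_missing
```
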