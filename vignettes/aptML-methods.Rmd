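---
title: "Machine-learning-guided particle display: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-learning-guided particle display: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aptML implements the computational side of machine-learning-guided
particle display (PD) screening of DNA aptamer libraries: partitioning a
library by affinity across a stringency ladder, training
sequence-to-affinity neural networks on the sequenced pools, walking
seed sequences uphill on the learned landscape, and truncating
candidates to minimal high-affinity cores. Because the wet-lab half of
the loop cannot run on a desk, the package ships a particle-display
simulator with a known ground-truth affinity oracle, so every stage is
exercisable and testable end to end.

# The screening physics

A bead displays many copies of one aptamer. At target concentration
$[T]$ the bound fraction follows the single-site isotherm

$$\mathrm{Fr} = \frac{[T]}{[T] + K_D},$$

and bead fluorescence is $F = F_\max \cdot \mathrm{Fr}$. Sorting with a
collection gate at $F \ge F_\max/3$ after incubation at $[T]$ therefore
collects exactly the aptamers with $K_D \le 2[T]$: the gate and the
concentration jointly define an affinity threshold. A fourfold ladder of
concentrations (256, 64, 16, 4 nM by default) yields the thresholds
512, 128, 32 and 8 nM. `bindingFraction()`,
`kdThresholdForConcentration()` and `stringencyLadder()` encode this
arithmetic; the gate boundary is inclusive ($F \ge F_\max/3$), matching
the gate definition rather than the one loose "greater than" phrasing.
$F_\max$ is normalized to 1 internally; all intensities are fractions
of it.

`fitKd()` recovers $K_D$ and $F_\max$ from a titration curve by
Levenberg–Marquardt least squares (via minpack.lm), and
`assignApproximateKd()` implements the coarse interval rules
($F \le F_\max/5 \Rightarrow K_D > 4[T]$;
$F_\max/5 < F \le F_\max/3 \Rightarrow 2[T] < K_D < 4[T]$;
$F > F_\max/3 \Rightarrow K_D < 2[T]$), intersecting per-concentration
intervals into the tightest consistent one. Inconsistent intervals
(possible under noise) return the spanning hull with a conflict flag
rather than an error.

# The simulator and its oracle

`affinityOracle()` stands in for the unknown true fitness landscape. A
sequence starts at a 10 µM baseline $K_D$; containing the planted 7-nt
core motif (`TGGATAG` by default, echoing the motif recovered in NGAL
screens) divides $K_D$ by a configurable fold (default 100×, i.e.
100 nM); optional per-k-mer weights act log-additively; and lognormal
noise (sdlog 0.5 by default) is hashed deterministically from the
sequence so the landscape is fixed: the same sequence always maps to
the same $K_D$. The noise grades affinities so that motif carriers
straddle the 128 nM and 32 nM thresholds instead of forming a binary
class, while the 100-fold motif effect dwarfs the noise (a planted
motif lowers $K_D$ essentially surely).

`simulateExperiment()` emulates one or more sort-amplify rounds:
per-bead fluorescence noise is multiplicative Gaussian with
configurable CV (default 0.1; the assay itself does not specify a
noise model), gate crossing is drawn binomially per sequence with the
exact per-bead crossing probability, every positive and negative pool
is sequenced by a multinomial draw over beads, and with two or more
rounds the round-1 positive pools are mixed at equal total bead mass
(1:1) and resampled abundance-proportionally into the round-2 input.
By default 10% of the library carries the planted motif — a deliberate
desk-scale enrichment of the high-affinity component (real libraries
carry far fewer binders; at 2,500 sequences a realistic rate would
leave no positives to learn from). Expected bead coverage (default 50
reads per sequence present in a pool) ties sequencing depth to the
labels' reliable-detection rule. One experiment-level seed fans out
into per-stage streams (`deriveSeed()`), so any stage can be re-run
independently and reproducibly.

What the simulator does *not* model: emulsion-PCR bias, polymerase
error, bead polyclonality, antibody-labeling kinetics, sequencing
error, or secondary-structure effects. Passing tests on simulated
screens therefore demonstrates that the algorithms are correct and the
loop is self-consistent — not that the models would reach any
particular performance on real NGS data.

# Clustering and train/test hygiene

Sequencing error makes near-duplicate reads of one underlying aptamer,
so models must never see a test sequence's neighbor during training.
Sequences are clustered on the graph linking pairs within Levenshtein
distance 5 (inclusive): candidate pairs come from an inverted 6-mer
index under cosine distance, candidates are verified by explicit
Levenshtein distance (`utils::adist`), and connected components
(igraph) become clusters. Each cluster's representative is its
highest-count member, ties broken lexicographically.

The candidate-stage cosine threshold matters only through one
property: the candidate set must be a superset of all true neighbor
pairs. A pair of 40-mers at edit distance 5 can share as few as ~5 of
35 6-mers, i.e. cosine distance up to ~0.86 in the adversarial case;
measured over planted mutant pairs at distance ≤ 5 the observed
distances reach ~0.72. The default threshold is therefore 0.9 —
deliberately loose, since false candidates are cheap (verification
discards them) while a missed true neighbor silently leaks clusters
across folds. The equivalence of the full pipeline with the naive
$O(n^2)$ graph is asserted against a brute-force union-find oracle in
the test suite.

At scale, an all-pairs pass over everything is intractable, so
`clusterWithProjection()` clusters exactly only the multi-read
sequences (summed count > 1, padded with singletons up to a cap;
default $10^5$ at desk scale) and projects every remaining sequence
onto its nearest verified all-pairs cluster — smaller Levenshtein
distance first, then smaller cluster id — or into a fresh singleton.
Projected sequences do not link to each other; that is the
approximation.

`splitFolds()` shuffles clusters with the seed and deals them
round-robin into five folds, the first fold (20%) being the test set.
No cluster ever spans folds; a giant cluster collapsing the split
triggers a warning.

# Labels, SuperBin and concordance

A sequence is *positive* at a stringency when it is reliably detected
in the positive pool — sequencing count at least 20% of the pool's
expected bead coverage — and more prevalent there than in the negative
pool by normalized sequencing fraction. The mirrored rule (the
methodology only defines the positive side) labels *negative*;
everything else is *ambiguous*. Normalization is per-pool by default
(fractions sum to one per pool and are comparable across pools); a
per-experiment switch exists.

`superBin()` collapses the per-stringency ternary labels into one
number: passing the first $p$ consecutive stringencies (weakest first)
gives level $2p$, plus one if the next stricter level is ambiguous
(borderline), yielding levels 0–6 for a three-stringency screen. The
exact level semantics are a reconstruction — only the seven-level
intent and the exclusion rules are fixed — so the mapping is isolated
in one function. Sequences positive at some level but negative at a
weaker one (conflicts) and fully ambiguous sequences are excluded.

`concordance()` reports, per stringency, the fraction of its positives
that are positive at every weaker level. A noise-free screen nests
perfectly (all fractions 1); levels with no positives are vacuously
concordant.

# Models

Inputs are 500-dimensional: a 160-value one-hot block (40 positions ×
4 bases, fixed A, C, G, T order) concatenated with overlapping k-mer
counts for k = 1..4 (4 + 16 + 64 + 256 = 340 values). Three output
formulations share this encoding:

* **Counts** predicts the normalized sequencing fraction in every
  pool, through a *latent-affinity* head: the hidden layers produce one
  scalar affinity, which maps to each pool output through a single
  trained multiplier. The affinity score of a sequence is the sum of
  its predicted fractions in the two highest-stringency final-round
  positive pools. A designated score pool must hold non-zero counts
  for at least 1% of sequences (and ≥ 5) — an unpopulated strictest
  pool would contribute pure noise to the ranking.
* **Binned** predicts the ternary label per stringency (positive = 1,
  negative = 0); ambiguous entries are masked out of the loss rather
  than coded 0.5, so they contribute no gradient. Scores are the
  stringency-rank-weighted sum of outputs.
* **SuperBin** predicts the single 0–6 level; excluded sequences are
  dropped from training. The score is the raw output.

All formulations train with mini-batch squared-error regression.
Selected hyperparameters: batch 64 throughout; Counts lr 0.00138;
Binned lr 0.00388, momentum 0.737; SuperBin lr 0.00203, momentum
0.498; two ReLU hidden layers (64, 32) by default, with 0–3
convolutional layers available over the one-hot block (the k-mer block
joins at the first dense layer). When positives exist, each batch is
topped up so they make at least 10% of it; for Counts, "positive"
means summed raw count across positive pools of at least 20% of
expected coverage (the labels' detection rule — an absolute count
threshold is depth-dependent and degenerates under the simulator's
symmetric pool depths).

Numerical choices, all measured on simulated screens: targets are
z-standardized per output over unmasked training entries (predictions
are mapped back to original units); gradients are clipped to global
norm 5, without which the heavy-tailed standardized count targets
destabilize momentum SGD; and the Counts preset defaults to **Adam**
at its selected learning rate, because plain momentum SGD at that rate
leaves the latent head's multiplicative bottleneck essentially at its
initialization (held-out AUC ~0.55 after 80 epochs, versus ~0.98 in
20 epochs under Adam; the same SGD preset trains a fully connected
head to ~0.99, isolating the bottleneck as the obstacle). Binned and
SuperBin default to momentum SGD; either optimizer can be requested
for any formulation. Training is deterministic given its seed.

Evaluation uses rank-based AUC with ties averaged. `aucTopFraction()`
ranks against membership in the top 1% of non-zero reference values;
`stringencyAuc()` takes as positives the concordant positives at a
level and as negatives the rest of the evaluated set. A seeded random
search (`hyperparameterSearch()`) stands in for a managed tuning
service.

# Walks and seed screening

`guidedWalk()` iterates mutate–score–select for five rounds: 10,000
mutants per round (desk-scale runs use fewer), each up to 4
substitutions from a uniformly chosen parent (the "0–2 substitutions"
phrasing elsewhere describes the same protocol more loosely; 4 is the
procedural definition and is configurable). The substitution count is
drawn uniformly on 0..max, positions without replacement, replacement
base uniform over the three alternatives. The top five mutants per
round are emitted as candidates and the top 200 become the next parent
set (so emitted candidates remain eligible parents). Ties always break
score-descending then lexicographic. `randomWalk()` mirrors the
sampling exactly but selects uniformly at random, so the only
difference is model guidance. `screenRandomSeeds()` streams uniform
random 40-mers in constant memory and keeps the top fraction (0.0005%
of $10^9$ in the full-scale protocol). `evaluateWalks()` scores
emitted candidates against an oracle per ladder threshold.

# Truncation and motif discovery

`scanCores()` embeds every subsequence of lengths 15, 19, 23, 27, 31,
35, 39 at every admissible position in all four homopolymer
backgrounds — $4(40-l+1)$ variants per core of length $l$, pure
homopolymers only — and records the score distribution. `rankCores()`
orders cores by maximal median or minimal variance (plus a
minimal-median sanity mode), ties by length then lexicographically.
On the simulator's landscape the planted motif is recovered inside the
top-ranked core at every scanned length.

`differentialKmerEnrichment()` replaces PWM/EM motif discovery with a
direct screen: per k-mer (k = 4..8) log-odds of occurrence frequency
in positives versus background with pseudocount 1, and a one-sided
Fisher exact test on presence/absence computed as a vectorized
hypergeometric tail (identical to `fisher.test(alternative =
"greater")`, verified in the tests), Bonferroni-corrected over all
$4^k$ k-mers. The consensus is the most significant k-mer overall,
with log-odds breaking ties — selecting by log-odds alone is fragile,
since a rare variant absent from the background can out-log-odds a
motif present in every positive sequence while being orders of
magnitude less significant. This is deliberately a simplification: it
finds exact enriched words, not degenerate position-weight motifs.

# Problem sizes and determinism

The shipped tests and the acceptance script run entirely on simulated
data sized for a single CPU: 2,500-sequence libraries (2,000 training
sequences after the cluster split) for model evaluation, 500 sequences
for the clustering-equivalence check, 50 paired seeds at 300 mutants ×
5 rounds for the walk comparison, and 100 replicates for the noisy
$K_D$-fit calibration. Every stochastic component draws from a stream
derived from one experiment seed, so reports regenerate
bit-identically. The demo (`runDemo()`) chains all stages at a reduced
scale and completes in well under a minute.

# Limitations

The Counts formulation's absolute predictions depend on pool depth;
only its ranking is meaningful across experiments. The SuperBin level
semantics and the negative-label rule are reconstructions (isolated in
single functions). The simulator's motif-dominated landscape is far
easier than a real binding landscape — held-out AUCs near 0.99 here say
nothing about AUCs attainable on experimental screens. Secondary
structure is not modeled anywhere; an external fold-energy scorer can
be plugged in as a walk/truncation scorer but none ships with the
package.
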