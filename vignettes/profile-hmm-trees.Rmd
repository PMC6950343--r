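---
title: "Co-emission alignment of profile HMMs and UPGMA family trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-emission alignment of profile HMMs and UPGMA family trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prcx` compares protein families represented as profile hidden Markov
models (pHMMs) and organizes whole libraries of them into ultrametric
trees. This vignette explains the model behind each stage, the tunable
parameters and their defaults, the numerical conventions, and what the
validation on simulated data does and does not establish.

## The pair-HMM co-emission model

A pHMM in the plan-7 architecture has, per match node, a 20-dimensional
match emission distribution, an insert emission distribution, and seven
transition probabilities (M→M, M→I, M→D, I→M, I→I, D→M, D→D). Two columns
are compared by their *co-emission* log-odds against a shared null model
$f$:

$$S(q_1, q_2) \;=\; \log_2 \sum_a \frac{q_1(a)\, q_2(a)}{f(a)},$$

which is 0 when both columns equal the background, $\log_2 20 \approx 4.32$
for identical point masses under a uniform null, and $-\infty$ for
orthogonal point masses (floored, see below). Two whole models are aligned
over the standard five pair states:

* **MM** — both models emit a match column; scores $S$ plus the product of
  both M→M-type transitions;
* **MI / IM** — one model advances through match states while the other
  idles in an insert; only transition weights are charged. Insert emissions
  are *not* co-emitted: inserts are near-background, and co-emitting them
  mostly injects noise into the score. (The recursion structure would admit
  an emission term; the package deliberately leaves it out.)
* **DG / GD** — one model passes a match column through a delete state
  while the other contributes no move.

Every pair step is weighted by the product of the two component models' own
transition probabilities, so the pair model inherits each pHMM's gap
structure rather than imposing external gap penalties. The **forward**
score log-sum-exps over all paths; **Viterbi** takes the best path and can
return its trace. In *local* mode any MM cell may start or end a path at no
cost; in *global* mode paths are anchored through the BEGIN and exit rows.
The local forward score is the "simple" co-emission score used for
distances; whether a best-path or summed variant is the better default is
genuinely open, so both are exposed and `score = "forward"` is the default
(summing is the more faithful probability statement and is smoother under
small model perturbations).

All recursions run in log2 domain in compiled code; models up to several
thousand columns stay finite (stress-tested at L = 2000). Scores are
reported in bits.

### Numerical conventions

* Co-emission scores are floored at **−16 bits** (`floor_bits`), so
  orthogonal point-mass columns yield a large finite penalty rather than
  $-\infty$; the same floor applies inside the alphabet substitution
  matrix before integer scaling.
* The shared null for a pair is the normalized average of the two models'
  own backgrounds; a common null is required for the kernel to be
  symmetric. Each model's background is its file's `COMPO` line when
  present, otherwise the Robinson–Robinson frequencies (`aa_background()`).
  Whether to trust `COMPO` is exposed as `read_hmmer3(use_compo = )`.
* `reverse_score()` subtracts the score against the position-reversed
  target — a cheap composition-bias normalization. Reversal mirrors
  emission rows and transition rows; it is an involution by construction.

### Verification

The dynamic program is checked against `enumerate_pair_alignments()`, a
shipped brute-force enumerator of *all* pair-HMM paths (feasible for
models of length ≤ 3). The test suite and the acceptance script fuzz
hundreds of short model pairs in both modes and require agreement to
1e-9 bits, along with exact score symmetry and forward ≥ Viterbi.

## Building pHMMs from sequences

`build_hmm()` converts a single sequence or an aligned FASTA into a valid
profile:

* **Match columns**: gap fraction < 0.5 (`match_threshold`), the standard
  convention.
* **Sequence weights**: position-based Henikoff weights over match
  columns, normalized to sum to one — duplicate sequences therefore
  collapse exactly onto the single-sequence model.
* **Effective sequence number**: `N_eff = exp(mean column entropy)` in
  nats (1 for a single sequence, up to ~20 for maximally diverse columns),
  switchable to a unique-row count (`neff_method`).
* **Pseudocount admixture**: τ = min(1, c / N_eff) with **c = 0.9** by
  default, so a single sequence receives a strong prior (τ = 0.9) and deep
  alignments are left nearly untouched. `params$tau` overrides the rule
  outright. The emission row is (1−τ)·observed + τ·pseudocount.
* **Transitions**: weighted match/insert/delete event counts along each
  row's implied state path, Laplace-smoothed with α = 0.1 per outcome
  (small, because weights sum to 1); the exit row forbids M→D and D→D.
  Plan-7 has no I↔D edges, so inserts flanking a deletion fold into the
  direct step.
* **Insert emissions** are fixed at the background.

Two pseudocount families are implemented. *Substitution* pseudocounts push
the observed frequencies through a conditional matrix derived from BLOSUM62
(half-bit log-odds joined with the background and renormalized).
*Context-specific* pseudocounts score the window of weighted counts around
each column against a library of window profiles (multinomial
log-likelihood plus log prior), and mix the contexts' central columns by
posterior responsibility. The library format is plain text (`K w` header,
then prior + w×20 rows per context), and `train_context_library()` learns a
small library by k-means over profile windows so no external data is
needed.

One subtlety is worth recording: a window-1 context library whose contexts
are the substitution-profile rows does *not* reproduce substitution
pseudocounts in general — the context route applies the conditional model
twice (once in the responsibilities, once in the mixture), so exact
equality holds only for idempotent conditional models. The equivalence is
tested where it is exact (rank-1/projection models and the degenerate
single-context library), which still exercises both code paths end to end.

## The discretized-alphabet prefilter

All-vs-all comparison is quadratic in library size with an expensive inner
loop. The prefilter replaces each model by a string over a small
**column-state alphabet**: K representative emission distributions
(default **K = 219**, the established discretized-profile alphabet size),
trained by k-means on probability columns in square-root coordinates
(Hellinger-like geometry) under a fixed seed. Each match column maps to the
state with maximal co-emission log-odds (ties to the lowest index). States
are compared by the integer substitution matrix

$$S(a, b) = \mathrm{round}\big(\text{scale} \cdot \log_2 \sum_x p_a(x)\,p_b(x)/f(x)\big),$$

symmetric by construction, at scale 2 (half-bit units). Strings are scored
by affine-gap Smith–Waterman (gap open 6, extend 1 in matrix units — i.e.
3 bits to open, 0.5 bits to extend, conventional for profile-letter
alignment; a gap of length g costs open + g·extend). Candidate pairs are
kept by absolute threshold or per-query top-N — the acceptance rule is not
fixed by precedent, so both are offered, with `threshold` as the default
mode surface. Self pairs are always kept and the kept set is symmetric.
Rejected pairs are assigned the maximum observed distance: UPGMA needs a
complete matrix, and being filtered out is itself evidence of
non-homology.

The package trains its default alphabet from an internal simulated-profile
corpus under a fixed seed (`default_alphabet()`), so no external alphabet
file is required; any library in the text format with w = 1 can be loaded
instead (`read_alphabet()`). Bit-compatibility with externally shipped
alphabets is a non-goal.

A striped/SIMD Smith–Waterman would change none of the scores; the
contract here is the exact affine-gap score, implemented in portable C++
and verified against a brute-force alignment enumerator on short strings.

## Distances and UPGMA

Scores become distances by self-score normalization
$d(i,j) = 1 - \max(0, s_{ij}) / \max(s_{ii}, s_{jj})$, clipped to [0, 1]:
identical models land at 0, non-positive scores at 1. The transform is
pluggable (`score_to_distance(transform = )`) so an alternative
normalization can be dropped in without touching the tree code.

UPGMA merges the closest pair, places the new node at height d/2, and
updates distances as size-weighted means. The implementation keeps a
nearest-neighbour candidate per cluster and rescans a row only when its
candidate is consumed by a merge — the accelerated scheme used by large
aligners, O(n²) total in the typical case. Ties are broken
deterministically by the lexicographically smallest pair of original leaf
indices (a cluster carries the smallest index among its members):
without a fixed rule, tied merges make results environment-dependent and
untestable. The naive full-rescan O(n³) implementation under the same tie
rule ships as `upgma_naive()`, and the suite requires *identical* merge
tables and heights on hundreds of random matrices (tie-prone integer
matrices included), plus agreement with `phangorn::upgma()` on tie-free
input. Every output is ultrametric by construction; tests bound the
root-to-leaf spread at 1e-9.

Output formats: square PHYLIP (relaxed whitespace-delimited labels by
default; a strict 10-character dialect with uniqueness suffixes behind
`strict = TRUE`) and Newick with branch lengths at 6 significant digits
and single-quoting of labels containing metacharacters.

## The pipeline and its fallbacks

`run_pipeline()` chains cluster → align → build → score → tree and writes
every artifact plus a manifest of per-stage counts, byte-identically under
a fixed seed. The built-in clustering is greedy: sequences in decreasing
length order join the first cluster whose representative they match at the
identity threshold (global alignment identity = matches / alignment
length, via Biostrings), default **0.70** — the standard family-level
grouping identity. Multi-member clusters are aligned by center-star
progressive alignment around the representative. Both are deliberately
simple, testing-grade components: production users with CD-HIT or a real
MSA program can run those upstream and feed the results in; reimplementing
them is out of scope. Clusters of one ("singletons") get single-sequence
pHMMs, so every input sequence ends up in exactly one model.

`classify_query()` scores a new sequence (or prebuilt profile) against the
library with the local forward score and reports ranked hits plus the best
hit's smallest enclosing clade when a tree is supplied.

## What the simulator emulates — and what it does not

`simulate_families()` evolves a background-drawn root sequence down a
Newick guide tree with i.i.d. per-site substitution (probability
$1 - e^{-b}$ per branch of length b, uniform replacement among the other
19 residues) and Poisson indels of geometric length, then emits several
sequences per leaf with extra tip divergence. The default spec — four
families, guide tree `((famA:0.5,famB:0.5):0.3,(famC:0.5,famD:0.5):0.3);`,
root length 80, 4 sequences per leaf, tip branch 0.25, indel rate 0.01 —
produces within-family identities around 55% (below the 70% clustering
threshold, so models are built per sequence) and cross-family identities
around 20–35%: deep enough that family structure is non-trivial, shallow
enough that a correct method should recover it. The end-to-end criterion
asks for monophyly of all four families in at least 19 of 20 seeded
replicates; when sequences do cluster, cluster leaves are mapped back to
their member families first.

The substitution model is intentionally crude: no realistic exchange
matrix (WAG/LG), no site-rate heterogeneity, no domain shuffling or
composition bias. Passing these tests therefore demonstrates that the
machinery — building, scoring, distances, trees — is internally correct
and recovers a clean phylogenetic signal; it does not demonstrate accuracy
on real superfamilies, where alignment quality and model depth dominate.

## Problem sizes used in validation

The shipped checks fuzz ~500 short model pairs (L ≤ 3) against exhaustive
path enumeration, compare fast and naive UPGMA on 200 matrices of up to 50
taxa, and run the four-family pipeline for 20 replicate seeds; the
acceptance script repeats the same measurements at moderately reduced
counts (200 pairs, 60 matrices, 10 replicates). These sizes were chosen to
exercise every code path and tie case while keeping a full validation run
in the low minutes on a single core; the quantities measured are
scale-free (agreement rates and maximal deviations), so larger sizes
change cost, not meaning.

## Known limitations

* Insert emissions are never co-emitted (documented switch-free choice);
  profiles whose signal lives in insert-state composition will be
  under-scored.
* The greedy clusterer and center-star aligner are fallbacks, not
  replacements for dedicated tools; alignment quality bounds model quality.
* Score calibration (E-values) is out of scope; scores are comparable
  within a library, not across databases.
* The distance transform is a normalized-score heuristic, not an
  evolutionary distance; trees are phenetic (UPGMA), assume a molecular
  clock, and inherit its known distortions for rate-variable families.
* DNA/RNA profiles and pre-HMMER3 formats are not supported.
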