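# prcx — profile-HMM comparison and UPGMA trees of protein families

Protein superfamilies (for example the lytic polysaccharide monooxygenase,
LPMO, enzymes) diverge far beyond the reach of sequence–sequence alignment:
members of different subfamilies can share well under 30% identity while
remaining clear structural and functional homologues. At that depth the
natural unit of comparison is not a sequence but a **profile hidden Markov
model (pHMM)** of each family, and the natural way to relate whole families
is to align profiles against profiles. `prcx` builds family-level
phylogenies this way: it reads and writes HMMER3 profiles, scores every pair
of pHMMs by co-emission alignment, converts the scores to distances, and
agglomerates them into an ultrametric UPGMA tree, all from R or from a thin
command-line wrapper.

## The method

**Co-emission scoring.** Two profile columns *q₁*, *q₂* are scored by the
log-odds that they emit the same residue relative to a null model *f*:

    S(q1, q2) = log2( Σ_a q1(a) · q2(a) / f(a) )   [bits]

Whole models are aligned over the five-state pair HMM
{MM, MI, IM, DG, GD}: MM co-emits a column pair with the kernel above, MI/IM
advance one model through an insert state (transition weight only), DG/GD
pass a match column through a delete. Each pair step is weighted by the
product of the two models' own transition probabilities. The **forward**
score sums over all alignments (log-sum-exp); the **Viterbi** score takes
the single best path. The local forward score is the "simple" co-emission
score used for tree building; both variants and a global mode are exposed
(`pair_forward()`, `pair_viterbi()`).

**Prefiltering.** For large libraries, profiles are discretized to a
219-letter column-state alphabet (k-means over probability columns in
square-root coordinates, `train_alphabet()` / `default_alphabet()`), and
candidate pairs are selected by integer Smith–Waterman over the states'
co-emission log-odds substitution matrix (`smith_waterman()`,
`prefilter_pairs()`). Pairs failing the filter skip the full dynamic
program and are imputed with the maximum distance.

**Trees.** All-vs-all scores *s(i,j)* become distances by self-score
normalization, `d(i,j) = 1 − max(0, s(i,j)) / max(s(i,i), s(j,j))`, clipped
to [0, 1], and the distance matrix is agglomerated by UPGMA with
per-cluster nearest-neighbour candidate lists (O(n²) total work, the
MUSCLE / Clustal Omega strategy) under a fully deterministic tie rule.
Outputs are a square PHYLIP matrix and a Newick tree; a naive O(n³)
reference (`upgma_naive()`) and a brute-force path enumerator
(`enumerate_pair_alignments()`) ship in the package for independent
verification.

**Building pHMMs.** `build_hmm()` turns a single sequence or an aligned
FASTA into a profile: match columns at gap fraction < 0.5, position-based
Henikoff sequence weights, and pseudocounts mixed by
τ = min(1, c / N_eff) — either classic BLOSUM62 substitution pseudocounts
or sequence context-specific pseudocounts driven by a context library
(`context_pseudocounts()`, trainable with `train_context_library()`).

## Worked example

Simulate four protein families down a known guide tree, run the whole
pipeline, and check the tree:

```r
library(prcx)
sim <- simulate_families(family_spec(seed = 42))   # 4 families x 4 sequences
res <- run_pipeline(sim$sequences, "prcx_out", pipeline_config(seed = 42))
res$manifest
#>   stage                 count
#> 1 sequences                16
#> 2 clusters                  0
#> 3 singletons               16
#> 4 hmms                     16
#> 5 pairs_scored            120
#> 6 pairs_prefiltered_out     0
```

At the default 70% clustering identity all 16 simulated sequences stay
singletons (their within-family identity is ~55%), so 16 single-sequence
pHMMs are built and 120 pairs scored. Two models of the same family score
far above a cross-family pair:

```r
compare_hmms(res$models[[1]], res$models[[2]])   # famC_s01 vs famC_s02
#>   query    target   qlen tlen mode  forward_bits viterbi_bits
#> 1 famC_s01 famC_s02   83   83 local         29.4         18.8
compare_hmms(res$models[[1]], res$models[[16]])  # famC_s01 vs famD_s03
#> 1 famC_s01 famD_s03   83   78 local         18.5         8.50
```

and the UPGMA tree groups each family as a clade:

```r
write_newick(res$tree)
#> ((((famC_s01:0.2773,(famC_s03:0.258359,famC_s04:0.258359):0.0189413):...
```

`prcx_out/` now holds the HMM library (`library.hmm`, readable by HMMER),
the score table, the PHYLIP distance matrix and the Newick tree. An unknown
sequence is placed with `classify_query(seq, res$models, tree = res$tree)`,
which ranks all models by forward bits and reports the best hit's clade.

The same workflow is scriptable:

```sh
Rscript inst/cli/prcx.R run --in families.fasta --out prcx_out --seed 42
Rscript inst/cli/prcx.R classify --query q.fasta --hmms prcx_out/library.hmm
```

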