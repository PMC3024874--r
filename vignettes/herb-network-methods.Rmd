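---
title: "Mining herb combination rules: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining herb combination rules: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

This vignette is the package's own account of the methods it implements:
the scoring model and its assumptions, the parameters that matter, what
the synthetic generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## Position encoding

A formula is an *ordered* list of herbs; order encodes the traditional
role hierarchy (Master, Adviser, Soldier, Guide), with earlier positions
more central. A corpus becomes an integer matrix **A** (`a_ij` = listed
position of herb *j* in formula *i*, 0 = absent) and the normalized
matrix **B** with `b_ij = a_ij / k_i`. Dividing by the formula size makes
positions comparable across formulae of different lengths: the last-listed
herb always has `b = 1`, and the nonzero entries of row *i* are exactly
`{1/k_i, ..., 1}`.

Two conventions are under-determined by the data model and fixed here:

- **Duplicate herbs within a raw record** are rejected at load time with
  an error naming the record (a duplicated herb makes "the position of
  herb *j*" ill-defined); `dedupe = TRUE` instead keeps the first, most
  important position.
- **Herb ids** are assigned in first-appearance order across the file,
  not alphabetically, so the encoding of a given file is reproducible and
  independent of locale collation.

When synonym substitution merges two herbs inside one formula, the
earliest position is kept and positions are compacted to `1..k'` — the
earlier slot is the more meaningful one under the role hierarchy.

## The pair score

For herbs x and y with presence frequencies `P(x)`, `P(y)` and
co-occurrence frequency `P(x,y)` over the `m` formulae:

- default mutual information (bits):
  `MI(x,y) = P(x,y) log2( P(x,y) / (P(x) P(y)) )`, with `MI = 0` when
  `P(x,y) = 0` (the `p log p` limit convention);
- between-herb-distance in formula *i*: `d(x,y,i) = |b_ix − b_iy|`,
  bounded by `[1/k_i, (k_i−1)/k_i]`;
- mean distance `d̄(x,y)`: the arithmetic mean of `d(x,y,i)` over exactly
  the co-occurring formulae (the distance is undefined elsewhere, so the
  denominator is the co-occurrence count);
- score: `S(x,y) = MI(x,y) / d̄(x,y)`.

Two compositions and two MI forms are exposed rather than hard-coded,
because the combination admits more than one formula with the required
qualitative behaviour — `S` must grow with MI at fixed distance and
shrink with distance at fixed MI. `score_form = "product"` uses
`MI · (1 − d̄)`; `mi_form = "joint2x2"` uses the full 2×2
presence/absence mutual information. The pointwise default is preferred
because the full 2×2 MI is also large under *anti*-correlation, which is
the opposite of a herb pair; the ratio default is the simplest form with
both monotonicities. Every ranking records which forms produced it (as
attributes and in the CLI output header). The log base (2) only rescales
scores uniformly and cannot change ranks.

Tunable parameters:

| parameter | default | meaning |
|---|---|---|
| `min_cooccur` | 3 | minimum co-occurrences before a pair is scored; a single co-occurrence gives an unstable distance estimate and a noisy MI |
| `mi_form` | `"pmi"` | MI functional form |
| `score_form` | `"ratio"` | score composition |
| `alpha` | 0.05 | per-pair χ² significance for module membership |
| `top_n` | 100 | edges kept when building the herb network |

The χ² test is the standard Pearson test on the 2×2 presence table, 1 df,
no continuity correction (a Yates-corrected variant would be recorded in
the configuration if enabled; none is by default). Degenerate tables
(a zero margin, e.g. a herb present in every formula paired with another
such herb) return `p = 1` with a `degenerate` flag rather than `NaN`.
Ranking ties are broken by smaller `d̄`, then lexicographic names, so
output order is a pure function of the input.

Raw p-values are used for module membership by default, matching the
per-pair significance convention of hub-module analyses; a
Benjamini–Hochberg option (`p_adjust = "BH"`) is available and recorded
in the graph attributes. The hub module is the one-hop closure: all
significant pairs touching a hub, plus significant pairs among the herbs
so included — closure is not iterated, since the object of interest is
the neighborhood of the hubs, not the significant component.

## Co-module analysis

The multilayer analysis consumes a user-supplied interaction network
(edge-list TSV), gene sets (GMT) and a phenotype-by-feature matrix (TSV);
it never fetches databases.

- **Enrichment**: one-sided Fisher exact test, i.e. the hypergeometric
  upper tail `P(X ≥ overlap)`, per pathway, with BH FDR across tested
  pathways. One-sided because only over-representation is of interest.
- **Closeness**: mean shortest-path length over all cross pairs of the
  two gene sets with distinct endpoints. Disconnected pairs are
  *excluded* from the mean and reported as a coverage fraction rather
  than imputed with an arbitrary large distance — imputation would make
  the statistic depend on a free constant. Self-pairs of genes present in
  both sets (distance 0) are excluded so shared genes cannot trivially
  deflate the mean.
- **Permutation null**: the herb-gene set stays fixed; the disease-gene
  set is redrawn, same size, without replacement from the supplied pool
  of networked disease genes. `p = (r + 1) / (n_perm + 1)` with `r` the
  number of permuted means ≤ observed; the plus-one form never reports
  zero, so an observed value beating all 2000 draws gives
  `p = 1/2001 ≈ 0.0005`.
- **Phenotype similarity**: mean pairwise cosine over the member rows,
  with the analogous permutation test (`r` counts permuted means ≥
  observed).
- **Projections**: two herbs are linked when they share ≥ `min_shared`
  responsive genes (edge weight = shared count); diseases likewise; the
  core genes are those in at least one herb set and one disease set,
  mapped onto the network. Whether the biomolecular layer should also
  include direct network neighbors of the core genes is genuinely open;
  `neighborhood = 0|1` exposes both, defaulting to the shared genes only.

## Synergy scoring

Dose-matrix experiments are scored against the highest-single-agent
additivity reference: the expected combination effect at `(dose_a_i,
dose_b_j)` is `max(effect_a_i, effect_b_j)` at the matched doses (the
matrix design guarantees exact dose alignment, so no interpolation is
performed). Positive excess calls synergy, negative antagonism, with a
dead-band of `tol = 5` percentage points by default — plate-reader
replicates of cell-proliferation assays commonly scatter by a few points,
so a smaller band would call noise. Replicates are expected pre-averaged;
replicate rows in the long input format are averaged per cell.

## The synthetic generator

`generate_corpus()` emulates the statistical structure the miner assumes:

- five **planted pairs** co-occurring in 30% of formulae, adjacent 90% of
  the time — a strong pair signal of the kind classical paired herbs
  show;
- one **guide herb** present in 40% of formulae at a uniformly random
  position — the profile of a ubiquitous supplementary herb, second only
  to the most common herbs by frequency (real corpora put such herbs
  near 38–40%) yet carrying no pairing signal;
- formulae of 4–10 herbs (sizes uniform), remaining slots filled with
  distinct herbs drawn from the 49 non-planted, non-guide fillers.

Restricting fillers to the non-special pool is a deliberate choice: it
makes the planted marginals exactly `co_prob` and the guide marginal
exactly `marginal_freq`, so recovery rates measure the score, not
generator leakage. The defaults (60 herbs, 500 formulae) are the study
condition for the planted-recovery checks; one integer seed fully
determines a corpus. When the included special herbs exceed the drawn
size `k`, `k` grows to fit them (a rare event at the default rates).

What the generator does **not** emulate: herb-frequency heavy tails
(fillers are uniform), correlated formulae (records are independent,
whereas real corpora contain near-duplicate prescriptions), dosage
information, and any semantic relationship between herb roles and
positions beyond the planted adjacency. Passing the recovery tests
therefore shows the score separates planted association from frequency
under clean conditions; it does not certify performance on corpora with
heavy redundancy.

`generate_omics()` produces an Erdős–Rényi (default, edge probability
0.04 over 200 genes) or scale-free interaction network, herb and disease
gene sets whose shared fraction is the `herb_disease_overlap` dial (the
non-shared remainder of each disease set is drawn from outside the
herb-gene pool, so overlap 0 guarantees an empty core), random pathway
sets, and a phenotype matrix with planted similarity blocks: each row is
`s · base_block + (1 − s) · noise` with `s = block_similarity`, so `s = 1`
makes within-block cosines exactly 1.

## Numerical choices and test scale

- `B` is floating point; `a_ij/k_i` is not always exactly representable,
  so equality tests on derived quantities use a 1e-12 tolerance, while
  round-trip IO is checked bit-identically.
- Brute-force oracles (direct loops over formula lists, plain-R BFS) back
  the matrix and igraph paths in the tests; oracle agreement is checked
  on 100 random corpora (≤10 herbs, ≤20 formulae) and 50 random graphs
  (≤50 nodes) — sizes at which exhaustive enumeration is instant.
- Permutation calibration uses 500 null replicates at 200 permutations
  each; planted-pair recovery uses 50 corpus seeds; the end-to-end
  pipeline check runs the default corpus with 200 permutations. These
  sizes give stable pass/fail behaviour at interactive runtimes.
- All randomness flows through explicit integer seeds (`corpus_spec`,
  `net_spec`, the permutation functions); `build_comodule()` seeds once
  and lets both permutation streams advance sequentially, so a single
  seed reproduces the whole result object byte-for-byte.

## Known limitations

- The score treats formulae as independent samples; redundant historical
  variants of one prescription inflate both MI and adjacency.
- Only pairs are scored; triples and larger subsets would need a
  multi-herb distance index and multivariate information measures.
- Closeness compares pooled gene sets; per-herb or per-disease closeness
  is not computed.
- The χ² p-values for strongly associated pairs underflow to the
  distribution tail's floating limit; ranking is by score, so this does
  not affect ordering, but the printed p-values saturate.
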