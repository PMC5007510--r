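---
title: "Methods: profile consensus sequences, score fusion and truncated-ROC evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile consensus sequences, score fusion and truncated-ROC evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudorank)
```

## The problem

Remote homologs — proteins descending from a common ancestor whose
sequence identity has decayed below roughly 30% — usually keep similar
structure and function, but plain sequence alignment no longer finds
them. Two ideas help: (i) replace the raw query sequence by a
representation that carries evolutionary information from its sequence
neighbourhood, and (ii) fuse the ranked hit lists of several
complementary search tools into one list. `pseudorank` implements both,
plus the evaluation machinery used in the SCOP-superfamily benchmark
tradition and a synthetic world in which every component can be tested
offline.

## Profile-based pseudo protein sequences

For a query **P** of length *L*, a multiple sequence alignment of its
homologs (typically produced upstream by an iterative profile search) is
summarised as a frequency profile **M**, a 20 × *L* matrix whose column
*i* holds the relative frequency of each canonical amino acid at query
position *i*. The pseudo protein sequence is the per-column argmax of
**M** — a consensus string that injects the conservation pattern of the
alignment into any downstream tool that accepts plain sequences.

Choices the construction must make, and what this package does:

* **Column indexing.** Profiles are indexed by non-gap *master*
  positions only, so *L* is always the query length. Columns where the
  master row has a gap are dropped.
* **Denominators.** Gaps and non-canonical codes (B, Z, X, U, O, J, `*`)
  are excluded from column counts, so every counted column is a proper
  distribution over the 20 canonical residues (sum 1 ± 1e-9).
* **Argmax ties.** If the master residue is among the tied maxima it is
  chosen (biasing toward the observed sequence); otherwise the
  alphabetically first tied residue. Deterministic by construction.
* **All-zero columns** (seen in malformed PSSMs) fall back to the master
  residue so the output is always a residue string.
* **Two profile routes** are provided because published descriptions do
  not fix one: raw MSA counting (`msa_to_frequency_profile()`) and the
  weighted observed percentages of a PSI-BLAST ASCII PSSM
  (`parse_ascii_pssm()`). PSI-BLAST prints integer percentages whose
  column sums drift from 100 by rounding; parsed columns are
  renormalized so both routes satisfy the same invariants.

## Rank aggregation

Given *k* predictors, each returning for query **P** a list of candidate
targets with raw alignment scores `s_j(p_i)` (higher is better), each
list is min–max normalized per query,

\[ norm_j(p_i) = \frac{s_j(p_i) - \min(s_j)}{\max(s_j) - \min(s_j)}, \]

and combined over the union of returned targets as a convex combination

\[ S(p_i) = \sum_{j=1}^{k} w_j \, norm_j(p_i), \qquad w_j \ge 0,\ \sum_j w_j = 1 . \]

The aggregated list is sorted by `S` descending. Policies where the
formula is silent:

* **Missing targets** score 0 for the predictor that did not return them
  (absence is the weakest evidence a list can offer).
* **Degenerate lists** (all scores equal, including single-hit lists)
  normalize to 1: a predictor's only hits are its best hits.
* **Ties in `S`** break by ascending target id under C collation, for
  bitwise reproducibility.
* Normalization is per query and per predictor, over the full returned
  list (not a truncated top-N).

Because min–max normalization is an increasing affine map, aggregation
is invariant to positive affine rescaling of any predictor's raw scores,
and with one predictor at weight 1 it reduces to the identity on
strictly-ordered lists. Both properties are enforced by tests.

## Evaluation: jackknife and truncated ROC

The benchmark is a set of sequences labelled with a family and a
superfamily, each family inside exactly one superfamily. Under the
jackknife (leave-one-out) protocol every sequence serves once as the
query; its positives are all *other* members of its superfamily and its
negatives everything else. A `--exclude-same-family` mode instead
ignores same-family members (neither positive nor negative), isolating
truly remote positives; the default counts them as positives.

ROC\_n names the area under the true-positive vs false-positive step
curve truncated at the *n*-th false positive, normalized to [0, 1]:

\[ ROC_n = \frac{1}{mP} \sum_{k=1}^{m} TP(k), \qquad m = \min(n, N), \]

where `TP(k)` is the number of positives ranked strictly before the
*k*-th false positive, `P` the number of positives and `N` the number of
negatives. Published usage names ROC1 and ROC50 without a formula; this
is the standard convention of the remote-homology benchmark literature.
Edge policies: positives missing from a ranking count as ranked after
every returned entry and after all false positives; with `N = 0` the
score is the fraction of positives returned; queries with `P = 0` (sole
members of their superfamily) are non-evaluable and excluded from mean
scores. The implementation is verified exactly against a brute-force
step-curve oracle over every labelled ranking of length ≤ 10, and
against a pair-counting AUC oracle at full truncation.

Two summary views mirror common practice: the exceedance curve (fraction
of queries whose score is at least each threshold — an empirical
survival function) and a pairwise per-query comparison with win/tie/loss
counts.

## Weight selection

Published work reports fused weights (e.g. 0.01/0.29/0.70 for a
three-predictor combination) without describing the selection procedure.
Since such weights are multiples of 0.01, this package reconstructs the
step as an exhaustive grid search of the probability simplex
(`enumerate_simplex()`, default step 0.01) maximizing mean ROC1
(mean ROC50 selectable), with ties broken by the earliest point in
lexicographic weight order. The per-query normalized score matrices are
computed once and re-weighted per grid point; a test pins this fast path
to the literal aggregate-then-evaluate route at sampled grid points.

Two caveats are inherent and documented rather than hidden: the search
optimizes on the same benchmark it reports (no train/test split — the
protocol it reconstructs does the same), and at grid resolution several
points can tie. The guarantee that the chosen combination never
underperforms the best single predictor holds *on the training
benchmark*, because the single-predictor vertices are grid points.

## The synthetic world

The generators state a fixed world; they are not tuned to tests.

* **Hierarchy.** Superfamily ancestors are uniform random residue
  strings; family ancestors substitute each site with probability
  `within_superfamily_mut_rate` (default 0.7 — remote-homolog-level
  divergence); members substitute at `within_family_mut_rate` (default
  0.2). A substituted site is redrawn uniformly over all 20 residues, so
  rate 1 yields an unrelated sequence and expected unrelated identity is
  exactly 1/20 — the `background` field records that constant (0.05); it
  is a reference value, not a dial.
* **Scale.** Default 10 superfamilies × 2 families × 4 sequences of
  length 60: seconds on one CPU, while keeping 7 positives and 72
  negatives per query so ROC50 truncation is non-trivial.
* **Scores.** Predictor *j* scores each query–target pair
  `a_j · 1[same superfamily] + N(0, noise_sd)`, independent across
  predictors (defaults `a = 3.0 / 1.5 / 0.0`, `noise_sd = 1`). This is
  the simplest model exhibiting predictor complementarity: equal-signal
  predictors err on different pairs, so averaging them reduces noise by
  √2 and the fused list beats either input — the ensemble premise in
  miniature. The two-predictor ensemble-gain test uses `a = 1.5`,
  chosen a priori as a mid-range separation.
* **MSAs.** `simulate_msa()` keeps the member residue per column with a
  stated conservation probability, else substitutes one of the 19
  others.

What a green test does **not** establish: the generators have no
substitution matrices, indels, rate heterogeneity, length variation or
database-size effects, so passing them says the *algorithms* are
correct, not that published benchmark values are reproduced. Full-scale
SCOP/Astral numbers require the external search engines and databases
and are out of scope by design.

All randomness flows through a fixed Mersenne-Twister configuration
(`normal.kind = "Inversion"`, `sample.kind = "Rejection"`), so every
generated object is bitwise reproducible from its seed across platforms.

## Numerical and degenerate-input policies

* Weights must sum to 1 within 1e-9 (1e-6 at the CLI, then renormalized).
* Equal aggregation scores at evaluation keep the ranking's own
  deterministic order — a single source of order truth.
* Score ties within a raw ranking list keep input order (stable sort).
* E-value-only outputs convert as `-log10(E)` with `E ≤ 1e-300` clamped,
  keeping scores finite and higher-is-better.
* Duplicate hits to one target (multiple HSPs/domains) collapse to the
  maximum score — one score per target, as a rank vector requires.

## Known limitations

* Score-based fusion only; no order-based (Borda/Kemeny) aggregation and
  no learning-to-rank.
* No execution of the search engines themselves: parsers cover BLAST
  tabular, HMMER tblout, HHR and a generic TSV; profile–profile tool
  output is expected pre-converted to the generic TSV. `run_predictor()`
  shells out to user-installed binaries with the documented parameters
  but is never exercised by the test suite.
* The weight search inherits the optimistic bias of optimizing on the
  evaluation benchmark; a holdout protocol is the user's responsibility.
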