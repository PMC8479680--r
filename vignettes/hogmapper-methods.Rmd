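---
title: "Alignment-free subfamily assignment with evolutionarily informed k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free subfamily assignment with evolutionarily informed k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hogmapper)
```

## The problem

Assigning a new protein to a known gene *family* is usually easy; assigning
it to the right *subfamily* is not. Subfamilies are the nested groups that
gene duplications carve out of a family — hierarchical orthologous groups
(HOGs), with the family itself as the root-HOG and each post-duplication
group as a sub-HOG. The common practice of giving a query the subfamily of
its closest sequence (best BLAST/Smith-Waterman hit) ignores the family
tree, and it fails in characteristic ways: a query that branched off before
a duplication has *no* correct nested subfamily, yet its closest sequence
necessarily sits inside one (an **over-specific** assignment); fast or
asymmetric post-duplication evolution can push the closest sequence into the
wrong branch altogether. Because duplicated proteins evolve faster and often
asymmetrically, these cases are common, and over-specific assignment is the
dominant error mode.

`hogmapper` implements an alignment-free alternative: reference proteomes
are pre-processed into a table of *evolutionarily informed k-mers*, and
queries are placed first into a family, then into the most specific sub-HOG
that their k-mer content genuinely supports.

## The k-mer table

All reference sequences are concatenated (one sentinel per protein) and a
suffix array is built by prefix doubling, so all occurrences of a k-mer sit
in one contiguous range. Every k-mer window of canonical residues is encoded
as a base-20 integer over the alphabetically ordered amino-acid alphabet
(`AA` is 0, `AC` is 1, ..., `YY` is `20^k - 1`). Windows containing
non-canonical residues (X, B, Z, U, `*`, gaps) are skipped, both at build
and at query time; the stored sequences are left untouched.

Within each family, a k-mer is attributed to the **last common ancestor**
of the most specific HOGs of the members containing it. The assumption is
that repeated occurrences of the same k-mer inside one family reflect
shared ancestry (homology) rather than independent invention (homoplasy).
When the assumption fails, the error is in the conservative direction: the
k-mer is attributed to a more ancestral HOG than where it arose, which can
only make assignments more general, never more specific. One entry per
(k-mer, family) is kept — the table is a flat buffer of
`(family, ancestral HOG)` pairs addressed CSR-style. The row pointers are
keyed by the sorted set of occurring k-mer codes; the dense `20^k + 1`
offset array is available through `kmer_index()` but is only materialised
for small `k` (a dense index at `k = 6` would spend 256 MB per table for no
functional gain at desk scale).

`k = 6` is the default: with a 20-letter alphabet, 5-mers are already
shared by chance between unrelated proteins at appreciable rates, while
7-mers decay too quickly with divergence; 6 balances specificity against
sensitivity and is configurable everywhere (`k` in [2, 7], so codes fit a
32-bit integer).

## Scores and placement

For a query with `n` distinct k-mers, each candidate family `F` gets a
coarse count `x` (distinct query k-mers with an entry for `F`; only the 100
families with the highest `x` are scored further). The family score is

> `score(F) = max(0, (x - E_F) / (n - E_F))`,  `E_F = n * (1 - (1 - 20^-k)^m_F)`

with `m_F` the number of distinct k-mers in `F`'s table: the excess of
matches over what a random query of the same length would collect against a
reference k-mer set of `F`'s size, rescaled so that a perfect match scores 1
and chance level scores 0. The query is assigned to the best-scoring family
if that score reaches `theta_family` (default 0.05); queries with no
canonical k-mer, or below threshold, are reported unassigned rather than
erroring.

Within the assigned family, each HOG `h` gets a subtree-specific count
`x_h` (query k-mers whose ancestral HOG lies in `subtree(h)`; by the LCA
rule these counts can only shrink from parent to child) and a subfamily
score that captures the *excess of similarity relative to its parent*:

> `s_h = (x_h - E_h) / (x_parent - E_h)`,  `E_h = x_parent * m_h / m_parent`

where `m_h` counts table entries attributed within `subtree(h)`. The null
hypothesis behind `E_h` is "the query belongs to the parent but not to
`h`": such a query's parent-level matches would fall into `h`'s subtree
roughly in proportion to `h`'s share of the parent's entries, so only
persistence *beyond* that share counts as evidence. Two normalizations were
considered for the denominator — the query's total k-mer count `n`, and the
parent-restricted count used here. With `n` in the denominator, scores of
deep sub-HOGs shrink toward zero simply because deep subtrees own few
k-mers, the usable threshold range collapses to a few hundredths, and the
score of a HOG depends on how much unrelated sequence the query carries.
The parent-relative form keeps scores on one scale at every depth (1 when
all parent similarity persists, 0 at chance), which is what makes a single
`theta_sub` meaningful along a whole root-to-leaf path.

Placement selects the root-to-leaf path with the largest sum of clamped
scores (ties to the lexicographically smallest leaf), then descends from
the root while the child's *unclamped* score excess reaches `theta_sub`,
reporting the deepest accepted HOG — the root-HOG itself if the first child
already fails. The unclamped comparison matters only at `theta_sub = 0`:
a child with no supporting k-mer has negative excess and must not be
entered, which is also what makes the self-query guarantee exact — for any
reference protein queried against a table containing it, every one of its
k-mers maps to its own HOG or an ancestor, so the assignment can never
leave the root-to-truth path. Raising `theta_sub` trades specificity for
safety monotonically: a higher threshold never yields a deeper assignment.

An **overlap score** accompanies each assignment: the fraction of query
residues covered by windows of k-mers that match the assigned family and
occur exactly once in the query. Chimeric or domain-level matches show up
as overlap well below 1 even when the family score is respectable.

## The closest-sequence baseline and its configurations

The baseline assigner gives each query the most specific HOG of its
highest-scoring Smith-Waterman match (exact affine-gap DP; BLOSUM62, gap
open 11, extend 1, a gap of length L costing `open + L*extend`; ties to the
smallest protein id). Each (query, closest) pair within a family falls into
exactly one of four configurations: **true subfamily** (same HOG),
**over-specific** (query's true HOG ancestral to the closest's),
**under-specific** (the reverse), or **wrong path** (neither). Queries
whose closest sequence is in a different family are family-level errors and
are excluded from the configuration denominator.

## Two-level validation

Family-level precision/recall follows the benchmark convention: negatives
(random sequences with stated residue frequencies and positive-matched
lengths, or proteins drawn from distinct out-of-scope donor families)
are mixed with leave-one-out positives; at a threshold `t`, false positives
are negatives and wrong-family positives scoring at least `t`; correct
positives split into TP/FN by `t`; wrong-family and unassigned positives
count as FN throughout, so recall is TP over all positives. Curves are
computed on the exact grid of observed scores, and `F1_max` with its
threshold is reported.

Subfamily-level validation is restricted to queries both methods assigned
to the correct family at their family-level `F1_max` thresholds. The
*implicit* scheme treats an assignment as implying all parental
subfamilies: with P and T the non-root HOGs on the root-to-prediction and
root-to-truth paths, a query contributes `|P∩T|` TPs, `|P\T|` FPs and
`|T\P|` FNs (the root itself is never rewarded — only within-family
placement is being assessed). The *stringent* scheme pays nothing for
partial correctness: exact hit = 1 TP; root-level prediction against a
deeper truth = 1 FN; anything else = 1 FP + 1 FN. Thresholds sweep the
stored per-node path scores, so the prediction at `t` is exactly what the
descent rule would have returned with `theta_sub = t`.

## The synthetic world

The generator exists so that every claim above is testable with known
truth, at desk scale, with no external database. What it emulates — and
what it does not — determines what a green test establishes.

* **Species tree.** Ultrametric, unit root-to-tip depth: a designated
  query lineage `S1` diverging at age 0.6, a deep reference outgroup `S2`
  at the root, and a random coalescent backbone `S3..Sn` of depth 0.45.
  This mirrors how subfamily benchmarks pick their held-out proteomes
  (platypus, spotted gar, amphioxus: early-diverging lineages without a
  close sampled relative, against a well-sampled backbone). A plain
  coalescent over all species leaves the query's divergence age to chance,
  and on many draws almost no duplication postdates it — the over-specific
  scenario then cannot arise structurally.
* **Duplications** fall on gene-tree branches as a Poisson process (one
  expected event per lineage per unit depth by default, nesting capped at
  depth 3). A duplication on an *internal* branch founds two nested
  sub-HOGs; on a *terminal* branch it leaves in-paralogs in the same HOG,
  because HOGs are delimited by speciation events and no taxonomic level
  exists below a terminal-branch duplication. (The naive alternative —
  every duplication founds sub-HOGs — creates species-private subfamilies
  that make leave-one-out queries structurally under-specific, a
  configuration that should require rate variation.)
* **Sequences** evolve by i.i.d. per-site replacement: along a branch of
  length `t` with rate multiplier `r_m`, each site substitutes with
  probability `1 - exp(-subst_rate * r_m * t)` to a residue drawn from the
  background frequencies (Swiss-Prot composition by default; the draw may
  resample the same residue, giving the familiar `1 - 1/20` correction
  under uniform frequencies). No exchangeability matrix, no site-rate
  heterogeneity, no codon structure: the artifact tests placement logic,
  not phylogenetic realism. Optional indels (1–3 residues) are off by
  default. `subst_rate = 0.3` per unit depth is calibrated to the regime
  the method targets — a query proteome from within the phylum of its
  references, where family-level assignment is highly accurate
  (~0.36 substitutions/site between query and backbone; at 1.0 the query
  would sit amphioxus-like at ~1.2 subs/site, where 6-mer survival is
  negligible and every method's family assignment collapses).
* **Post-duplication acceleration**: both daughter lineages multiply their
  substitution rate by `rate_boost` until the next speciation, one of them
  additionally by `asymmetry` — the premise that duplicated proteins evolve
  faster and often asymmetrically, and the knob that makes under-specific
  and wrong-path configurations appear.

Under clock-like settings (`rate_boost = asymmetry = 1`) over-specific
closest sequences still arise (a query predating a duplication has no
correct nested subfamily), under-specific ones essentially vanish, and a
small wrong-path noise floor remains from substitutional drift — the
qualitative fingerprint the four-configuration taxonomy predicts. The
rate-asymmetric benchmark (`rate_boost = 4`, `asymmetry = 3`) makes about
a fifth of queries over-specific by closest sequence; thresholded LCA
placement at `theta_sub = 0.1` cuts that fraction by roughly a third to a
half while matching or beating the Smith-Waterman baseline's subfamily
`F1_max` — a scaled-down analog of the full-database findings, computed
entirely by this package's tests.

What a green suite does **not** establish: behavior on real proteomes with
domain shuffling, alternative splicing, annotation noise, or horizontal
transfer; absolute accuracy numbers (the synthetic world is cleaner than
any real database); and runtime scaling (out of scope).

## Numerical choices and degenerate inputs

* Ties break deterministically everywhere: smallest family id, smallest
  protein id, lexicographically smallest leaf — benchmarks are reproducible
  bit-for-bit under a fixed seed.
* Queries shorter than `k`, or consisting entirely of non-canonical
  windows, yield `n = 0` profiles and are reported unassigned, never an
  error; empty sequences score 0 in Smith-Waterman.
* Scores are clamped to [0, 1] for reporting; descent decisions use the
  unclamped excess (identical behavior for any positive threshold).
* `k` is capped at 7 so codes stay below 2^31; the suffix array is an
  intermediate and is not serialized.
* The ancestor relation is strict (`is_ancestor(h, h)` is false), which is
  what makes the four configurations mutually exclusive and exhaustive;
  "ancestral or equal" is spelled out at call sites.
* Species removal prunes a HOG only when its entire subtree loses all
  members; a sub-HOG with no remaining members is unobservable to any
  method being benchmarked. Proteins of a root-HOG with no sub-HOG
  membership keep the root retained as long as anything in the subtree
  survives.

## Known limitations

The LCA attribution is deliberately conservative: homoplasy inside a family
is misread as ancestral signal, so very short or low-complexity subfamily
diagnostics are diluted upward. Distant queries (beyond roughly one
substitution per site from the nearest reference) lose too many exact
6-mers for reliable family assignment — reduced alphabets or spaced seeds
would be the natural extensions, and are out of scope here. The
closest-sequence oracle is brute-force quadratic DP; it is the benchmark's
gold standard, not a production aligner.
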