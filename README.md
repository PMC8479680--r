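# hogmapper

Alignment-free assignment of protein sequences to gene families and
subfamilies organized as hierarchical orthologous groups (HOGs).

## The problem

A protein family accumulates nested *subfamilies* every time a gene
duplication splits it; the family is the root-HOG, the subfamilies are
sub-HOGs. The standard way to place a new protein — give it the subfamily
of its closest reference sequence — ignores the family tree and is wrong
surprisingly often: a query that diverged *before* a duplication has no
correct nested subfamily at all, yet its closest sequence necessarily lives
inside one (an over-specific assignment), and the accelerated, often
asymmetric evolution of duplicated genes pushes closest sequences into
wrong branches. `hogmapper` is for anyone who needs subfamily-level calls
at database scale — annotation transfer, phylogenomic database curation,
contamination screening — and for benchmarking such callers.

## The method

Reference proteomes are preprocessed into a table of *evolutionarily
informed k-mers* via a suffix array over the concatenated sequences. Each
k-mer (base-20 encoded: AA → 0, AC → 1, ...) is attributed, within every
family F, to the last common ancestor of the subfamilies containing it —
homoplasy is deliberately misread as homology, which errs toward the root,
never toward over-specificity. A query with *n* distinct k-mers and *x* of
them matching family F scores

    score(F) = max(0, (x − E_F) / (n − E_F)),   E_F = n · (1 − (1 − 20⁻ᵏ)^m_F)

(m_F = distinct k-mers of F). Within the winning family, each sub-HOG h
with subtree-restricted hit count x_h is scored relative to its parent,

    s_h = (x_h − E_h) / (x_par − E_h),   E_h = x_par · m_h / m_par

and the assignment descends the highest-scoring root-to-leaf path while
s_child ≥ θ_sub, stopping at the deepest supported sub-HOG. An
overlap score (fraction of the query covered by family-matching,
query-unique k-mers) flags partial/domain-level matches.

The package also ships the full evaluation framework — an exact
Smith-Waterman closest-sequence baseline (BLOSUM62, affine gaps), the
four-way configuration taxonomy (true subfamily / over-specific /
under-specific / wrong path), two-level precision-recall validation with
negative query sets — and a synthetic gene-family generator (duplication
nesting, post-duplication rate acceleration and asymmetry, leave-one-out
fixtures with truth labels) so the whole system is testable without any
external database.

## Worked example

Simulate a 5-family fixture with a held-out query proteome, build the
k-mer table, and search:

```r
library(hogmapper)

fx  <- make_fixture(sim_params(n_families = 5, n_species = 6, seed = 42),
                    out_dir = "demo", k = 6)
db  <- load_reference("demo/ref.fasta", "demo/hierarchy.tsv", k = 6)
tab <- build_kmer_table(db)
tab
#> <kmer_table> k = 6; 4568 distinct k-mers; 4570 entries across 5 families

res <- search_queries("demo/queries.fasta", tab,
                      theta_family = 0.05, theta_sub = 0.1)
head(res[, 1:6], 5)
#>      query_id family_id family_score subfamily_id subfamily_score overlap_score
#> 1 F0001_S1_g1     F0001        0.297      F0001.1           0.480         0.720
#> 2 F0001_S1_g2     F0001        0.228        F0001           0.228         0.513
#> 3 F0002_S1_g1     F0002        0.317    F0002.1.1           0.690         0.647
#> 4 F0002_S1_g2     F0002        0.359        F0002           0.359         0.693
#> 5 F0002_S1_g3     F0002        0.269    F0002.1.2           0.557         0.527
```

Every query lands in its true family (`family_score` is the excess of
shared k-mers over chance: 0.3 means ~30% of the query's k-mers match
beyond noise). `subfamily_id` is the deepest sub-HOG whose parent-relative
score clears θ_sub = 0.1 — query 2 stays at the root-HOG because no
subfamily is supported, the conservative answer for a protein that diverged
before the family's duplications. `overlap_score` near 1 means the match
spans the whole sequence rather than a single domain.

A thin CLI wraps the same functions:

```sh
exec/hogmapper simulate --out demo --n-families 5 --n-species 6 --seed 42
exec/hogmapper mkdb   --db demo.db --fasta demo/ref.fasta --hierarchy demo/hierarchy.tsv
exec/hogmapper search --db demo.db --query demo/queries.fasta --out hits.tsv
```

## Acceptance script

`scripts/acceptance.R` re-derives the package's checkable reference values
from scratch against the installed package (here: the printed worked
examples of the k-mer integer encoding) and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The broader behavioral claims — LCA attribution against brute-force
oracles, Smith-Waterman against an independent DP implementation, the
self-query path-safety guarantee, and the rate-asymmetric benchmark in
which thresholded LCA placement cuts over-specific assignments below the
closest-sequence baseline at equal-or-better subfamily F1 — are asserted by
the test suite (`tests/testthat/test-acceptance.R`).
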