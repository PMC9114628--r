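---
title: "Methods: cell-centric atlas assembly, querying and annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-centric atlas assembly, querying and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellensemble)
```

# The data model

`cellensemble` treats the cell, not the dataset, as the unit of storage.
A `unified_table` is a sparse cells-by-genes matrix of normalized
expression over one fixed approved-gene axis, plus a 17-column per-cell
metadata frame (`metadata_fields()`), keyed by a contiguous 0-based
integer cid. Two conventions make the table totally queryable:

* **Missing metadata is the empty string, never `NA`** — text comparisons
  in the query language are total functions.
* **Values stored are normalized expression.** Raw counts exist only
  upstream of ingestion; the published sorting convention ("expression
  above 0.5") refers to this normalized scale.

Persistence is deliberately plain text (MatrixMarket + CSV + two line
files): portable, diffable, and exactly round-trippable. The MatrixMarket
writer emits 17 significant digits because the stock writer's `%g`
precision would silently perturb values across a save/load cycle; the
reader is the standard `Matrix::readMM`, which doubles as an independent
check that the written files are valid MatrixMarket.

# Ingest: symbol unification and normalization

**Gene unification.** Every dataset's gene identifiers are mapped onto a
closed approved-symbol list (in production use, the HGNC approved symbols;
in the synthetic world, `GENE0001...`). Approved names map to themselves,
known aliases map through the alias table, everything else is dropped and
reported. Two policies here were genuinely open and are our declared
choices:

* **Collisions are summed.** When an alias and its approved symbol (or two
  aliases of one locus) both appear, they denote the same locus, and
  summation is the only policy that conserves count mass — the package
  tests conservation exactly, in integer arithmetic.
* **Matching is case-sensitive and exact.** Fuzzy matching trades silent
  errors for coverage; a curated alias file is the supported way to widen
  coverage.

Unification is idempotent, and output column order is always the approved
order, so every processed dataset shares one gene coordinate system.

**Normalization.** Cell i is rescaled to a common depth and
log-transformed: `x_gi = ln(1 + c_gi * s / L_i)` with `s = 10000` reads
per cell and `L_i` the library size. The identity
`sum_g expm1(x_gi) = s` holds exactly for every non-empty cell and is the
package's conservation invariant (tested at 1e-6 relative tolerance); it
also makes the transform invertible, which the batch-correction module
relies on. The log base of *incoming* pre-logged data is dataset metadata
(`delog()` supports e, 2, 10 with pseudo-count 1); our own transform uses
the natural log, the convention of the standard scRNA-seq normalization
routines. Cells with an empty library are kept as all-zero rows and
reported — dropping cells is quality control, which belongs to the caller.

# The query language

Filters are boolean combinations of comparisons
(`column op value`, `op` in `==, !=, >, >=, <, <=`) with `!`, `&&`, `||`.
Choices a grammar has to make, and ours:

* **Precedence** NOT > AND > OR, left-associative, parentheses override —
  the C convention.
* **Unquoted values.** A comparison's value extends to the next logical
  operator or closing parenthesis and is trimmed, so `cell_type == T cell`
  parses without quoting. The price: values may not contain `&`, `|`,
  `(`, `)`.
* **Canonical tokens only.** The typeset variant `= =` seen in print is
  rejected with a positioned error rather than guessed at.
* **Numeric comparisons are exact floating comparisons** — thresholds are
  user-chosen, so no epsilon is imposed. Unparseable text in a
  numeric-declared field simply never matches.
* **`donor_age` is text** (values like "fetal week 9" occur in real
  atlases); pass `numeric_fields = "donor_age"` to compare it numerically.

`include_children` expands an equality test on `cell_type` (via `is_a`
edges) or `organ` (via `is_a` + `part_of`) to the entire ontology subtree,
and `!=` is its exact complement. Whether organ equality should also
expand is not externally fixed; we put both fields behind the one flag.
The engine is vectorized but its contract is per-row: the test suite holds
it to a scalar brute-force oracle over 1000 randomized (table, expression)
pairs.

# The annotation ontology

A typed DAG: macroscopic nodes (system, organ, region, subregion) linked
by `part_of`, microscopic nodes (tissue_type, cell_type) specialized by
`is_a` (same-kind only). Validation rejects cycles (naming a witness),
duplicate names, unknown kinds and cross-kind `is_a`. Subtree and ancestor
queries are breadth-first set closures — a diamond contributes its
grandchild once.

Cell Ontology mapping is a deterministic three-stage function: exact label
match, else first exact match walking `is_a` parents upward (file order
breaks ties among multiple parents), else a curated lookup table, else
`"none"`. The curated table stands in for what is irreducibly human
judgment; we model it as data, not code. Standardized labels compose as
`organ-tissue_type-cell_type-markers`; an unresolvable cell type yields
`"Unclassified"` — we also treat an *empty* cell type as unresolvable,
since a cluster with no identity is precisely an unclassified one.

# Quantitative portraits

Gene portraits report, per group, the expressing fraction (`value > 0` —
distinct from the 0.5 *sorting* threshold, which is a selection
convention) and the median/quartiles of the *nonzero* values: zeros are
truncated first, because in sparse droplet data the zero mass otherwise
swamps every location statistic.

Marker tables compare one cell type against all other annotated cells:
per gene a two-sided Wilcoxon rank-sum test in the normal approximation
with tie and continuity correction (the test is validated against
`stats::wilcox.test` rather than calling it: the vectorized path is ~50x
faster over a gene axis, and the dual route keeps the oracle independent).
Adjustment is Bonferroni by default (Benjamini–Hochberg available);
records must have `p_adj <= 0.05`, in-group prevalence at least 25%, and
positive fold change; the top 50 by
`log_fc = ln((mean(expm1 x_in)+1)/(mean(expm1 x_out)+1))` are kept. The
fold change is computed on de-logged values with a unit pseudo-count so it
reads on expression scale; whether the original tables were one- or
two-sided is not documented anywhere we could check, so we declare
two-sided-with-positive-FC. Marker lists are exactly invariant to cell
order; they are *not* asserted invariant under duplicating the whole
table, since test statistics scale with n.

# Batch correction by inverse transformation

The correction model is intentionally minimal: per-gene mean and standard
deviation (sample sd; zero-variance genes clamp to 1, contributing nothing
to any component) and the top-k right singular vectors of the scaled
matrix, with k = 100 by default — enough dimensions to span cell-identity
structure in practice. Component signs are fixed by making each
component's largest-magnitude loading positive, so fits are bit-for-bit
reproducible.

The module deliberately does **not** integrate batches itself. Embedding
correction (Harmony and friends) is a solved, external problem; the
contribution here is the inverse step
`X_hat = (Z_corrected %*% t(V)) * sd + mean` that turns *any* corrected
embedding back into a corrected expression matrix on the original scale.
Negative reconstructed values are clipped to 0 (expression semantics) and
the clip count reported — whether the original pipeline clipped or
re-logged is unstated, and clipping is the choice that preserves the
stored-value invariants. Orchestration applies one model per organ
(`correct_per_organ()`): cross-organ correction mixes biology into the
batch term and is known to work poorly.

Full-rank round-trips reconstruct to 1e-6; the parameter-recovery test
plants an additive embedding-span batch offset on a 500-cell atlas and
verifies that correcting the embedding by the known offset restores the
batch-free matrix to 1e-4 RMSE.

# Label transfer and is-a-aware evaluation

References are built by query (`build_reference()`); unlabeled cells are
excluded with a warning, never silently. Transfer is a k = 10 Euclidean
nearest-neighbour majority vote in a caller-chosen embedding (typically
the correction model's). Vote ties were undocumented; our declared
tie-break is smallest summed distance among tied labels, then
lexicographic — deterministic and favoring the nearer label mass.

Evaluation reports accuracy with an exact Clopper–Pearson binomial CI
(the method behind a printed interval is rarely stated; exact is the
conservative default), Cohen's kappa, and the confusion matrix. With
`allow_is_a = TRUE` a prediction that is an `is_a` *ancestor* of the truth
counts correct — calling a cDC1 a dendritic cell is right, only less
specific; the converse (predicting a descendant, i.e. inventing
specificity) is not credited. Kappa and the confusion matrix always use
strict labels: folding hierarchy credit into the chance-expected agreement
has no defined semantics, so we do not improvise one.

# The synthetic world

`generate_atlas()` is first-class, tested code, and its defaults are a
stated world, chosen once:

* counts are negative binomial with dispersion 0.1 (size 10) — the
  standard stand-in for droplet-data noise; no external source prescribes
  a value, and 0.1 sits in the typical empirical range;
* baseline gene means are Gamma(2, 1) (mean 2), giving a realistic mix of
  low- and moderately-expressed genes;
* 2 organs x 2 cell types x 200 cells, 3 markers per type at 4-fold —
  200 cells/type matches the scale at which marker recovery is asserted;
* the toy ontology is a 3-level tree (body -> organ -> tissue -> cell
  type, each type with one `is_a` subtype) — the minimal shape exercising
  both edge types, subtree queries and is-a evaluation. Half of each
  type's cells are labeled with the subtype; the subtype shares its
  parent's expression profile *exactly*, which is deliberate: subtree
  queries must recover the full type, and strict-label transfer must not
  be able to cheat;
* 10% of gene names are replaced by recorded aliases, so the unification
  step always has real work;
* batches are assigned round-robin with library-size multipliers (1, 2) —
  a pure depth effect, which library-size normalization removes by
  construction. In-span additive embedding offsets for correction
  experiments are constructed by the tests from the truth record, since
  an additive expression-space effect cannot be expressed in count space
  without breaking the count model.

What the generator does **not** emulate: gene-gene covariance, doublets,
ambient RNA, batch effects that bend rather than shift the manifold, and
annotation noise. A green marker-recovery or transfer test therefore
establishes correctness of the machinery on its stated world, not
performance on real tissue.

# Numerical and degenerate-input policy

* Save/load round-trips are exact (17-digit MatrixMarket, string-exact
  CSV read back with `colClasses = "character"`).
* Depth conservation: 1e-6 relative; PCA orthonormality: 1e-8; full-rank
  reconstruction: 1e-6; composition fractions sum to 1 within 1e-12.
* Empty tables query to empty cid lists; empty row sets produce empty
  sets/tables rather than errors; empty libraries and all-zero groups are
  reported, not dropped.
* Everything stochastic is seeded; same seed, same atlas, bitwise.

# Known limitations

* The store is an in-memory embedded structure: millions of cells need
  the out-of-core backends the original cloud deployment used, which are
  out of scope here along with concurrency and authentication.
* Query evaluation is a linear scan with column pruning; no indexes.
* `celltype_markers()` densifies the in/out submatrix; fine at package
  scale, a memory concern at atlas scale.
* Ensembl-ID conversion requires a pre-supplied alias file; no live
  lookups.
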