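---
title: "Methods: models, parameters and design choices in scRadial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in scRadial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scRadial)
```

scRadial packages the computational primitives of interactive single-cell
exploration — import, filter, aggregate, compare, embed, color, chart — as
plain, deterministic library functions. This vignette explains the models
behind each primitive, the parameters that matter, the numerical and
design decisions that were genuinely open, and what the synthetic test
data does and does not demonstrate.

## The dataset model and its conventions

A dataset is three tables. The count matrix has cells as rows and genes as
columns; any finite numeric values are accepted (raw counts or normalized
expression — the package applies no normalization, quality control or
drop-out correction, and assumes those happened upstream). The gene
annotation is keyed by a `Locus_Tag` column; `Start`/`End` hold 1-based
inclusive genomic coordinates; any other column is a metadata category
whose cells may hold several comma-separated values; columns named
`G_<name>` define binary gene groups (`1` member, blank not). The
phenotypic table is keyed by cell identifiers and every further column is
one per-cell label.

Conventions worth spelling out:

* Column-name matching is **case sensitive** (`Locus_Tag`, `Start`, `End`,
  the `G_` prefix); all other headers are taken verbatim.
* Comma-split values are whitespace-trimmed, so `a, b` and `a,b` parse
  identically; a blank cell parses to an *empty list*, not `[""]`.
  Splitting then re-joining is idempotent for trimmed values, which is
  what makes annotation export/reload round trips field-identical.
* A `G_` column containing anything other than `1` or blank is an error
  rather than silently coerced — junk in a membership column usually
  signals a formatting mistake upstream.
* Excel import reads the first worksheet only. For GFF3, features of type
  `gene` are used (falling back to `CDS` if none), `locus_tag` is the
  identifier (falling back to `ID`), and every remaining attribute key
  becomes a category; this mapping is a reasoned default, since GFF
  attribute schemas vary between annotation pipelines.
* Cross-file validation is asymmetric by design: a matrix gene missing
  from the annotation (or a matrix cell missing from the phenotype) is an
  error, because downstream joins would fail; extra annotation genes or
  phenotype cells are tolerated as surplus metadata and only warned
  about.

## Filter chains

A filter chain is an ordered list of specifications applied left-to-right
to the gene universe (the count-matrix gene list, in matrix order). The
composition rule is *sequential narrowing*: each step's output is a subset
of its input.

* **Set filters** (genomic region, metadata value, gene group, custom
  set) intersect with the current list while preserving its order. Any
  permutation of set filters therefore yields the same result — the
  property tests prove this on random chains.
* **Rank filters** (top expressed, top differential) re-rank the current
  list by their context vector and truncate to `n`. They are inherently
  order-sensitive: "top 50 then region" differs from "region then top
  50", and both are meaningful queries. Repeating the identical rank
  filter is idempotent.

Two decisions here were open and are pinned by tests: the genomic-region
filter uses **inclusive interval overlap**, not containment, because genes
partially inside a window are biologically relevant to it; and rank ties
break by count-matrix gene order, which makes every result deterministic.
Differential ranking offers `absolute`, `up` and `down` modes rather than
guessing a single intent for "strongest change". The default display size
of the top-expressed filter is 50 genes, the radial chart's default.

## Metacells and fold change

A metacell aggregates all cells carrying one label of one phenotype
category into a single per-gene profile, by mean or median (median of an
even-sized cluster is the midpoint of the two central values). Single-cell
clusters reproduce the cell's vector exactly, and each aggregated value
lies within the member cells' range — both are tested invariants. Cells
can also be painted into ad-hoc groups (`paintGroups()`), which become
ordinary binary phenotype categories and therefore metacell-eligible and
exportable.

Fold change between two profiles `a`, `b` is
`log2((a_g + p) / (b_g + p))` with pseudocount `p` applied symmetrically.
Zeros are unavoidable in scRNA-seq counts, so `p = 1` is the default; with
`p = 0` any zero entry raises an error instead of producing infinities.
For metacells the ratio is taken between *aggregated* values, not averaged
per-cell log ratios. The sign follows a-over-b, and the algebra is exact:
antisymmetry holds to machine precision. Fold change is a heuristic screen
— the package deliberately provides no test statistics, normalization or
outlier removal within predefined clusters.

## Embeddings

PCA runs on the column-mean-centered matrix (optionally unit-variance
scaled; centering-only is the default, matching common practice for
expression matrices). No log transformation is applied implicitly — the
analysis runs on whatever values were loaded, and any transformation is
the caller's responsibility. The user chooses either a component count or
a target cumulative explained-variance fraction; the smallest component
set reaching the target is returned, with a floor of two so results remain
plottable. Two numerical conventions keep results reproducible: components
are ordered by decreasing explained variance, and each component's sign is
flipped so that its largest-absolute gene loading is positive (PCA is
otherwise sign-ambiguous). The test suite checks scores against an
explicit covariance eigendecomposition to 1e-8.

UMAP (via uwot) supports 2 or 3 output dimensions and a neighbor count
`2 <= n_neighbors < cells`. The layout runs single-threaded under a caller
seed (default 42, recorded in the embedding's metadata), making runs
bitwise reproducible; the original interactive workflow offers no such
guarantee, and reproducibility was judged worth the modest speed cost.

Precomputed coordinate matrices need at least two dimensions and exactly
the matrix's cell set; rows are reordered to matrix order on load. Axis
selection takes 1-based component indices (idiomatic R), requires them
distinct and in range, and preserves provenance metadata.

## Coloring and charts

Expression coloring is a linear ramp anchored at zero: intensity
`x / max(x)` over cells, black at 0 to full red at 1, so intensities are
invariant under positive rescaling of the gene. Categorical coloring sorts
the label set lexicographically (C locale) before assigning colors from a
fixed 16-color cycle, so the mapping is independent of cell order; empty
labels get a reserved neutral gray, and more than 16 labels wrap the
palette with a warning — determinism is prioritized over aesthetics.
Shared-category coloring grays the selected gene, gives each of its values
a distinct palette color, and colors every displayed gene sharing at least
one value by the *first* shared value in the selected gene's list order.

The radial chart draws one bar per displayed gene: bars in descending
expression order (stable ties), equal angular widths `2*pi/n`, starting at
12 o'clock and proceeding clockwise, heights normalized by the per-chart
maximum so every chart uses its full radial range (per-chart rather than
global normalization was chosen deliberately; a `logScale` flag switches
heights to `log2(1 + x)` normalization). Genes sharing a category value
with the selected gene are connected to it by chords in the shared value's
color; chords are stored as unordered pairs, so linkage is symmetric by
construction. Fold-change charts sign-color bars (red up, blue down) with
lengths normalized by the displayed maximum `|log2FC|`. Scatter layouts
place one point per cell, with metacells as flagged extra points at the
centroid of their member cells' embedding coordinates.

SVG export is a pure function of the layout spec — identical specs yield
byte-identical files (coordinates are printed with fixed six-decimal
formatting), and every bar/point is one addressable shape element. 3D
scatter specs are projected orthographically onto their first two selected
axes; interactive navigation is a GUI concern outside this library's
scope. PNG export rasterizes the same layouts at requested pixel
dimensions.

## The synthetic data generator

`generateDataset()` emulates the three-file model with known ground truth:
negative-binomial counts (default mean 20, dispersion 0.5 — overdispersion
is the norm in scRNA-seq; a Poisson variant exists for analytic sanity
checks), balanced clusters recorded in the phenotype, and 10% of genes
designated markers whose mean is multiplied by `2^clusterSeparation` in
one cluster. The default separation of 2 log2 units is a moderate,
realistic effect; recovery tests use 4, where all markers should rank in
the top decile of metacell fold changes, and 0, where cluster differences
must be statistically indistinguishable. Annotation intervals are
consecutive and non-overlapping (900 bp genes, 1 kb spacing), categories
draw 0-3 comma-separated values per gene, and everything is a
deterministic function of the seed, down to file bytes.

What the generator does *not* emulate: library-size variation, batch
effects, zero inflation beyond the negative binomial, doublets, or any
QC artifact — the package declares QC upstream, so its tests demonstrate
algorithmic correctness on clean data, not robustness to real-world
artifacts.

## Problem sizes and numerical tolerances

The test and verification suites run on deliberately small problems —
datasets up to 100 cells x 300 genes, 200 random filter chains of up to 6
steps, 1000 random fold-change pairs, 20 random PCA fixtures — sizes at
which independent brute-force oracles (per-gene loops, full sorts,
explicit eigendecompositions) are cheap to run alongside the
implementation. Tolerances reflect the arithmetic: exact equality for
integer/ordering contracts, 1e-12 for elementary algebra, 1e-8 against the
eigendecomposition oracle, 1e-9 for text round trips of coordinates
(written with 15 significant digits).

## Known limitations

* Dense in-memory matrices only; no HDF5/MTX/AnnData-style containers or
  out-of-core streaming.
* No normalization, QC, drop-out correction, or statistical testing of
  differential expression.
* No t-SNE or autoencoder latent spaces (precomputed coordinates cover
  importing them from elsewhere).
* Excel reading is first-worksheet-only; Excel writing is not offered
  (exports are CSV).
* The categorical palette wraps past 16 labels.
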