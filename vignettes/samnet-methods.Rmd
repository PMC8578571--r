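---
title: "Methods: permutation-based differential expression and network ranking"
author: "samnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based differential expression and network ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samnet)
```

# Scope and model

`samnet` implements the computational chain of a two-group microarray
study on a balanced design (the motivating shape: 6 control vs 6
experimental arrays, ~15,000 features): quantile normalization, SAM
(Significance Analysis of Microarrays) differential expression with a
permutation null and q-value FDR control, Fisher's-exact gene-set
over-representation, a degree-ranked pathway-interaction network, and a
betweenness-ranked gene signal network.  This vignette records the model
assumptions, the tunable parameters, and the design choices made where
the underlying procedure is conventionally under-specified.

# Expression preparation

All statistics are computed on the **log2 scale**; fold changes are
reported as signed linear ratios (`R` if `R >= 1`, else `-1/R`), so a
halving prints as −2.  This pairing — log2 internally, signed ratios in
tables — matches how such studies print fold changes of e.g. −2.47 for
downregulated genes.

Quantile normalization maps every column onto the across-column mean of
sorted values.  Tied values within a column receive the **mean of the
reference values over their rank span** (the standard microarray
convention).  Consequences worth knowing:

* the operation is idempotent (to machine precision) and equivariant
  under column permutation;
* after normalization all tie-free columns carry the identical multiset
  of values;
* rows containing missing values are dropped at read time and counted in
  a message — the simplest defensible policy, since probe-level
  imputation is out of scope.

`readExpressionTable()` accepts a plain TSV dialect (feature-id column +
sample header) and the GEO series-matrix dialect (`!`-prefixed metadata
skipped, or the block between `!series_matrix_table_begin/_end` when
present).

# SAM differential expression

For gene *i*, `d_i = r_i / (s_i + s0)` with `r_i` the experimental-minus-
control mean difference and `s_i` the pooled standard error.  Parameters:

| parameter | default | meaning |
|---|---|---|
| `nPermutations` | 1000 | ceiling on group relabellings |
| `s0Strategy` | `cv_minimisation` | fudge-factor estimator |
| `qThreshold` | 0.05 | q-value gate for calling |
| `fcThreshold` | 1.5 | signed linear fold-change gate |
| `seed` | 1 | used only when the null must be sampled |

**s0.** The originating description gives the `d` formula but no s0
algorithm, only that low-abundance variance is "adjusted".  We default to
the canonical Tusher-style choice: candidate values are the percentiles
0, 5, …, 100 of `s`, and the winner minimises the coefficient of
variation of the d-spread (median absolute deviation) across 100
s-quantile bins.  A plain percentile strategy (default median) and a
fixed value are available as alternatives.

**Null distribution.**  Samples are relabelled into pseudo-groups of the
original sizes, reusing the observed-data s0.  When the number of
distinct assignments is at most `nPermutations` — for 6 vs 6,
`C(12,6) = 924 ≤ 1000` — all assignments are enumerated exactly once, so
the null (and everything downstream) is fully deterministic; otherwise
assignments are sampled without replacement under `seed`.  Complementary
assignments are both kept: they give distinct signed `d` whose magnitudes
pair, so the pooled null is symmetric about zero for balanced designs.
The observed labelling is itself one of the relabellings; its column (and
its complement's) is computed through the same code path as the observed
statistics, so the pooled null contains the observed `d` bitwise and
exceedance counts at these self-ties are exact.

**p-values.** Null `d` are pooled across genes and relabellings (924
relabellings alone are far too few for per-gene nulls on 12 arrays);
the two-sided p is the add-one exceedance fraction
`(1 + #{|null| ≥ |d|}) / (1 + N_null)`, never zero — which keeps
`-log10 p` finite for the volcano export.

**q-values.** Discretised rejection regions: for every threshold Δ at an
observed `|d|`, `O(Δ)` counts observed exceedances, `F(Δ)` is the median
over relabellings of null exceedances, and
`FDR(Δ) = π0 · F(Δ) / max(O(Δ), 1)` clipped to [0, 1]; a gene's q is the
minimum over thresholds at or below its `|d|`, hence monotone
non-increasing in `|d|`.  `π0` is the ratio of observed to
per-relabelling null mass at or below the null median of `|d|`, capped at
1.  The q-value construction behind the original analysis platform is not
published; ours is declared here, not inferred as theirs, so exact
reproduction of any published d/p/q table is explicitly not promised.

**Calling and ranking.** `up` ⇔ `q < 0.05` and `FC > 1.5`; `down` ⇔
`q < 0.05` and `FC < −1.5`; called genes are ranked jointly by increasing
p, then q, then gene id.

# Over-representation

One-sided Fisher's exact test: `p = P[X ≥ k]`, `X ~ Hypergeom(N, K, n)`.
Design choices where conventions vary:

* **Universe** = all features on the expression matrix after filtering —
  the only universe the artifact can know without annotation databases.
* **FDR** = Benjamini–Hochberg across the collection.
* **Gates**: reported conventions differ between `p < 0.05` and
  `FDR < 0.05` for pathway-style analyses; `significantSets()` exposes
  both gates, with FDR < 0.05 the default.
* **Probe collapse**: when several features share a symbol,
  `collapseToGenes()` keeps the most significant one before enrichment.

# Networks and centrality

Both networks are **induced subgraphs**: the pathway network on the
significant pathways over a directed relation catalogue, the gene
network on the called DEGs over a typed interaction list.  Edges carry a
type (`c`, `a`, `ind`, `inh`, `ex`, `b`, `link`) and a directedness flag;
an undirected edge is stored once and expands to both directions in the
adjacency view, on which all degree and shortest-path computations run.
Numerical/semantic choices:

* **Ordered-pair betweenness.** `B(i) = Σ_{s≠i≠t} σ_st(i)/σ_st` is summed
  over ordered pairs without halving, because the graph is genuinely
  directed and the formula's sum has no 1/2 factor.  No normalisation is
  applied: magnitudes like 125.4 on a ~70-node graph are raw counts.
  Fractional credit is shared across tied shortest paths (Brandes'
  accumulation); disconnected pairs contribute zero.
* **Edge types are annotation only** — inhibition and indirect edges are
  traversable like any other, since no type-specific semantics are
  defined for shortest paths.
* **Degrees**: indegree = upstream neighbours, outdegree = downstream,
  degree = their sum; an undirected edge contributes one to each at both
  endpoints.  Core pathways and hub genes are nodes with degree ≥ 1;
  pathway tables are ordered by decreasing degree, gene tables by
  decreasing betweenness, ties by the other criterion then id.
* **Pathway up/down feature** = the majority direction of its hit DEGs
  first (`Down`, `Up`, `Down|up`, `Up|down`; equal counts give
  `Down|up`); a gene's feature is its own call.

# The synthetic study design

`simulationSpec()` defaults define the conditions every test and the
acceptance script run under:

| parameter | default | rationale |
|---|---|---|
| `nGenes` | 15,000 | array-scale feature count |
| `nPerGroup` | 6 | the 6 vs 6 balanced design |
| `fracDown`, `fracUp` | 4.8%, 1.4% | echoes a ~720:205 down:up imbalance |
| `effectLog2` | 1.5 | clears the linear fold-change gate (1.5) with margin |
| `sigma` | 0.25 | plausible within-group log2 SD for arrays |
| baseline | Normal(8, 2) | typical log2 intensity range |

Noise is Gaussian on the log2 scale with equal group variances — the
simplest model consistent with a two-group comparison.  The generator
deliberately does **not** emulate probe-level artefacts, batch effects,
mean–variance coupling, heavy tails or correlated genes; passing tests
therefore demonstrate correctness of the pipeline's computations and its
operating characteristics under idealised conditions, not performance on
real arrays.

`simulateGeneSets()` plants one designated set (optionally several, a
strong primary plus weaker secondaries) filled to `plantedFraction` with
planted DE genes, the remainder drawn from the whole universe so a
fraction of zero yields a plain background draw.  `simulateRelationGraph()`
plants either a guaranteed-maximal-degree node (pathway style) or a
two-clique bridge node (gene style).  The bridge attaches through two
gateway nodes per cluster, which provably gives it strictly maximal
betweenness regardless of the cluster-size split, while gateway nodes
split their credit across tied paths.  A fraction of clique edges is
written as reciprocal directed arcs so the edge set genuinely mixes
directedness without changing any shortest path.

# Pipeline, determinism and problem sizes

`runPipeline()` fixes the stage order (normalize → SAM → enrichment ×2 →
pathway network → gene network) and writes seven tables, each headed by
the package version, seed and stage parameters — a rerun under the same
config is byte-identical.  All randomness fans out from the single config
seed with fixed per-stage offsets.  In synthetic mode the pathway-relation
catalogue is generated over the significant pathways (a catalogue that
did not cover them would make the induced network trivially empty), and
the gene-interaction list covers the top called DEGs plus a margin of
non-DEGs so the induced-subgraph restriction is genuinely exercised.

The test suite validates the SAM chain against exhaustive-enumeration
oracles at 4 vs 4 (70 relabellings, 200 genes), Fisher p against draw
enumeration for every universe size up to 12, and betweenness against
explicit shortest-path enumeration on 20 random mixed graphs of up to 12
nodes.  Operating characteristics use 20 replicates at the default
15,000-gene design (recovery) and 20 pure-null replicates at 5,000 genes
(false-calling rate) — sizes chosen to give stable Monte-Carlo estimates
while keeping a full suite run in a few minutes on one CPU.

# Degenerate inputs and limitations

* Zero-variance genes with `s0 = 0` make `d` undefined; the fit stops
  with an instruction to use a positive s0 (the default estimator
  effectively always does).
* Fewer than 2 samples per group, empty DEG lists, empty universes and
  empty gene-set collections are hard errors, not silent empties.
* Hierarchical-clustering export standardises each gene row (constant
  rows to zero) and uses average linkage on Euclidean distance — the most
  common microarray heatmap convention; linkage is configurable.
* The dendrogram operation takes the gene list as an argument rather than
  fixing it to all DEGs, since published figures differ in which subset
  they cluster.
* Exact reproduction of any published study's gene lists or network
  tables would additionally require the original annotation and
  interaction databases, which this package does not ship; the optional
  real-data path (`pipelineConfig(synthetic = NULL, ...)`) accepts
  user-supplied expression, design, GMT and edge-list files in the plain
  formats documented in the function reference.
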