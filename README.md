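# samnet

Significance Analysis of Microarrays with permutation-based FDR control,
gene-set over-representation, and interaction-network ranking — the full
computational chain of a classic two-group microarray study, packaged as
tested, reusable R functions.

## The problem

A typical two-group expression study (here: a balanced design of n = 6
control vs n = 6 experimental arrays, tens of thousands of probes, as in
rat soleus-muscle atrophy profiling) is analysed in five chained stages:

1. **Quantile normalization** — each sample column is mapped onto the
   across-column mean of sorted values, so every array carries the same
   intensity distribution.
2. **SAM differential expression** — for each gene a regularised statistic

   `d = r / (s + s0)`

   where `r` is the difference of group means (log2), `s` the pooled
   standard error `sqrt((1/n1 + 1/n2) · SSwithin / (n1 + n2 − 2))`, and
   `s0` a fudge factor that stabilises `d` for low-variance genes
   (chosen by coefficient-of-variation minimisation across s-quantile
   bins).  The null distribution comes from relabelling samples into
   pseudo-groups: for 6 vs 6 all `C(12,6) = 924` distinct assignments are
   enumerated, making the null deterministic.  Two-sided p-values pool the
   null across genes; q-values are built from discretised rejection
   regions, `FDR(Δ) = π0 · F(Δ) / O(Δ)` with `F` the median permutation
   count of `|d_null| ≥ Δ` and `O` the observed count.  A gene is called
   differentially expressed when `q < 0.05` and its signed linear fold
   change exceeds 1.5 in magnitude (downregulation reported as −R).
3. **Over-representation** — Fisher's exact (hypergeometric upper tail)
   test of the DEG list against GMT gene-set collections, with
   Benjamini–Hochberg FDR across each collection.
4. **Pathway-interaction network** — the directed relation catalogue
   induced on the significant pathways; core pathways are the nodes with
   degree ≥ 1, ranked by decreasing degree (`degree = indegree +
   outdegree` on the adjacency view, undirected relations counting both
   ways).
5. **Gene signal network** — typed gene–gene interactions (compound `c`,
   activation `a`, indirect `ind`, inhibition `inh`, expression `ex`,
   binding `b`) induced on the DEGs; hub genes are ranked by unnormalised
   betweenness centrality `B(i) = Σ_{s≠i≠t} σ_st(i)/σ_st` over ordered
   node pairs (Brandes' algorithm, fractional credit on tied shortest
   paths).

A synthetic-data module generates every input with planted structure
(differential genes with a down:up imbalance, enriched sets, high-degree
and high-betweenness nodes), so the whole chain is testable end to end
without any download.

## Worked example

```r
library(samnet)

sim <- simulateExpression(simulationSpec(nGenes = 2000, seed = 42))
sim$expr
#> ExpressionExperiment: 2000 features x 12 samples [ log2 scale ]
#>   design: control n = 6 | experimental n = 6

fit <- samFit(quantileNormalize(sim$expr))
fit
#> SamFit: 2000 genes | 924 enumerated relabellings
#>   s0 = 0.2507 | pi0 = 0.915 | thresholds: q < 0.05, |FC| > 1.5
#>   called: 28 up, 96 down

degs <- callDEGs(fit)
head(as.data.frame(degs$table[, c("gene","d","fold_change","p","q","regulation","rank")]), 3)
#>          gene         d fold_change            p q regulation rank
#> G01322 G01322 -4.845875   -3.034605 1.623376e-06 0       down    1
#> G00951 G00951  4.716822    3.354056 2.705626e-06 0         up    2
#> G01540 G01540 -4.692634   -3.096013 3.787877e-06 0       down    3

gs  <- simulateGeneSets(sim$truth, nSets = 50, seed = 7)
enr <- fisherEnrich(degs$table$gene, gs$collection)
head(as.data.frame(enr[, c("set_id","k","K","p","fdr","rank")]), 3)
#>          set_id  k  K            p          fdr rank
#> SET0050 SET0050 40 50 4.097837e-42 2.048918e-40    1
#> SET0036 SET0036 12 87 6.164102e-03 1.541026e-01    2
#> SET0045 SET0045  7 54 4.603058e-02 7.671763e-01    3

net <- simulateRelationGraph(20, "gene", seed = 3)
rankHubs(centralityTable(net$graph), topK = 3)[, c("id","betweenness","degree","rank")]
#>        id betweenness degree rank
#> N001 N001         180      8    1
#> N011 N011          80     20    2
#> N012 N012          80     20    3
```

The 28 up / 96 down split recovers the planted 1.4% up / 4.8% down genes
exactly; the planted enriched set (SET0050, 40 of its 50 members
differential) ranks first with a vanishing hypergeometric p; and the
planted bridge node N001 tops the betweenness ranking even though denser
cluster nodes have larger degree.

The whole chain runs from one config with `runPipeline(pipelineConfig(...))`,
which writes seven stage tables (DEGs, two enrichment tables, both
networks, core pathways, hubs) with parameter/seed headers.  Plot-ready
exports (`volcanoData()`, `dendrogramData()`) and the qRT-PCR `2^-ΔΔCt`
helper (`ddctFold()`) round out the reporting layer.

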