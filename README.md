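# phenonet

Neuronal phenotype discovery and paracrine interaction-network inference
from single-cell qPCR panels.

## What it does and for whom

Single-cell qPCR studies of heterogeneous tissue — the motivating system is
the suprachiasmatic nucleus (SCN), the brain's circadian pacemaker — face
two linked problems: classical marker-threshold classifications (Vip+/Avp+/
Adcyap1+ and their combinations) produce incoherent clusters, and the
resulting "cell types" say nothing about how the types signal to each
other. phenonet is for researchers with a genes × cells table of raw Ct
values who want both answers from the data alone:

1. **Phenotype discovery.** Normalize Ct values with the two-step −ΔΔCt
   method (housekeeping referencing, then per-gene median centering), build
   a cell–cell Pearson correlation network, and find its densely
   interconnected communities with Newman's leading-eigenvector modularity
   method (implemented from scratch, with deterministic conventions and
   fine-tuning). Cells with few or no strong correlations are pooled into a
   residual group. Cluster quality is quantified with silhouette scores,
   PCA and classical MDS.
2. **Interaction inference.** For measured ligand–receptor pairs, each
   cell's signaling role is the sign quadrant of its normalized (ligand,
   receptor) expression — paracrine source (+, ≤0), paracrine target (≤0, +),
   autocrine (+, +), none (≤0, ≤0). Groups significantly enriched in a role
   (one-sided Fisher/hypergeometric test) for pairs that survive a
   permutation screen of their expression correlation become the nodes and
   directed edges of a group-interaction network.

The core quantities, in the field's notation:

* −ΔCt(g, c) = mean_h Ct(h, c) − Ct(g, c) over housekeeping genes h
  (higher = more transcript); −ΔΔCt subtracts the per-gene median across
  all cells; modified z divides by the per-gene SD.
* Modularity Q = (1/2m) Σᵢⱼ [Aᵢⱼ − kᵢkⱼ/2m] δ(cᵢ, cⱼ); communities come
  from the signs of the leading eigenvector of B = A − kkᵀ/2m, bisecting
  recursively.
* Silhouette s(i) = (b(i) − a(i)) / max{a(i), b(i)}.

A synthetic-data generator (`sim_config()`, `simulate_cells()`) plants
phenotype groups, housekeeping genes, ligand–receptor roles, Vip-like
dropout, spatial bias on a 7×7 grid and a dark/light treatment effect on
the raw Ct scale, so the whole pipeline is testable without any download.

## Worked example

```r
library(phenonet)

sim <- simulate_cells(sim_config())          # 60 genes x 200 cells, 4 groups
res <- run_pipeline(sim$ct, pairs = sim$config$lr_pairs,
                    n_perm = 200, seed = 7)

glance(res)
#> # A tibble: 1 × 8
#>   n_nodes n_groups n_residual     q pc3_variance n_cell_edges n_gene_edges
#>     <int>    <int>      <int> <dbl>        <dbl>        <int>        <int>
#> 1     200        4          0 0.749        0.572         3256          114

glance(res$silhouette)
#> # A tibble: 4 × 3
#>   cluster     n mean_s
#>     <int> <int>  <dbl>
#> 1       1    50  0.606
#> 2       2    50  0.736
#> 3       3    50  0.694
#> 4       4    50  0.659

res$network
#> <interaction_network> 4 groups, 4 directed edges (alpha = 0.05)
#>   group 1 -> group 2 via Lig1-Rec1
#>   group 3 (autocrine) via Lig1-Rec1
#>   group 1 (autocrine) via Lig2-Rec2
#>   group 3 -> group 4 via Lig2-Rec2
```

Reading the numbers: all 200 cells land in four communities of 50 (none
pooled to the residual group) with modularity Q = 0.749 — far above the 0
of a random degree-preserving graph — and every group has a clearly
positive mean silhouette in the MDS plane. The first three principal
components carry 57% of the expression variance. The interaction step
recovers exactly the planted signaling structure: group 1 is a paracrine
source driving group 2 through the first ligand–receptor pair, group 3
drives group 4 through the second, and the planted autocrine roles appear
as self-loops.

`autoplot(res$partition, res$mds)`, `autoplot(res$enrichment)`,
`plot_regimes(res$regimes, "Lig1-Rec1")` and `autoplot(res$network)` draw
the MDS map, the enrichment heat map, the bivariate regime quadrants and
the interaction network. `write_pipeline_outputs(res, dir)` writes every
table, edge list (TSV + GraphML) and a JSON manifest. A thin command-line
wrapper with `simulate` and `run-all` verbs ships in `inst/cli/phenonet.R`.

Real data enter through `read_ct_table()` (wide or long TSV/CSV, with
`Undetermined`/`999` non-detect tokens and an optional cell-metadata
sidecar carrying treatment labels and grid coordinates).

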