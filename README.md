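# xtalknet

Typed multilayer gene networks, spectral module detection, exact
enrichment scoring, and cell-death crosstalk statistics.

## What problem this solves

Programmed cell death is not one pathway but a family of modes —
apoptosis, autophagy, necroptosis, ferroptosis, pyroptosis and others —
whose genes interact through many molecular mechanisms at once:
protein–protein binding, activation, phosphorylation, cleavage,
translocation, transcription and more. Each mechanism is one **layer** of
a typed gene–gene network. `xtalknet` is for systems biologists who have
such typed edge lists (plus pathway gene sets in GMT format) and want to:

1. integrate the layers into one weighted network by **convex
   aggregation**, `M_ij = Σ_l w_l A_l,ij` with `w_l ≥ 0`, `Σ w_l = 1`;
2. detect **subnetwork modules** by normalized-Laplacian spectral
   clustering (scan range 25–30 modules by default, the typical count for
   one cell-death-mode network), with planted-partition likelihood
   refinement;
3. **annotate** each module against pathway gene sets with the
   hypergeometric network score

       score = −log10 P(X ≥ f),   X ~ Hypergeom(N, G, s)

   over genes or gene pairs (`N` universe elements, `G` in the module,
   `s` in the pathway, `f` in both), equal to one-sided Fisher's exact
   test on the corresponding 2×2 table; pathways with `score > 4`
   (`p < 1e-4`) form the composite network and the top 25 records are
   reported;
4. quantify **crosstalk** between two modes' module structures with the
   same overlap tail, plus bridging-edge counts and annotation-profile
   Jaccard similarity, and list genes shared across modes.

A seeded generator of planted-module multilayer networks
(`simulate_multilayer()`, `simulate_genesets()`, `simulate_mode_pair()`)
provides ground truth for every stage; nothing needs to be downloaded.

## Worked example

```r
library(xtalknet)

cfg  <- synth_config(n_genes = 150, k_true = 6, p_in = 0.45,
                     p_out = 0.01, n_sets = 12, seed = 42)
sim  <- simulate_multilayer(cfg)
glance(sim$network)
#> # A tibble: 1 × 5
#>   n_genes n_edges n_layers n_hallmark mode
#> 1     150    1927        3          0 <NA>

W    <- aggregate_layers(sim$network)           # uniform convex weights
part <- spectral_partition(W, clustering_config(k_min = 4, k_max = 8,
                                                seed = 42))
glance(part)
#> # A tibble: 1 × 6
#>       k n_genes n_isolated modularity min_size max_size
#> 1     6     150          0      0.730       25       25
adjusted_rand(part, sim$truth)
#> [1] 1

gs  <- simulate_genesets(sim$truth, cfg)
rec <- annotate_modules(part, sim$network, gs$genesets,
                        element_mode = "genes")
report_top(rec, 5)
#> # A tibble: 5 × 10
#>   module pathway     N     G     s     f  p_value score  q_value passed
#> 1      1 SET001    150    25    25    20 6.43e-16  15.2 7.72e-15 TRUE
#> 2      2 SET002    150    25    25    20 6.43e-16  15.2 7.72e-15 TRUE
#> ...
```

The generator planted 6 modules of 25 genes; the detector selects `k = 6`
and recovers them exactly (ARI 1). Each planted gene set covers 20 of its
module's 25 genes, giving a hypergeometric score of 15.2 — far above the
inclusion threshold of 4 — while decoy sets stay below it.

Reading real data instead: `read_edge_table("edges.tsv")` (TSV/SIF, 16
relation labels, see `default_vocabulary()`), `read_gmt("sets.gmt")`,
`read_node_attributes("nodes.tsv")`; results write back as headered TSV
via `write_network()`, `write_partition()`, `write_enrichment()`,
`write_crosstalk()`. A thin command-line wrapper with `simulate`,
`integrate`, `cluster`, `score`, `annotate`, `crosstalk` and `report`
subcommands lives at `inst/cli/xtalknet` (see `xtn_main()`).

## Method notes

See the vignette (`vignettes/network-modules.Rmd`) for the model and its
assumptions, the likelihood-refinement and module-count-selection design
(including why Newman modularity under-selects `k` at this sparsity), the
numerical conventions, what the synthetic benchmark does and does not
emulate, and known limitations.
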