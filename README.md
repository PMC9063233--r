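# cellgwas

Map complex-trait GWAS signal onto gene sets derived from single-cell
transcriptomics, and score cell states over an immune stimulation time
course.

Single-cell studies of livestock immune responses (e.g. bovine PBMCs
challenged with LPS) produce gene sets — cell-type marker genes, DEGs
between treatment time points — whose relevance to breeding traits can
be asked directly of GWAS summary statistics: *do the markers near
these genes carry more association signal than expected?* `cellgwas`
implements the statistical layer for that question, together with the
cell-state scores used to characterise the same single-cell data.

## The core methods

**Sum-based marker-set enrichment.** For a gene set whose 20-kb gene
windows contain markers *F* (|*F*| = m_f) with signed single-marker
effects *b*, the statistic is

> T_sum = Σ_{i ∈ F} b_i²

Its null distribution is built by **cyclical permutation**: the
genome-ordered vector of squared effects is rotated (effects wrap
around the genome, gene windows stay fixed), which preserves both set
size and local LD structure. Exact enumeration over all m − 1 rotations
is used when feasible, otherwise 10,000 sampled rotations. The p-value
is the one-tailed exceedance proportion (strict `>`, floored at 1/n),
and Benjamini–Hochberg FDR is applied across the whole trait × set
grid.

**Cell-state scores.** A per-cell cell-cycle score (mean normalized
expression of a 43 G1/S + 55 G2/M gene panel) is thresholded at the
mean of cluster means to call actively proliferating cells; the
**cell-cycle index** of a group is its proliferating fraction.
LPS-response **module scores** (core antiviral, peaked inflammatory,
sustained inflammatory) are group-wise z-scaled mean expressions whose
temporal shape is classified as *peaked*, *sustained*, or *flat*.
**Pseudocells** (means of 100 random cells per cluster) support
downstream co-expression analysis.

Seeded synthetic generators for both data types make every stage
verifiable offline with known ground truth.

## Worked example

Simulate one trait with enrichment injected into `set02`
(effect-SD inflation ×3 inside that set's genes), then run the grid:

```r
library(cellgwas)
library(dplyr)

sim  <- simulate_gwas(gwas_sim_config(enrichment_lambda = 3, seed = 11),
                      enriched_set_ids = "set02", trait_id = "milk_yield")
grid <- run_grid(sim$markers, sim$sets, sim$genes,
                 window_bp = 20000, n_perm = 10000, seed = 5)
tidy(grid) |> arrange(q_fdr) |> head(3)
#> # A tibble: 3 × 11
#>   trait_id   set_id n_genes   m_f t_obs n_perm n_exceed   p_emp  q_fdr exact note
#>   <chr>      <chr>    <int> <int> <dbl>  <int>    <int>   <dbl>  <dbl> <lgl> <chr>
#> 1 milk_yield set02        6    54 5.05     999        2 0.00200 0.0160 TRUE  ""
#> 2 milk_yield set01        6    52 0.256    999      997 0.998   0.998  TRUE  ""
#> 3 milk_yield set03        6    48 0.363    999      855 0.856   0.998  TRUE  ""
```

The injected set is recovered: 54 markers fall in its windows, the
observed T_sum is exceeded by only 2 of the 999 exactly enumerated
rotations (`exact = TRUE` because m − 1 < n_perm), giving p ≈ 0.002 and
q ≈ 0.016 — the only FDR < 0.05 cell of the grid:

```r
glance(grid)
#> # A tibble: 1 × 7
#>   n_traits n_sets n_tested n_untestable n_significant  min_q n_exact
#>      <int>  <int>    <int>        <int>         <int>  <dbl>   <int>
#> 1        1      8        8            0             1 0.0160       8
```

`autoplot(grid)` draws the trait × set heat map with FDR stars.

On the single-cell side, simulate three clusters with true cycling
fractions 0.2 / 0.4 / 0.5 over the Control → 2 h → 4 h → 8 h LPS
course, then recover cell states:

```r
sc    <- simulate_sc(sc_sim_config(n_cells_per_group = 150, seed = 2))
norm  <- normalize_cells(sc$counts)
flags <- classify_proliferating(cycle_score(norm, sc$panels), sc$cell_meta)
cycle_index(flags, sc$cell_meta, group_by = "cluster")
#> # A tibble: 3 × 4
#>   cluster  n_cells n_proliferating cycle_index
#>   <chr>      <int>           <int>       <dbl>
#> 1 B            600             300         0.5
#> 2 CD4T         600             240         0.4
#> 3 monocyte     600             120         0.2

mono <- sc$cell_meta$cell_id[sc$cell_meta$cluster == "monocyte"]
ms   <- module_score(norm[, mono], sc$cell_meta,
                     sc$panels[!sc$panels$panel_id %in% c("G1S", "G2M"), ])
classify_module_trajectories(ms)
#> # A tibble: 3 × 2
#>   module                 pattern
#>   <chr>                  <chr>
#> 1 core_antiviral         peaked
#> 2 peaked_inflammatory    peaked
#> 3 sustained_inflammatory sustained
```

The recovered cycle indices equal the configured cycling fractions, and
the three injected module shapes are classified to their generating
patterns. `autoplot(ms)` plots the module trajectories;
`run_pipeline(pipeline_config(...))` drives the whole synthetic
analysis end to end and writes a reproducibility manifest.

Real data enter through `read_gwas_tsv()`, `read_genes_bed()` /
`read_genes_gff3()`, `read_gene_sets()`, `read_panels()` and
`read_sc_bundle()` (MatrixMarket + TSV metadata).

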