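# mptf

Stage-resolved transcription factor (TF) activity from grouped single-cell
expression data.

Tumor progression rewires transcriptional regulation differently in every
cell population of the tumor microenvironment. Given (i) a curated
TF→target edge list (TRRUST-style), (ii) a protein–protein interaction
list (HPRD-style) and (iii) a cells × genes expression matrix annotated
with cell types and ordered disease stages, `mptf` answers, for every TF:
in which cell type and stage is its regulatory program significantly
activated or inhibited, and how does its activity move across stages? The
package is aimed at computational biologists analyzing staged single-cell
cohorts (tumor progression, differentiation series, dose/time courses)
who want TF-level readouts with a calibrated permutation null.

## Method in brief

1. **Module mining.** The two edge lists are merged into one undirected
   network. Each TF seeds a random walk with restart,
   `p ← (1−r)·W·p + r·e_seed` (`r = 0.5` by default), and its module is the
   top 50 genes by stationary influence. A module is kept when the induced
   subnetwork has more than 5 edges and its overlap `x` with the TF's
   curated targets is hypergeometrically significant:
   `p = P(X ≥ x)` for `X ~ Hypergeom(N, M, n)` with `N` the network genes
   excluding the seed, `M` the TF's in-network targets, `n` the module
   size.
2. **Activity scoring.** For gene `i` and (cell type, stage) group `j`,
   `E[i,j]` is the group mean, `R[i,j] = E[i,j] / mean_j E[i,·]` the
   relative expression (centered at 1), and the module activity is the
   weighted mean `M[t,j] = Σ w_i R[i,j] / Σ w_i` over module genes with
   `1/3 ≤ R ≤ 3` (outliers excluded per group), where
   `w_i = 1 / #modules containing gene i`. `M > 1` reads as activation,
   `M < 1` as inhibition.
3. **Permutation significance.** Group labels are shuffled (5000× by
   default) and the whole chain recomputed; add-one tail proportions give
   a two-sided p-value `min(1, 2·min(p_up, p_low))` (the plain directional
   proportion is available as `tail = "directional"`). Significant scores
   are called `activated`/`inhibited`.
4. **Stage trajectories.** Per TF and cell type, the activity profile
   across ordered stages is classified as `Increase`, `Decrease`, or
   `"<stage> Max"` (peak stage), with a plateau tolerance. Modules can also
   be tested for enrichment in trajectory-associated gene lists
   (hypergeometric + Benjamini–Hochberg).

A negative-binomial simulator with planted modules and planted per-group
fold changes (`simulate_dataset()`) makes the whole pipeline testable
without any external data.

## Worked example

Simulate the reference study (5 TFs × 50 targets; fold-2 activation
planted for TF01–TF04 in stages I, II, III and Normal; TF05 untouched),
mine modules, score activity, classify trajectories:

```r
library(mptf)
cfg <- synthetic_config(cells_per_group = 100, seed = 42)
ds  <- simulate_dataset(cfg)
ds$network
#> regulatory_network: 342 nodes, 450 undirected edges, 5 TFs

modules <- mine_tf_modules(ds$network, k = 50)
modules[, c("tf", "n_genes", "connectivity", "overlap_x", "overlap_p", "passed")]
#>     tf n_genes connectivity overlap_x    overlap_p passed
#> 1 TF01      50           52        50 3.069044e-61   TRUE
#> 2 TF02      50           51        50 3.069044e-61   TRUE
#> 3 TF03      50           56        48 1.586801e-53   TRUE
#> 4 TF04      50           54        49 4.465765e-57   TRUE
#> 5 TF05      50           55        48 1.586801e-53   TRUE

expr <- grouped_expression(ds$expr$counts, ds$expr$genes,
                           ds$expr$cells$cell_id, ds$expr$cells,
                           stage_levels = cfg$stages)
activity <- permutation_significance(expr, modules, n_perm = 1000, seed = 7)
subset(activity, tf %in% c("TF01", "TF05"),
       c(tf, stage, M_score, p_perm, call))
#>      tf  stage   M_score      p_perm      call
#> 1  TF01 Normal 0.7846465 0.001998002 inhibited
#> 2  TF01      I 1.6277786 0.001998002 activated
#> 3  TF01     II 0.7894049 0.001998002 inhibited
#> 4  TF01    III 0.7981699 0.001998002 inhibited
#> 17 TF05 Normal 1.0216651 0.087912088        ns
#> 18 TF05      I 0.9950637 0.725274725        ns
#> 19 TF05     II 0.9941101 0.671328671        ns
#> 20 TF05    III 0.9891612 0.405594406        ns

classify_stage_trajectories(activity, cfg$stages)[, c("tf", "category")]
#>     tf   category
#> 1 TF01      I Max
#> 2 TF02     II Max
#> 3 TF03   Increase
#> 4 TF04 Normal Max
#> 5 TF05   Decrease

mp_tfs(activity)
#> [1] "TF01" "TF02" "TF03" "TF04"
```

Reading the output: every module recovers (at least) 48 of its 50 planted
targets with vanishing overlap p-values; TF01's module is significantly
*activated* exactly in its planted stage I (`M = 1.63`, permutation
`p = 0.002`) and, because relative expression is centered across groups,
correspondingly *inhibited* elsewhere; the untouched TF05 stays
non-significant everywhere. TF03 (planted in stage III, the last stage)
classifies as `Increase` — a monotone approach to a boundary-stage peak is
monotone first, peak second. `mp_tfs()` lists the TFs with at least one
significant group call.

The same pipeline runs from files (MatrixMarket + TSVs) and YAML
configuration via `run_pipeline()`, or from a shell through
`inst/cli/mptf.R`:

```sh
Rscript inst/cli/mptf.R run --config pipeline.yaml --out-dir run/
```

Each run writes `modules.tsv`, `activity.tsv`, `categories.tsv` and a
`manifest.json` with parameters, per-stage seeds and file checksums;
reruns from the same config are byte-identical.

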