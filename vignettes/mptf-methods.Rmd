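---
title: "Methods: TF module mining and stage-resolved activity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF module mining and stage-resolved activity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptf)
```

## The problem

Tumor progression reorganizes transcriptional regulation across every cell
population of the tumor microenvironment. Given single-cell expression data
annotated with cell types and ordered disease stages, we want to know, for
every transcription factor (TF), *where* (which cell type), *when* (which
stage) and *in which direction* its regulatory program deviates from its
cross-stage average. `mptf` implements a three-part procedure: mine a gene
module per TF from a curated regulatory network, score the module's relative
expression per (cell type, stage) group, and assign significance by label
permutation. TFs with at least one significant group call are the
progression-associated TFs the package is named after.

## Network and module mining

The substrate is an undirected simple graph built from two curated inputs: a
directed TF→target edge list (TRRUST-style) and an undirected
protein–protein interaction list (HPRD-style). Both are symmetrized and
merged; the directed TF→target map is kept separately because it later
serves as the reference set for the overlap test. Propagation on an
undirected graph is the standard network-propagation choice when no
directionality of influence is asserted, and it makes the walk matrix a
column-normalized adjacency with well-understood convergence behavior.

For each TF $t$ the influence of $t$ on every gene is the stationary vector
of a random walk with restart,

$$ p^{(k+1)} = (1-r)\,W p^{(k)} + r\,e_t, $$

with $W$ the column-normalized adjacency, $e_t$ the indicator of the seed,
and $r$ the restart probability. Degree-zero columns teleport their mass
back to the seed, so $\sum_i p_i = 1$ at every iteration and genes in
components unreachable from the seed score exactly 0. We iterate until the
L1 change falls below `tol` ($10^{-10}$ by default, capped at 1000
iterations); the tests verify the iterate against the exact dense solve
$p = r\,(I-(1-r)W)^{-1}e_t$ to $10^{-8}$ in the sup norm.

The TF's **module** is the top $k = 50$ genes by influence, seed excluded,
ties broken by lexicographic gene symbol so results are byte-reproducible.
Other TFs may rank into a module; only the seed itself is excluded. Two
filters then apply:

* **Connectivity.** The number of edges of the subgraph induced by the TF
  plus its module must exceed 5 (strictly). Edge count is the simplest
  quantitative reading of "stable network connection"; the size of the
  largest connected component is available as an alternative
  (`connectivity_measure = "component"`).
* **Target overlap.** With $N$ the number of network genes excluding the
  seed, $M$ the TF's curated targets among them, $n$ the module size and $x$
  the observed overlap, the upper-tail hypergeometric probability
  $P(X \ge x)$ must fall below $\alpha = 0.05$. The tail is computed by
  `stats::phyper`; the tests pin it against exact term-by-term enumeration
  over the full grid $N \le 25$.

A TF failing either filter is retained in the output with `passed = FALSE`
and a reason code, never silently dropped.

## Activity scoring

Cells are partitioned into groups — by default cell type crossed with
disease stage; a cell-type-only mode exists because some analyses score
across cell types at fixed stage. For gene $i$ and group $j$ with $n_j$
cells:

$$ E_{i,j} = \frac{1}{n_j}\sum_{k=1}^{n_j} g_{i,k}, \qquad
   R_{i,j} = \frac{E_{i,j}}{\frac{1}{N}\sum_{j'} E_{i,j'}}, \qquad
   M_{t,j} = \frac{\sum_{i \in t} w_i R_{i,j}}{\sum_{i \in t} w_i}. $$

$R$ centers every gene at 1 across groups by construction (asserted to
$10^{-9}$ in the tests), so $M_{t,j} > 1$ reads as activation of module $t$
in group $j$ and $M_{t,j} < 1$ as inhibition. The weight
$w_i = 1/(\text{number of passed modules containing } i)$ down-weights
promiscuous genes. Before averaging, module genes with $R_{i,j} > 3$ or
$R_{i,j} < 1/3$ are excluded *in that group* as outliers (the bound is a
ratio, which is why the pipeline requires linear-scale expression; on log
scale the same rule would mean something entirely different). The exclusion
is applied per (gene, group) entry because the rule is phrased in terms of
relative expression, which is group-specific; a per-gene variant (drop the
gene from the module everywhere if it is out of band anywhere) is available
via `exclusion = "per_gene"`. Genes whose cross-group mean is 0 are
undefined and excluded; a group where no module gene survives yields
`M = NA` and a withheld call.

Expression is consumed as an already-normalized linear-scale matrix.
`normalize_cp10k()` (counts per 10,000, no log) is offered for raw-count
input, with a caveat worth stating: per-cell library normalization couples
genes through the library sum, so a strong genuine shift in one gene set
deflates the relative expression of every other gene in that group — a
compositional effect that the permutation test will faithfully detect. For
data generated on a common scale (such as this package's simulator output)
no normalization should be applied.

## Permutation significance

Group labels are shuffled over all cells (group sizes preserved) and the
whole $E \to R \to M$ chain, including outlier exclusion, is recomputed per
permutation; 5000 permutations is the package default, and scoring only
enters through per-group means, so the implementation restricts the matrix
to module genes and reduces each permutation to one sparse matrix product.
Both tail proportions use the add-one estimator
$p_{\uparrow} = (1 + \#\{M^{perm} \ge M^{obs}\})/(1 + B)$ (and the mirror
$p_{\downarrow}$), which avoids $p = 0$ and keeps the estimator
super-uniform. Permutations in which a score is undefined (fully excluded
module) are dropped from both numerator and denominator for that score.

The direction of a call is decided by the observed score's side of 1. A
single tail reported as-is — the proportion of permuted scores at least as
extreme in the observed direction — is an intuitive summary, but because
the direction is chosen after seeing the data its two-direction type-I
error is about twice the nominal level. `mptf` therefore reports
$p = \min(1,\, 2\min(p_{\uparrow}, p_{\downarrow}))$ by default, which is
super-uniform under a label-exchangeable null, so calling significance at
$\alpha$ realizes type-I error at most $\alpha$; the plain one-tail
proportion remains available as `tail = "directional"` for comparability
with analyses that used it. A score exactly equal to 1 gets $p = 1$. The
acceptance suite verifies the realized type-I error of the default on a
200-pair null study at $\alpha = 0.05$.

## Stage trajectories and enrichment

Per (TF, cell type), the vector of $M$ scores along the ordered stages is
classified into five categories: **Increase** (no step falls by more than
`flat_tol`, at least one rises by more), **Decrease** (mirror image), or
**"stage Max"** named after the argmax stage (earliest stage on ties) for
single-peak or irregular profiles. `flat_tol` (default 0.01 on the $M$
scale) operationalizes "gradually increasing/decreasing" — without a
plateau tolerance, sampling noise of order $10^{-3}$ would almost never
permit a monotone label. The rule is scale-aware rather than scale-free:
affinely rescaling the scores together with the tolerance leaves the
category unchanged, which is the invariance the tests assert. Note the
categories genuinely overlap at the boundary stages: a profile peaking in
the last stage after a monotone approach is Increase, not "last-stage Max";
which label applies is decided by the monotonicity test first. The stage
list is always an input — different analyses legitimately use
Normal/I/II/III or I–III — and a trajectory with a missing stage or an
undefined score is withheld with a reason, not guessed.

Modules can additionally be tested for over-representation of a
trajectory-associated gene list (computed upstream by any pseudotime
method; producing it is out of scope here) against a background universe:
upper-tail hypergeometric per module, Benjamini–Hochberg across modules,
significant iff raw $p$ and adjusted $q$ both fall below their cutoffs
(0.05/0.05 by default).

## The synthetic study

The generator exists so that every stage of the pipeline is testable with
known ground truth. `simulate_network()` gives each of `n_tfs` TFs
`targets_per_tf` dedicated targets (directed edges) and sprinkles
`ppi_edges` undirected edges uniformly over all node pairs (no self-loops
or duplicates). `simulate_expression()` draws counts
$\mathrm{NB}(\mu = e^{b_i} f_{i,g},\ \mathrm{size} = \theta)$ with gene
baselines $b_i \sim U(\log 0.5, \log 8)$ and $f_{i,g}$ the planted fold of
a TF's target set in its planted (cell type, stage) group; a Poisson switch
covers the $\theta \to \infty$ limit. The reference scenario is 5 TFs × 50
targets, 150 bystander genes, 200 PPI edges, one cell type over stages
Normal/I/II/III with 300 cells each, dispersion 2, and fold 2 planted for
TFs 1–4 in stages I, II, III and Normal respectively; the fifth TF carries
no effect and serves as a negative control. Patients are assigned
round-robin within groups — the label is carried through but unused by the
score, matching the scoring model's assumption of exchangeable cells within
a group.

What the generator deliberately does not emulate: dropout beyond NB
sampling, ambient RNA, batch or patient effects, correlated gene programs,
or realistic cluster structure. Passing the recovery tests therefore shows
the statistical machinery is correct under its own assumptions, not that
the method is robust to violations of them (patient-correlated cells, for
example, break label exchangeability and would require shuffling within
patients — an option the spec of this package leaves to the caller via the
grouping columns).

Random PPI edges occasionally attach a planted gene directly to the null
TF, letting it rank into that TF's top-50 module; the shared-gene weights
halve its contribution but a trace of genuine signal remains. This is the
realistic price of mining modules from a connected network rather than
reading off the planted sets.

## Numerical and reproducibility choices

* RWR: L1 tolerance $10^{-10}$, `max_iter` 1000, restart probability 0.5 —
  a balanced default in the absence of a stated value, configurable
  everywhere.
* All orderings (nodes, module ties, group levels) are deterministic
  (C-locale lexicographic), so equal inputs give byte-identical outputs;
  the pipeline writes input/output checksums into its manifest.
* Every source of randomness takes an explicit seed; the pipeline's single
  seed fans out to fixed per-stage offsets (+0 network, +1 expression, +2
  permutations) so stages rerun in isolation reproduce the pipeline run.
* Validation problem sizes: the test suite exercises graphs up to 200
  nodes against the dense oracle, the full hypergeometric grid to
  $N = 25$, a 200-pair permutation null and 20 replicate recovery runs of
  the reference scenario at 1000 permutations — sizes chosen to make the
  binomial error bars of the checked rates informative while keeping the
  suite fast; the package default of 5000 permutations is for real
  analyses.

## Known limitations

* Gene symbols are matched exactly and case-sensitively; no alias
  resolution. Mode-of-regulation (activation vs repression of individual
  targets) and interaction confidence are ignored.
* The activity score is a relative quantity across the supplied groups:
  adding or removing a group changes every $R_{i,j}$ and hence every
  $M_{t,j}$. Scores from runs with different group sets are not comparable.
* Global label shuffling assumes cells are exchangeable across groups under
  the null; strong patient structure violates this.
* The 3×/⅓ outlier rule and the ratio form of $R$ require linear-scale,
  nonnegative expression; log-transformed input would silently change the
  meaning of every threshold.
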