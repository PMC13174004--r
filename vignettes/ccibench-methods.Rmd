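---
title: "Simulation design and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation design and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccibench)
```

## The benchmarking problem

Cell-cell interaction (CCI) inference tools predict which ligand-receptor
(L-R) signals are exchanged between cell types in spatial transcriptomics
(ST) data. Evaluating them is hard because real tissue carries no ground
truth: nobody knows the complete set of interactions in a section. ccibench
takes the standard way out — simulation with embedded truth — and adds the
surrounding machinery a fair comparison needs: a harmonized L-R universe so
no tool benefits from a larger private database, standardized call
ingestion, and both simulation-defined and literature-curated (silver
standard) scoring.

The simulators are *expression-based embedders*: a ground-truth interaction
is written into the data by multiplying the ligand's counts in designated
sender cells and the receptor's counts in spatially proximal receiver cells
by a known fold change. Expression magnitude is the observable that every
evaluated tool consumes, so embedding at the expression level tests exactly
what the tools can see. Diffusion kinetics, receptor occupancy and
downstream signaling are deliberately not modeled; spatial dependence is
enforced purely by *where* the upregulation is applied.

## Expression model

Counts are generated from per-(gene, cell type) negative binomial (NB)
models with mean $m$ and size $r$ (variance $m + m^2/r$), the standard
overdispersed model for UMI counts. Models are fitted from a single-cell
reference by method of moments:

$$\hat m = \bar x, \qquad \hat r = \frac{\hat m^2}{\hat v - \hat m}
\quad (\hat v > \hat m),$$

with two guard rails:

* **Sparsity filter.** Genes with fewer than 10 total UMIs or detected in
  fewer than 10 cells across the reference are flagged `filtered` and
  sample as exact zeros. Zero columns are retained so gene indices stay
  aligned between reference and simulation.
* **Poisson fallback.** When $\hat v \le \hat m$ the NB size is undefined;
  the group is sampled as Poisson($\hat m$). NB is preferred over Poisson
  only where overdispersion actually exists.

Method of moments was chosen over maximum likelihood because it is
closed-form and deterministic, and at reference sizes of a few thousand
cells its error is dominated by sampling noise, not estimator
inefficiency (see the tolerance policy below).

An optional *rank-based skew* step models the common situation where a
subset of cells carries most of a gene's expression: within each
(gene, type) group a seeded random subset of `ceiling(high_fraction * n)`
cells receives the largest sampled values. The default `high_fraction` is
0.3 — a minority of high-expressing cells over a baseline majority — and
the operation is a pure permutation, so group-level moments are untouched.
It is exposed for both resolutions but off by default in the single-cell
scenarios, where the embedding itself defines the signal.

## Synthetic reference generator

So that nothing needs to be downloaded, `make_synthetic_reference()` plays
the role of a dissociated single-cell atlas. Its defaults were fixed once,
on distributional grounds:

* per-(type, gene) means $\sim$ Lognormal(meanlog = 0.7, sdlog = 1.3):
  median about 2 UMIs with a heavy right tail, the shape of UMI mean
  distributions after light gene filtering;
* NB sizes $\sim$ Uniform(0.6, 5): substantial but variable
  overdispersion, the regime where NB modeling matters;
* ten pancreatic cell types (alpha, beta, ductal, acinar, delta, gamma,
  activated/quiescent stellate, endothelial, macrophage) at frequencies
  approximating a human pancreas atlas; the spot-level simulator uses the
  seven abundant types renormalized, because rare types contribute
  negligibly to 12-cell spots and destabilize parameter estimates.

The generating parameters are attached to the returned object, which makes
parameter recovery testable: fitting a 5,000-cell synthetic reference
recovers per-gene means within a few percent and dispersions within a few
percent to tens of percent depending on expression level.

What the generator does *not* emulate: gene-gene correlation, batch
effects, ambient RNA, zero inflation beyond NB sparsity, or continuous
spatial expression gradients. Tests passing on these simulations therefore
demonstrate correctness of the benchmarking machinery and sensitivity under
controlled signal, not performance on the full messiness of real tissue.

## Single-cell-resolution simulator

`voronoi_layout()` places one seed point per cell type uniformly in the
unit square and positions each cell by rejection sampling inside its type's
Voronoi region. This produces contiguous type territories with variable
inter-territory distances — tissue-like structure that random placement
lacks — and per-type counts follow largest-remainder rounding of the
configured proportions (deterministic and proportion-preserving). The
default scenario has 3,593 cells over the ten types.

Interactions are embedded with `embed_interactions_sc()`: ligand counts of
all sender-type cells are multiplied by the fold change (grid 5, 10, 15),
and receptor counts are multiplied for the receiver-type cells that appear
in the Euclidean k-nearest-neighbor lists (k grid 18, 36, 60) of at least
one sender cell. Only neighborhood-resident receiver cells are touched —
the alternative (all receiver cells) would break the spatial specificity
the benchmark is probing. kNN is exact brute force with ties broken toward
the lower index, cheap at these sizes and free of approximation artifacts.

The *distal* mode is a negative control: seed points are resampled until
the sender and receiver territories share no Voronoi boundary and their
seeds are at least twice the median nearest-neighbor seed spacing apart
(adjacency is checked on a 60x60 ownership grid). Upregulation is applied
within each territory but the truth tuple is recorded as a negative
control, testing whether tools suppress calls when proximity is absent.

The truth universe is all ordered (sender, receiver) type pairs crossed
with the evaluated L-R pairs. Autocrine (sender = receiver) embedding
must be enabled explicitly; default scenarios use distinct types.

## Spot-level simulator

`build_scaffold()` generates a hexagonal grid sized by default to 782
spots (23 x 34), the footprint of a typical Visium section; real
coordinates can be supplied as a TSV instead. Adjacency connects spots
within 1.5x the minimum inter-spot distance, which captures the six
hexagonal neighbors. Each spot receives 12 cells (the typical 10-15 cell
Visium capture) drawn multinomially from the seven-type proportions.

`select_central_region()` takes the 130 spots nearest the centroid as the
interaction region; the adjacent ring is every non-central spot bordering
it. Ligands are fold-scaled in sender-type cells of central spots and
receptors in receiver-type cells of adjacent spots; cells are then summed
within spots, so embedding strictly precedes aggregation and peripheral
spots are bitwise independent of the fold setting.

Truth is labeled by global quantiles (`label_spot_truth()`): a tuple is
positive iff the mean ligand expression over central spots exceeds the
ligand's q-quantile over all spots *and* the mean receptor expression over
adjacent spots exceeds the receptor's q-quantile, with q in
{0.25, 0.5, 0.75}. The quantile is computed per gene over all spots and
compared against region means — the simplest operationalization of
"overexpressed relative to global expression"; raising q is provably
monotone (positives can only be lost).

Purity regimes stress-test deconvolution-dependent tools: in the `high`
regime the designated dominant type (the sender type in central spots, the
receiver type in the adjacent ring) is re-weighted to an expected share of
0.85 and spots are resampled until its realized share exceeds 0.8; `mixed`
targets 0.6 and enforces a dominant share below 0.8. The 0.8 boundary is
the conventional cut between "dominated" and "mixed" spots; 0.85/0.6
targets keep the rejection rate low while clearing the strict bound.

## L-R database harmonization

`load_lr_table()` normalizes symbols (uppercase, whitespace-stripped) and
flags multi-subunit complexes by separator detection (`_`, `+`, `&`, `,`,
covering CellPhoneDB- and CellChat-style conventions).
`intersect_databases()` keeps pairs present in every input — the
"common-DB" that puts all tools on an identical universe — and
`filter_single_chain()` drops complexes, since several tools cannot model
them. `feasibility_filter()` requires the ligand expressed in the sender
type and the receptor in the receiver type of the reference, using the
same 10-cell / 10-count thresholds as the gene filter (the natural reading
of "detected", kept consistent across the package). Embedded pairs are
then drawn by uniform seeded sampling with no pathway or alphabetical
ordering, so pair selection carries no knowledge bias. No ortholog or
synonym mapping is attempted; intersection keys on normalized text.

## Evaluation

`confusion_counts()` thresholds calls (strict `p < alpha`, matching the
conventional "p < 0.05" phrasing, with the grid 0.05-0.2; or a
rank-fraction cutoff such as top 20% for score-only tools) and intersects
with the truth universe; calls outside the universe are dropped and
counted. Precision, recall, F1 and specificity follow their textbook
definitions; zero-denominator cases return 0 with a degeneracy flag so
reports can show blanks instead of fake zeros.

`normalize_scores()` implements per-scenario min-max normalization across
methods with the per-method summary being the mean over scenarios; an
`x / max` variant sits behind a flag since more than one reading of
"normalized mean" exists, and outputs are labeled with the scheme used.
All-tied scenarios map every method to 1.

`jaccard_index()` / `mean_jaccard()` quantify cross-replicate consistency;
the empty-empty case is defined as 0 with a degeneracy flag (absent
results render as missing, not as agreement).

`distance_rank_profile()` ranks ordered type pairs by mean cross-type
Euclidean distance (types over 500 members are seeded-subsampled to that
cap) with dense ranks from 1 = most proximal, annotating each call with
its pair's rank. The profile distinguishes tools that preferentially call
proximal (paracrine-like) interactions from those that call across distant
populations, and is invariant to translation, rotation and scaling of the
coordinates.

`enrich_lr_genes()` performs one-sided hypergeometric enrichment (the
classical over-representation test) of the significant ligands and
receptors against the evaluated background, BH-adjusts across tested
pathways, and flags adjusted p < 0.05. Pathways with no background overlap
are skipped rather than assigned p = 1, keeping the adjustment family
meaningful. `pathway_prf()` scores enriched pathways against a
supported / not_supported / unknown silver standard with unknowns excluded
from all four confusion cells (a three-way labeling feeding a two-class
decision); an unknown-as-negative variant is available behind a flag.

## Numerical choices and reproducibility

* Fold-scaled counts are rounded half up, keeping matrices integral and
  the rounding rule documented.
* All per-stage randomness derives from a master seed via
  `derive_seed(master, stage)` (a small polynomial hash), so changing one
  stage's configuration never perturbs another stage's draws, and a
  bundle's manifest (configuration + seed + package version) replays to a
  bitwise-identical counts matrix.
* kNN and centroid ties break toward the lower index; type-count rounding
  uses largest remainder with ties by remainder then name.
* Degenerate inputs (empty call sets, empty adjacent rings, all-zero
  genes, single-spot scaffolds) return defined values with warnings or
  flags rather than NA surprises.

**Tolerance policy for stochastic checks.** Fixed relative bounds (5% on
recovered means, 25% on recovered dispersions) are statistically
unattainable near the information floor: at 2,500 cells per type, the
sampling SE of a mean-1 gene's MoM mean estimate alone approaches 3%, and
the delta-method SE of the dispersion estimator exceeds 25% for
near-Poisson genes. The test suite therefore bounds each gene's error by
`max(fixed bound, 3 x analytic sampling SE)` of the estimator, computed
from the true generating parameters via NB moment formulas. For
well-expressed genes the fixed bound is the binding constraint; the SE
floor only covers genes where no estimator could do better. Monte-Carlo
comparisons (sampled moments, embedding fold recovery, multinomial
compositions) use 3-3.5 SE bands with the band width chosen up front from
the number of simultaneous comparisons.

**Problem sizes in the test suite.** The default designs are exercised at
full size — 100 spot-level bundles of 782 spots and 50 single-cell bundles
of 3,593 cells per batch — alongside reduced instances (60-100-spot
scaffolds, 300-800-cell maps) for property checks where size adds nothing,
keeping the whole suite within a couple of minutes on one CPU. These sizes
are the package's own test design choices.

## Known limitations

* The NB models are independent across genes; co-expression structure that
  some tools exploit (e.g. pathway coherence) is absent by design.
* The quantile truth rule is one of several defensible operationalizations
  of "overexpressed relative to global signal"; it is exposed as
  configuration and alternatives can be plugged in at the
  `label_spot_truth()` boundary.
* Silver-standard scoring inherits the biases of literature curation;
  `unknown` labels are common and excluded rather than guessed.
* The harmonizer does not resolve gene synonyms or orthologs; inputs are
  assumed to be standardized to a single species' symbol space.
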