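# ccibench

Simulation-based benchmarking of cell-cell interaction (CCI) inference for
spatial transcriptomics.

Tools that infer ligand-receptor (L-R) signaling between cell types from
spatial data cannot be validated on real tissue, where the true interaction
set is unknown. `ccibench` builds the evaluation substrate instead: spatial
datasets with *known, embedded* interactions, a harmonized L-R universe so
every tool is scored on the same interaction space, and metrics that
compare any tool's calls against the simulation-defined truth or against
literature-curated pathway silver standards.

The package is aimed at method developers and benchmarkers: everything is a
plain R function over matrices and data frames, with TSV/MTX/JSON as the
interchange formats and a thin command-line wrapper for batch use.

## What it implements

**Expression model.** Counts follow per-(gene, cell type) negative binomial
models, NB(m, r) with variance m + m²/r, fitted from a single-cell
reference by method of moments (r̂ = m̂²/(v̂ − m̂)); genes under 10 total
UMIs or 10 detected cells are zeroed, underdispersed fits fall back to
Poisson. A bundled synthetic reference generator (lognormal means, uniform
NB sizes, pancreatic cell-type frequencies) makes the package fully
self-contained and exposes its generating parameters for recovery testing.

**Single-cell simulator.** Voronoi tessellation lays out contiguous
cell-type territories (3,593 cells, 10 types by default). A truth
interaction multiplies the ligand in sender-type cells and the receptor in
receiver-type cells resident in the k-nearest neighborhood of a sender
(fold ∈ {5, 10, 15}, k ∈ {18, 36, 60}), with a distal territory
configuration as a spatial-awareness negative control.

**Spot simulator.** A 782-spot hexagonal scaffold with 12-cell multinomial
type mixtures per spot (7 types); ligands upregulated in a 130-spot central
region, receptors in its adjacent ring, cells summed per spot; truth
labeled by per-gene global quantile thresholds (q ∈ {0.25, 0.5, 0.75});
high-purity (dominant share > 0.8) and mixed (< 0.8) composition regimes.

**Harmonizer.** Loading with symbol normalization and complex detection
(`_`, `+`, `&`, `,` subunit separators), database intersection
("common-DB"), single-chain restriction, expression feasibility filtering,
and uniform seeded pair sampling.

**Evaluation.** Confusion counts under p-value or rank-fraction
thresholds; precision = TP/(TP+FP), recall = TP/(TP+FN),
F1 = 2PR/(P+R), specificity = TN/(TN+FP) with flagged degenerate cases;
per-scenario min-max score normalization; pairwise and mean Jaccard
consistency J(A,B) = |A∩B|/|A∪B|; spatial proximity rank profiles of
called type pairs; hypergeometric pathway enrichment with
Benjamini-Hochberg correction scored against supported / not_supported /
unknown silver standards.

## Worked example

```r
library(ccibench)

# Harmonize two L-R tables into a common single-chain universe
db <- intersect_databases(list(
  load_lr_table(system.file("extdata", "lr_toy_a.tsv", package = "ccibench")),
  load_lr_table(system.file("extdata", "lr_toy_b.tsv", package = "ccibench"))))
db <- filter_single_chain(db)
db
#> <lr_database> common: 6 pairs (0 complex)

# Self-contained reference and NB models
ref <- make_synthetic_reference(n_cells = 1500, n_genes = 100, seed = 1)
models <- fit_nb_models(ref)
models
#> <nb_models> 100 genes x 10 cell types (0 filtered genes)

# Feasibility-filtered pairs, sampled without bias
g <- ref$gene_names
cand <- lr_database(data.frame(ligand = g[1:12], receptor = g[51:62]), "bench")
feas <- feasibility_filter(cand, ref, sender = "beta", receiver = "ductal")
pairs <- sample_pairs(feas, 4, seed = 1)

# One spot-level dataset with embedded truth
bundle <- simulate_spot_dataset(models, pairs, "beta", "ductal",
                                fold = 10, q = 0.5, seed = 1)
bundle
#> <sim_bundle> spot: 782 x 100 counts, 4 positive truth tuples

# Score a caller against the truth (here: a perfect oracle caller)
pos <- subset(bundle$truth$interactions, label == "positive",
              c(ligand, receptor, sender_type, receiver_type))
calls <- interaction_call_set(cbind(pos, p_value = 0.001), "demo_tool")
cc <- confusion_counts(calls, bundle$truth, alpha = 0.05)
cc
#> <confusion_counts> TP=4 FP=0 FN=0 TN=192
m <- prf_metrics(cc)
sprintf("precision %.2f recall %.2f F1 %.2f specificity %.2f",
        m$precision, m$recall, m$f1, m$specificity)
#> "precision 1.00 recall 1.00 F1 1.00 specificity 1.00"
```

The 196-tuple universe is all 7 x 7 ordered sender-receiver type pairs
crossed with the 4 evaluated L-R pairs; the perfect caller recovers every
embedded positive without false calls, and a null caller scores F1 = 0
with degeneracy flags. Real tool outputs enter the same way through
`ingest_call_table()`.

A command-line wrapper with the same functionality lives at
`inst/cli/ccibench.R` (verbs: `harmonize-db`, `make-reference`,
`simulate-sc`, `simulate-spot`, `evaluate`, `pathway-eval`).

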