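# Shared fixtures, built once per test run.

extdata <- function(f) system.file("extdata", f, package = "ccibench")

# Small synthetic reference + fitted models used across simulator tests.
fix_ref <- make_synthetic_reference(1200, 60, seed = 101)
fix_models <- fit_nb_models(fix_ref)

# A handful of feasible L-R pairs built from the reference's own genes.
fix_pairs <- local({
  g <- fix_ref$gene_names
  db <- lr_database(data.frame(ligand = g[1:10], receptor = g[31:40]), "fix")
  db <- feasibility_filter(db, fix_ref, "beta", "ductal")
  db$pairs[seq_len(min(4, nrow(db$pairs))), ]
})

write_tsv_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent set-algebra oracle for confusion counts: explicit loops over
# the universe, no reuse of package internals.
oracle_confusion <- function(called_keys, positive_keys, universe_keys) {
  tp <- fp <- fn <- tn <- 0L
  for (u in universe_keys) {
    called <- u %in% called_keys
    pos <- u %in% positive_keys
    if (called && pos) tp <- tp + 1L
    else if (called && !pos) fp <- fp + 1L
    else if (!called && pos) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Brute-force kNN oracle: all pairwise distances with explicit loops.
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) if (j != i)
      d[j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    order(d, seq_len(n))[seq_len(k)]
  })
}

# Exact hypergeometric upper-tail oracle by term-wise enumeration.
oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Hand step-up BH oracle.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}
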