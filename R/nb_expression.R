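#' Single-cell reference dataset
#'
#' Container for a cells-by-genes matrix of nonnegative integer UMI counts
#' with one cell-type label per cell, the source object for all
#' negative-binomial expression modeling.
#'
#' @param counts cells x genes integer matrix (rows = cells).
#' @param cell_types character vector, one label per cell.
#' @param gene_names unique gene symbols, one per column.
#' @param params optional list of generating parameters (for synthetic
#'   references): matrices `mean` and `dispersion` of dimension
#'   types x genes.
#' @return An object of class `reference_dataset`.
#' @export
reference_dataset <- function(counts, cell_types, gene_names = colnames(counts),
                              params = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(ncol(counts)))
  stopifnot(nrow(counts) == length(cell_types),
            ncol(counts) == length(gene_names))
  if (anyDuplicated(gene_names)) stop("gene names must be unique", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (anyNA(cell_types)) stop("every cell must have a type label", call. = FALSE)
  colnames(counts) <- gene_names
  structure(list(counts = counts, cell_types = as.character(cell_types),
                 gene_names = as.character(gene_names), params = params),
            class = "reference_dataset")
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat(sprintf("<reference_dataset> %d cells x %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_types))))
  invisible(x)
}

#' Representative cell-type frequencies
#'
#' Default cell-type compositions used by the simulators: ten major
#' pancreatic cell types for single-cell-resolution scenarios, and the seven
#' abundant types retained for spot-level scenarios (rare types contribute
#' negligibly once aggregated into 12-cell spots and destabilize parameter
#' estimates). Frequencies approximate a human pancreas single-cell atlas.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
sc_default_proportions <- function() {
  c(alpha = 0.28, beta = 0.31, ductal = 0.12, acinar = 0.11, delta = 0.06,
    gamma = 0.03, activated_stellate = 0.03, endothelial = 0.03,
    quiescent_stellate = 0.02, macrophage = 0.01)
}

#' @rdname sc_default_proportions
#' @export
spot_default_proportions <- function() {
  c(beta = 0.535, ductal = 0.207, delta = 0.103, activated_stellate = 0.052,
    endothelial = 0.052, quiescent_stellate = 0.034, macrophage = 0.017)
}

#' Generate a synthetic single-cell reference
#'
#' Draws per-(type, gene) negative-binomial parameters -- means from a
#' long-tailed lognormal, dispersions (NB size r, variance = m + m^2/r)
#' uniform on a realistic UMI overdispersion range -- then samples counts.
#' The generating parameters are attached to the result so that model
#' fitting can be tested for parameter recovery. Cell-type counts follow
#' largest-remainder rounding of the requested proportions.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param type_proportions named proportions summing to 1
#'   (default [sc_default_proportions()]).
#' @param seed integer seed.
#' @param mean_log,mean_sdlog lognormal parameters of the gene means
#'   (defaults 0.7 and 1.3: median ~2 UMIs, heavy right tail).
#' @param dispersion_range range of the uniform NB size draw
#'   (default `c(0.6, 5)`).
#' @return A [reference_dataset] with `params` populated.
#' @export
make_synthetic_reference <- function(n_cells, n_genes,
                                     type_proportions = sc_default_proportions(),
                                     seed = 1L,
                                     mean_log = 0.7, mean_sdlog = 1.3,
                                     dispersion_range = c(0.6, 5)) {
  n_cells <- check_scalar_count(n_cells, "n_cells")
  n_genes <- check_scalar_count(n_genes, "n_genes")
  if (is.null(names(type_proportions)) || any(type_proportions < 0) ||
      abs(sum(type_proportions) - 1) > 1e-9)
    stop("type_proportions must be named, nonnegative and sum to 1",
         call. = FALSE)
  alloc <- largest_remainder(n_cells, type_proportions)
  types <- names(alloc)
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    mu <- matrix(stats::rlnorm(length(types) * n_genes, mean_log, mean_sdlog),
                 nrow = length(types), dimnames = list(types, genes))
    size <- matrix(stats::runif(length(types) * n_genes, dispersion_range[1],
                                dispersion_range[2]),
                   nrow = length(types), dimnames = list(types, genes))
    cell_types <- rep(types, alloc)
    counts <- matrix(0L, n_cells, n_genes, dimnames = list(NULL, genes))
    for (ty in types) {
      rows <- which(cell_types == ty)
      if (!length(rows)) next
      draw <- stats::rnbinom(length(rows) * n_genes,
                             size = rep(size[ty, ], each = length(rows)),
                             mu = rep(mu[ty, ], each = length(rows)))
      counts[rows, ] <- draw
    }
    reference_dataset(counts, cell_types, genes,
                      params = list(mean = mu, dispersion = size))
  })
}

#' Fit per-gene, per-cell-type negative-binomial models
#'
#' For each gene within each cell type, estimates the NB mean and size by
#' method of moments: `m = mean(x)`, `r = m^2 / (v - m)` with `v = var(x)`.
#' Genes with fewer than `min_total` total UMIs or detected in fewer than
#' `min_cells` cells across the whole reference are flagged `filtered`
#' (they sample as exact zeros, keeping gene indices aligned). Underdispersed
#' groups (`v <= m`) fall back to a Poisson model (`poisson_fallback`).
#'
#' @param ref a [reference_dataset].
#' @param min_total,min_cells sparsity thresholds (defaults 10 and 10).
#' @return An object of class `nb_models`: list with `genes`, `types` and
#'   types x genes matrices `mean`, `dispersion` (NA when not NB), and
#'   `status` (`"fitted"`, `"poisson_fallback"` or `"filtered"`).
#'   Coerce with `as.data.frame()` for one row per (gene, type).
#' @export
fit_nb_models <- function(ref, min_total = 10L, min_cells = 10L) {
  stopifnot(inherits(ref, "reference_dataset"))
  types <- sort(unique(ref$cell_types))
  for (ty in types) {
    if (sum(ref$cell_types == ty) < 1)
      stop("empty cell type group: ", ty, call. = FALSE)
  }
  genes <- ref$gene_names
  total <- colSums(ref$counts)
  detected <- colSums(ref$counts > 0)
  filtered <- total < min_total | detected < min_cells
  mean_m <- disp_m <- matrix(NA_real_, length(types), length(genes),
                             dimnames = list(types, genes))
  status <- matrix("fitted", length(types), length(genes),
                   dimnames = list(types, genes))
  for (ty in types) {
    x <- ref$counts[ref$cell_types == ty, , drop = FALSE]
    m <- colMeans(x)
    v <- apply(x, 2, stats::var)
    if (nrow(x) == 1L) v <- rep(0, length(m))
    r <- ifelse(v > m, m^2 / (v - m), NA_real_)
    mean_m[ty, ] <- m
    disp_m[ty, ] <- r
    status[ty, !(v > m)] <- "poisson_fallback"
  }
  status[, filtered] <- "filtered"
  disp_m[status == "filtered"] <- NA_real_
  structure(list(genes = genes, types = types, mean = mean_m,
                 dispersion = disp_m, status = status),
            class = "nb_models")
}

#' @export
print.nb_models <- function(x, ...) {
  cat(sprintf("<nb_models> %d genes x %d cell types (%d filtered genes)\n",
              length(x$genes), length(x$types),
              sum(x$status[1, ] == "filtered")))
  invisible(x)
}

#' @export
as.data.frame.nb_models <- function(x, ...) {
  data.frame(
    gene = rep(x$genes, each = length(x$types)),
    cell_type = rep(x$types, times = length(x$genes)),
    mean = as.vector(x$mean),
    dispersion = as.vector(x$dispersion),
    status = as.vector(x$status),
    stringsAsFactors = FALSE)
}

#' Sample a counts matrix from fitted NB models
#'
#' Draws each entry independently from the (gene, cell type) model of the
#' cell's assigned type: NB for fitted models, Poisson for the fallback, and
#' exact zeros for filtered genes. Reproducible under a fixed seed.
#'
#' @param models an `nb_models` object from [fit_nb_models()].
#' @param assignments character vector of cell-type labels, one per cell to
#'   simulate.
#' @param seed integer seed.
#' @return cells x genes integer matrix with `assignments` in row order.
#' @export
sample_counts <- function(models, assignments, seed) {
  stopifnot(inherits(models, "nb_models"))
  assignments <- as.character(assignments)
  bad <- setdiff(unique(assignments), models$types)
  if (length(bad))
    stop("no fitted models for cell type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- length(assignments)
  ng <- length(models$genes)
  out <- matrix(0L, n, ng, dimnames = list(NULL, models$genes))
  with_seed(seed, {
    for (ty in models$types) {
      rows <- which(assignments == ty)
      if (!length(rows)) next
      st <- models$status[ty, ]
      mu <- models$mean[ty, ]
      size <- models$dispersion[ty, ]
      nb <- which(st == "fitted")
      if (length(nb)) {
        out[rows, nb] <- stats::rnbinom(
          length(rows) * length(nb),
          size = rep(size[nb], each = length(rows)),
          mu = rep(mu[nb], each = length(rows)))
      }
      po <- which(st == "poisson_fallback")
      if (length(po)) {
        out[rows, po] <- stats::rpois(
          length(rows) * length(po),
          lambda = rep(mu[po], each = length(rows)))
      }
    }
  })
  out
}

#' Rank-based skew assignment
#'
#' Within each (gene, cell type) group, reassigns the sampled values so that
#' a seeded random subset of `ceiling(high_fraction * n)` cells receives the
#' largest values (in descending order) and the remaining cells receive the
#' rest in seeded random order. A pure permutation: the per-group value
#' multiset is exactly preserved, modeling skewed expression where a subset
#' of cells carries high expression over a baseline majority.
#'
#' @param counts cells x genes matrix.
#' @param assignments cell-type label per row.
#' @param high_fraction fraction of cells assigned the high values,
#'   in (0, 1) (default 0.3).
#' @param seed integer seed.
#' @return Matrix of the same dimensions and per-group value multisets.
#' @export
apply_skew <- function(counts, assignments, high_fraction = 0.3, seed = 1L) {
  stopifnot(is.matrix(counts), length(assignments) == nrow(counts))
  if (!(high_fraction > 0 && high_fraction < 1))
    stop("high_fraction must be in (0, 1)", call. = FALSE)
  out <- counts
  with_seed(seed, {
    for (ty in sort(unique(as.character(assignments)))) {
      rows <- which(assignments == ty)
      n <- length(rows)
      if (n < 2) next
      nh <- ceiling(high_fraction * n)
      for (j in seq_len(ncol(counts))) {
        vals <- sort(counts[rows, j], decreasing = TRUE)
        high <- sample(rows, nh)
        low <- setdiff(rows, high)
        if (length(low) > 1) low <- sample(low)
        out[high, j] <- vals[seq_len(nh)]
        if (length(low)) out[low, j] <- vals[(nh + 1):n]
      }
    }
  })
  out
}
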