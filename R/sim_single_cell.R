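#' Cell map: planar coordinates with cell-type labels
#'
#' @param coordinates n x 2 numeric matrix of planar positions.
#' @param types character label per cell.
#' @return An object of class `cell_map`.
#' @export
cell_map <- function(coordinates, types) {
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(coordinates) == 2, nrow(coordinates) == length(types),
            all(is.finite(coordinates)))
  colnames(coordinates) <- c("x", "y")
  structure(list(coordinates = coordinates, types = as.character(types)),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d cells, %d types\n", nrow(x$coordinates),
              length(unique(x$types))))
  invisible(x)
}

# Index of the nearest seed point for each row of pts.
nearest_seed <- function(pts, seeds) {
  d2 <- outer(rowSums(pts^2), rowSums(seeds^2), "+") - 2 * pts %*% t(seeds)
  max.col(-d2, ties.method = "first")
}

#' Voronoi tissue layout
#'
#' Places one seed point per cell type in the unit square and positions each
#' cell uniformly at random inside its type's Voronoi region (rejection
#' sampling against nearest-seed membership). This yields contiguous,
#' type-specific territories resembling tissue organization, with variable
#' inter-territory distances. Per-type cell counts follow largest-remainder
#' rounding of the proportions; types allocated zero cells are dropped with
#' a warning.
#'
#' @param n_cells total number of cells (at least the number of types).
#' @param type_proportions named proportions summing to 1.
#' @param seed integer seed.
#' @param seed_points optional fixed types x 2 matrix of territory seed
#'   points (rows in `names(type_proportions)` order); drawn uniformly when
#'   omitted.
#' @return A [cell_map]; territory seed points in attribute `"seed_points"`.
#' @export
voronoi_layout <- function(n_cells, type_proportions, seed = 1L,
                           seed_points = NULL) {
  n_cells <- check_scalar_count(n_cells, "n_cells")
  if (is.null(names(type_proportions)) ||
      abs(sum(type_proportions) - 1) > 1e-9)
    stop("type_proportions must be named and sum to 1", call. = FALSE)
  types <- names(type_proportions)
  if (n_cells < length(types))
    stop("n_cells must be at least the number of types", call. = FALSE)
  alloc <- largest_remainder(n_cells, type_proportions)
  if (any(alloc == 0)) {
    warning("type(s) allocated zero cells omitted: ",
            paste(names(alloc)[alloc == 0], collapse = ", "))
    types <- names(alloc)[alloc > 0]
    alloc <- alloc[types]
  }
  with_seed(seed, {
    if (is.null(seed_points)) {
      seed_points <- cbind(stats::runif(length(types)),
                           stats::runif(length(types)))
    } else {
      seed_points <- as.matrix(seed_points)[seq_along(types), , drop = FALSE]
    }
    rownames(seed_points) <- types
    coords <- matrix(NA_real_, sum(alloc), 2)
    labels <- rep(types, alloc)
    need <- alloc
    filled <- stats::setNames(integer(length(types)), types)
    offsets <- c(0, cumsum(alloc))
    names(offsets) <- c(types, "")
    guard <- 0L
    while (any(need > 0) && guard < 10000L) {
      guard <- guard + 1L
      batch <- max(2000L, 4L * sum(need))
      pts <- cbind(stats::runif(batch), stats::runif(batch))
      owner <- nearest_seed(pts, seed_points)
      for (i in seq_along(types)) {
        if (need[i] == 0) next
        hit <- which(owner == i)
        take <- min(length(hit), need[i])
        if (take > 0) {
          rows <- offsets[i] + filled[i] + seq_len(take)
          coords[rows, ] <- pts[hit[seq_len(take)], , drop = FALSE]
          filled[i] <- filled[i] + take
          need[i] <- need[i] - take
        }
      }
    }
    if (any(need > 0))
      stop("rejection sampling failed to fill all territories", call. = FALSE)
    out <- cell_map(coords, labels)
    attr(out, "seed_points") <- seed_points
    out
  })
}

#' Euclidean k-nearest neighbors
#'
#' Exact (brute-force) k-nearest-neighbor lists, self excluded, sorted by
#' distance with ties broken toward the lower index.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k neighborhood size, `1 <= k < n`.
#' @param query optional indices of the cells to compute lists for
#'   (default: all cells). Neighbors are always searched among all cells.
#' @return List of integer vectors of length `k`, one per query cell.
#' @export
knn_neighbors <- function(coords, k, query = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- check_scalar_count(k, "k")
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  if (is.null(query)) query <- seq_len(n)
  ss <- rowSums(coords^2)
  lapply(query, function(i) {
    d2 <- ss + ss[i] - 2 * drop(coords %*% coords[i, ])
    d2[i] <- Inf
    ord <- order(d2, seq_len(n))
    ord[seq_len(k)]
  })
}

#' Truth set of embedded interactions
#'
#' @param interactions data.frame with columns `ligand`, `receptor`,
#'   `sender_type`, `receiver_type`, `fold`, `k`, `mode`
#'   (`"proximal"`/`"distal"`), `label` (`"positive"`/`"negative_control"`).
#' @param universe data.frame of all evaluated
#'   (sender_type, receiver_type, ligand, receptor) tuples.
#' @return An object of class `truth_set`.
#' @export
truth_set <- function(interactions, universe) {
  stopifnot(is.data.frame(interactions), is.data.frame(universe))
  if (nrow(interactions)) {
    stopifnot(all(c("ligand", "receptor", "sender_type", "receiver_type",
                    "label") %in% names(interactions)))
    if (any(interactions$mode == "distal" &
            interactions$label != "negative_control"))
      stop("distal interactions must be negative controls", call. = FALSE)
    pos <- interactions[interactions$label == "positive", , drop = FALSE]
    if (nrow(pos) &&
        !all(tuple_key(pos) %in% tuple_key(universe)))
      stop("positive interactions must lie inside the universe", call. = FALSE)
  }
  structure(list(interactions = interactions, universe = universe),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d positives / universe of %d tuples\n",
              sum(x$interactions$label == "positive"), nrow(x$universe)))
  invisible(x)
}

tuple_key <- function(df) {
  paste(df$sender_type, df$receiver_type, df$ligand, df$receptor, sep = "\r")
}

# All ordered (sender, receiver) type pairs crossed with the evaluated pairs.
make_universe <- function(types, pairs) {
  grid <- expand.grid(sender_type = types, receiver_type = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(grid, pairs[, c("ligand", "receptor")], by = NULL)
  out[order(out$sender_type, out$receiver_type, out$ligand, out$receptor),
      c("sender_type", "receiver_type", "ligand", "receptor")]
}

#' Embed ground-truth L-R interactions at single-cell resolution
#'
#' Proximal mode: multiplies the ligand counts of every sender-type cell by
#' `fold` (rounded half up) and the receptor counts of the receiver-type
#' cells that appear in the k-nearest-neighbor list of at least one sender
#' cell, recording the (sender, receiver, ligand, receptor) tuple as a
#' positive. Distal mode leaves labels as negative controls: upregulation is
#' applied to sender and receiver territories that the caller has placed in
#' non-adjacent regions (see [simulate_sc_dataset()]), probing whether
#' methods suppress calls when spatial proximity is absent.
#'
#' @param counts cells x genes matrix (columns named by gene).
#' @param cellmap a [cell_map] aligned with `counts` rows.
#' @param pairs data.frame of L-R pairs to embed (`ligand`, `receptor`).
#' @param sender,receiver cell-type labels (distinct unless
#'   `allow_autocrine`).
#' @param fold multiplicative fold change (> 1).
#' @param k neighborhood size.
#' @param mode `"proximal"` or `"distal"`.
#' @param universe_pairs data.frame of all evaluated L-R pairs defining the
#'   truth universe (defaults to `pairs`).
#' @param allow_autocrine permit `sender == receiver` (default FALSE).
#' @return List with elements `counts` (modified matrix) and `truth`
#'   (a [truth_set]).
#' @export
embed_interactions_sc <- function(counts, cellmap, pairs, sender, receiver,
                                  fold, k, mode = c("proximal", "distal"),
                                  universe_pairs = pairs,
                                  allow_autocrine = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cellmap, "cell_map"), nrow(counts) ==
              nrow(cellmap$coordinates))
  if (sender == receiver && !allow_autocrine)
    stop("autocrine embedding (sender == receiver) must be enabled explicitly",
         call. = FALSE)
  sender_cells <- which(cellmap$types == sender)
  receiver_cells <- which(cellmap$types == receiver)
  nn <- knn_neighbors(cellmap$coordinates, k, query = sender_cells)
  in_nbhd <- intersect(unique(unlist(nn)), receiver_cells)
  if (!length(in_nbhd) && mode == "proximal")
    warning("no receiver cell lies in any sender neighborhood; ",
            "recording tuples with zero receptor-upregulated cells")
  lig <- intersect(unique(pairs$ligand), colnames(counts))
  rec <- intersect(unique(pairs$receptor), colnames(counts))
  counts[sender_cells, lig] <-
    fold_scale(counts[sender_cells, lig], fold, is.integer(counts))
  if (length(in_nbhd))
    counts[in_nbhd, rec] <-
      fold_scale(counts[in_nbhd, rec], fold, is.integer(counts))
  label <- if (mode == "proximal") "positive" else "negative_control"
  interactions <- data.frame(
    ligand = pairs$ligand, receptor = pairs$receptor,
    sender_type = if (nrow(pairs)) sender else character(0),
    receiver_type = if (nrow(pairs)) receiver else character(0),
    fold = if (nrow(pairs)) fold else numeric(0),
    k = if (nrow(pairs)) k else integer(0),
    mode = if (nrow(pairs)) mode else character(0),
    label = if (nrow(pairs)) label else character(0),
    stringsAsFactors = FALSE)
  universe <- make_universe(sort(unique(cellmap$types)), universe_pairs)
  list(counts = counts,
       truth = truth_set(interactions, universe),
       receptor_upregulated_cells = in_nbhd)
}

# Seed-point configurations for the distal negative control: resample until
# the sender and receiver territories share no Voronoi boundary and their
# seeds are at least twice the median seed spacing apart.
distal_seed_points <- function(types, sender, receiver, seed,
                               grid_n = 60L, max_tries = 200L) {
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      pts <- cbind(stats::runif(length(types)), stats::runif(length(types)))
      rownames(pts) <- types
      d <- as.matrix(stats::dist(pts))
      diag(d) <- Inf
      med <- stats::median(apply(d, 1, min))  # median seed spacing
      i <- match(sender, types); j <- match(receiver, types)
      if (d[i, j] < 2 * med) next
      g <- seq(0, 1, length.out = grid_n)
      gp <- as.matrix(expand.grid(x = g, y = g))
      owner <- matrix(nearest_seed(gp, pts), grid_n, grid_n)
      row_adj <- (owner[-1, ] == i & owner[-grid_n, ] == j) |
        (owner[-1, ] == j & owner[-grid_n, ] == i)
      col_adj <- (owner[, -1] == i & owner[, -grid_n] == j) |
        (owner[, -1] == j & owner[, -grid_n] == i)
      if (!any(row_adj) && !any(col_adj)) return(pts)
    }
    stop("could not place sender and receiver in non-adjacent regions",
         call. = FALSE)
  })
}

#' Simulate one single-cell-resolution spatial dataset
#'
#' Orchestrates the full generative pipeline: Voronoi layout of cell-type
#' territories, NB count sampling from fitted models, optional rank-based
#' skew, and ground-truth embedding of the configured L-R pairs in a
#' sender-receiver k-neighborhood (proximal) or in deliberately separated
#' territories (distal negative control).
#'
#' @param models an `nb_models` object from [fit_nb_models()].
#' @param pairs data.frame of feasibility-filtered L-R pairs to embed.
#' @param sender,receiver cell-type labels.
#' @param n_cells number of cells (default 3593).
#' @param type_proportions named proportions (default
#'   [sc_default_proportions()]).
#' @param fold fold change, one of the default grid 5, 10, 15.
#' @param k neighborhood size, one of the default grid 18, 36, 60.
#' @param mode `"proximal"` or `"distal"`.
#' @param skew optional `high_fraction` in (0,1) for [apply_skew()];
#'   `NULL` disables skewing.
#' @param universe_pairs L-R pairs defining the truth universe
#'   (default `pairs`).
#' @param seed master seed; stage seeds are derived with [derive_seed()].
#' @return A `sim_bundle`: list with `counts`, `cellmap`, `truth`,
#'   `manifest`.
#' @export
simulate_sc_dataset <- function(models, pairs, sender, receiver,
                                n_cells = 3593L,
                                type_proportions = sc_default_proportions(),
                                fold = 10, k = 36L,
                                mode = c("proximal", "distal"),
                                skew = NULL, universe_pairs = pairs,
                                seed = 1L) {
  mode <- match.arg(mode)
  types <- names(type_proportions)
  seed_points <- if (mode == "distal") {
    distal_seed_points(types, sender, receiver, derive_seed(seed, "distal"))
  } else NULL
  map <- voronoi_layout(n_cells, type_proportions,
                        seed = derive_seed(seed, "layout"),
                        seed_points = seed_points)
  counts <- sample_counts(models, map$types, seed = derive_seed(seed, "counts"))
  if (!is.null(skew))
    counts <- apply_skew(counts, map$types, high_fraction = skew,
                         seed = derive_seed(seed, "skew"))
  emb <- embed_interactions_sc(counts, map, pairs, sender, receiver,
                               fold = fold, k = k, mode = mode,
                               universe_pairs = universe_pairs)
  manifest <- list(
    command = "simulate-sc", n_cells = n_cells,
    type_proportions = as.list(type_proportions),
    sender = sender, receiver = receiver, fold = fold, k = k, mode = mode,
    skew = skew, n_pairs = nrow(pairs), seed = seed,
    package_version = as.character(utils::packageVersion("ccibench")),
    resolution = "single_cell")
  structure(list(counts = emb$counts, cellmap = map, truth = emb$truth,
                 receptor_upregulated_cells = emb$receptor_upregulated_cells,
                 manifest = manifest),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %s: %d x %d counts, %d positive truth tuples\n",
              x$manifest$resolution, nrow(x$counts), ncol(x$counts),
              sum(x$truth$interactions$label == "positive")))
  invisible(x)
}
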