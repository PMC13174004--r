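#' Spot scaffold: capture-spot coordinates with adjacency
#'
#' Builds the spatial scaffold for spot-level simulations either from real
#' spot-center coordinates (matrix or TSV with `x`, `y` columns) or as a
#' generated hexagonal grid sized by default to 782 spots, matching a
#' typical Visium section. Two spots are adjacent when their center distance
#' is at most 1.5 times the minimum positive inter-spot distance, which
#' captures the six hexagonal neighbors of an interior Visium spot.
#'
#' @param coordinates optional s x 2 matrix, data.frame, or path to a TSV
#'   with columns `x` and `y`. When omitted a hex grid is generated.
#' @param rows,cols,pitch hex-grid parameters (defaults 23 x 34 = 782 spots
#'   at unit pitch).
#' @return An object of class `spot_scaffold` with `coordinates` (s x 2)
#'   and `adjacency` (list of neighbor index vectors, symmetric, no self).
#' @export
build_scaffold <- function(coordinates = NULL, rows = 23L, cols = 34L,
                           pitch = 1) {
  if (is.null(coordinates)) {
    rows <- check_scalar_count(rows, "rows")
    cols <- check_scalar_count(cols, "cols")
    g <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
    coordinates <- cbind(
      x = g$col * pitch + (g$row %% 2) * pitch / 2,
      y = g$row * pitch * sqrt(3) / 2)
  } else if (is.character(coordinates)) {
    tab <- utils::read.table(coordinates, sep = "\t", header = TRUE)
    if (!all(c("x", "y") %in% names(tab)))
      stop("coordinate TSV must have columns 'x' and 'y'", call. = FALSE)
    coordinates <- cbind(x = tab$x, y = tab$y)
  } else {
    coordinates <- as.matrix(coordinates)
    colnames(coordinates) <- c("x", "y")
  }
  if (anyDuplicated(coordinates))
    stop("duplicate spot coordinates", call. = FALSE)
  n <- nrow(coordinates)
  adjacency <- vector("list", n)
  if (n > 1) {
    d <- as.matrix(stats::dist(coordinates))
    diag(d) <- Inf
    thr <- 1.5 * min(d)
    adjacency <- lapply(seq_len(n), function(i) unname(which(d[i, ] <= thr)))
  } else {
    adjacency[[1]] <- integer(0)
  }
  structure(list(coordinates = coordinates, adjacency = adjacency),
            class = "spot_scaffold")
}

#' @export
print.spot_scaffold <- function(x, ...) {
  cat(sprintf("<spot_scaffold> %d spots, mean degree %.1f\n",
              nrow(x$coordinates), mean(lengths(x$adjacency))))
  invisible(x)
}

#' Select the central interaction region and its adjacent ring
#'
#' The central region is the `n_central` spots nearest the coordinate
#' centroid (ties broken by index); the adjacent ring is every non-central
#' spot with at least one central neighbor under the scaffold adjacency.
#' Ligands are later upregulated in the central region and receptors in the
#' ring, the paracrine spatial configuration of the spot-level truth.
#'
#' @param scaffold a [build_scaffold()] result.
#' @param n_central number of central spots (default 130).
#' @return List with integer vectors `central` and `adjacent` (disjoint).
#' @export
select_central_region <- function(scaffold, n_central = 130L) {
  stopifnot(inherits(scaffold, "spot_scaffold"))
  n <- nrow(scaffold$coordinates)
  n_central <- check_scalar_count(n_central, "n_central")
  if (n_central >= n)
    stop("n_central must be smaller than the number of spots", call. = FALSE)
  ctr <- colMeans(scaffold$coordinates)
  d <- sqrt(rowSums(sweep(scaffold$coordinates, 2, ctr)^2))
  central <- order(d, seq_len(n))[seq_len(n_central)]
  in_central <- logical(n); in_central[central] <- TRUE
  adjacent <- which(!in_central &
                      vapply(scaffold$adjacency,
                             function(nb) any(in_central[nb]), logical(1)))
  list(central = sort(central), adjacent = adjacent)
}

#' Compose cell-type mixtures per spot
#'
#' Assigns `cells_per_spot` cells to every spot by multinomial draws from
#' the type proportions. Inside the designated region, purity regimes
#' reshape the draw: `"high"` re-weights so the designated dominant type has
#' expected share 0.85 and resamples until its realized share exceeds 0.8;
#' `"mixed"` targets 0.6 and resamples until the realized dominant share is
#' below 0.8. The 0.8 boundary separates spots dominated by one cell type
#' from genuinely mixed spots.
#'
#' @param scaffold a `spot_scaffold`.
#' @param proportions named type proportions summing to 1.
#' @param cells_per_spot cells per spot (default 12, the typical Visium
#'   capture of 10-15 cells).
#' @param purity_regime `"none"`, `"high"` or `"mixed"`.
#' @param region integer spot indices subject to the regime.
#' @param seed integer seed.
#' @param dominant_type designated dominant type for regime spots: length 1
#'   or `length(region)` (default: the most abundant type overall).
#' @param max_retries resampling bound per spot before erroring.
#' @return An object of class `spot_composition`: list with `counts`
#'   (spots x types integer matrix), `dominant_type`, `purity`.
#' @export
compose_spots <- function(scaffold, proportions,
                          cells_per_spot = 12L,
                          purity_regime = c("none", "high", "mixed"),
                          region = integer(0), seed = 1L,
                          dominant_type = NULL, max_retries = 1000L) {
  stopifnot(inherits(scaffold, "spot_scaffold"))
  purity_regime <- match.arg(purity_regime)
  cells_per_spot <- check_scalar_count(cells_per_spot, "cells_per_spot")
  if (abs(sum(proportions) - 1) > 1e-9 || is.null(names(proportions)))
    stop("proportions must be named and sum to 1", call. = FALSE)
  types <- names(proportions)
  n <- nrow(scaffold$coordinates)
  if (is.null(dominant_type)) dominant_type <- types[which.max(proportions)]
  if (length(dominant_type) == 1L) dominant_type <-
      rep(dominant_type, length(region))
  stopifnot(length(dominant_type) == length(region))
  target <- c(high = 0.85, mixed = 0.6)
  counts <- matrix(0L, n, length(types), dimnames = list(NULL, types))
  with_seed(seed, {
    for (i in seq_len(n)) {
      ridx <- match(i, region)
      if (purity_regime != "none" && !is.na(ridx)) {
        dom <- dominant_type[ridx]
        w <- proportions
        w[dom] <- 0
        w <- w / sum(w) * (1 - target[[purity_regime]])
        w[dom] <- target[[purity_regime]]
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          draw <- stats::rmultinom(1, cells_per_spot, w)[, 1]
          share <- if (purity_regime == "high") draw[dom] / cells_per_spot
                   else max(draw) / cells_per_spot
          if ((purity_regime == "high" && share > 0.8) ||
              (purity_regime == "mixed" && share < 0.8)) { ok <- TRUE; break }
        }
        if (!ok)
          stop(sprintf(
            "purity constraint for regime '%s' infeasible at spot %d",
            purity_regime, i), call. = FALSE)
        counts[i, ] <- draw
      } else {
        counts[i, ] <- stats::rmultinom(1, cells_per_spot, proportions)[, 1]
      }
    }
  })
  dom <- types[max.col(counts, ties.method = "first")]
  purity <- apply(counts, 1, max) / cells_per_spot
  structure(list(counts = counts, dominant_type = dom, purity = purity,
                 cells_per_spot = cells_per_spot),
            class = "spot_composition")
}

#' @export
print.spot_composition <- function(x, ...) {
  cat(sprintf("<spot_composition> %d spots x %d types, %d cells/spot\n",
              nrow(x$counts), ncol(x$counts), x$cells_per_spot))
  invisible(x)
}

# Expand a composition into per-cell type assignments plus the cell->spot map.
expand_roster <- function(composition) {
  types <- colnames(composition$counts)
  per_spot <- rowSums(composition$counts)
  spot_of <- rep(seq_len(nrow(composition$counts)), per_spot)
  type_of <- unlist(lapply(seq_len(nrow(composition$counts)), function(i)
    rep(types, composition$counts[i, ])), use.names = FALSE)
  list(spot_of = spot_of, type_of = type_of)
}

# Pure embedding step on an already-sampled cell-level matrix: fold-scale
# ligand counts of sender cells in central spots and receptor counts of
# receiver cells in adjacent spots (round half up). No RNG.
embed_spot_cells <- function(cell_counts, spot_of, type_of, central, adjacent,
                             pairs, sender, receiver, fold) {
  lig <- intersect(unique(pairs$ligand), colnames(cell_counts))
  rec <- intersect(unique(pairs$receptor), colnames(cell_counts))
  s_cells <- which(spot_of %in% central & type_of == sender)
  r_cells <- which(spot_of %in% adjacent & type_of == receiver)
  if (!length(s_cells))
    warning("sender type absent from all central spots; zero embedding")
  if (length(s_cells) && length(lig))
    cell_counts[s_cells, lig] <-
      fold_scale(cell_counts[s_cells, lig], fold, is.integer(cell_counts))
  if (length(r_cells) && length(rec))
    cell_counts[r_cells, rec] <-
      fold_scale(cell_counts[r_cells, rec], fold, is.integer(cell_counts))
  cell_counts
}

# Sum cell-level counts into spot-level rows.
aggregate_spots <- function(cell_counts, spot_of, n_spots) {
  out <- rowsum(cell_counts, group = factor(spot_of, levels = seq_len(n_spots)))
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Sample cell-level counts, embed truth, and aggregate to spots
#'
#' Samples each spot's 12-cell roster from the fitted NB models, optionally
#' applies the rank-based skew, fold-scales the ligand counts of sender-type
#' cells in central spots and the receptor counts of receiver-type cells in
#' adjacent spots, then sums cells within each spot to produce the
#' spot-level expression matrix. Peripheral spots are untouched by the
#' embedding.
#'
#' @param models an `nb_models` object.
#' @param composition a [compose_spots()] result.
#' @param central,adjacent integer spot index vectors.
#' @param pairs L-R pairs to embed.
#' @param sender,receiver cell-type labels.
#' @param fold fold change.
#' @param skew optional `high_fraction` for [apply_skew()] (NULL = off).
#' @param seed integer seed.
#' @return spots x genes integer matrix.
#' @export
simulate_and_embed_spot <- function(models, composition, central, adjacent,
                                    pairs, sender, receiver, fold,
                                    skew = NULL, seed = 1L) {
  stopifnot(inherits(models, "nb_models"),
            inherits(composition, "spot_composition"))
  roster <- expand_roster(composition)
  cell_counts <- sample_counts(models, roster$type_of, seed = seed)
  if (!is.null(skew))
    cell_counts <- apply_skew(cell_counts, roster$type_of,
                              high_fraction = skew,
                              seed = derive_seed(seed, "skew"))
  cell_counts <- embed_spot_cells(cell_counts, roster$spot_of, roster$type_of,
                                  central, adjacent, pairs, sender, receiver,
                                  fold)
  aggregate_spots(cell_counts, roster$spot_of, nrow(composition$counts))
}

#' Label spot-level truth by global quantile thresholds
#'
#' An embedded pair's (sender, receiver, ligand, receptor) tuple is positive
#' iff the mean ligand expression over central spots exceeds the ligand's
#' global q-quantile over all spots AND the mean receptor expression over
#' adjacent spots exceeds the receptor's global q-quantile. The quantile
#' grid 0.25 / 0.5 / 0.75 mimics increasingly stringent notions of
#' overexpression relative to global signal sparsity. All other universe
#' tuples are negative.
#'
#' @param spot_counts spots x genes matrix.
#' @param central,adjacent integer spot index vectors.
#' @param pairs embedded L-R pairs.
#' @param sender,receiver cell-type labels of the embedding.
#' @param q quantile in (0, 1).
#' @param types all evaluated cell types (defines the universe).
#' @param universe_pairs L-R pairs defining the universe (default `pairs`).
#' @param fold,k,mode passthrough metadata recorded on the interactions.
#' @return A [truth_set].
#' @export
label_spot_truth <- function(spot_counts, central, adjacent, pairs,
                             sender, receiver, q, types,
                             universe_pairs = pairs,
                             fold = NA_real_, mode = "proximal") {
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)", call. = FALSE)
  if (!length(adjacent)) {
    warning("empty adjacent ring: all embedded tuples labeled negative")
  }
  positive <- vapply(seq_len(nrow(pairs)), function(i) {
    lig <- pairs$ligand[i]; rec <- pairs$receptor[i]
    if (!lig %in% colnames(spot_counts) || !rec %in% colnames(spot_counts))
      return(FALSE)
    if (!length(adjacent)) return(FALSE)
    mean(spot_counts[central, lig]) >
      stats::quantile(spot_counts[, lig], q, names = FALSE) &&
      mean(spot_counts[adjacent, rec]) >
      stats::quantile(spot_counts[, rec], q, names = FALSE)
  }, logical(1))
  interactions <- data.frame(
    ligand = pairs$ligand, receptor = pairs$receptor,
    sender_type = sender, receiver_type = receiver,
    fold = fold, k = NA_integer_, mode = mode,
    label = ifelse(positive, "positive", "negative"),
    stringsAsFactors = FALSE)
  truth_set(interactions, make_universe(sort(types), universe_pairs))
}

#' Simulate one spot-level spatial dataset
#'
#' Orchestrates scaffold construction, central-region selection, spot
#' composition (with optional purity regime on the interacting region),
#' NB sampling with embedding and aggregation, and quantile truth labeling.
#'
#' @param models an `nb_models` object.
#' @param pairs feasibility-filtered L-R pairs to embed.
#' @param sender,receiver cell-type labels.
#' @param scaffold optional prebuilt `spot_scaffold` (default: 782-spot hex
#'   grid).
#' @param proportions named type proportions (default
#'   [spot_default_proportions()]).
#' @param n_central central-region size (default 130).
#' @param cells_per_spot cells per spot (default 12).
#' @param fold fold change (default 10).
#' @param q truth quantile, one of the default grid 0.25 / 0.5 / 0.75.
#' @param purity_regime `"none"`, `"high"` or `"mixed"` on the interacting
#'   (central + adjacent) spots; `"high"` designates the sender type
#'   dominant in central spots and the receiver type in adjacent spots.
#' @param skew optional `high_fraction` for [apply_skew()].
#' @param universe_pairs L-R pairs defining the truth universe.
#' @param seed master seed.
#' @return A `sim_bundle` with `counts` (spots x genes), `scaffold`,
#'   `composition`, `regions`, `truth`, `manifest`.
#' @export
simulate_spot_dataset <- function(models, pairs, sender, receiver,
                                  scaffold = NULL,
                                  proportions = spot_default_proportions(),
                                  n_central = 130L, cells_per_spot = 12L,
                                  fold = 10, q = 0.5,
                                  purity_regime = c("none", "high", "mixed"),
                                  skew = NULL, universe_pairs = pairs,
                                  seed = 1L) {
  purity_regime <- match.arg(purity_regime)
  if (is.null(scaffold)) scaffold <- build_scaffold()
  regions <- select_central_region(scaffold, n_central)
  region <- c(regions$central, regions$adjacent)
  dominant <- c(rep(sender, length(regions$central)),
                rep(receiver, length(regions$adjacent)))
  composition <- compose_spots(scaffold, proportions, cells_per_spot,
                               purity_regime = purity_regime, region = region,
                               seed = derive_seed(seed, "composition"),
                               dominant_type = if (purity_regime == "none")
                                 NULL else dominant)
  counts <- simulate_and_embed_spot(models, composition, regions$central,
                                    regions$adjacent, pairs, sender, receiver,
                                    fold = fold, skew = skew,
                                    seed = derive_seed(seed, "counts"))
  truth <- label_spot_truth(counts, regions$central, regions$adjacent, pairs,
                            sender, receiver, q = q,
                            types = names(proportions),
                            universe_pairs = universe_pairs, fold = fold)
  manifest <- list(
    command = "simulate-spot", n_spots = nrow(scaffold$coordinates),
    n_central = n_central, cells_per_spot = cells_per_spot,
    proportions = as.list(proportions), sender = sender, receiver = receiver,
    fold = fold, q = q, purity_regime = purity_regime, skew = skew,
    n_pairs = nrow(pairs), seed = seed,
    package_version = as.character(utils::packageVersion("ccibench")),
    resolution = "spot")
  structure(list(counts = counts, scaffold = scaffold,
                 composition = composition, regions = regions, truth = truth,
                 manifest = manifest),
            class = "sim_bundle")
}
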