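#' Interaction call set
#'
#' Standardized container for one method's predicted interactions. Each
#' record is an ordered (ligand, receptor, sender_type, receiver_type)
#' tuple with a score and/or a p-value (and optionally a rank fraction for
#' score-only tools). Keys must be unique within a method.
#'
#' @param records data.frame with columns `ligand`, `receptor`,
#'   `sender_type`, `receiver_type` and at least one of `p_value`, `score`,
#'   `rank_fraction`.
#' @param method method name.
#' @return An object of class `interaction_call_set`.
#' @export
interaction_call_set <- function(records, method = "method") {
  stopifnot(is.data.frame(records))
  need <- c("ligand", "receptor", "sender_type", "receiver_type")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing call columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!any(c("p_value", "score", "rank_fraction") %in% names(records)))
    stop("records need at least one of p_value / score / rank_fraction",
         call. = FALSE)
  if (nrow(records) && anyDuplicated(tuple_key(records)))
    stop("duplicate (ligand, receptor, sender, receiver) keys", call. = FALSE)
  if (!is.null(records$p_value) && nrow(records)) {
    bad <- which(!is.na(records$p_value) &
                   (records$p_value < 0 | records$p_value > 1))
    if (length(bad))
      stop("p_value outside [0, 1] in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(method = method, records = records),
            class = "interaction_call_set")
}

#' @export
print.interaction_call_set <- function(x, ...) {
  cat(sprintf("<interaction_call_set> %s: %d records\n", x$method,
              nrow(x$records)))
  invisible(x)
}

#' Confusion counts against a truth set
#'
#' Thresholds the call set (strict `p < alpha` for p-value calls, or
#' `rank_fraction <= alpha` for score-ranked calls) and intersects with the
#' truth universe: TP = called positives, FP = called non-positives,
#' FN = missed positives, TN = the rest of the universe. Calls outside the
#' universe are dropped and their number reported in attribute
#' `"n_dropped"`.
#'
#' @param calls an [interaction_call_set].
#' @param truth a [truth_set].
#' @param alpha significance level (conventional grid 0.05, 0.1, 0.15, 0.2)
#'   or rank-fraction cutoff (e.g. 0.2 for the top 20 percent).
#' @param use `"p_value"` or `"rank"`; which record field is thresholded.
#' @return An object of class `confusion_counts`: list `TP`, `FP`, `FN`,
#'   `TN` with `TP+FP+FN+TN = |universe|`.
#' @export
confusion_counts <- function(calls, truth, alpha = 0.05,
                             use = c("p_value", "rank")) {
  stopifnot(inherits(calls, "interaction_call_set"),
            inherits(truth, "truth_set"))
  use <- match.arg(use)
  rec <- calls$records
  field <- if (use == "p_value") "p_value" else "rank_fraction"
  if (nrow(rec)) {
    has_any <- rep(FALSE, nrow(rec))
    for (f in c("p_value", "rank_fraction"))
      if (!is.null(rec[[f]])) has_any <- has_any | !is.na(rec[[f]])
    if (any(!has_any))
      stop("records with neither p_value nor rank_fraction at row(s): ",
           paste(which(!has_any), collapse = ", "), call. = FALSE)
    if (is.null(rec[[field]]))
      stop("call set has no ", field, " field", call. = FALSE)
  }
  called <- if (!nrow(rec)) character(0)
    else if (use == "p_value") tuple_key(rec[!is.na(rec$p_value) &
                                               rec$p_value < alpha, ])
    else tuple_key(rec[!is.na(rec$rank_fraction) &
                         rec$rank_fraction <= alpha, ])
  uni <- tuple_key(truth$universe)
  n_dropped <- sum(!called %in% uni)
  called <- intersect(called, uni)
  pos <- intersect(
    tuple_key(truth$interactions[truth$interactions$label == "positive", ,
                                 drop = FALSE]), uni)
  TP <- length(intersect(called, pos))
  FP <- length(setdiff(called, pos))
  FN <- length(setdiff(pos, called))
  TN <- length(uni) - TP - FP - FN
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            n_dropped = n_dropped, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Precision, recall, F1 and specificity
#'
#' Computes precision = TP/(TP+FP), recall = TP/(TP+FN),
#' specificity = TN/(TN+FP) and F1 = 2PR/(P+R). Zero-denominator cases
#' return 0 and are recorded in `degenerate_flags` so that report tables
#' can render them as blank rather than as spurious zeros.
#'
#' @param counts a [confusion_counts] object (or list with TP/FP/FN/TN).
#' @return List with `precision`, `recall`, `f1`, `specificity`,
#'   `degenerate_flags` (character vector).
#' @export
prf_metrics <- function(counts) {
  with(counts, {
    flags <- character(0)
    safe <- function(num, den, flag) {
      if (den == 0) { flags <<- c(flags, flag); 0 } else num / den
    }
    precision <- safe(TP, TP + FP, "precision")
    recall <- safe(TP, TP + FN, "recall")
    specificity <- safe(TN, TN + FP, "specificity")
    f1 <- if (precision + recall == 0) {
      flags <- c(flags, "f1"); 0
    } else 2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall, f1 = f1,
         specificity = specificity, degenerate_flags = flags)
  })
}

#' Normalize a method x scenario metric table
#'
#' Per scenario (column), rescales the metric across methods to [0, 1]:
#' min-max by default, or division by the column maximum (`scheme = "max"`).
#' Columns where every method ties map to 1 for all methods. The per-method
#' summary is the mean of the normalized values over scenarios, the
#' "normalized mean" used to compare methods across heterogeneous scenarios.
#'
#' @param values numeric matrix or data.frame, methods in rows, scenarios in
#'   columns.
#' @param scheme `"minmax"` (default) or `"max"`.
#' @param percent return percentages instead of proportions (default FALSE).
#' @return List with `normalized` (same shape) and `summary` (named
#'   per-method means).
#' @export
normalize_scores <- function(values, scheme = c("minmax", "max"),
                             percent = FALSE) {
  scheme <- match.arg(scheme)
  values <- as.matrix(values)
  if (nrow(values) < 2)
    stop("normalization needs at least two methods per scenario",
         call. = FALSE)
  norm <- apply(values, 2, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) return(rep(1, length(col)))
    if (scheme == "minmax") (col - rng[1]) / diff(rng)
    else col / rng[2]
  })
  norm <- matrix(norm, nrow = nrow(values), dimnames = dimnames(values))
  if (percent) norm <- norm * 100
  list(normalized = norm, summary = rowMeans(norm))
}

#' Jaccard index of two interaction sets
#'
#' Intersection over union of two tuple sets (character vectors of keys or
#' data.frames of ordered interaction tuples). Two empty sets yield 0 with
#' attribute `"degenerate" = TRUE`, the convention used to render absent
#' results as blank in consistency reports.
#'
#' @param set_a,set_b character vectors, or data.frames with `ligand`,
#'   `receptor`, `sender_type`, `receiver_type` columns.
#' @return Numeric in [0, 1].
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(as_tuple_keys(set_a))
  b <- unique(as_tuple_keys(set_b))
  if (!length(a) && !length(b))
    return(structure(0, degenerate = TRUE))
  length(intersect(a, b)) / length(union(a, b))
}

as_tuple_keys <- function(x) {
  if (is.data.frame(x)) tuple_key(x) else as.character(x)
}

#' Mean pairwise Jaccard index over several sets
#'
#' Average of [jaccard_index()] over all n(n-1)/2 unordered pairs of sets,
#' the global reproducibility score used for cross-slice consistency.
#'
#' @param sets list of 2 or more tuple sets.
#' @return Numeric in [0, 1].
#' @export
mean_jaccard <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  pairs <- utils::combn(length(sets), 2)
  mean(apply(pairs, 2, function(ij)
    as.numeric(jaccard_index(sets[[ij[1]]], sets[[ij[2]]]))))
}

#' Spatial proximity rank profile of interaction calls
#'
#' Ranks ordered sender-receiver type pairs by average spatial proximity:
#' the mean Euclidean distance over all cross-type cell pairs (types larger
#' than `subsample_cap` are seeded-subsampled to the cap). Dense ranks
#' ascend from 1 = most proximal; each call is annotated with its type
#' pair's rank, summarizing whether a method preferentially detects
#' proximal (paracrine-like) or distal interactions.
#'
#' @param map a [cell_map], or data.frame with `x`, `y` and a type column
#'   (`cell_type` or `dominant_type`).
#' @param calls an [interaction_call_set].
#' @param subsample_cap per-type subsample cap (default 500).
#' @param seed integer seed for the subsampling.
#' @return List with `pair_ranks` (ordered distinct-type pairs with
#'   `proximity` and dense `rank`), `call_ranks` (call records with a
#'   `rank` column; autocrine calls get NA), and `distribution` (rank
#'   frequency table over calls).
#' @export
distance_rank_profile <- function(map, calls, subsample_cap = 500L,
                                  seed = 1L) {
  if (inherits(map, "cell_map")) {
    coords <- map$coordinates
    types <- map$types
  } else {
    tcol <- intersect(c("cell_type", "dominant_type"), names(map))[1]
    if (is.na(tcol)) stop("map needs a cell_type or dominant_type column",
                          call. = FALSE)
    coords <- cbind(map$x, map$y)
    types <- as.character(map[[tcol]])
  }
  stopifnot(inherits(calls, "interaction_call_set"))
  called_types <- unique(c(calls$records$sender_type,
                           calls$records$receiver_type))
  missing <- setdiff(called_types, types)
  if (length(missing))
    stop("called type(s) absent from the map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ulev <- sort(unique(types))
  idx <- with_seed(seed, lapply(ulev, function(ty) {
    i <- which(types == ty)
    if (length(i) > subsample_cap) sort(sample(i, subsample_cap)) else i
  }))
  names(idx) <- ulev
  pairs <- expand.grid(sender_type = ulev, receiver_type = ulev,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$sender_type != pairs$receiver_type, , drop = FALSE]
  pairs$proximity <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- idx[[pairs$sender_type[r]]]
    b <- idx[[pairs$receiver_type[r]]]
    ax <- coords[a, 1]; ay <- coords[a, 2]
    bx <- coords[b, 1]; by <- coords[b, 2]
    mean(sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2))
  }, numeric(1))
  # dense ranks: equal proximities (within tolerance) share a rank
  prox <- round(pairs$proximity, 12)
  pairs$rank <- match(prox, sort(unique(prox)))
  rownames(pairs) <- NULL
  rec <- calls$records
  key <- paste(rec$sender_type, rec$receiver_type)
  pkey <- paste(pairs$sender_type, pairs$receiver_type)
  rec$rank <- pairs$rank[match(key, pkey)]
  list(pair_ranks = pairs, call_ranks = rec,
       distribution = table(rank = rec$rank))
}
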