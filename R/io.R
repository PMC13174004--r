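#' Ingest a standardized interaction-call table
#'
#' Reads a TSV of interaction calls exported by an external CCI tool into an
#' [interaction_call_set]. Rows with malformed p-values (outside [0, 1] or
#' non-numeric) abort with their line numbers; duplicate
#' (ligand, receptor, sender, receiver) keys are collapsed keeping the
#' minimum p-value, with the number of collapsed rows reported in attribute
#' `"n_collapsed"` on the records.
#'
#' @param path TSV file.
#' @param dialect named list mapping standard columns to the file's column
#'   names (defaults: `ligand`, `receptor`, `sender_type`, `receiver_type`,
#'   `p_value`, `score`, `rank_fraction`) plus optional `sep`.
#' @param method method name (default: file base name).
#' @return An [interaction_call_set].
#' @export
ingest_call_table <- function(path, dialect = list(), method = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- dialect$sep %||% "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  std <- c("ligand", "receptor", "sender_type", "receiver_type",
           "p_value", "score", "rank_fraction")
  cols <- stats::setNames(std, std)
  for (s in std) if (!is.null(dialect[[s]])) cols[s] <- dialect[[s]]
  key_cols <- cols[c("ligand", "receptor", "sender_type", "receiver_type")]
  miss <- key_cols[!key_cols %in% names(tab)]
  if (length(miss))
    stop("missing key column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec <- data.frame(
    ligand = normalize_symbol(tab[[cols["ligand"]]]),
    receptor = normalize_symbol(tab[[cols["receptor"]]]),
    sender_type = as.character(tab[[cols["sender_type"]]]),
    receiver_type = as.character(tab[[cols["receiver_type"]]]),
    stringsAsFactors = FALSE)
  have_stat <- FALSE
  for (s in c("p_value", "score", "rank_fraction")) {
    if (cols[s] %in% names(tab)) {
      rec[[s]] <- suppressWarnings(as.numeric(tab[[cols[s]]]))
      have_stat <- TRUE
    }
  }
  if (!have_stat)
    stop("call table needs at least one of p_value / score / rank_fraction",
         call. = FALSE)
  if (!is.null(rec$p_value)) {
    raw <- tab[[cols["p_value"]]]
    bad <- which(!is.na(raw) & raw != "" &
                   (is.na(rec$p_value) | rec$p_value < 0 | rec$p_value > 1))
    if (length(bad))
      stop("malformed p-value at line(s): ",
           paste(bad + 1L, collapse = ", "),  # +1 for the header line
           call. = FALSE)
  }
  key <- tuple_key(rec)
  n_collapsed <- 0L
  if (anyDuplicated(key)) {
    ord <- if (!is.null(rec$p_value))
      order(key, rec$p_value, na.last = TRUE) else order(key)
    rec <- rec[ord, , drop = FALSE]
    dup <- duplicated(tuple_key(rec))
    n_collapsed <- sum(dup)
    rec <- rec[!dup, , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "n_collapsed") <- n_collapsed
  if (is.null(method)) method <- sub("\\.[^.]*$", "", basename(path))
  interaction_call_set(rec, method = method)
}

#' Write a simulation bundle to a directory
#'
#' Emits the standard file set: counts as Matrix Market (`counts.mtx`,
#' 1-based indices), `genes.tsv`, per-cell or per-spot metadata
#' (`cells.tsv`: cell_id, x, y, cell_type; or `spots.tsv`: spot_id, x, y,
#' dominant_type, purity plus `composition.tsv`), `truth.tsv`,
#' `universe.tsv`, and `manifest.json`. After writing, the bundle is read
#' back and compared for exact round-trip equality of counts, coordinates,
#' labels and truth; on any failure the partial output is removed.
#'
#' @param bundle a `sim_bundle` from [simulate_sc_dataset()] or
#'   [simulate_spot_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  created <- !dir.exists(dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(if (created) dir else
    file.path(dir, c("counts.mtx", "genes.tsv", "cells.tsv", "spots.tsv",
                     "composition.tsv", "truth.tsv", "universe.tsv",
                     "manifest.json")), recursive = TRUE))
  Matrix::writeMM(Matrix::Matrix(bundle$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  utils::write.table(data.frame(gene = colnames(bundle$counts)),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (bundle$manifest$resolution == "single_cell") {
    cells <- data.frame(cell_id = seq_len(nrow(bundle$counts)),
                        x = bundle$cellmap$coordinates[, 1],
                        y = bundle$cellmap$coordinates[, 2],
                        cell_type = bundle$cellmap$types)
    utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    spots <- data.frame(spot_id = seq_len(nrow(bundle$counts)),
                        x = bundle$scaffold$coordinates[, 1],
                        y = bundle$scaffold$coordinates[, 2],
                        dominant_type = bundle$composition$dominant_type,
                        purity = bundle$composition$purity)
    utils::write.table(spots, file.path(dir, "spots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    comp <- data.frame(spot_id = seq_len(nrow(bundle$composition$counts)),
                       bundle$composition$counts, check.names = FALSE)
    utils::write.table(comp, file.path(dir, "composition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(bundle$truth$interactions, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$universe, file.path(dir, "universe.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  back <- read_bundle(dir)
  if (!isTRUE(all.equal(unname(as.matrix(back$counts)),
                        unname(bundle$counts))) ||
      !isTRUE(all.equal(back$truth$interactions$label,
                        bundle$truth$interactions$label)))
    stop("bundle round-trip verification failed", call. = FALSE)
  ok <- TRUE
  invisible(dir)
}

#' Read a simulation bundle back from disk
#'
#' @param dir a directory written by [write_bundle()].
#' @return List with `counts` (dense integer matrix), `meta` (cells.tsv or
#'   spots.tsv content), `composition` (spot bundles), `truth`
#'   (a [truth_set]) and `manifest`.
#' @export
read_bundle <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE)$gene
  colnames(counts) <- genes
  storage.mode(counts) <- "integer"
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  meta_file <- if (manifest$resolution == "single_cell") "cells.tsv"
               else "spots.tsv"
  meta <- utils::read.table(file.path(dir, meta_file), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  composition <- if (file.exists(file.path(dir, "composition.tsv")))
    utils::read.table(file.path(dir, "composition.tsv"), sep = "\t",
                      header = TRUE, check.names = FALSE)
  else NULL
  interactions <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                                    header = TRUE, stringsAsFactors = FALSE)
  universe <- utils::read.table(file.path(dir, "universe.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, composition = composition,
       truth = truth_set(interactions, universe), manifest = manifest)
}

#' Replay a simulation manifest
#'
#' Re-runs the simulator recorded in a bundle manifest with its stored
#' configuration and seed. Given the same fitted models and L-R pairs,
#' replay reproduces the counts matrix exactly.
#'
#' @param manifest a bundle manifest (list, e.g. from [read_bundle()]).
#' @param models the `nb_models` object used for the original run.
#' @param pairs the embedded L-R pair table used for the original run.
#' @param universe_pairs the universe pair table (default `pairs`).
#' @return A `sim_bundle`.
#' @export
replay_manifest <- function(manifest, models, pairs, universe_pairs = pairs) {
  if (manifest$command == "simulate-sc") {
    simulate_sc_dataset(
      models, pairs, manifest$sender, manifest$receiver,
      n_cells = manifest$n_cells,
      type_proportions = unlist(manifest$type_proportions),
      fold = manifest$fold, k = manifest$k, mode = manifest$mode,
      skew = manifest$skew, universe_pairs = universe_pairs,
      seed = manifest$seed)
  } else if (manifest$command == "simulate-spot") {
    simulate_spot_dataset(
      models, pairs, manifest$sender, manifest$receiver,
      proportions = unlist(manifest$proportions),
      n_central = manifest$n_central,
      cells_per_spot = manifest$cells_per_spot,
      fold = manifest$fold, q = manifest$q,
      purity_regime = manifest$purity_regime, skew = manifest$skew,
      universe_pairs = universe_pairs, seed = manifest$seed)
  } else stop("unknown manifest command: ", manifest$command, call. = FALSE)
}

#' Write a synthetic reference to disk
#'
#' Matrix Market counts plus genes and cell-label TSVs, with a JSON sidecar
#' of the generating NB parameters when present.
#'
#' @param ref a [reference_dataset].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "reference_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(ref$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  utils::write.table(data.frame(gene = ref$gene_names),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(cell_id = seq_along(ref$cell_types),
                                cell_type = ref$cell_types),
                     file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ref$params))
    jsonlite::write_json(
      list(mean = as.data.frame(ref$params$mean),
           dispersion = as.data.frame(ref$params$dispersion)),
      file.path(dir, "params.json"), digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a reference dataset from disk
#'
#' Accepts either a directory written by [write_reference()] (MTX + TSVs)
#' or a single dense TSV (genes in columns, a `cell_type` column).
#'
#' @param path directory or dense TSV file.
#' @return A [reference_dataset].
#' @export
read_reference <- function(path) {
  if (dir.exists(path)) {
    counts <- as.matrix(Matrix::readMM(file.path(path, "counts.mtx")))
    storage.mode(counts) <- "integer"
    genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                               header = TRUE)$gene
    cells <- utils::read.table(file.path(path, "cells.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    reference_dataset(counts, cells$cell_type, genes)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!"cell_type" %in% names(tab))
      stop("dense reference TSV needs a 'cell_type' column", call. = FALSE)
    types <- tab$cell_type
    tab$cell_type <- NULL
    tab$cell_id <- NULL
    reference_dataset(as.matrix(tab), types, colnames(tab))
  }
}
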