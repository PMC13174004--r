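#' Ligand-receptor database objects
#'
#' An `lr_database` holds a deduplicated set of ligand-receptor (L-R) pairs.
#' Gene symbols are uppercase-normalized; a pair is flagged `is_complex` when
#' either side of the raw record named more than one subunit (separators
#' `_`, `+`, `&`, `,` as used by CellPhoneDB- and CellChat-style tables).
#' `sources` records the database name(s) each pair came from.
#'
#' @param pairs data.frame with columns `ligand`, `receptor` and optionally
#'   `is_complex` (logical) and `sources` (character, `;`-separated).
#' @param name database name.
#' @return An object of class `lr_database` with elements `name` and `pairs`.
#' @export
lr_database <- function(pairs, name = "lr_db") {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) {
    pairs <- data.frame(ligand = character(), receptor = character(),
                        is_complex = logical(), sources = character(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(pairs$is_complex)) pairs$is_complex <- FALSE
  if (is.null(pairs$sources)) pairs$sources <- name
  pairs$ligand <- normalize_symbol(pairs$ligand)
  pairs$receptor <- normalize_symbol(pairs$receptor)
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor)))
    stop("ligand and receptor symbols must be non-empty after normalization",
         call. = FALSE)
  key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    src <- vapply(split(pairs$sources, key), function(s)
      paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";"),
      character(1))
    pairs <- pairs[keep, , drop = FALSE]
    pairs$sources <- unname(src[paste(pairs$ligand, pairs$receptor, sep = "\r")])
  }
  pairs <- pairs[order(pairs$ligand, pairs$receptor), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(name = name, pairs = pairs), class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("<lr_database> %s: %d pairs (%d complex)\n",
              x$name, nrow(x$pairs), sum(x$pairs$is_complex)))
  invisible(x)
}

#' @export
length.lr_database <- function(x) nrow(x$pairs)

normalize_symbol <- function(x) toupper(trimws(as.character(x)))

# Separators that mark a multi-subunit (complex) ligand or receptor field.
COMPLEX_SEPARATORS <- c("_", "+", "&", ",")

has_complex_separator <- function(x) {
  grepl("[_+&,]", x)
}

#' Load an L-R table from a delimited file
#'
#' Reads a TSV/CSV of ligand-receptor pairs, normalizes gene symbols
#' (uppercase, whitespace stripped), flags multi-subunit complexes by
#' separator detection and deduplicates on the (ligand, receptor) key.
#'
#' @param path path to a delimited text file.
#' @param dialect named list: `ligand_col`, `receptor_col` (column names,
#'   defaults `"ligand"`, `"receptor"`) and `sep` (field separator, default
#'   tab for `.tsv`/`.txt`, comma for `.csv`).
#' @param name database name recorded in `sources`; defaults to the file
#'   base name.
#' @return An [lr_database].
#' @export
load_lr_table <- function(path, dialect = list(), name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- dialect$sep
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lig_col <- dialect$ligand_col %||% "ligand"
  rec_col <- dialect$receptor_col %||% "receptor"
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, quote = "\"", comment.char = ""),
    error = function(e) stop("empty or unreadable L-R table: ", path, call. = FALSE))
  if (nrow(tab) == 0) stop("empty L-R database: ", path, call. = FALSE)
  for (col in c(lig_col, rec_col)) {
    if (!col %in% names(tab))
      stop(sprintf("missing required column '%s' in %s", col, path), call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw_l <- as.character(tab[[lig_col]])
  raw_r <- as.character(tab[[rec_col]])
  pairs <- data.frame(
    ligand = raw_l, receptor = raw_r,
    is_complex = has_complex_separator(raw_l) | has_complex_separator(raw_r),
    sources = name, stringsAsFactors = FALSE)
  lr_database(pairs, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict a database to single-chain pairs
#'
#' Drops every pair where either the ligand or the receptor is a
#' multi-subunit complex, leaving only single-chain L-R pairs compatible
#' with tools that cannot model complexes. Idempotent.
#'
#' @param db an [lr_database].
#' @return An [lr_database] containing exactly the non-complex pairs.
#' @export
filter_single_chain <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  lr_database(db$pairs[!db$pairs$is_complex, , drop = FALSE], name = db$name)
}

#' Intersect several L-R databases
#'
#' Keeps the pairs whose normalized (ligand, receptor) key occurs in every
#' input database; `sources` becomes the union of contributing database
#' names. Used to build the harmonized "common-DB" universe so all evaluated
#' methods operate on an identical interaction space.
#'
#' @param dbs list of two or more [lr_database] objects.
#' @param name name for the result (default `"common"`).
#' @return An [lr_database], a subset of every input.
#' @export
intersect_databases <- function(dbs, name = "common") {
  if (!is.list(dbs) || length(dbs) < 2)
    stop("need at least two databases to intersect", call. = FALSE)
  stopifnot(all(vapply(dbs, inherits, logical(1), "lr_database")))
  keys <- lapply(dbs, function(d) paste(d$pairs$ligand, d$pairs$receptor, sep = "\r"))
  common <- Reduce(intersect, keys)
  out <- do.call(rbind, lapply(dbs, function(d) {
    k <- paste(d$pairs$ligand, d$pairs$receptor, sep = "\r")
    d$pairs[k %in% common, , drop = FALSE]
  }))
  lr_database(out, name = name)
}

#' Feasibility-filter an L-R database against a reference
#'
#' Keeps pairs whose ligand is expressed in the sender cell type and whose
#' receptor is expressed in the receiver cell type of a single-cell
#' reference. "Expressed" means detected in at least `min_cells` cells with
#' a nonzero count and at least `min_total` summed counts within that type.
#' Genes absent from the reference fail the test (the pair is dropped, not
#' an error).
#'
#' @param db an [lr_database].
#' @param ref a [reference_dataset].
#' @param sender,receiver cell-type labels present in `ref`.
#' @param min_cells,min_total detection thresholds (defaults 10 and 10).
#' @return A filtered [lr_database].
#' @export
feasibility_filter <- function(db, ref, sender, receiver,
                               min_cells = 10L, min_total = 10L) {
  stopifnot(inherits(db, "lr_database"), inherits(ref, "reference_dataset"))
  min_cells <- check_scalar_count(min_cells, "min_cells")
  min_total <- check_scalar_count(min_total, "min_total")
  for (ty in c(sender, receiver)) {
    if (!ty %in% ref$cell_types)
      stop("unknown cell type label: ", ty, call. = FALSE)
  }
  expressed_in <- function(genes, type) {
    sub <- ref$counts[ref$cell_types == type, , drop = FALSE]
    idx <- match(genes, ref$gene_names)
    ok <- !is.na(idx)
    res <- logical(length(genes))
    if (any(ok)) {
      m <- sub[, idx[ok], drop = FALSE]
      res[ok] <- Matrix::colSums(m > 0) >= min_cells &
        Matrix::colSums(m) >= min_total
    }
    res
  }
  keep <- expressed_in(db$pairs$ligand, sender) &
    expressed_in(db$pairs$receptor, receiver)
  lr_database(db$pairs[keep, , drop = FALSE], name = db$name)
}

#' Randomly sample L-R pairs for embedding
#'
#' Uniform sample without replacement, reproducible under a fixed seed. No
#' ordering by pathway, prior knowledge or alphabet enters the draw, so the
#' selection carries no bias toward particular molecular classes.
#'
#' @param db an [lr_database].
#' @param n number of pairs, `1 <= n <= length(db)`.
#' @param seed integer seed.
#' @return A data.frame of `n` sampled pair rows.
#' @export
sample_pairs <- function(db, n, seed) {
  stopifnot(inherits(db, "lr_database"))
  n <- check_scalar_count(n, "n")
  if (n > nrow(db$pairs))
    stop(sprintf("cannot sample %d pairs from a database of %d", n,
                 nrow(db$pairs)), call. = FALSE)
  idx <- with_seed(seed, sample.int(nrow(db$pairs), n))
  out <- db$pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a harmonized database to TSV
#'
#' Columns `ligand`, `receptor`, `sources`, `is_complex` in deterministic
#' lexicographic row order.
#'
#' @param db an [lr_database].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lr_database <- function(db, path) {
  stopifnot(inherits(db, "lr_database"))
  out <- db$pairs[order(db$pairs$ligand, db$pairs$receptor),
                  c("ligand", "receptor", "sources", "is_complex")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
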