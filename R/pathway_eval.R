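#' Read pathway annotations from a GMT file
#'
#' @param path GMT file (one pathway per line: id, description, genes...).
#' @return Named list of uppercase gene-symbol vectors; empty pathways are
#'   rejected.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) unique(normalize_symbol(g)))
  if (any(lengths(sets) == 0))
    stop("empty pathway set(s) in ", path, call. = FALSE)
  sets
}

#' Hypergeometric pathway enrichment of significant L-R genes
#'
#' Builds the input gene set as the union of ligands and receptors from
#' calls meeting the significance threshold, against a background of all
#' ligand and receptor genes the method evaluated. For each pathway
#' restricted to the background, computes the one-sided hypergeometric
#' upper-tail p-value for the observed overlap (equivalently a one-sided
#' Fisher test), adjusts across tested pathways with Benjamini-Hochberg,
#' and flags pathways with adjusted p < 0.05 as enriched. Pathways with no
#' background overlap are skipped to keep the adjustment family meaningful;
#' gene-set members outside the background are dropped with a report.
#'
#' @param calls an [interaction_call_set] (or a character gene set).
#' @param alpha significance threshold on the calls' p-values
#'   (default 0.05).
#' @param background character vector of all evaluated ligand/receptor
#'   genes.
#' @param annotation named list of pathway gene sets (see [read_gmt()]).
#' @param enrich_cutoff adjusted-p cutoff for the `enriched` flag
#'   (default 0.05).
#' @return data.frame with one row per tested pathway: `pathway`,
#'   `overlap`, `pathway_size`, `background_size`, `gene_set_size`, `p`,
#'   `p_adjusted`, `enriched`. Attribute `"n_outside_background"` reports
#'   dropped gene-set members.
#' @export
enrich_lr_genes <- function(calls, alpha = 0.05, background, annotation,
                            enrich_cutoff = 0.05) {
  if (!length(background)) stop("background must be nonempty", call. = FALSE)
  background <- unique(normalize_symbol(background))
  if (inherits(calls, "interaction_call_set")) {
    rec <- calls$records
    sig <- rec[!is.na(rec$p_value) & rec$p_value < alpha, , drop = FALSE]
    genes <- unique(normalize_symbol(c(sig$ligand, sig$receptor)))
  } else {
    genes <- unique(normalize_symbol(as.character(calls)))
  }
  n_outside <- sum(!genes %in% background)
  genes <- intersect(genes, background)
  empty <- data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), background_size = integer(),
                      gene_set_size = integer(), p = numeric(),
                      p_adjusted = numeric(), enriched = logical())
  if (!length(genes)) {
    warning("empty significant-gene set; no enrichment computed")
    return(structure(empty, n_outside_background = n_outside))
  }
  N <- length(background)
  n <- length(genes)
  rows <- lapply(names(annotation), function(pw) {
    members <- intersect(annotation[[pw]], background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, pathway_size = K,
               background_size = N, gene_set_size = n, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(structure(empty, n_outside_background = n_outside))
  rows$p_adjusted <- stats::p.adjust(rows$p, method = "BH")
  rows$enriched <- rows$p_adjusted < enrich_cutoff
  rownames(rows) <- NULL
  structure(rows, n_outside_background = n_outside)
}

#' Read a literature-curated silver standard
#'
#' @param path TSV with columns `pathway_id` and `label` in
#'   supported / not_supported / unknown.
#' @return Named character vector of labels.
#' @export
read_silver_standard <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "label") %in% names(tab)))
    stop("silver standard needs columns 'pathway_id' and 'label'",
         call. = FALSE)
  bad <- setdiff(tab$label, c("supported", "not_supported", "unknown"))
  if (length(bad))
    stop("invalid silver-standard label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stats::setNames(tab$label, tab$pathway_id)
}

#' Score enriched pathways against a silver standard
#'
#' Pathways labeled `unknown` are excluded from all four confusion cells
#' (set `unknown_as = "negative"` to count them as not supported instead).
#' TP = enriched and supported, FP = enriched and not supported,
#' FN = supported but not enriched, TN = not supported and not enriched.
#'
#' @param enriched character vector of enriched pathway ids (e.g. from
#'   [enrich_lr_genes()] rows with `enriched = TRUE`).
#' @param silver named label vector (see [read_silver_standard()]).
#' @param unknown_as `"exclude"` (default) or `"negative"`.
#' @return List with `counts` (a `confusion_counts`) and `metrics`
#'   (a [prf_metrics()] result).
#' @export
pathway_prf <- function(enriched, silver,
                        unknown_as = c("exclude", "negative")) {
  unknown_as <- match.arg(unknown_as)
  if (!length(silver)) stop("silver standard is empty", call. = FALSE)
  labels <- silver
  if (unknown_as == "negative") labels[labels == "unknown"] <- "not_supported"
  labels <- labels[labels != "unknown"]
  if (!length(labels))
    stop("silver standard contains no supported/not_supported pathways",
         call. = FALSE)
  ids <- names(labels)
  is_enr <- ids %in% enriched
  is_sup <- labels == "supported"
  counts <- structure(list(
    TP = sum(is_enr & is_sup), FP = sum(is_enr & !is_sup),
    FN = sum(!is_enr & is_sup), TN = sum(!is_enr & !is_sup)),
    class = "confusion_counts")
  list(counts = counts, metrics = prf_metrics(counts))
}
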