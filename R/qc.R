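## Per-cell QC metrics and threshold filtering: genes detected, total UMIs,
## mitochondrial percentage and the novelty index (genes detected / total
## UMIs, a library-complexity measure), plus externally supplied doublet
## scores and empty-droplet FDRs consumed as annotation columns.

#' QC thresholds
#'
#' Defaults are the filtering values used throughout the package: at least
#' 500 genes detected, at least 750 total UMIs, at most 15% mitochondrial
#' counts, novelty index at least 0.4, doublet score at most 0.25 and
#' empty-droplet FDR at most 0.01. All thresholds are inclusive on the
#' passing side.
#'
#' @param min_genes,min_counts,max_pct_mito,min_novelty,max_doublet_score,max_empty_fdr
#'   Scalar thresholds, all nonnegative.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 500L, min_counts = 750L, max_pct_mito = 15,
                          min_novelty = 0.4, max_doublet_score = 0.25,
                          max_empty_fdr = 0.01) {
  th <- list(
    min_genes = min_genes, min_counts = min_counts, max_pct_mito = max_pct_mito,
    min_novelty = min_novelty, max_doublet_score = max_doublet_score,
    max_empty_fdr = max_empty_fdr
  )
  for (f in names(th)) {
    if (!is_scalar_num(th[[f]]) || th[[f]] < 0) {
      abort(sprintf("invalid `%s`: must be a nonnegative number", f))
    }
  }
  structure(th, class = "qc_thresholds")
}

#' Compute per-cell QC metrics
#'
#' @param counts Validated count matrix (genes x cells).
#' @param genes Gene annotation tibble with `gene` and `is_mito` columns;
#'   its gene set must match the matrix rows.
#' @return A tibble with one row per barcode: `barcode`, `n_genes` (genes
#'   with count > 0), `n_counts` (total UMIs), `pct_mito` (percent of counts
#'   on mitochondrial genes) and `novelty` (`n_genes / n_counts`, 0 for
#'   zero-count cells).
#' @export
compute_qc_metrics <- function(counts, genes) {
  validate_counts(counts)
  if (!setequal(rownames(counts), genes$gene)) {
    abort("gene sets of `counts` and `genes` do not match")
  }
  mito <- genes$gene[genes$is_mito]
  n_counts <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito_counts <- if (length(mito) > 0L) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  tibble::tibble(
    barcode = colnames(counts),
    n_genes = as.integer(n_genes),
    n_counts = as.integer(n_counts),
    pct_mito = ifelse(n_counts > 0, 100 * mito_counts / n_counts, 0),
    novelty = ifelse(n_counts > 0, n_genes / n_counts, 0)
  )
}

#' Filter cells on QC metrics and external doublet/empty flags
#'
#' A cell is kept iff `n_genes >= min_genes`, `n_counts >= min_counts`,
#' `pct_mito <= max_pct_mito`, `novelty >= min_novelty`, and its
#' `doublet_score` and `empty_fdr` (when present in the annotation and
#' non-missing) do not exceed their thresholds. Every rejected cell carries
#' the full list of failed criteria.
#'
#' @param metrics QC metrics from [compute_qc_metrics()]; must cover every
#'   annotated barcode.
#' @param annotation Cell annotation tibble (see [read_cell_annotation()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `kept` (character vector of passing barcodes) and
#'   `report` (tibble: `barcode`, `kept`, `reasons` -- failed criteria as a
#'   comma-separated string, empty for kept cells).
#' @export
filter_cells <- function(metrics, annotation, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (!all(annotation$barcode %in% metrics$barcode)) {
    abort("`metrics` does not cover all annotated barcodes")
  }
  m <- dplyr::left_join(annotation, metrics, by = "barcode")
  fail <- cbind(
    min_genes = m$n_genes < thresholds$min_genes,
    min_counts = m$n_counts < thresholds$min_counts,
    max_pct_mito = m$pct_mito > thresholds$max_pct_mito,
    min_novelty = m$novelty < thresholds$min_novelty,
    doublet = !is.na(m$doublet_score) & m$doublet_score > thresholds$max_doublet_score,
    empty = !is.na(m$empty_fdr) & m$empty_fdr > thresholds$max_empty_fdr
  )
  reasons <- apply(fail, 1L, function(f) paste(colnames(fail)[f], collapse = ","))
  kept <- rowSums(fail) == 0L
  list(
    kept = m$barcode[kept],
    report = tibble::tibble(barcode = m$barcode, kept = kept, reasons = reasons)
  )
}
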