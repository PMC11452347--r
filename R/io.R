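## Readers and writers for every on-disk artifact, with strict validation.
## All tables are UTF-8, tab-delimited, with a header row; the count matrix
## is MatrixMarket coordinate format (1-based on disk) with single-column,
## header-less gene and barcode sidecars.

LOCALIZATION_CLASSES <- c("plasma_membrane", "secreted", "extracellular_matrix", "other", "unknown")
ELIGIBLE_CLASSES <- c("plasma_membrane", "secreted", "extracellular_matrix")

## strict TSV reader: schema-checked columns, malformed numerics rejected
read_tsv_checked <- function(path, col_types) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # malformed values are re-raised as errors below, so silence readr's warning
  x <- suppressWarnings(readr::read_tsv(path, col_types = col_types, progress = FALSE))
  missing <- setdiff(names(col_types$cols), names(x))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(x)
  if (nrow(probs) > 0L) {
    abort(sprintf(
      "%s: malformed value in row %d, column %d (expected %s)",
      path, probs$row[1], probs$col[1], probs$expected[1]
    ))
  }
  x[names(col_types$cols)]
}

#' Validate a gene-by-cell count matrix
#'
#' Checks that `counts` is a sparse nonnegative integer matrix with unique,
#' non-empty gene and barcode identifiers in its dimnames.
#'
#' @param counts A `Matrix::dgCMatrix` (genes in rows, cells in columns).
#' @return `counts`, invisibly.
#' @export
validate_counts <- function(counts) {
  if (!methods::is(counts, "sparseMatrix")) abort("`counts` must be a sparse Matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene ids (rownames) and barcodes (colnames)")
  }
  if (anyDuplicated(rownames(counts))) abort("`counts`: duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) abort("`counts`: duplicate barcodes")
  v <- counts@x
  if (length(v) > 0L) {
    if (any(v < 0)) abort("`counts`: negative entries")
    if (any(v != floor(v))) abort("`counts`: non-integer entries")
  }
  invisible(counts)
}

#' Read a count matrix from MatrixMarket format with TSV sidecars
#'
#' @param matrix_path MatrixMarket coordinate file (1-based indices on disk).
#' @param genes_path Single-column, header-less file of gene identifiers
#'   (one per matrix row).
#' @param barcodes_path Single-column, header-less file of cell barcodes
#'   (one per matrix column).
#' @return A validated `dgCMatrix`, genes in rows and cells in columns.
#' @export
read_counts <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  m <- tryCatch(
    Matrix::readMM(matrix_path),
    error = function(e) abort(sprintf("%s: not a valid MatrixMarket file (%s)", matrix_path, conditionMessage(e)))
  )
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (anyDuplicated(genes)) abort(sprintf("%s: duplicate gene identifier at line %d", genes_path, anyDuplicated(genes)))
  if (anyDuplicated(barcodes)) abort(sprintf("%s: duplicate barcode at line %d", barcodes_path, anyDuplicated(barcodes)))
  if (nrow(m) != length(genes)) {
    abort(sprintf("%s: %d rows but %d gene identifiers in %s", matrix_path, nrow(m), length(genes), genes_path))
  }
  if (ncol(m) != length(barcodes)) {
    abort(sprintf("%s: %d columns but %d barcodes in %s", matrix_path, ncol(m), length(barcodes), barcodes_path))
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(genes, barcodes)
  validate_counts(m)
  m
}

#' Write a count matrix to MatrixMarket format with TSV sidecars
#'
#' @inheritParams read_counts
#' @param counts A validated count matrix (see [validate_counts()]).
#' @return The paths, invisibly.
#' @export
write_counts <- function(counts, matrix_path, genes_path, barcodes_path) {
  validate_counts(counts)
  Matrix::writeMM(counts, matrix_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), barcodes_path)
  invisible(c(matrix_path, genes_path, barcodes_path))
}

#' Read per-cell annotation (region, subtype, QC flags)
#'
#' Columns: `barcode`, `region`, `subtype`, and optional `doublet_score`
#' (scrublet-style, in `[0,1]`) and `empty_fdr` (EmptyDrops-style FDR, in
#' `[0,1]`); missing flag values are allowed and treated as passing by QC.
#'
#' @param path TSV file with header.
#' @return A tibble with one row per barcode.
#' @export
read_cell_annotation <- function(path) {
  x <- read_tsv_checked(path, readr::cols(
    barcode = readr::col_character(), region = readr::col_character(),
    subtype = readr::col_character(),
    doublet_score = readr::col_double(), empty_fdr = readr::col_double()
  ))
  validate_cell_annotation(x)
  x
}

validate_cell_annotation <- function(x) {
  if (anyDuplicated(x$barcode)) abort("cell annotation: duplicate barcodes")
  if (any(is.na(x$region) | !nzchar(x$region))) abort("cell annotation: empty `region`")
  if (any(is.na(x$subtype) | !nzchar(x$subtype))) abort("cell annotation: empty `subtype`")
  for (col in c("doublet_score", "empty_fdr")) {
    v <- x[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) abort(sprintf("cell annotation: `%s` outside [0, 1]", col))
  }
  invisible(x)
}

#' @rdname read_cell_annotation
#' @param cells Cell-annotation tibble.
#' @export
write_cell_annotation <- function(cells, path) {
  validate_cell_annotation(cells)
  readr::write_tsv(cells, path)
  invisible(path)
}

#' Read per-gene annotation (subcellular localization and mitochondrial flag)
#'
#' Columns: `gene`, `localization_class`, `is_mito` (0/1). Localization
#' values outside the controlled vocabulary (`plasma_membrane`, `secreted`,
#' `extracellular_matrix`, `other`, `unknown`) are collapsed to `other` --
#' never to an eligible class -- so unrecognized annotations can never make
#' a gene a candidate ligand or receptor.
#'
#' @param path TSV file with header.
#' @return A tibble with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  x <- read_tsv_checked(path, readr::cols(
    gene = readr::col_character(),
    localization_class = readr::col_character(),
    is_mito = readr::col_integer()
  ))
  out_of_vocab <- !(x$localization_class %in% LOCALIZATION_CLASSES)
  if (any(out_of_vocab)) {
    warn(sprintf(
      "%s: %d localization value(s) outside the vocabulary collapsed to 'other' (e.g. %s)",
      path, sum(out_of_vocab), dQuote(x$localization_class[which(out_of_vocab)[1]])
    ))
    x$localization_class[out_of_vocab] <- "other"
  }
  x$is_mito <- as.logical(x$is_mito)
  validate_gene_annotation(x)
  x
}

validate_gene_annotation <- function(x) {
  if (anyDuplicated(x$gene)) abort("gene annotation: duplicate gene identifiers")
  if (!all(x$localization_class %in% LOCALIZATION_CLASSES)) {
    abort("gene annotation: localization_class outside the controlled vocabulary")
  }
  if (any(is.na(x$is_mito))) abort("gene annotation: missing `is_mito`")
  invisible(x)
}

#' @rdname read_gene_annotation
#' @param genes Gene-annotation tibble.
#' @export
write_gene_annotation <- function(genes, path) {
  validate_gene_annotation(genes)
  out <- genes
  out$is_mito <- as.integer(out$is_mito)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Columns: `gene_a`, `gene_b`, `experimental` (0/1 flag for experimental
#' evidence). Edges are unordered; self-edges and duplicate pairs are
#' rejected. Each edge is stored with `gene_a <= gene_b` lexicographically.
#'
#' @param path TSV file with header.
#' @return A tibble of unique undirected edges.
#' @export
read_ppi <- function(path) {
  x <- read_tsv_checked(path, readr::cols(
    gene_a = readr::col_character(), gene_b = readr::col_character(),
    experimental = readr::col_integer()
  ))
  x$experimental <- as.logical(x$experimental)
  validate_ppi(x)
  normalize_ppi(x)
}

normalize_ppi <- function(x) {
  swap <- x$gene_a > x$gene_b
  tmp <- x$gene_a[swap]
  x$gene_a[swap] <- x$gene_b[swap]
  x$gene_b[swap] <- tmp
  x
}

validate_ppi <- function(x) {
  if (any(x$gene_a == x$gene_b)) abort("PPI network: self-edges are not allowed")
  key <- paste(pmin(x$gene_a, x$gene_b), pmax(x$gene_a, x$gene_b))
  if (anyDuplicated(key)) abort("PPI network: duplicate edge records")
  if (any(is.na(x$experimental))) abort("PPI network: missing `experimental` flag")
  invisible(x)
}

#' @rdname read_ppi
#' @param ppi PPI edge tibble.
#' @export
write_ppi <- function(ppi, path) {
  validate_ppi(ppi)
  out <- ppi
  out$experimental <- as.integer(out$experimental)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read reference ligand-receptor pairs
#'
#' Columns: `ligand`, `receptor` (ordered: ligand in the sender, receptor in
#' the receiver). Duplicate ordered pairs are rejected.
#'
#' @param path TSV file with header.
#' @return A tibble of ordered pairs.
#' @export
read_reference_pairs <- function(path) {
  x <- read_tsv_checked(path, readr::cols(
    ligand = readr::col_character(), receptor = readr::col_character()
  ))
  validate_reference_pairs(x)
  x
}

validate_reference_pairs <- function(x) {
  if (any(!nzchar(x$ligand) | !nzchar(x$receptor))) abort("reference pairs: empty gene symbol")
  if (anyDuplicated(paste(x$ligand, x$receptor))) abort("reference pairs: duplicate ordered pair")
  invisible(x)
}

#' @rdname read_reference_pairs
#' @param pairs Reference-pair tibble.
#' @export
write_reference_pairs <- function(pairs, path) {
  validate_reference_pairs(pairs)
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' Read or write an assembled ligand-receptor database
#'
#' Columns: `ligand`, `receptor`, `provenance` (`established` or
#' `candidate`), `display_name`.
#'
#' @param path TSV file with header.
#' @return A tibble (see [build_database()]).
#' @export
read_lr_database <- function(path) {
  x <- read_tsv_checked(path, readr::cols(
    ligand = readr::col_character(), receptor = readr::col_character(),
    provenance = readr::col_character(), display_name = readr::col_character()
  ))
  validate_lr_database(x)
  x
}

validate_lr_database <- function(x) {
  if (!all(x$provenance %in% c("established", "candidate"))) {
    abort("ligand-receptor database: provenance must be 'established' or 'candidate'")
  }
  if (anyDuplicated(paste(x$ligand, x$receptor))) {
    abort("ligand-receptor database: duplicate ordered pair")
  }
  invisible(x)
}

#' @rdname read_lr_database
#' @param db Database tibble.
#' @export
write_lr_database <- function(db, path) {
  validate_lr_database(db)
  readr::write_tsv(db, path)
  invisible(path)
}

#' Read a segment-level average-expression profile
#'
#' A two-column TSV (`gene`, `value`) holding linear-scale average
#' expression for one cell subtype, e.g. exported from a spatial profiling
#' platform. Feed the result to [ingest_external_profile()].
#'
#' @param path TSV file with header.
#' @return A tibble with columns `gene` and `value`.
#' @export
read_expression_profile <- function(path) {
  x <- read_tsv_checked(path, readr::cols(
    gene = readr::col_character(), value = readr::col_double()
  ))
  if (any(is.na(x$value) | x$value < 0)) abort(sprintf("%s: profile values must be nonnegative", path))
  x
}

#' @rdname read_expression_profile
#' @param profile Profile tibble (`gene`, `value`).
#' @export
write_expression_profile <- function(profile, path) {
  readr::write_tsv(profile[c("gene", "value")], path)
  invisible(path)
}

#' Write or read planted ground truth as JSON
#'
#' @param truth Ground-truth list produced by [generate_dataset()].
#' @param path JSON file path.
#' @return `read_ground_truth()` returns the ground-truth list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "list")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("true_markers", "true_pairs", "contaminant_barcodes", "doublet_parents")) {
    x[[f]] <- tibble::as_tibble(x[[f]])
  }
  x
}
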