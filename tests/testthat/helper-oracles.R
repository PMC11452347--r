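# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sided rank-sum p by bitmask enumeration of all group
# assignments (independent of the combn-based implementation path).
oracle_rank_sum_p <- function(x, y) {
  n_a <- length(x)
  n <- n_a + length(y)
  r <- rank(c(x, y))
  mu <- n_a * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n_a)]) - mu)
  hits <- 0L
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    if (length(idx) != n_a) next
    total <- total + 1L
    if (abs(sum(r[idx]) - mu) >= obs - 1e-8) hits <- hits + 1L
  }
  hits / total
}

# dense matrix (with dimnames) -> validated sparse count matrix
make_counts <- function(mat, genes = NULL, barcodes = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(mat)))
  barcodes <- barcodes %||% sprintf("c%02d", seq_len(ncol(mat)))
  out <- Matrix::Matrix(mat, sparse = TRUE, dimnames = list(genes, barcodes))
  methods::as(out, "CsparseMatrix")
}

# minimal gene annotation for a count matrix (no mito genes by default)
make_gene_annotation <- function(counts, mito = character(0)) {
  tibble::tibble(
    gene = rownames(counts),
    localization_class = "other",
    is_mito = rownames(counts) %in% mito
  )
}

# small two-region simulation config for fast structural tests (the gene
# panel is too small for the default novelty gate; QC tests that need
# realistic metrics use near-default configs instead)
tiny_sim_config <- function(seed = 1L, n_cells = 20L, ...) {
  simulation_config(
    n_genes = 80L, n_mito_genes = 5L,
    subtype_spec = tibble::tibble(
      region = c("cortex", "cortex", "ME", "ME"),
      subtype = c("cEC", "pericyte", "cEC", "pericyte"),
      n_cells = n_cells
    ),
    depth_log_mean = log(300), depth_log_sd = 0.2,
    marker_spec = tibble::tibble(
      gene = "g0005", subtype = "cEC", region = "ME", fold_change = 6
    ),
    planted_pairs = tibble::tibble(
      ligand = "g0010", receptor = "g0011", sender = "cEC", receiver = "pericyte",
      region = "ME", ligand_fold = 6, receptor_fold = 6, in_reference = TRUE
    ),
    n_reference_pairs = 12L, n_decoy_edges = 15L,
    seed = seed, ...
  )
}

# relaxed thresholds usable with tiny_sim_config's small gene panel
tiny_thresholds <- function() {
  qc_thresholds(min_genes = 10, min_counts = 100, max_pct_mito = 50, min_novelty = 0.02)
}
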