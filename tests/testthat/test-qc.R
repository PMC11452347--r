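test_that("QC metrics follow their definitions, including degenerate cells", {
  counts <- make_counts(
    cbind(c(600, 400, 0), c(0, 0, 0)),
    genes = c("gA", "gB", "mitoG"), barcodes = c("c1", "c2")
  )
  genes <- make_gene_annotation(counts, mito = "mitoG")
  m <- compute_qc_metrics(counts, genes)
  expect_identical(m$n_genes, c(2L, 0L))
  expect_identical(m$n_counts, c(1000L, 0L))
  expect_identical(m$pct_mito, c(0, 0))
  expect_identical(m$novelty, c(0.002, 0))

  # 400 distinct genes each with one count, 600 extra on one of them
  v <- rep(1, 400)
  v[1] <- 601
  counts2 <- make_counts(matrix(v, ncol = 1), genes = sprintf("g%03d", 1:400))
  m2 <- compute_qc_metrics(counts2, make_gene_annotation(counts2))
  expect_identical(m2$n_genes, 400L)
  expect_identical(m2$n_counts, 1000L)
  expect_identical(m2$novelty, 0.4)

  expect_error(compute_qc_metrics(counts, make_gene_annotation(counts2)), "gene sets")
})

filter_one <- function(n_genes = 500L, n_counts = 750L, pct_mito = 15, novelty = 0.4,
                       doublet_score = NA_real_, empty_fdr = NA_real_) {
  metrics <- tibble::tibble(
    barcode = "c1", n_genes = n_genes, n_counts = n_counts,
    pct_mito = pct_mito, novelty = novelty
  )
  annotation <- tibble::tibble(
    barcode = "c1", region = "ME", subtype = "cEC",
    doublet_score = doublet_score, empty_fdr = empty_fdr
  )
  filter_cells(metrics, annotation)
}

test_that("thresholds are inclusive on the passing side and name failed criteria", {
  expect_identical(filter_one()$kept, "c1") # exactly at every boundary
  r <- filter_one(n_genes = 499L)
  expect_length(r$kept, 0L)
  expect_identical(r$report$reasons, "min_genes")
  r <- filter_one(doublet_score = 0.26)
  expect_identical(r$report$reasons, "doublet")
  expect_identical(filter_one(doublet_score = 0.25)$kept, "c1")
  r <- filter_one(empty_fdr = 0.011)
  expect_identical(r$report$reasons, "empty")
  r <- filter_one(n_genes = 10L, n_counts = 20L, novelty = 0.5)
  expect_identical(r$report$reasons, "min_genes,min_counts")
})

test_that("tightening any threshold never grows the kept set; partition is complete", {
  set.seed(42)
  n <- 300
  metrics <- tibble::tibble(
    barcode = sprintf("c%03d", 1:n),
    n_genes = as.integer(rpois(n, 600)), n_counts = as.integer(rpois(n, 900)),
    pct_mito = runif(n, 0, 30), novelty = runif(n, 0.2, 0.9)
  )
  annotation <- tibble::tibble(
    barcode = metrics$barcode, region = "ME", subtype = "cEC",
    doublet_score = runif(n), empty_fdr = runif(n)
  )
  base <- qc_thresholds(max_doublet_score = 0.5, max_empty_fdr = 0.5)
  kept0 <- filter_cells(metrics, annotation, base)$kept
  tighter <- list(
    qc_thresholds(min_genes = 650, max_doublet_score = 0.5, max_empty_fdr = 0.5),
    qc_thresholds(min_counts = 950, max_doublet_score = 0.5, max_empty_fdr = 0.5),
    qc_thresholds(max_pct_mito = 5, max_doublet_score = 0.5, max_empty_fdr = 0.5),
    qc_thresholds(min_novelty = 0.6, max_doublet_score = 0.5, max_empty_fdr = 0.5),
    qc_thresholds(max_doublet_score = 0.1, max_empty_fdr = 0.5),
    qc_thresholds(max_doublet_score = 0.5, max_empty_fdr = 0.1)
  )
  for (th in tighter) {
    kept <- filter_cells(metrics, annotation, th)$kept
    expect_true(all(kept %in% kept0))
  }
  res <- filter_cells(metrics, annotation, base)
  expect_setequal(res$report$barcode, metrics$barcode)
  expect_identical(sort(c(res$kept, res$report$barcode[!res$report$kept])), sort(metrics$barcode))
})

test_that("on synthetic data every low-quality contaminant is rejected and clean cells pass", {
  cfg <- simulation_config(
    subtype_spec = tibble::tibble(
      region = c("cortex", "ME"), subtype = "cEC", n_cells = 120L
    ),
    marker_spec = default_marker_spec()[0, ],
    planted_pairs = default_planted_pairs()[0, ],
    seed = 21L
  )
  sim <- generate_dataset(cfg)
  metrics <- compute_qc_metrics(sim$counts, sim$genes)
  res <- filter_cells(metrics, sim$cells)
  truth <- sim$ground_truth$contaminant_barcodes
  for (cls in c("low_quality", "doublet", "empty")) {
    expect_length(intersect(res$kept, truth$barcode[truth$class == cls]), 0L)
  }
  clean <- setdiff(sim$cells$barcode, truth$barcode)
  expect_gte(mean(clean %in% res$kept), 0.99)
})
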