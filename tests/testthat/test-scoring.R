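test_that("interaction scores are profile products with absorbing zero", {
  s <- c(L = 8, R = 1, Z = 0)
  r <- c(R = 5, L = 2, Z = 7)
  expect_identical(interaction_score(s, r, "L", "R"), 40)
  expect_identical(interaction_score(s, r, "Z", "R"), 0)
  # orientations are independent computations: (L,R) forward vs reversed roles
  expect_false(isTRUE(all.equal(
    interaction_score(s, r, "L", "R"),
    interaction_score(r, s, "L", "R")
  )))
})

test_that("empirical p follows the add-one upper-tail estimator and is monotone", {
  expect_identical(empirical_pvalue(c(1, 2, 3, 4), 2.5), 0.6)
  null <- runif(999)
  expect_identical(empirical_pvalue(null, 2), 1 / 1000) # above every null value
  expect_identical(empirical_pvalue(c(0, 1, 2), 0), 1)
  s <- sort(runif(50))
  p <- empirical_pvalue(null, s)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(empirical_pvalue(numeric(0), 1), "empty")
})

test_that("the bootstrap null has the contracted size, determinism, and zero behavior", {
  set.seed(2)
  sender <- matrix(runif(5 * 4, 0, 10), 5, dimnames = list(letters[1:5], NULL))
  receiver <- matrix(runif(5 * 4, 0, 10), 5, dimnames = list(letters[1:5], NULL))
  null <- bootstrap_null(sender, receiver,
    database_size = 3, ligand_pool = c("a", "b"),
    detected_genes = letters[1:5], n_iterations = 2, seed = 7
  )
  expect_length(null, 6L)
  null2 <- bootstrap_null(sender, receiver,
    database_size = 3, ligand_pool = c("a", "b"),
    detected_genes = letters[1:5], n_iterations = 2, seed = 7
  )
  expect_identical(null, null2)
  zero_receiver <- receiver * 0
  null0 <- bootstrap_null(sender, zero_receiver,
    database_size = 3, ligand_pool = c("a", "b"),
    detected_genes = letters[1:5], n_iterations = 4, seed = 1
  )
  expect_true(all(null0 == 0))
  expect_error(
    bootstrap_null(sender, receiver,
      database_size = 9, ligand_pool = "a",
      detected_genes = letters[1:5], n_iterations = 1
    ),
    "exceeds"
  )
})

test_that("the Bonferroni cutoff matches closed-form quantiles of a known null", {
  set.seed(5)
  null <- runif(10000)
  scores <- seq(0, 1, by = 1e-4)
  cutoff <- determine_cutoff(scores, null, alpha = 0.01, m = 10)
  expect_lt(abs(cutoff - quantile(null, 0.999)), 0.003)
  # m = 1 reduces to the raw alpha tail quantile
  cutoff1 <- determine_cutoff(scores, null, alpha = 0.01, m = 1)
  expect_lt(abs(cutoff1 - quantile(null, 0.99)), 0.005)
  # all-zero null: any positive score is significant for modest m
  expect_identical(determine_cutoff(5, rep(0, 1000), alpha = 0.01, m = 9), 5)
  # nothing qualifies -> +Inf sentinel
  expect_identical(determine_cutoff(0.5, runif(50), alpha = 0.01, m = 10), Inf)
})

test_that("the full scoring path reproduces a brute-force reference exactly", {
  # 5 genes, 4 cells per group, 3 pairs, 3 iterations, fixed seed
  set.seed(8)
  genes <- c("L1", "L2", "R1", "R2", "X")
  raw <- matrix(rpois(5 * 8, 6), nrow = 5, dimnames = list(genes, sprintf("c%d", 1:8)))
  counts <- make_counts(raw, genes = genes, barcodes = colnames(raw))
  cells <- tibble::tibble(
    barcode = colnames(raw), region = "ME",
    subtype = rep(c("cEC", "pericyte"), each = 4),
    doublet_score = NA_real_, empty_fdr = NA_real_
  )
  db <- tibble::tibble(
    ligand = c("L1", "L2", "X"), receptor = c("R1", "R2", "L1"),
    provenance = "established",
    display_name = c("L1-R1", "L2-R2", "X-L1")
  )
  norm <- normalize_counts(counts)
  sc <- score_interactions(norm, cells, db, "ME:cEC", "ME:pericyte",
    n_iterations = 3, alpha = 0.5, seed = 42
  )

  # ---- brute-force reference: plain loops over the same draw protocol ----
  cp10k <- matrix(0, 5, 8, dimnames = dimnames(raw))
  for (j in 1:8) cp10k[, j] <- raw[, j] / sum(raw[, j]) * 1e4
  sender_cells <- 1:4
  receiver_cells <- 5:8
  prof_s <- apply(cp10k[, sender_cells], 1, mean)
  prof_r <- apply(cp10k[, receiver_cells], 1, mean)
  obs <- prof_s[db$ligand] * prof_r[db$receptor]
  detected <- genes[rowSums(raw) > 0]
  pool <- unique(db$ligand[prof_s[db$ligand] > 0])
  null_ref <- c()
  withr::with_seed(42, {
    for (i in 1:3) {
      bs <- cp10k[, sender_cells][, sample.int(4, 4, replace = TRUE)]
      br <- cp10k[, receiver_cells][, sample.int(4, 4, replace = TRUE)]
      ms <- apply(bs, 1, mean)
      mr <- apply(br, 1, mean)
      pseudo <- sample(detected, 3)
      ligs <- sample(pool, 3, replace = TRUE)
      null_ref <- c(null_ref, ms[ligs] * mr[pseudo])
    }
  })
  p_ref <- vapply(obs, function(s) (1 + sum(null_ref >= s)) / (1 + length(null_ref)), numeric(1))

  expect_equal(sc$results$score, unname(obs), tolerance = 1e-12)
  expect_equal(sc$null, unname(null_ref), tolerance = 1e-12)
  expect_equal(sc$results$p_raw, unname(p_ref))
  expect_equal(sc$results$p_bonferroni, pmin(1, unname(p_ref) * 3))
  expect_identical(
    sc$results$significant,
    unname(p_ref * 3 < 0.5 & obs > 0)
  )
})

test_that("scoring is deterministic under a fixed seed and respects region boundaries", {
  sim <- generate_dataset(tiny_sim_config(seed = 4L, n_cells = 15L))
  norm <- normalize_counts(sim$counts)
  db <- build_database(sim$reference_pairs, list(), sim$genes, sim$ppi)
  a <- score_interactions(norm, sim$cells, db, "ME:cEC", "ME:pericyte",
    n_iterations = 10, seed = 3
  )
  b <- score_interactions(norm, sim$cells, db, "ME:cEC", "ME:pericyte",
    n_iterations = 10, seed = 3
  )
  expect_identical(a$results, b$results)
  expect_identical(a$null, b$null)
  expect_error(
    score_interactions(norm, sim$cells, db, "ME:cEC", "cortex:pericyte", n_iterations = 2),
    "same region"
  )
  expect_error(parse_group("MEpericyte"), "region:subtype")
})

test_that("pairs with genes missing from the profiles are skipped with a warning", {
  set.seed(1)
  counts <- make_counts(matrix(rpois(20, 5) + 1, 4), genes = c("L", "R", "A", "B"))
  cells <- tibble::tibble(
    barcode = colnames(counts), region = "ME",
    subtype = rep(c("cEC", "pericyte"), length.out = 5),
    doublet_score = NA_real_, empty_fdr = NA_real_
  )
  db <- tibble::tibble(
    ligand = c("L", "Ghost"), receptor = c("R", "R"),
    provenance = "established", display_name = c("L-R", "GHOST-R")
  )
  norm <- normalize_counts(counts)
  expect_warning(
    sc <- score_interactions(norm, cells, db, "ME:cEC", "ME:pericyte",
      n_iterations = 2, seed = 1
    ),
    "skipped"
  )
  expect_true(is.na(sc$results$score[2]))
  expect_false(sc$results$significant[2])
})

test_that("external receiver profiles are used as-is and extend the scoreable genes", {
  counts <- make_counts(matrix(c(8, 2, 0, 4), 2, dimnames = NULL), genes = c("L", "A"))
  cells <- tibble::tibble(
    barcode = colnames(counts), region = "ME", subtype = c("cEC", "cEC"),
    doublet_score = NA_real_, empty_fdr = NA_real_
  )
  norm <- normalize_counts(counts)
  prof <- ingest_external_profile(
    tibble::tibble(gene = c("R_offmatrix", "A"), value = c(5, 1)), "pericyte"
  )
  db <- tibble::tibble(
    ligand = "L", receptor = "R_offmatrix",
    provenance = "established", display_name = "L-R_OFFMATRIX"
  )
  sc <- score_interactions(norm, cells, db, "ME:cEC", "ME:pericyte",
    n_iterations = 2, seed = 1, receiver_profile = prof
  )
  lig_mean <- mean(expm1(norm["L", ]))
  expect_equal(sc$results$score, lig_mean * 5)
  expect_identical(sc$results$receiver_source, "external_profile")

  expect_error(ingest_external_profile(tibble::tibble(gene = character(0), value = numeric(0)), "x"), "empty")
  expect_error(
    ingest_external_profile(tibble::tibble(gene = c("a", "a"), value = c(1, 2)), "x"),
    "duplicate"
  )
})

nonspecific_fixture <- function(sig_receivers, target = "pericyte",
                                all_sub = c("pericyte", "astrocyte", "fibroblast", "tanycyte")) {
  dplyr::bind_rows(lapply(all_sub, function(rc) {
    tibble::tibble(
      ligand = "L", receptor = "R", display_name = "L-R", provenance = "established",
      sender = "cEC", receiver = rc, region = "ME", receiver_source = "cells",
      score = 50, p_raw = 0.001, p_bonferroni = 0.005,
      significant = rc %in% sig_receivers, excluded_nonspecific = FALSE
    )
  }))
}

test_that("the non-specific screen flags exactly the all-but-target pattern", {
  # significant only for pericytes -> retained
  r <- flag_nonspecific_pairs(nonspecific_fixture("pericyte"), "pericyte", "ME")
  expect_false(any(r$excluded_nonspecific))
  # significant everywhere except pericytes -> excluded
  r <- flag_nonspecific_pairs(
    nonspecific_fixture(c("astrocyte", "fibroblast", "tanycyte")), "pericyte", "ME"
  )
  expect_true(all(r$excluded_nonspecific[r$receiver == "pericyte"]))
  expect_false(any(r$excluded_nonspecific[r$receiver != "pericyte"]))
  expect_false(any(r$significant & r$excluded_nonspecific))
  # significant everywhere including pericytes -> retained (set equality fails)
  r <- flag_nonspecific_pairs(
    nonspecific_fixture(c("pericyte", "astrocyte", "fibroblast", "tanycyte")), "pericyte", "ME"
  )
  expect_false(any(r$excluded_nonspecific))
  expect_error(
    flag_nonspecific_pairs(nonspecific_fixture("pericyte"), "pericyte", "ME",
      subtypes = c("pericyte", "missing_type")
    ),
    "not computed"
  )
})

test_that("summaries keep a zero-filled scaffold and ignore input order", {
  res <- nonspecific_fixture(character(0))
  s <- summarize_interactions(res)
  expect_identical(nrow(s), 4L)
  expect_true(all(s$n_significant == 0))
  res2 <- nonspecific_fixture(c("pericyte", "astrocyte"))
  expect_identical(
    summarize_interactions(res2),
    summarize_interactions(res2[sample(nrow(res2)), ])
  )
  expect_identical(
    summarize_interactions(res2)$n_significant[summarize_interactions(res2)$receiver == "pericyte"],
    1L
  )
})
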