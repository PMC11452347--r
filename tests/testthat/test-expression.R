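test_that("log-normalization matches the stated transform and conserves totals", {
  counts <- make_counts(cbind(c(5, 9995), c(2, 19998), c(0, 0)))
  norm <- normalize_counts(counts)
  expect_equal(norm["g01", "c01"], log(6))
  expect_equal(norm["g01", "c02"], log(2))
  expect_identical(norm["g01", "c03"], 0) # zero count and zero-total cell -> 0

  set.seed(7)
  counts <- make_counts(matrix(rnbinom(600, mu = 4, size = 1), nrow = 30))
  norm <- normalize_counts(counts)
  totals <- Matrix::colSums(counts)
  desum <- Matrix::colSums(expm1(norm))
  expect_equal(unname(desum[totals > 0]), rep(1e4, sum(totals > 0)), tolerance = 1e-10)
  expect_true(all(norm@x >= 0))
})

test_that("average expression means linear CP10K values per group", {
  # two cells with CP10K 4 and 6 for one gene
  counts <- make_counts(cbind(c(4, 9996), c(6, 9994), c(0, 50)))
  norm <- normalize_counts(counts)
  avg <- average_expression(norm, c(c01 = "grp", c02 = "grp", c03 = "zero"))
  expect_equal(avg["g01", "grp"], 5)
  expect_equal(avg["g01", "zero"], 0)
  single <- average_expression(norm, c(c02 = "solo"))
  expect_equal(single["g01", "solo"], 6)
  logavg <- average_expression(norm, c(c01 = "grp", c02 = "grp"), scale = "log")
  expect_equal(logavg["g01", "grp"], mean(log1p(c(4, 6))))
  expect_error(average_expression(norm, list(grp = character(0))), "empty")
  expect_error(average_expression(norm, c(nope = "grp")), "unknown barcode")
})

test_that("avg_log2fc applies the pseudocount on the linear scale and is antisymmetric", {
  expect_identical(avg_log2fc(3, 1), 1)
  expect_identical(avg_log2fc(5, 5), 0)
  set.seed(1)
  a <- runif(20, 0, 50)
  b <- runif(20, 0, 50)
  expect_equal(avg_log2fc(a, b), -avg_log2fc(b, a))
})

test_that("exact rank-sum p equals exhaustive enumeration, with and without ties", {
  expect_identical(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(99)
  for (rep in 1:40) {
    n_a <- sample(1:8, 1)
    n_b <- sample(1:(10 - n_a), 1)
    x <- sample(1:4, n_a, replace = TRUE) # small support forces ties
    y <- sample(1:4, n_b, replace = TRUE)
    expect_equal(rank_sum_test(x, y), oracle_rank_sum_p(x, y),
      info = sprintf("n_a=%d n_b=%d x=%s y=%s", n_a, n_b, toString(x), toString(y))
    )
  }
  # no ties: agrees with the distribution-based exact test
  for (rep in 1:10) {
    x <- sample(1:100, 6)
    y <- sample(101:200, 7) / 1.5
    expect_equal(
      rank_sum_test(x, y),
      stats::wilcox.test(x, y, exact = TRUE)$p.value
    )
  }
})

test_that("large-sample rank-sum p uses the tie-corrected normal approximation", {
  set.seed(3)
  x <- rpois(60, 5)
  y <- rpois(50, 6)
  expect_equal(
    rank_sum_test(x, y),
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  )
  expect_identical(rank_sum_test(rep(1, 30), rep(1, 25)), 1)
})

test_that("DE gates are applied before testing and adjustment covers tested genes only", {
  set.seed(11)
  n <- 40
  base <- matrix(rpois(50 * 2 * n, 5), nrow = 50)
  base[1, 1:n] <- rpois(n, 40) # strong planted difference
  base[2, ] <- 0
  base[2, 1:6] <- 1 # detected in 15% of A, 0% of B -> below min_pct
  counts <- make_counts(base, barcodes = sprintf("c%03d", 1:(2 * n)))
  norm <- normalize_counts(counts)
  a <- colnames(counts)[1:n]
  b <- colnames(counts)[(n + 1):(2 * n)]
  de <- wilcoxon_de(norm, a, b, min_pct = 0.25, logfc_threshold = 0.6)
  expect_true("g01" %in% de$gene)
  expect_false("g02" %in% de$gene)
  expect_true(all(abs(de$avg_log2fc) >= 0.6))
  expect_true(all(pmax(de$pct_a, de$pct_b) >= 0.25))
  expect_equal(de$p_adjusted, p.adjust(de$p_value, "BH"))
  expect_true(all(de$p_adjusted >= de$p_value))

  pos <- wilcoxon_de(norm, a, b, only_pos = TRUE)
  expect_true(all(pos$avg_log2fc >= 0.6))
  bonf <- wilcoxon_de(norm, a, b, adjust = "bonferroni")
  expect_equal(bonf$p_adjusted, pmin(1, bonf$p_value * nrow(bonf)))
  expect_error(wilcoxon_de(norm, character(0), b), "non-empty")
})

test_that("a gene with identical values everywhere is gated out with p = 1 logic", {
  counts <- make_counts(rbind(rep(5, 8), rep(3, 8)), barcodes = sprintf("c%d", 1:8))
  norm <- normalize_counts(counts)
  de <- wilcoxon_de(norm, sprintf("c%d", 1:4), sprintf("c%d", 5:8))
  expect_identical(nrow(de), 0L) # lfc = 0 for both genes -> gated out
  expect_identical(rank_sum_test(rep(2, 4), rep(2, 4)), 1)
})

test_that("planted regional markers are recovered through the DE gates", {
  cfg <- simulation_config(
    subtype_spec = tibble::tibble(
      region = c("cortex", "ME"), subtype = "cEC", n_cells = 150L
    ),
    planted_pairs = default_planted_pairs()[0, ],
    frac_low_quality = 0, frac_doublet = 0, frac_empty = 0,
    seed = 31L
  )
  sim <- generate_dataset(cfg)
  norm <- normalize_counts(sim$counts)
  de <- wilcoxon_de(
    norm,
    sim$cells$barcode[sim$cells$region == "ME"],
    sim$cells$barcode[sim$cells$region == "cortex"]
  )
  hits <- de$gene[de$p_adjusted < 0.05 & de$avg_log2fc > 0.6]
  expect_gte(mean(sim$ground_truth$true_markers$gene %in% hits), 0.9)
})
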