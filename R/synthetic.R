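## Synthetic two-region vascular/perivascular scRNA-seq datasets with known
## ground truth: negative-binomial counts with lognormal baseline rates and
## lognormal per-cell depths, planted region-enriched markers, planted
## directional ligand-receptor pairs, mitochondrial genes and
## low-quality/doublet/empty contaminant cells.

default_subtype_spec <- function(n_cells = 150L) {
  tibble::tibble(
    region = c(rep("cortex", 4), rep("ME", 5)),
    subtype = c(
      "cEC", "pericyte", "astrocyte", "fibroblast",
      "cEC", "pericyte", "astrocyte", "fibroblast", "tanycyte"
    ),
    n_cells = as.integer(n_cells)
  )
}

default_marker_spec <- function(fold = 5) {
  tibble::tibble(
    gene = sprintf("g%04d", 101:110),
    subtype = "cEC",
    region = "ME",
    fold_change = fold
  )
}

default_planted_pairs <- function(fold = 5) {
  tibble::tibble(
    ligand = sprintf("g%04d", 201:208),
    receptor = sprintf("g%04d", 301:308),
    sender = "cEC",
    receiver = rep(c("pericyte", "pericyte", "astrocyte", "astrocyte"), 2),
    region = rep(c("ME", "cortex"), each = 4),
    ligand_fold = fold,
    receptor_fold = fold,
    in_reference = rep(c(TRUE, FALSE), 4)
  )
}

#' Configuration of the synthetic two-region dataset
#'
#' Defaults emulate the study design the package targets: two brain regions
#' (`cortex`, `ME`) with capillary endothelial cells (cEC), pericytes,
#' astrocytes and fibroblasts in both regions plus ME tanycytes, 150 cells
#' per subtype, about 2,000 genes of which 50 are mitochondrial, and a
#' 200-pair reference ligand-receptor database. Planted marker genes and
#' planted directional ligand-receptor pairs carry a fold change of 5 and
#' sit on well-expressed baselines (`planted_base_factor` times the central
#' rate), as real vascular signaling genes do.
#'
#' @param n_genes Total number of genes (including mitochondrial).
#' @param n_mito_genes Number of mitochondrial genes (ids prefixed `mt-`).
#' @param subtype_spec Tibble with columns `region`, `subtype`, `n_cells`.
#' @param baseline_log_mean,baseline_log_sd Lognormal parameters of per-gene
#'   baseline expression rates (relative scale; only ratios matter).
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param depth_log_mean,depth_log_sd Lognormal parameters of per-cell
#'   library size (total UMIs).
#' @param marker_spec Tibble with columns `gene`, `subtype`, `region`,
#'   `fold_change` (> 1): planted region-enriched markers.
#' @param planted_pairs Tibble with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `region`, `ligand_fold`, `receptor_fold` (> 1) and optional
#'   `in_reference` (whether the pair is seeded into the reference database;
#'   pairs not in the reference must be recovered via the candidate route).
#' @param frac_low_quality,frac_doublet,frac_empty Contaminant cell counts
#'   as fractions of the clean cell count, each in `[0, 1)`.
#' @param planted_base_factor Baseline rate of planted genes relative to the
#'   central rate `exp(baseline_log_mean)`.
#' @param mito_rate_factor Baseline rate multiplier for mitochondrial genes.
#' @param n_reference_pairs Total size of the reference pair list (planted
#'   `in_reference` pairs plus random decoys).
#' @param n_decoy_edges Random PPI edges (about a quarter carry the
#'   experimental flag) in addition to one experimental edge per planted pair.
#' @param frac_annotated_eligible Fraction of non-planted genes annotated to
#'   an eligible localization class.
#' @param seed Master seed; every generation stage derives its own stream.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_mito_genes = 50L,
                              subtype_spec = default_subtype_spec(),
                              baseline_log_mean = 0,
                              baseline_log_sd = 0.5,
                              nb_dispersion = 2,
                              depth_log_mean = log(1800),
                              depth_log_sd = 0.15,
                              marker_spec = default_marker_spec(),
                              planted_pairs = default_planted_pairs(),
                              frac_low_quality = 0.05,
                              frac_doublet = 0.05,
                              frac_empty = 0.05,
                              planted_base_factor = 3,
                              mito_rate_factor = 2,
                              n_reference_pairs = 200L,
                              n_decoy_edges = 200L,
                              frac_annotated_eligible = 0.2,
                              seed = 1L) {
  marker_spec <- tibble::as_tibble(marker_spec)
  planted_pairs <- tibble::as_tibble(planted_pairs)
  if (nrow(marker_spec) == 0L) marker_spec <- default_marker_spec()[0, ]
  if (nrow(planted_pairs) == 0L) {
    planted_pairs <- default_planted_pairs()[0, ]
  } else if (is.null(planted_pairs$in_reference)) {
    planted_pairs$in_reference <- TRUE
  }
  config <- list(
    n_genes = n_genes, n_mito_genes = n_mito_genes, subtype_spec = tibble::as_tibble(subtype_spec),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    nb_dispersion = nb_dispersion, depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    marker_spec = marker_spec, planted_pairs = planted_pairs,
    frac_low_quality = frac_low_quality, frac_doublet = frac_doublet, frac_empty = frac_empty,
    planted_base_factor = planted_base_factor, mito_rate_factor = mito_rate_factor,
    n_reference_pairs = n_reference_pairs, n_decoy_edges = n_decoy_edges,
    frac_annotated_eligible = frac_annotated_eligible, seed = seed
  )
  class(config) <- "simulation_config"
  validate_simulation_config(config)
  config
}

gene_ids <- function(config) {
  n_plain <- config$n_genes - config$n_mito_genes
  c(sprintf("g%04d", seq_len(n_plain)), sprintf("mt-g%02d", seq_len(config$n_mito_genes)))
}

validate_simulation_config <- function(config) {
  bad <- function(field, why) abort(sprintf("invalid `%s`: %s", field, why))
  if (!is_count(config$n_genes)) bad("n_genes", "must be a positive integer")
  if (!is_count(config$n_mito_genes) || config$n_mito_genes >= config$n_genes) {
    bad("n_mito_genes", "must be a positive integer smaller than n_genes")
  }
  ss <- config$subtype_spec
  if (!all(c("region", "subtype", "n_cells") %in% names(ss)) || nrow(ss) == 0L) {
    bad("subtype_spec", "needs columns region, subtype, n_cells and at least one row")
  }
  if (!all(vapply(ss$n_cells, is_count, logical(1)))) bad("subtype_spec", "n_cells must be positive integers")
  if (anyDuplicated(paste(ss$region, ss$subtype))) bad("subtype_spec", "subtype labels must be unique per region")
  if (!is_scalar_num(config$baseline_log_mean)) bad("baseline_log_mean", "must be a number")
  for (f in c("baseline_log_sd", "nb_dispersion", "planted_base_factor", "mito_rate_factor")) {
    if (!is_scalar_num(config[[f]]) || config[[f]] <= 0) bad(f, "must be a positive number")
  }
  for (f in c("depth_log_mean", "depth_log_sd")) {
    if (!is_scalar_num(config[[f]])) bad(f, "must be a number")
  }
  for (f in c("frac_low_quality", "frac_doublet", "frac_empty")) {
    if (!is_prop(config[[f]])) bad(f, "must be a proportion in [0, 1)")
  }
  total_frac <- config$frac_low_quality + config$frac_doublet + config$frac_empty
  if (total_frac >= 1) bad("frac_low_quality", "contaminant fractions must sum to < 1")
  if (!is_prop(config$frac_annotated_eligible)) bad("frac_annotated_eligible", "must be a proportion in [0, 1)")
  ids <- gene_ids(config)
  groups <- paste(ss$region, ss$subtype)
  ms <- config$marker_spec
  if (nrow(ms) > 0L) {
    if (!all(c("gene", "subtype", "region", "fold_change") %in% names(ms))) {
      bad("marker_spec", "needs columns gene, subtype, region, fold_change")
    }
    if (!all(ms$gene %in% ids)) bad("marker_spec", "planted genes must exist among n_genes")
    if (!all(ms$fold_change > 1)) bad("marker_spec", "all fold changes must be > 1")
    if (!all(paste(ms$region, ms$subtype) %in% groups)) bad("marker_spec", "unknown (region, subtype)")
  }
  pp <- config$planted_pairs
  if (nrow(pp) > 0L) {
    need <- c("ligand", "receptor", "sender", "receiver", "region", "ligand_fold", "receptor_fold")
    if (!all(need %in% names(pp))) bad("planted_pairs", "missing required columns")
    if (!all(c(pp$ligand, pp$receptor) %in% ids)) bad("planted_pairs", "planted genes must exist among n_genes")
    if (!all(pp$ligand_fold > 1 & pp$receptor_fold > 1)) bad("planted_pairs", "all fold changes must be > 1")
    if (!all(paste(pp$region, pp$sender) %in% groups) || !all(paste(pp$region, pp$receiver) %in% groups)) {
      bad("planted_pairs", "unknown (region, subtype)")
    }
  }
  for (f in c("n_reference_pairs", "n_decoy_edges")) {
    if (!is.numeric(config[[f]]) || config[[f]] < 0 || config[[f]] != floor(config[[f]])) {
      bad(f, "must be a nonnegative integer")
    }
  }
  if (!is_scalar_num(config$seed) || config$seed != floor(config$seed)) bad("seed", "must be an integer")
  invisible(config)
}

planted_genes <- function(config) {
  unique(c(config$marker_spec$gene, config$planted_pairs$ligand, config$planted_pairs$receptor))
}

## per-(gene, group) expected expression rates with planted folds applied
build_rate_matrix <- function(config, ids) {
  base <- with_stage_seed(config$seed, "rates", {
    rlnorm(config$n_genes, config$baseline_log_mean, config$baseline_log_sd)
  })
  names(base) <- ids
  is_mito <- startsWith(ids, "mt-")
  base[is_mito] <- base[is_mito] * config$mito_rate_factor
  base[planted_genes(config)] <- config$planted_base_factor * exp(config$baseline_log_mean)

  ss <- config$subtype_spec
  groups <- paste(ss$region, ss$subtype, sep = ":")
  rates <- matrix(base, nrow = config$n_genes, ncol = nrow(ss), dimnames = list(ids, groups))
  ms <- config$marker_spec
  for (i in seq_len(nrow(ms))) {
    g <- paste(ms$region[i], ms$subtype[i], sep = ":")
    rates[ms$gene[i], g] <- rates[ms$gene[i], g] * ms$fold_change[i]
  }
  pp <- config$planted_pairs
  for (i in seq_len(nrow(pp))) {
    gs <- paste(pp$region[i], pp$sender[i], sep = ":")
    gr <- paste(pp$region[i], pp$receiver[i], sep = ":")
    rates[pp$ligand[i], gs] <- rates[pp$ligand[i], gs] * pp$ligand_fold[i]
    rates[pp$receptor[i], gr] <- rates[pp$receptor[i], gr] * pp$receptor_fold[i]
  }
  rates
}

#' Generate a synthetic two-region dataset with planted ground truth
#'
#' Counts are drawn per gene and cell from a negative binomial whose mean is
#' the cell's lognormal library size times the gene's (region, subtype) rate
#' share. Marker genes and planted ligand/receptor genes have their rates
#' multiplied by the configured folds in their target groups. Contaminant
#' cells are appended after the clean cells: low-quality cells (library size
#' drawn below the default QC minimum of 750 counts), doublets (elementwise
#' sum of two clean cells of the same region, `doublet_score` > 0.25) and
#' empty droplets (draws from the ambient average profile, `empty_fdr` >
#' 0.01). Identical `(config, seed)` give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return A list of class `lr_sim` with elements `counts` (sparse
#'   gene-by-cell matrix), `cells` (cell annotation tibble), `genes`
#'   (gene annotation tibble), `ppi` (edge tibble), `reference_pairs`
#'   (tibble), `ground_truth` (list) and `config`.
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  ids <- gene_ids(config)
  rates <- build_rate_matrix(config, ids)
  probs <- sweep(rates, 2, colSums(rates), "/")
  ss <- config$subtype_spec
  n_clean <- sum(ss$n_cells)

  clean <- with_stage_seed(config$seed, "cells", {
    mats <- vector("list", nrow(ss))
    for (i in seq_len(nrow(ss))) {
      n <- ss$n_cells[i]
      depth <- rlnorm(n, config$depth_log_mean, config$depth_log_sd)
      mu <- outer(probs[, i], depth)
      mats[[i]] <- matrix(rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
        nrow = config$n_genes
      )
    }
    do.call(cbind, mats)
  })
  clean_region <- rep(ss$region, ss$n_cells)
  clean_subtype <- rep(ss$subtype, ss$n_cells)

  n_low <- round(config$frac_low_quality * n_clean)
  n_dbl <- round(config$frac_doublet * n_clean)
  n_emp <- round(config$frac_empty * n_clean)
  contam <- with_stage_seed(config$seed, "contaminants", {
    cols <- vector("list", n_low + n_dbl + n_emp)
    region <- subtype <- class <- character(length(cols))
    parents <- matrix(NA_integer_, nrow = n_dbl, ncol = 2)
    k <- 0L
    for (i in seq_len(n_low)) {
      g <- sample.int(nrow(ss), 1L)
      depth <- sample(150:600, 1L)
      k <- k + 1L
      cols[[k]] <- as.vector(rmultinom(1L, depth, probs[, g]))
      region[k] <- ss$region[g]; subtype[k] <- ss$subtype[g]; class[k] <- "low_quality"
    }
    for (i in seq_len(n_dbl)) {
      g <- sample.int(nrow(ss), 1L)
      pool <- which(clean_region == ss$region[g])
      pr <- sample(pool, 2L)
      k <- k + 1L
      cols[[k]] <- clean[, pr[1]] + clean[, pr[2]]
      parents[i, ] <- pr
      region[k] <- ss$region[g]; subtype[k] <- clean_subtype[pr[1]]; class[k] <- "doublet"
    }
    ambient <- rowMeans(probs)
    for (i in seq_len(n_emp)) {
      g <- sample.int(nrow(ss), 1L)
      depth <- sample(20:200, 1L)
      k <- k + 1L
      cols[[k]] <- as.vector(rmultinom(1L, depth, ambient))
      region[k] <- ss$region[g]; subtype[k] <- ss$subtype[g]; class[k] <- "empty"
    }
    mat <- if (k > 0L) matrix(unlist(cols), nrow = config$n_genes) else matrix(0L, config$n_genes, 0L)
    list(mat = mat, region = region, subtype = subtype, class = class, parents = parents)
  })

  n_total <- n_clean + ncol(contam$mat)
  barcodes <- sprintf("bc%05d", seq_len(n_total))
  counts <- methods::as(Matrix::Matrix(cbind(clean, contam$mat), sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(ids, barcodes)

  cells <- with_stage_seed(config$seed, "annotation", {
    cls <- c(rep("clean", n_clean), contam$class)
    doublet_score <- runif(n_total, 0, 0.2)
    empty_fdr <- runif(n_total, 0, 0.005)
    doublet_score[cls == "doublet"] <- runif(sum(cls == "doublet"), 0.3, 0.9)
    empty_fdr[cls == "empty"] <- runif(sum(cls == "empty"), 0.05, 1)
    tibble::tibble(
      barcode = barcodes,
      region = c(clean_region, contam$region),
      subtype = c(clean_subtype, contam$subtype),
      doublet_score = doublet_score,
      empty_fdr = empty_fdr
    )
  })

  planted <- planted_genes(config)
  genes <- with_stage_seed(config$seed, "gene_annotation", {
    class <- rep("other", config$n_genes)
    names(class) <- ids
    free <- setdiff(ids, planted)
    n_elig <- round(config$frac_annotated_eligible * length(free))
    elig <- sample(free, n_elig)
    class[elig] <- sample(ELIGIBLE_CLASSES, n_elig, replace = TRUE)
    unknown <- sample(setdiff(free, elig), round(0.1 * length(free)))
    class[unknown] <- "unknown"
    class[config$planted_pairs$ligand] <- "secreted"
    class[config$planted_pairs$receptor] <- "plasma_membrane"
    tibble::tibble(gene = ids, localization_class = unname(class), is_mito = startsWith(ids, "mt-"))
  })

  ppi <- with_stage_seed(config$seed, "ppi", {
    pp <- config$planted_pairs
    planted_edges <- tibble::tibble(gene_a = pp$ligand, gene_b = pp$receptor, experimental = TRUE)
    pool <- setdiff(ids[!startsWith(ids, "mt-")], planted)
    decoys <- tibble::tibble(
      gene_a = sample(pool, config$n_decoy_edges, replace = TRUE),
      gene_b = sample(pool, config$n_decoy_edges, replace = TRUE),
      experimental = runif(config$n_decoy_edges) < 0.25
    )
    decoys <- decoys[decoys$gene_a != decoys$gene_b, ]
    edges <- normalize_ppi(rbind(planted_edges, decoys))
    edges[!duplicated(paste(edges$gene_a, edges$gene_b)), ]
  })
  validate_ppi(ppi)

  reference_pairs <- with_stage_seed(config$seed, "reference", {
    pp <- config$planted_pairs
    seeded <- if (nrow(pp) > 0L) pp[pp$in_reference, c("ligand", "receptor")] else pp[, c("ligand", "receptor")]
    n_decoy <- max(0L, config$n_reference_pairs - nrow(seeded))
    pool <- setdiff(ids[!startsWith(ids, "mt-")], planted)
    decoys <- tibble::tibble(
      ligand = sample(pool, n_decoy, replace = TRUE),
      receptor = sample(pool, n_decoy, replace = TRUE)
    )
    decoys <- decoys[decoys$ligand != decoys$receptor, ]
    ref <- rbind(seeded, decoys)
    ref[!duplicated(paste(ref$ligand, ref$receptor)), ]
  })
  validate_reference_pairs(reference_pairs)

  contaminant_barcodes <- tibble::tibble(
    barcode = barcodes[seq_len(ncol(contam$mat)) + n_clean],
    class = contam$class
  )
  doublet_parents <- tibble::tibble(
    barcode = contaminant_barcodes$barcode[contaminant_barcodes$class == "doublet"],
    parent1 = barcodes[contam$parents[, 1]],
    parent2 = barcodes[contam$parents[, 2]]
  )
  ground_truth <- list(
    true_markers = config$marker_spec[, c("gene", "subtype", "region")],
    true_pairs = config$planted_pairs[, c("ligand", "receptor", "sender", "receiver", "region")],
    contaminant_barcodes = contaminant_barcodes,
    doublet_parents = doublet_parents
  )

  structure(
    list(
      counts = counts, cells = cells, genes = genes, ppi = ppi,
      reference_pairs = reference_pairs, ground_truth = ground_truth, config = config
    ),
    class = "lr_sim"
  )
}

#' Generate a matched null dataset (no planted signal)
#'
#' Identical to [generate_dataset()] except that `marker_spec` and
#' `planted_pairs` are forced empty, so all genes are exchangeable within a
#' subtype and the ground truth is empty. Used to check family-wise error
#' calibration of the scoring pipeline.
#'
#' @inheritParams generate_dataset
#' @return As [generate_dataset()].
#' @export
generate_null_dataset <- function(config) {
  config$marker_spec <- config$marker_spec[0, ]
  config$planted_pairs <- config$planted_pairs[0, ]
  generate_dataset(config)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param sim An `lr_sim` object from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "lr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"), genes = file.path(dir, "genes.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"), cells = file.path(dir, "cells.tsv"),
    genes_annot = file.path(dir, "genes_annot.tsv"), ppi = file.path(dir, "ppi.tsv"),
    reference_pairs = file.path(dir, "reference_pairs.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_counts(sim$counts, paths["matrix"], paths["genes"], paths["barcodes"])
  write_cell_annotation(sim$cells, paths["cells"])
  write_gene_annotation(sim$genes, paths["genes_annot"])
  write_ppi(sim$ppi, paths["ppi"])
  write_reference_pairs(sim$reference_pairs, paths["reference_pairs"])
  write_ground_truth(sim$ground_truth, paths["ground_truth"])
  invisible(paths)
}

#' Read or write a simulation configuration as YAML
#'
#' Tabular fields (`subtype_spec`, `marker_spec`, `planted_pairs`) are
#' stored as lists of records.
#'
#' @param path YAML file path.
#' @return `read_simulation_config()` returns a validated
#'   [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("subtype_spec", "marker_spec", "planted_pairs")) {
    if (!is.null(raw[[f]])) {
      raw[[f]] <- dplyr::bind_rows(lapply(raw[[f]], tibble::as_tibble))
    }
  }
  do.call(simulation_config, raw)
}

#' @rdname read_simulation_config
#' @param config A [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  out <- unclass(config)
  for (f in c("subtype_spec", "marker_spec", "planted_pairs")) {
    df <- out[[f]]
    out[[f]] <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
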