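## End-to-end pipeline: simulate -> qc -> de -> build-db -> score -> report.
## Stages communicate through files so each is independently runnable (also
## from the command-line wrapper in inst/scripts/pipeline.R) and partial
## re-runs can resume from completed outputs when input checksums match.

#' Pipeline stage: write a synthetic dataset
#'
#' @param config A [simulation_config()].
#' @param dir Output directory for the dataset files.
#' @param null_data Generate a matched null dataset (no planted signal).
#' @return Named vector of written paths.
#' @export
pipeline_simulate <- function(config, dir, null_data = FALSE) {
  sim <- if (null_data) generate_null_dataset(config) else generate_dataset(config)
  write_dataset(sim, dir)
}

#' Pipeline stage: QC metrics and cell filtering
#'
#' @param matrix_path,genes_path,barcodes_path Count matrix files.
#' @param genes_annot_path Gene annotation TSV.
#' @param cells_path Cell annotation TSV.
#' @param thresholds A [qc_thresholds()].
#' @param out_report,out_kept Output TSVs: the full per-cell report
#'   (barcode, kept, reasons, metrics) and the kept barcodes.
#' @return Named vector of written paths.
#' @export
pipeline_qc <- function(matrix_path, genes_path, barcodes_path, genes_annot_path,
                        cells_path, thresholds = qc_thresholds(),
                        out_report, out_kept) {
  counts <- read_counts(matrix_path, genes_path, barcodes_path)
  genes <- read_gene_annotation(genes_annot_path)
  cells <- read_cell_annotation(cells_path)
  metrics <- compute_qc_metrics(counts, genes)
  res <- filter_cells(metrics, cells, thresholds)
  report <- dplyr::left_join(res$report, metrics, by = "barcode")
  readr::write_tsv(report, out_report)
  readr::write_tsv(tibble::tibble(barcode = res$kept), out_kept)
  invisible(c(report = out_report, kept = out_kept))
}

read_kept <- function(path) read_tsv_checked(path, readr::cols(barcode = readr::col_character()))$barcode

#' Pipeline stage: regional differential expression per subtype
#'
#' For each subtype, compares `region_a` cells against `region_b` cells
#' among QC-passing cells of that subtype.
#'
#' @inheritParams pipeline_qc
#' @param kept_path Kept-barcode TSV from [pipeline_qc()].
#' @param subtypes Subtypes to test (e.g. `c("cEC", "astrocyte")`).
#' @param region_a,region_b The two regions compared.
#' @param min_pct,logfc_threshold,only_pos,adjust Passed to [wilcoxon_de()].
#' @param out_dir Directory for `de_<subtype>.tsv` outputs.
#' @return Named vector of written paths.
#' @export
pipeline_de <- function(matrix_path, genes_path, barcodes_path, cells_path, kept_path,
                        subtypes, region_a = "ME", region_b = "cortex",
                        min_pct = 0.25, logfc_threshold = 0.6, only_pos = FALSE,
                        adjust = "bh", out_dir) {
  counts <- read_counts(matrix_path, genes_path, barcodes_path)
  cells <- read_cell_annotation(cells_path)
  kept <- read_kept(kept_path)
  cells <- cells[cells$barcode %in% kept, ]
  norm <- normalize_counts(counts[, kept, drop = FALSE])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (st in subtypes) {
    de <- wilcoxon_de(
      norm,
      group_barcodes(cells, region_a, st),
      group_barcodes(cells, region_b, st),
      min_pct = min_pct, logfc_threshold = logfc_threshold,
      only_pos = only_pos, adjust = adjust
    )
    p <- file.path(out_dir, sprintf("de_%s.tsv", st))
    readr::write_tsv(de, p)
    paths[st] <- p
  }
  invisible(paths)
}

#' Pipeline stage: assemble the ligand-receptor database
#'
#' @param reference_path Reference pair TSV.
#' @param de_paths DE table TSVs from [pipeline_de()].
#' @param genes_annot_path,ppi_path Gene annotation and PPI TSVs.
#' @param max_p_adjusted Passed to [build_database()].
#' @param out_db Output database TSV.
#' @return The output path.
#' @export
pipeline_build_db <- function(reference_path, de_paths, genes_annot_path, ppi_path,
                              max_p_adjusted = 0.05, out_db) {
  de_cols <- readr::cols(
    gene = readr::col_character(), avg_log2fc = readr::col_double(),
    pct_a = readr::col_double(), pct_b = readr::col_double(),
    p_value = readr::col_double(), p_adjusted = readr::col_double()
  )
  de_tables <- lapply(de_paths, read_tsv_checked, col_types = de_cols)
  db <- build_database(
    read_reference_pairs(reference_path), de_tables,
    read_gene_annotation(genes_annot_path), read_ppi(ppi_path),
    max_p_adjusted = max_p_adjusted
  )
  write_lr_database(db, out_db)
  invisible(out_db)
}

#' Pipeline stage: score all comparisons and flag non-specific pairs
#'
#' Scores the database for every (region, sender -> receiver) comparison,
#' then flags pairs aimed at `exclusion_target` in `exclusion_region` that
#' are significant in every other receiving subtype of that region. Each
#' comparison uses its own seed derived from `seed` and the comparison
#' labels, so adding comparisons never changes existing results.
#'
#' @inheritParams pipeline_de
#' @param db_path Database TSV from [pipeline_build_db()].
#' @param sender_subtype Sending subtype (default `"cEC"`).
#' @param receivers Named list mapping region to receiver subtypes; default:
#'   every annotated subtype of the region except the sender.
#' @param n_iterations,alpha Passed to [score_interactions()].
#' @param seed Master seed.
#' @param external_profile_path,external_profile_subtype,external_profile_region
#'   Optional external receiver profile (TSV of `gene`, `value`) replacing
#'   the receiver cells for one (region, subtype) comparison.
#' @param exclusion_target,exclusion_region Non-specific pair screen (set
#'   `exclusion_target = NULL` to skip).
#' @param out_results Output results TSV (one row per pair x comparison).
#' @return The output path.
#' @export
pipeline_score <- function(matrix_path, genes_path, barcodes_path, cells_path, kept_path,
                           db_path, sender_subtype = "cEC", receivers = NULL,
                           n_iterations = 1000L, alpha = 0.01, seed = 1L,
                           external_profile_path = NULL, external_profile_subtype = NULL,
                           external_profile_region = NULL,
                           exclusion_target = "pericyte", exclusion_region = "ME",
                           out_results) {
  counts <- read_counts(matrix_path, genes_path, barcodes_path)
  cells <- read_cell_annotation(cells_path)
  kept <- read_kept(kept_path)
  cells <- cells[cells$barcode %in% kept, ]
  norm <- normalize_counts(counts[, kept, drop = FALSE])
  db <- read_lr_database(db_path)

  regions <- unique(cells$region)
  if (is.null(receivers)) {
    receivers <- lapply(setNames(regions, regions), function(rg) {
      setdiff(unique(cells$subtype[cells$region == rg]), sender_subtype)
    })
  }
  ext <- NULL
  if (!is.null(external_profile_path)) {
    ext <- ingest_external_profile(
      read_expression_profile(external_profile_path), external_profile_subtype
    )
  }
  out <- list()
  for (rg in names(receivers)) {
    for (rc in receivers[[rg]]) {
      use_ext <- !is.null(ext) &&
        identical(rc, external_profile_subtype) && identical(rg, external_profile_region)
      sc <- score_interactions(
        norm, cells, db,
        sender = paste0(rg, ":", sender_subtype),
        receiver = paste0(rg, ":", rc),
        n_iterations = n_iterations, alpha = alpha,
        seed = stage_seed(seed, paste("score", rg, sender_subtype, rc)),
        receiver_profile = if (use_ext) ext else NULL
      )
      out[[paste(rg, rc)]] <- sc$results
    }
  }
  results <- dplyr::bind_rows(out)
  if (!is.null(exclusion_target) && exclusion_region %in% names(receivers) &&
    exclusion_target %in% receivers[[exclusion_region]]) {
    results <- flag_nonspecific_pairs(results, exclusion_target, exclusion_region)
  }
  readr::write_tsv(results, out_results)
  invisible(out_results)
}

#' Pipeline stage: summary counts of significant pairs
#'
#' @param results_path Results TSV from [pipeline_score()].
#' @param out_summary Output TSV.
#' @return The output path.
#' @export
pipeline_report <- function(results_path, out_summary) {
  results <- readr::read_tsv(results_path, progress = FALSE, show_col_types = FALSE)
  readr::write_tsv(summarize_interactions(results), out_summary)
  invisible(out_summary)
}

#' Pipeline run configuration
#'
#' Defaults mirror the analysis the package implements: QC at 500 genes /
#' 750 counts / 15% mito / novelty 0.4 with doublet and empty-droplet
#' flags, regional DE for capillary ECs and astrocytes at min.pct 0.25 and
#' log2 fold change 0.6, 1,000 bootstrap iterations and a one-sided
#' Bonferroni-corrected alpha of 0.01, and the ME-pericyte non-specific
#' pair screen.
#'
#' @param out_dir Output directory for all stage outputs and the manifest.
#' @param seed Master seed; stages derive independent streams from it.
#' @param simulation A [simulation_config()] (its `seed` is replaced by
#'   `seed`), or `NULL` to run on existing files given in `inputs`.
#' @param inputs Named list of input paths (`matrix`, `genes`, `barcodes`,
#'   `cells`, `genes_annot`, `ppi`, `reference_pairs`) when `simulation` is
#'   `NULL`.
#' @param null_data Simulate a null dataset (no planted signal).
#' @param qc A [qc_thresholds()].
#' @param de_subtypes,de_region_a,de_region_b,de_min_pct,de_logfc,de_only_pos,de_adjust
#'   DE stage parameters (see [pipeline_de()]).
#' @param max_p_adjusted Candidate gate for [pipeline_build_db()].
#' @param sender_subtype,receivers,n_iterations,alpha Scoring parameters
#'   (see [pipeline_score()]).
#' @param external_profile_path,external_profile_subtype,external_profile_region
#'   Optional external receiver profile.
#' @param exclusion_target,exclusion_region Non-specific pair screen.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulation = simulation_config(),
                       inputs = NULL, null_data = FALSE, qc = qc_thresholds(),
                       de_subtypes = c("cEC", "astrocyte"), de_region_a = "ME",
                       de_region_b = "cortex", de_min_pct = 0.25, de_logfc = 0.6,
                       de_only_pos = FALSE, de_adjust = "bh", max_p_adjusted = 0.05,
                       sender_subtype = "cEC", receivers = NULL,
                       n_iterations = 1000L, alpha = 0.01,
                       external_profile_path = NULL, external_profile_subtype = NULL,
                       external_profile_region = NULL,
                       exclusion_target = "pericyte", exclusion_region = "ME") {
  config <- as.list(environment())
  class(config) <- "run_config"
  validate_run_config(config)
  config
}

validate_run_config <- function(config) {
  bad <- function(field, why) abort(sprintf("invalid `%s`: %s", field, why))
  if (!is.character(config$out_dir) || length(config$out_dir) != 1L) bad("out_dir", "must be a path")
  if (!is_scalar_num(config$seed) || config$seed != floor(config$seed)) bad("seed", "must be an integer")
  if (!is_scalar_num(config$alpha) || config$alpha <= 0 || config$alpha > 1) {
    bad("alpha", "must be in (0, 1]")
  }
  if (!is_count(config$n_iterations)) bad("n_iterations", "must be a positive integer")
  if (!is_scalar_num(config$de_min_pct) || config$de_min_pct < 0 || config$de_min_pct > 1) {
    bad("de_min_pct", "must be in [0, 1]")
  }
  if (!is_scalar_num(config$de_logfc) || config$de_logfc < 0) bad("de_logfc", "must be nonnegative")
  if (!is_prop(config$max_p_adjusted) && config$max_p_adjusted != 1) bad("max_p_adjusted", "must be in (0, 1]")
  if (!inherits(config$qc, "qc_thresholds")) bad("qc", "must be a qc_thresholds() object")
  if (is.null(config$simulation)) {
    need <- c("matrix", "genes", "barcodes", "cells", "genes_annot", "ppi", "reference_pairs")
    if (is.null(config$inputs) || !all(need %in% names(config$inputs))) {
      bad("inputs", sprintf("must name the input files (%s) when no simulation is configured", paste(need, collapse = ", ")))
    }
    missing <- !vapply(config$inputs[need], file.exists, logical(1))
    if (any(missing)) bad("inputs", sprintf("file not found: %s", config$inputs[need][missing][[1]]))
  } else if (!inherits(config$simulation, "simulation_config")) {
    bad("simulation", "must be a simulation_config() object")
  }
  invisible(config)
}

#' Read a pipeline run configuration from YAML
#'
#' Top-level keys match the arguments of [run_config()]; `simulation` is a
#' mapping of [simulation_config()] arguments (or `~` for none) and `qc` a
#' mapping of [qc_thresholds()] arguments.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    for (f in c("subtype_spec", "marker_spec", "planted_pairs")) {
      if (!is.null(raw$simulation[[f]])) {
        raw$simulation[[f]] <- dplyr::bind_rows(lapply(raw$simulation[[f]], tibble::as_tibble))
      }
    }
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_thresholds, raw$qc)
  do.call(run_config, raw)
}

stage_inputs_current <- function(manifest, stage, inputs) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(unlist(rec$outputs)))) return(FALSE)
  old <- unlist(rec$input_md5)
  new <- unname(tools::md5sum(unlist(inputs)))
  length(old) == length(new) && all(!is.na(new)) && all(old == new)
}

#' Run the full pipeline
#'
#' Chains simulate (optional) -> qc -> de -> build-db -> score -> report,
#' writing every stage output plus a JSON manifest (parameters, derived
#' seeds, input/output checksums, versions, wall-clock) sufficient to re-run
#' bit-identically. With `resume = TRUE`, stages whose recorded input
#' checksums still match are skipped and their outputs reused.
#'
#' @param config A [run_config()] (validated before any stage runs).
#' @param resume Reuse completed stage outputs when their inputs are
#'   unchanged.
#' @param verbose Log stage progress to stderr.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE, verbose = FALSE) {
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- list(
    package = as.character(utils::packageVersion("vasctalk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stages = list()
  )
  old <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list(stages = list())
  }
  log <- function(...) if (verbose) message(sprintf(...))

  run_stage <- function(name, inputs, fn) {
    if (resume && stage_inputs_current(old, name, inputs)) {
      log("[%s] up to date, skipping", name)
      manifest$stages[[name]] <<- old$stages[[name]]
      return(invisible(unlist(old$stages[[name]]$outputs)))
    }
    log("[%s] running", name)
    t0 <- Sys.time()
    outputs <- fn()
    manifest$stages[[name]] <<- list(
      outputs = as.list(outputs),
      input_md5 = as.list(unname(tools::md5sum(unlist(inputs)))),
      output_md5 = as.list(unname(tools::md5sum(unlist(outputs)))),
      elapsed_s = as.numeric(Sys.time() - t0, units = "secs")
    )
    invisible(outputs)
  }

  if (!is.null(config$simulation)) {
    data_dir <- file.path(out, "data")
    config_echo <- file.path(out, "simulation_config.yaml")
    sim_cfg <- config$simulation
    sim_cfg$seed <- config$seed
    write_simulation_config(sim_cfg, config_echo)
    data_paths <- run_stage("simulate", config_echo, function() {
      pipeline_simulate(sim_cfg, data_dir, null_data = config$null_data)
    })
    names(data_paths) <- c(
      "matrix", "genes", "barcodes", "cells", "genes_annot", "ppi",
      "reference_pairs", "ground_truth"
    )
  } else {
    data_paths <- unlist(config$inputs)
  }

  qc_out <- c(report = file.path(out, "qc_report.tsv"), kept = file.path(out, "kept.tsv"))
  run_stage("qc", data_paths[c("matrix", "genes", "barcodes", "genes_annot", "cells")], function() {
    pipeline_qc(
      data_paths["matrix"], data_paths["genes"], data_paths["barcodes"],
      data_paths["genes_annot"], data_paths["cells"],
      thresholds = config$qc, out_report = qc_out["report"], out_kept = qc_out["kept"]
    )
  })

  de_paths <- run_stage("de", c(data_paths[c("matrix", "genes", "barcodes", "cells")], qc_out["kept"]), function() {
    pipeline_de(
      data_paths["matrix"], data_paths["genes"], data_paths["barcodes"],
      data_paths["cells"], qc_out["kept"],
      subtypes = config$de_subtypes, region_a = config$de_region_a,
      region_b = config$de_region_b, min_pct = config$de_min_pct,
      logfc_threshold = config$de_logfc, only_pos = config$de_only_pos,
      adjust = config$de_adjust, out_dir = out
    )
  })

  db_path <- file.path(out, "lrdb.tsv")
  run_stage("build-db", c(data_paths[c("reference_pairs", "genes_annot", "ppi")], de_paths), function() {
    pipeline_build_db(
      data_paths["reference_pairs"], de_paths, data_paths["genes_annot"],
      data_paths["ppi"], max_p_adjusted = config$max_p_adjusted, out_db = db_path
    )
  })

  results_path <- file.path(out, "results.tsv")
  run_stage("score", c(data_paths[c("matrix", "genes", "barcodes", "cells")], qc_out["kept"], db_path), function() {
    pipeline_score(
      data_paths["matrix"], data_paths["genes"], data_paths["barcodes"],
      data_paths["cells"], qc_out["kept"], db_path,
      sender_subtype = config$sender_subtype, receivers = config$receivers,
      n_iterations = config$n_iterations, alpha = config$alpha, seed = config$seed,
      external_profile_path = config$external_profile_path,
      external_profile_subtype = config$external_profile_subtype,
      external_profile_region = config$external_profile_region,
      exclusion_target = config$exclusion_target,
      exclusion_region = config$exclusion_region,
      out_results = results_path
    )
  })

  summary_path <- file.path(out, "summary.tsv")
  run_stage("report", results_path, function() {
    pipeline_report(results_path, summary_path)
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("manifest written to %s", manifest_path)
  invisible(manifest)
}
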