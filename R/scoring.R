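## Co-expression interaction scoring with a bootstrap-calibrated null:
## score(pair) = average ligand expression in the sender subtype times
## average receptor expression in the receiver subtype (linear CP10K scale);
## significance from a one-sided empirical p against a null built by
## resampling cells with replacement and scoring random pseudo-receptor
## genes, Bonferroni-corrected over the pairs of the comparison.

## dense linear-scale (CP10K) expression of one (region, subtype) group
group_linear_matrix <- function(norm, cells, region, subtype) {
  bc <- group_barcodes(cells, region, subtype)
  as.matrix(expm1(norm[, bc, drop = FALSE]))
}

#' Interaction score of one ligand-receptor pair
#'
#' The product of the ligand's average expression in the sender and the
#' receptor's average expression in the receiver, both on the linear CP10K
#' scale. Scores for the two orientations of a pair are computed
#' independently; equality is not implied.
#'
#' @param sender_profile,receiver_profile Named numeric vectors of linear
#'   average expression (gene -> mean CP10K).
#' @param ligand,receptor Gene symbols (vectorized; recycled as usual).
#' @return Numeric score(s); `NA` where a gene is missing from its profile.
#' @export
interaction_score <- function(sender_profile, receiver_profile, ligand, receptor) {
  unname(sender_profile[ligand] * receiver_profile[receptor])
}

#' Bootstrap null distribution of interaction scores
#'
#' Per iteration, cells are resampled with replacement independently within
#' the sender and receiver groups, linear average expression is recomputed,
#' and `database_size` pseudo-receptor genes are drawn uniformly without
#' replacement from all detected genes, each paired with a ligand drawn
#' uniformly from `ligand_pool`; the products are pooled across iterations,
#' so the null holds `n_iterations * database_size` scores. With an external
#' receiver profile only the sender side is resampled.
#'
#' @param sender_mat,receiver_mat Dense linear-scale (CP10K) expression
#'   matrices (genes x cells) of the two groups; `receiver_mat` may instead
#'   be a fixed named profile vector from [ingest_external_profile()].
#' @param database_size Number of pseudo-receptor genes per iteration
#'   (defaults in callers to the database size).
#' @param ligand_pool Genes the null ligand is drawn from (the database's
#'   detected ligands in callers).
#' @param detected_genes Pool of pseudo-receptor genes.
#' @param n_iterations Number of bootstrap iterations.
#' @param seed Optional seed for reproducibility.
#' @return Numeric vector of `n_iterations * database_size` null scores.
#' @export
bootstrap_null <- function(sender_mat, receiver_mat, database_size, ligand_pool,
                           detected_genes, n_iterations = 1000L, seed = NULL) {
  if (database_size > length(detected_genes)) {
    abort(sprintf(
      "database_size (%d) exceeds the number of detected genes (%d)",
      database_size, length(detected_genes)
    ))
  }
  if (length(ligand_pool) == 0L) abort("`ligand_pool` is empty")
  fixed_receiver <- !is.matrix(receiver_mat)
  run <- function() {
    n_s <- ncol(sender_mat)
    scores <- numeric(n_iterations * database_size)
    for (i in seq_len(n_iterations)) {
      prof_s <- rowMeans(sender_mat[, sample.int(n_s, n_s, replace = TRUE), drop = FALSE])
      prof_r <- if (fixed_receiver) {
        receiver_mat
      } else {
        n_r <- ncol(receiver_mat)
        rowMeans(receiver_mat[, sample.int(n_r, n_r, replace = TRUE), drop = FALSE])
      }
      pseudo <- sample(detected_genes, database_size)
      ligs <- sample(ligand_pool, database_size, replace = TRUE)
      scores[((i - 1L) * database_size + 1L):(i * database_size)] <- prof_s[ligs] * prof_r[pseudo]
    }
    scores
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' One-sided empirical p-value against a null distribution
#'
#' `p = (1 + #[null >= score]) / (1 + |null|)` (upper tail, add-one
#' estimator, so p is never zero). Monotone non-increasing in the score for
#' a fixed null.
#'
#' @param null Numeric vector of null scores (non-empty).
#' @param score Observed score(s).
#' @return p-value(s) in `(0, 1]`; `NA` scores give `NA`.
#' @export
empirical_pvalue <- function(null, score) {
  if (length(null) == 0L) abort("`null` is empty")
  vapply(score, function(s) {
    if (is.na(s)) return(NA_real_)
    (1 + sum(null >= s)) / (1 + length(null))
  }, numeric(1))
}

#' Bonferroni-corrected interaction-score cutoff
#'
#' The smallest observed score whose empirical p-value times the family size
#' `m` is below `alpha`; `Inf` when no observed score qualifies. All pairs
#' scoring at or above the cutoff are significant.
#'
#' @param scores Observed pair scores.
#' @param null Null distribution (see [bootstrap_null()]).
#' @param alpha One-sided significance level after Bonferroni correction.
#' @param m Family size (number of scored pairs in the comparison).
#' @return A single score cutoff.
#' @export
determine_cutoff <- function(scores, null, alpha = 0.01, m = length(scores)) {
  stopifnot(m >= 1)
  p <- empirical_pvalue(null, scores)
  ok <- !is.na(p) & p * m < alpha
  if (!any(ok)) Inf else min(scores[ok])
}

#' Ingest an external average-expression profile as a receiver
#'
#' Wraps a segment-level profile (e.g. spatial transcriptomics pericyte
#' averages) as a named linear-expression vector usable as the receiver
#' side of [score_interactions()]. Values are used as-is; genes absent from
#' the count matrix remain scoreable through the profile. Provenance is
#' recorded in the scoring output (`receiver_source = "external_profile"`).
#'
#' @param profile Tibble with columns `gene` and `value` (nonnegative), see
#'   [read_expression_profile()].
#' @param subtype_label Subtype the profile stands for (e.g. `"pericyte"`).
#' @return A named numeric vector with attributes `subtype` and `source`.
#' @export
ingest_external_profile <- function(profile, subtype_label) {
  if (nrow(profile) == 0L) abort("external profile is empty")
  if (anyDuplicated(profile$gene)) abort("external profile: duplicate genes")
  if (any(is.na(profile$value) | profile$value < 0)) abort("external profile: values must be nonnegative")
  out <- setNames(profile$value, profile$gene)
  attr(out, "subtype") <- subtype_label
  attr(out, "source") <- "external_profile"
  out
}

#' Score a ligand-receptor database for one sender/receiver comparison
#'
#' Computes the observed interaction score of every database pair between
#' the sender and receiver groups, builds the bootstrap null, and calls a
#' pair significant when its Bonferroni-corrected one-sided empirical
#' p-value is below `alpha` (family size = number of scored pairs in this
#' comparison). Database ligands undetected in the sender score 0 and are
#' reported, not dropped; pairs whose gene is missing from the matrix (and
#' from the external profile, when one is used) get `NA` scores and are
#' skipped with a warning. Cross-region comparisons are disallowed unless
#' `allow_cross_region`.
#'
#' @param norm Log-normalized matrix from [normalize_counts()] (QC-passing
#'   cells).
#' @param cells Cell annotation covering the matrix barcodes.
#' @param db Ligand-receptor database from [build_database()].
#' @param sender,receiver Group labels `"region:subtype"`.
#' @param n_iterations Bootstrap iterations for the null.
#' @param alpha One-sided Bonferroni-corrected significance level.
#' @param seed Seed for the bootstrap.
#' @param receiver_profile Optional external receiver profile from
#'   [ingest_external_profile()]; replaces the receiver cells.
#' @param fixed_cutoff Optional fixed score cutoff overriding the
#'   bootstrap-calibrated significance call (scores strictly above it are
#'   significant), mirroring analyses that reuse a published cutoff.
#' @param allow_cross_region Permit sender and receiver from different
#'   regions.
#' @return A list of class `lr_scoring`: `results` (tibble with one row per
#'   pair: `ligand`, `receptor`, `display_name`, `provenance`, `sender`,
#'   `receiver`, `region`, `receiver_source`, `score`, `p_raw`,
#'   `p_bonferroni`, `significant`, `excluded_nonspecific`), `null` (the
#'   pooled null scores), `cutoff` (from [determine_cutoff()]) and `params`.
#' @export
score_interactions <- function(norm, cells, db, sender, receiver,
                               n_iterations = 1000L, alpha = 0.01, seed = NULL,
                               receiver_profile = NULL, fixed_cutoff = NULL,
                               allow_cross_region = FALSE) {
  validate_lr_database(db)
  s <- parse_group(sender)
  r <- parse_group(receiver)
  if (!allow_cross_region && s$region != r$region) {
    abort("sender and receiver must come from the same region (cross-region signaling disallowed by default)")
  }
  sender_mat <- group_linear_matrix(norm, cells, s$region, s$subtype)
  if (is.null(receiver_profile)) {
    receiver_mat <- group_linear_matrix(norm, cells, r$region, r$subtype)
    prof_r <- rowMeans(receiver_mat)
    receiver_source <- "cells"
  } else {
    receiver_mat <- receiver_profile
    prof_r <- receiver_profile
    receiver_source <- attr(receiver_profile, "source") %||% "external_profile"
  }
  prof_s <- rowMeans(sender_mat)

  score <- unname(prof_s[db$ligand] * prof_r[db$receptor])
  missing <- is.na(score)
  if (any(missing)) {
    warn(sprintf(
      "%d pair(s) skipped: gene missing from the expression profiles (e.g. %s)",
      sum(missing), db$display_name[which(missing)[1]]
    ))
  }

  detected <- rownames(norm)[Matrix::rowSums(norm) > 0]
  ligand_pool <- unique(db$ligand[db$ligand %in% names(prof_s) & prof_s[db$ligand] > 0])
  null <- bootstrap_null(
    sender_mat, receiver_mat,
    database_size = nrow(db), ligand_pool = ligand_pool,
    detected_genes = detected, n_iterations = n_iterations, seed = seed
  )

  m <- sum(!missing)
  p_raw <- empirical_pvalue(null, score)
  p_bonf <- pmin(1, p_raw * m)
  significant <- if (is.null(fixed_cutoff)) {
    !missing & p_bonf < alpha & score > 0
  } else {
    !missing & score > fixed_cutoff
  }
  cutoff <- if (is.null(fixed_cutoff)) {
    determine_cutoff(score[!missing], null, alpha = alpha, m = m)
  } else {
    fixed_cutoff
  }

  results <- tibble::tibble(
    ligand = db$ligand, receptor = db$receptor,
    display_name = db$display_name, provenance = db$provenance,
    sender = s$subtype, receiver = r$subtype, region = s$region,
    receiver_source = receiver_source,
    score = score, p_raw = p_raw, p_bonferroni = p_bonf,
    significant = significant, excluded_nonspecific = FALSE
  )
  structure(
    list(
      results = results, null = null, cutoff = cutoff,
      params = list(
        sender = sender, receiver = receiver, n_iterations = n_iterations,
        alpha = alpha, seed = seed, m = m, database_size = nrow(db),
        ligand_pool_size = length(ligand_pool), receiver_source = receiver_source
      )
    ),
    class = "lr_scoring"
  )
}

#' @export
print.lr_scoring <- function(x, ...) {
  cat(sprintf(
    "<lr_scoring> %s -> %s: %d pairs, %d significant, cutoff %.4g (alpha %g, m %d, %d iterations)\n",
    x$params$sender, x$params$receiver, nrow(x$results), sum(x$results$significant),
    x$cutoff, x$params$alpha, x$params$m, x$params$n_iterations
  ))
  invisible(x)
}

#' Flag pairs significant in every receiver subtype except the target
#'
#' Within one region, a pair aimed at `target_subtype` is flagged
#' `excluded_nonspecific` iff the set of receiver subtypes where it is
#' significant equals all receiving subtypes minus the target -- the
#' signature of a methodological artifact rather than target-specific
#' signaling. Flagged rows are removed from the significant set.
#'
#' @param results Combined results tibble (rows from [score_interactions()]
#'   across all receiver subtypes of one region).
#' @param target_subtype Receiver subtype being screened (e.g.
#'   `"pericyte"`).
#' @param region Region of the screen (e.g. `"ME"`).
#' @param subtypes All receiving subtypes of the screen; defaults to the
#'   receiver subtypes present in `results` for `region`. Significance must
#'   have been computed for each of them.
#' @return `results` with `excluded_nonspecific` and `significant` updated.
#' @export
flag_nonspecific_pairs <- function(results, target_subtype, region, subtypes = NULL) {
  in_region <- results$region == region
  present <- unique(results$receiver[in_region])
  subtypes <- subtypes %||% present
  if (!all(subtypes %in% present)) {
    abort(sprintf(
      "significance not computed for receiver subtype(s): %s",
      paste(setdiff(subtypes, present), collapse = ", ")
    ))
  }
  others <- setdiff(subtypes, target_subtype)
  key <- paste(results$ligand, results$receptor)
  for (k in unique(key[in_region & results$receiver == target_subtype])) {
    rows <- in_region & key == k
    sig_set <- unique(results$receiver[rows & results$significant])
    if (setequal(sig_set, others)) {
      target_rows <- rows & results$receiver == target_subtype
      results$excluded_nonspecific[target_rows] <- TRUE
      results$significant[target_rows] <- FALSE
    }
  }
  results
}

#' Summarize significant pairs per (region, sender, receiver)
#'
#' Counts significant, non-excluded pairs for every comparison present in
#' the results, keeping zero-count rows (the tidy input to an alluvial
#' plot of sender-to-receiver communication).
#'
#' @param results Combined results tibble (or a list of `lr_scoring`
#'   objects / results tibbles, which are row-bound first).
#' @return A tibble: `region`, `sender`, `receiver`, `n_significant`,
#'   sorted by region, sender, receiver. Invariant to input row order.
#' @export
summarize_interactions <- function(results) {
  results <- combine_results(results)
  results |>
    dplyr::group_by(.data$region, .data$sender, .data$receiver) |>
    dplyr::summarize(
      n_significant = sum(.data$significant & !.data$excluded_nonspecific),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$region, .data$sender, .data$receiver)
}

#' Row-bind scoring outputs into one results table
#'
#' @param results A results tibble, an `lr_scoring` object, or a list of
#'   either.
#' @return A single results tibble.
#' @export
combine_results <- function(results) {
  if (inherits(results, "lr_scoring")) return(results$results)
  if (inherits(results, "data.frame")) return(tibble::as_tibble(results))
  dplyr::bind_rows(lapply(results, combine_results))
}
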