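## Log-normalization to 10,000 transcripts per cell, group average
## expression, and Wilcoxon rank-sum differential expression with detection
## (min.pct) and average log2 fold-change gates.

#' Log-normalize counts to 10,000 transcripts per cell
#'
#' `value(g, c) = ln(1 + count(g, c) * 10000 / total(c))`. Cells with zero
#' total map to all zeros. For every nonzero cell,
#' `sum(exp(value) - 1) = 10000` up to floating point.
#'
#' @param counts Validated count matrix (genes x cells).
#' @param scale_factor Per-cell target total on the de-logged scale.
#' @return A sparse matrix of the same shape.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  validate_counts(counts)
  totals <- Matrix::colSums(counts)
  f <- ifelse(totals > 0, scale_factor / totals, 0)
  scaled <- counts %*% Matrix::Diagonal(x = f)
  out <- methods::as(log1p(scaled), "CsparseMatrix")
  dimnames(out) <- dimnames(counts)
  out
}

#' Average expression per group
#'
#' On the `linear` scale (the default, used for interaction scoring) this is
#' the arithmetic mean of the de-logged normalized values, i.e. mean counts
#' per 10,000 (CP10K); on the `log` scale it is the arithmetic mean of the
#' log-normalized values.
#'
#' @param norm Log-normalized matrix from [normalize_counts()].
#' @param groups Named character vector or factor mapping barcode to group
#'   label (names = barcodes), or a list of barcode vectors named by group.
#' @param scale `"linear"` or `"log"`.
#' @return A dense matrix, genes x groups.
#' @export
average_expression <- function(norm, groups, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (!is.list(groups)) {
    if (is.null(names(groups))) abort("`groups` must be named by barcode")
    groups <- split(names(groups), as.character(groups))
  }
  if (length(groups) == 0L) abort("`groups` is empty")
  out <- matrix(0, nrow = nrow(norm), ncol = length(groups),
    dimnames = list(rownames(norm), names(groups)))
  for (j in seq_along(groups)) {
    bc <- groups[[j]]
    if (length(bc) == 0L) abort(sprintf("group %s is empty", dQuote(names(groups)[j])))
    missing <- setdiff(bc, colnames(norm))
    if (length(missing) > 0L) abort(sprintf("unknown barcode(s): %s", paste(utils::head(missing, 3), collapse = ", ")))
    sub <- norm[, bc, drop = FALSE]
    out[, j] <- if (scale == "linear") Matrix::rowMeans(expm1(sub)) else Matrix::rowMeans(sub)
  }
  out
}

#' Average log2 fold change between two groups
#'
#' `log2((mean CP10K in A + pseudocount) / (mean CP10K in B + pseudocount))`
#' with the pseudocount applied on the de-logged (linear) mean scale. The
#' default gate of 0.6 used for regional enrichment corresponds to a linear
#' ratio of `2^0.6 ~ 1.52`, i.e. more than 1.5-fold.
#'
#' @param mean_a,mean_b Linear-scale (CP10K) mean expression, vectors or
#'   scalars.
#' @param pseudocount Added to both means before the ratio.
#' @return `avg_log2fc(A, B) = -avg_log2fc(B, A)` elementwise.
#' @export
avg_log2fc <- function(mean_a, mean_b, pseudocount = 1) {
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Wilcoxon rank-sum test (midranks; exact or normal approximation)
#'
#' Two-sided rank-sum p-value. With `n_a + n_b <= exact_limit` the p-value
#' is computed by exhaustive enumeration of all `choose(n, n_a)` group
#' assignments of the pooled midranks (ties handled by the midrank
#' statistic); otherwise a normal approximation with tie-corrected variance
#' and no continuity correction is used. Returns 1 when all pooled values
#' are identical.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @param exact_limit Largest pooled size for exact enumeration.
#' @return A p-value in `(0, 1]`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 20L) {
  n_a <- length(x)
  n_b <- length(y)
  if (n_a == 0L || n_b == 0L) abort("both groups must be non-empty")
  n <- n_a + n_b
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  if (n <= exact_limit) {
    perms <- combn(n, n_a)
    w_perm <- colSums(matrix(r[perms], nrow = n_a))
    return(mean(abs(w_perm - mu) >= abs(w - mu) - 1e-8))
  }
  ties <- table(r)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  min(1, 2 * pnorm(-abs(w - mu) / sqrt(sigma2)))
}

#' Wilcoxon differential expression with detection and fold-change gates
#'
#' A gene is tested only if it is detected in at least `min_pct` of the
#' cells of one of the groups and its average log2 fold change passes
#' `logfc_threshold` (`|lfc| >= threshold`, or `lfc >= threshold` when
#' `only_pos`). The multiple-testing adjustment is applied over the tested
#' genes only, after both gates, matching the behavior of the single-cell
#' toolkits this gate convention comes from.
#'
#' @param norm Log-normalized matrix from [normalize_counts()].
#' @param barcodes_a,barcodes_b Barcodes of the two groups (non-empty).
#' @param min_pct Detection gate: minimum fraction of expressing cells in
#'   the better-detected group.
#' @param logfc_threshold Fold-change gate on [avg_log2fc()] (0.25 is the
#'   conventional cluster-marker setting; 0.6, about 1.5-fold, the regional
#'   enrichment setting).
#' @param only_pos Keep only genes enriched in group A.
#' @param adjust `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @param pseudocount Passed to [avg_log2fc()].
#' @return A tibble sorted by p-value: `gene`, `avg_log2fc`, `pct_a`,
#'   `pct_b`, `p_value`, `p_adjusted`.
#' @export
wilcoxon_de <- function(norm, barcodes_a, barcodes_b, min_pct = 0.25,
                        logfc_threshold = 0.6, only_pos = FALSE,
                        adjust = c("bh", "bonferroni"), pseudocount = 1) {
  adjust <- match.arg(adjust)
  if (length(barcodes_a) == 0L || length(barcodes_b) == 0L) abort("both groups must be non-empty")
  a <- norm[, barcodes_a, drop = FALSE]
  b <- norm[, barcodes_b, drop = FALSE]
  pct_a <- Matrix::rowMeans(a > 0)
  pct_b <- Matrix::rowMeans(b > 0)
  lfc <- avg_log2fc(Matrix::rowMeans(expm1(a)), Matrix::rowMeans(expm1(b)), pseudocount)
  tested <- pmax(pct_a, pct_b) >= min_pct &
    (if (only_pos) lfc >= logfc_threshold else abs(lfc) >= logfc_threshold)
  idx <- which(tested)
  ad <- as.matrix(a[idx, , drop = FALSE])
  bd <- as.matrix(b[idx, , drop = FALSE])
  p <- vapply(seq_along(idx), function(i) rank_sum_test(ad[i, ], bd[i, ]), numeric(1))
  res <- tibble::tibble(
    gene = rownames(norm)[idx],
    avg_log2fc = unname(lfc[idx]),
    pct_a = unname(pct_a[idx]),
    pct_b = unname(pct_b[idx]),
    p_value = p,
    p_adjusted = p.adjust(p, method = if (adjust == "bh") "BH" else "bonferroni")
  )
  dplyr::arrange(res, .data$p_value, .data$gene)
}
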