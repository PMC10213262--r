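#' Score cross-dataset feature transferability of panel genes
#'
#' A gene is a usable classifier feature only if its expression behaves
#' consistently across datasets from different platforms and tissues. This
#' score quantifies that consistency from rank statistics: within each
#' dataset, every candidate gene gets the normalized rank (in \[0, 1\]) of
#' its median expression among the candidate genes; the transferability
#' score is `1 - mean(|rank difference|)` over all dataset pairs, so a gene
#' sitting at the same relative expression level everywhere scores 1 and a
#' gene that migrates across the panel's expression range scores low.
#' Because it is rank-based, the score is invariant to per-dataset monotone
#' transformations (platform effects).
#'
#' Genes that are effectively silent on some platform are caught separately:
#' a gene absent from a dataset, or whose dispersion (median absolute
#' deviation across samples) falls below the dispersion floor in any
#' dataset, is flagged and scored 0. The floor defaults to `floor_frac`
#' times the median panel dispersion of that dataset, i.e. it trips only for
#' genes an order of magnitude less variable than a typical panel gene
#' (constant or absent probes), not for the quiet tail of a healthy panel.
#'
#' @param datasets List of >= 2 expression matrices (genes x samples).
#' @param candidates A [gene_panel()] of candidate genes; each dataset must
#'   contain at least half of them.
#' @param threshold Keep/drop score threshold recorded in the report
#'   (default 0.7).
#' @param floor_frac Dispersion floor as a fraction of the median panel
#'   dispersion per dataset.
#' @return A tibble (one row per candidate gene): `gene_id`, `axis`,
#'   `score`, `flagged` (dispersion floor or absence), `keep`
#'   (`score >= threshold & !flagged`), `threshold`. Per-dataset
#'   diagnostics (median rank, dispersion, floor flag) are attached as the
#'   `"diagnostics"` attribute.
#' @export
transferability_scores <- function(datasets, candidates, threshold = 0.7,
                                   floor_frac = 0.1) {
  assert_panel(candidates)
  if (!is.list(datasets) || length(datasets) < 2) {
    abort("need at least 2 datasets to score transferability")
  }
  if (is.null(names(datasets))) names(datasets) <- sprintf("dataset_%d", seq_along(datasets))
  genes <- candidates$gene_id
  diag <- purrr::imap_dfr(datasets, function(m, nm) {
    assert_expression_matrix(m, nm)
    present <- intersect(genes, rownames(m))
    if (length(present) < length(genes) / 2) {
      abort(sprintf("%s contains fewer than half of the candidate genes", nm))
    }
    sub <- m[present, , drop = FALSE]
    med <- apply(sub, 1, stats::median)
    disp <- apply(sub, 1, stats::mad)
    floor_val <- floor_frac * stats::median(disp)
    nr <- if (length(present) > 1) (rank(med, ties.method = "average") - 1) / (length(present) - 1) else 0.5
    idx <- match(genes, present)
    is_present <- !is.na(idx)
    tibble::tibble(
      gene_id = genes,
      dataset = nm,
      present = is_present,
      median_rank = nr[idx],
      dispersion = disp[idx],
      floor_violated = !is_present | disp[idx] <= floor_val | disp[idx] == 0
    )
  })
  pair_idx <- utils::combn(length(datasets), 2)
  wide <- tidyr::pivot_wider(diag[, c("gene_id", "dataset", "median_rank")],
                             names_from = "dataset", values_from = "median_rank")
  rank_mat <- as.matrix(wide[, -1])
  pair_diff <- vapply(seq_len(ncol(pair_idx)), function(k) {
    abs(rank_mat[, pair_idx[1, k]] - rank_mat[, pair_idx[2, k]])
  }, numeric(nrow(rank_mat)))
  if (is.null(dim(pair_diff))) pair_diff <- matrix(pair_diff, nrow = 1)
  score <- 1 - rowMeans(pair_diff)
  flagged <- tapply(diag$floor_violated, diag$gene_id, any)[wide$gene_id]
  score[flagged | is.na(score)] <- 0
  report <- tibble::tibble(
    gene_id = wide$gene_id,
    axis = candidates$axis[match(wide$gene_id, candidates$gene_id)],
    score = unname(score),
    flagged = unname(flagged),
    keep = unname(score) >= threshold & !flagged,
    threshold = threshold
  )
  report <- report[match(genes, report$gene_id), ]
  attr(report, "diagnostics") <- diag
  report
}

#' Filter a gene panel by transferability
#'
#' Keeps candidate genes whose transferability score reaches the threshold
#' and whose dispersion floor flag is unset, preserving axis annotations.
#'
#' @param report Output of [transferability_scores()].
#' @param candidates The candidate [gene_panel()].
#' @param threshold Score threshold in \[0, 1\] (default 0.7).
#' @return The filtered panel tibble.
#' @export
filter_panel <- function(report, candidates, threshold = 0.7) {
  assert_panel(candidates)
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  keep_ids <- report$gene_id[report$score >= threshold & !report$flagged]
  out <- candidates[candidates$gene_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0) abort("transferability filter removed every candidate gene")
  missing_axis <- setdiff(unique(candidates$axis), unique(out$axis))
  if (length(missing_axis)) {
    abort(sprintf("transferability filter eliminated an entire axis: %s",
                  paste(missing_axis, collapse = ", ")))
  }
  out
}
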