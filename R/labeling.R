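#' Population-dependent axis scores
#'
#' The preliminary labeling model: each weighted panel gene is z-scored
#' across the samples of the cohort (sd with n - 1), and a sample's immune
#' and angiogenesis scores are the means of those z-scores over the weighted
#' genes of each axis. The scores are population statistics — changing the
#' cohort changes the scores — which is exactly why the trained classifier,
#' not this scorer, is used for population-independent inference.
#'
#' Zero-variance genes are excluded with a warning; an axis left with no
#' usable weighted gene is an error. Unweighted panel genes never contribute.
#'
#' @param expr Expression matrix (genes x samples), >= 2 samples.
#' @param panel A [gene_panel()].
#' @return Tibble: `sample_id`, `immune_score`, `angio_score` (z-units).
#' @export
axis_scores <- function(expr, panel) {
  assert_expression_matrix(expr, "expr")
  assert_panel(panel)
  if (ncol(expr) < 2) abort("axis scores need at least 2 samples (population z-scores)")
  used <- panel[panel$weighted & panel$gene_id %in% rownames(expr), , drop = FALSE]
  m <- expr[used$gene_id, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("excluding %d zero-variance gene(s) from axis scores: %s",
                 sum(sds == 0), paste(utils::head(rownames(m)[sds == 0], 5), collapse = ", ")))
    used <- used[sds > 0, , drop = FALSE]
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  for (ax in c("immune", "angiogenesis")) {
    if (!any(used$axis == ax)) abort(sprintf("no usable weighted genes on the %s axis", ax))
  }
  z <- (m - rowMeans(m)) / sds
  tibble::tibble(
    sample_id = colnames(expr),
    immune_score = unname(colMeans(z[used$axis == "immune", , drop = FALSE])),
    angio_score = unname(colMeans(z[used$axis == "angiogenesis", , drop = FALSE]))
  )
}

#' Quadrant subtype labels from axis scores
#'
#' Maps each sample's (immune, angiogenesis) score pair to one of the four
#' TME subtypes by quadrant: both high = IS (immune suppressed), immune-only
#' high = IA (immune active), angio-only high = A (angiogenic), both low =
#' ID (immune desert). "High" means strictly above the threshold, so a
#' sample exactly on a boundary is assigned the low side — deterministic,
#' and measure-zero on continuous data.
#'
#' @param scores Tibble from [axis_scores()].
#' @param thresholds Numeric pair `c(immune, angio)` of z cutoffs,
#'   default `c(0, 0)`.
#' @return Tibble: `sample_id`, `subtype` (factor with levels A, IA, ID, IS).
#' @export
quadrant_label <- function(scores, thresholds = c(0, 0)) {
  stopifnot(all(c("sample_id", "immune_score", "angio_score") %in% names(scores)))
  tibble::tibble(
    sample_id = scores$sample_id,
    subtype = factor(quadrant_of(scores$immune_score, scores$angio_score, thresholds),
                     levels = TME_SUBTYPES)
  )
}

#' One-step cohort labeling
#'
#' Convenience wrapper: [axis_scores()] then [quadrant_label()], returning
#' scores and subtype together.
#'
#' @inheritParams axis_scores
#' @inheritParams quadrant_label
#' @return Tibble: `sample_id`, `immune_score`, `angio_score`, `subtype`.
#' @export
label_cohort <- function(expr, panel, thresholds = c(0, 0)) {
  sc <- axis_scores(expr, panel)
  dplyr::left_join(sc, quadrant_label(sc, thresholds), by = "sample_id")
}
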