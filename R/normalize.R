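#' Freeze the training data's expression distribution
#'
#' Stores everything needed to map new cohorts onto the training
#' distribution without ever touching the training data again: the pooled
#' sorted vector of all training expression values (the reference quantile
#' function) and per-gene z-scaling parameters for the panel genes.
#'
#' Pass the full training matrix, not just the panel rows: the pooled
#' reference and the per-sample mapping both use every gene, because the
#' non-panel background genes are what anchor a sample's panel genes at the
#' right amplitude (a sample in which every panel gene is shifted up keeps
#' that shift only relative to its background). The z-scaling mean/sd are
#' computed on the quantile-mapped training matrix so that training-time
#' and prediction-time features are on an identical scale.
#'
#' @param train Expression matrix (genes x samples) of the training cohort;
#'   must contain every panel gene.
#' @param panel The model's [gene_panel()].
#' @param id Free-text provenance label for the training dataset.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `tme_reference` with fields `quantiles`
#'   (nondecreasing pooled vector), `gene_order`, `mean`, `sd`, and
#'   `provenance`.
#' @export
fit_reference <- function(train, panel, id = "training", seed = NA_integer_) {
  assert_expression_matrix(train, "train")
  assert_panel(panel)
  missing <- setdiff(panel$gene_id, rownames(train))
  if (length(missing)) {
    abort(sprintf("panel gene(s) missing from training data: %s",
                  paste(missing, collapse = ", ")))
  }
  sds <- apply(train[panel$gene_id, , drop = FALSE], 1, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance panel gene(s) in training data: %s",
                  paste(panel$gene_id[sds == 0], collapse = ", ")))
  }
  quantiles <- sort(as.vector(train))
  mapped <- quantile_map_samples(train, quantiles)[panel$gene_id, , drop = FALSE]
  ref <- structure(list(
    quantiles = quantiles,
    gene_order = panel$gene_id,
    mean = rowMeans(mapped),
    sd = apply(mapped, 1, stats::sd),
    provenance = list(train_id = id, seed = seed,
                      n_genes = nrow(train), n_samples = ncol(train))
  ), class = "tme_reference")
  if (any(ref$sd == 0)) {
    abort(sprintf("zero variance after reference mapping for gene(s): %s",
                  paste(names(ref$sd)[ref$sd == 0], collapse = ", ")))
  }
  ref
}

# per-sample quantile mapping: within each sample, the value with midrank r
# among G genes is replaced by the reference quantile at plotting position
# (r - 0.5) / G, linearly interpolated and clamped at the extremes
quantile_map_samples <- function(m, ref_quantiles) {
  G <- nrow(m)
  mapped <- apply(m, 2, function(x) {
    p <- (rank(x, ties.method = "average") - 0.5) / G
    stats::quantile(ref_quantiles, probs = p, names = FALSE, type = 7)
  })
  if (is.null(dim(mapped))) mapped <- matrix(mapped, nrow = G)
  dimnames(mapped) <- dimnames(m)
  mapped
}

#' Map a new dataset onto a frozen reference distribution
#'
#' Two-stage, per-sample mapping: (1) each sample's full expression profile
#' is replaced by reference quantiles at the sample's own empirical
#' plotting positions, so the sample's pooled distribution becomes the
#' training distribution while within-sample ordering is preserved exactly;
#' (2) the panel genes are extracted and z-scaled with the reference's
#' frozen per-gene mean and standard deviation. The result is the
#' model-ready feature matrix in reference gene order. The mapping is
#' monotone per sample and invariant to any strictly increasing
#' transformation of the new dataset's values; no parameter is re-estimated
#' from the new cohort.
#'
#' Supply the same kind of matrix that was used to fit the reference (panel
#' plus background genes): the background anchors each sample's panel
#' amplitudes.
#'
#' @param new Expression matrix containing all reference panel genes.
#' @param ref A `tme_reference` from [fit_reference()].
#' @param zscale Apply the per-gene z-scaling stage (default `TRUE`; turn
#'   off to inspect the quantile-mapped values on the training scale, for
#'   all genes of `new`).
#' @return Numeric matrix (reference panel genes x new samples), or the
#'   full quantile-mapped matrix when `zscale = FALSE`.
#' @export
map_to_reference <- function(new, ref, zscale = TRUE) {
  stopifnot(inherits(ref, "tme_reference"))
  assert_expression_matrix(new, "new")
  missing <- setdiff(ref$gene_order, rownames(new))
  if (length(missing)) {
    abort(sprintf("panel gene(s) absent from new data: %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(new) < 2) abort("need at least 2 genes per sample to quantile-map")
  mapped <- quantile_map_samples(new, ref$quantiles)
  if (!zscale) return(mapped)
  m <- mapped[ref$gene_order, , drop = FALSE]
  (m - ref$mean) / ref$sd
}
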