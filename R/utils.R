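#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data
#' @importFrom generics tidy glance
#' @import ggplot2
NULL

# canonical subtype order, used everywhere incl. argmax tie-breaks
TME_SUBTYPES <- c("A", "IA", "ID", "IS")

#' @export
generics::tidy

#' @export
generics::glance

# half-up rounding at `digits` decimals; base round() is half-even, but
# reported rates follow the usual clinical-table convention
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples)", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames", arg))
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("duplicate gene ids in `%s`: %s", arg,
                  paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("duplicate sample ids in `%s`: %s", arg,
                  paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  }
  if (any(!is.finite(x))) abort(sprintf("`%s` contains non-finite values", arg))
  invisible(x)
}

assert_panel <- function(panel) {
  req <- c("gene_id", "axis", "weighted")
  if (!is.data.frame(panel) || !all(req %in% names(panel))) {
    abort("panel must be a data frame with columns gene_id, axis, weighted")
  }
  if (anyDuplicated(panel$gene_id)) {
    abort(sprintf("duplicate gene ids in panel: %s",
                  paste(unique(panel$gene_id[duplicated(panel$gene_id)]), collapse = ", ")))
  }
  bad <- setdiff(unique(panel$axis), c("immune", "angiogenesis"))
  if (length(bad)) {
    abort(sprintf("unknown axis token(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(panel)
}
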