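#' Tidy a trained subtype classifier
#'
#' One row per gene-to-neuron hidden weight, with the panel axis annotation
#' when a panel is supplied — the tabular form behind the neuron-weight
#' interpretability display.
#'
#' @param x A `tme_model`.
#' @param panel Optional [gene_panel()] to annotate genes with their axis.
#' @param ... Unused.
#' @return Tibble: `gene_id`, `neuron`, `weight` (+ `axis` if annotated).
#' @method tidy tme_model
#' @export
tidy.tme_model <- function(x, panel = NULL, ...) {
  out <- tibble::as_tibble(x$hidden_weights, rownames = "gene_id")
  out <- tidyr::pivot_longer(out, -"gene_id", names_to = "neuron",
                             values_to = "weight")
  if (!is.null(panel)) {
    out$axis <- panel$axis[match(out$gene_id, panel$gene_id)]
  }
  out
}

#' Training summary of a subtype classifier
#'
#' @param x A `tme_model`.
#' @param ... Unused.
#' @return One-row tibble: gene count, seed, L2 strength, iterations run,
#'   initial and final loss, stopping reason.
#' @method glance tme_model
#' @export
glance.tme_model <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_order),
    seed = x$metadata$seed,
    l2 = x$metadata$l2,
    iterations = x$metadata$iterations,
    initial_loss = x$metadata$initial_loss,
    final_loss = x$metadata$final_loss,
    stopping_reason = x$metadata$stopping_reason,
    has_reference = !is.null(x$reference)
  )
}

#' @export
print.tme_model <- function(x, ...) {
  cat(sprintf("TME subtype classifier: %d genes -> 2 tanh neurons -> 4 subtypes (%s)\n",
              length(x$gene_order), paste(x$class_order, collapse = ", ")))
  cat(sprintf("  trained %d iterations (%s), loss %.5f -> %.5f, seed %d\n",
              x$metadata$iterations, x$metadata$stopping_reason,
              x$metadata$initial_loss, x$metadata$final_loss, x$metadata$seed))
  cat(sprintf("  reference distribution: %s\n",
              if (is.null(x$reference)) "none" else
                sprintf("%d pooled values (%s)", length(x$reference$quantiles),
                        x$reference$provenance$train_id)))
  invisible(x)
}

#' @export
print.tme_reference <- function(x, ...) {
  cat(sprintf("frozen reference distribution: %d genes, %d pooled values (%s, seed %s)\n",
              length(x$gene_order), length(x$quantiles),
              x$provenance$train_id, x$provenance$seed))
  invisible(x)
}
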