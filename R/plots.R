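#' Probability surface over the latent plane
#'
#' Applies the model's output layer (softmax over the hidden-to-output
#' weights) to a regular grid over the latent square (-1, 1)^2. This is the
#' same map [predict_subtypes()] applies to each sample's hidden
#' activations, so the surface is consistent with the calls by construction.
#'
#' @param model A `tme_model`.
#' @param resolution Grid points per axis (>= 20).
#' @return Tibble: `neuron1`, `neuron2`, `p_A` ... `p_IS`, `max_probability`,
#'   `subtype`.
#' @export
latent_probability_grid <- function(model, resolution = 101) {
  stopifnot(inherits(model, "tme_model"))
  if (resolution < 20) abort("grid resolution must be >= 20")
  ax <- seq(-1, 1, length.out = resolution)
  grid <- expand.grid(neuron1 = ax, neuron2 = ax)
  P <- output_layer_probs(model, as.matrix(grid))
  tibble::tibble(
    neuron1 = grid$neuron1, neuron2 = grid$neuron2,
    p_A = P[, 1], p_IA = P[, 2], p_ID = P[, 3], p_IS = P[, 4],
    max_probability = apply(P, 1, max),
    subtype = factor(model$class_order[apply(P, 1, which.max)],
                     levels = model$class_order)
  )
}

# output layer only: latent (n x 2) -> class probabilities (n x 4)
output_layer_probs <- function(model, latent) {
  softmax_rows(sweep(latent %*% model$output_weights, 2,
                     model$output_biases, "+"))
}

#' Latent-space plot of classified samples
#'
#' Scatters samples at their hidden-neuron coordinates over gray
#' probability-gradient contours (levels of the maximum subtype
#' probability). Neuron 1 (x) tracks the immune axis and neuron 2 (y) the
#' angiogenesis axis in an aligned model, so the plot mirrors the quadrant
#' phenotype diagram: confident calls sit near the corners, ambiguous ones
#' near the center.
#'
#' @param model A `tme_model`.
#' @param calls Tibble from [predict_subtypes()] on that model.
#' @param clinical Optional clinical tibble joined by `sample_id` when
#'   `annotate` names one of its columns.
#' @param annotate Column to color glyphs by: `"subtype"`,
#'   `"max_probability"`, or any clinical column (e.g. `"bor"`).
#' @param resolution Contour grid resolution (>= 20).
#' @param contour_levels Levels of max subtype probability to draw.
#' @return A ggplot object.
#' @export
plot_latent_space <- function(model, calls, clinical = NULL,
                              annotate = "subtype", resolution = 101,
                              contour_levels = c(0.3, 0.5, 0.7, 0.9)) {
  grid <- latent_probability_grid(model, resolution)
  df <- calls
  if (!annotate %in% names(df)) {
    if (is.null(clinical) || !annotate %in% names(clinical)) {
      abort(sprintf("annotation channel '%s' not found in calls or clinical table", annotate))
    }
    df <- dplyr::left_join(df, clinical, by = "sample_id")
  }
  p <- ggplot(df, aes(x = .data$neuron1, y = .data$neuron2))
  if (diff(range(grid$max_probability)) > 1e-9) {
    p <- p + geom_contour(
      data = grid,
      aes(x = .data$neuron1, y = .data$neuron2, z = .data$max_probability),
      breaks = contour_levels, colour = "grey70", linewidth = 0.3
    )
  }
  p +
    geom_hline(yintercept = 0, linetype = "dotted", colour = "grey60") +
    geom_vline(xintercept = 0, linetype = "dotted", colour = "grey60") +
    geom_point(aes(colour = .data[[annotate]]), size = 2) +
    coord_fixed(xlim = c(-1, 1), ylim = c(-1, 1)) +
    labs(x = "hidden neuron 1 (immune axis)",
         y = "hidden neuron 2 (angiogenesis axis)",
         colour = annotate) +
    theme_minimal()
}

#' Biomarker score distribution plot
#'
#' Per-sample signed biomarker scores (2 x combined probability - 1) with
#' the decision boundary at 0; samples with score >= 0 are B+. A
#' well-separated cohort shows a bimodal distribution with a gap around the
#' boundary.
#'
#' @param biomarker Tibble from [biomarker_call()].
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(biomarker) {
  if (!nrow(biomarker)) abort("no biomarker calls supplied")
  df <- dplyr::arrange(biomarker, .data$score)
  df$index <- seq_len(nrow(df))
  ggplot(df, aes(x = .data$index, y = .data$score)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    geom_point(aes(colour = .data$status), size = 2) +
    scale_colour_manual(values = c("B+" = "#C0392B", "B-" = "#2C3E50")) +
    ylim(-1, 1) +
    labs(x = "samples (ordered by score)", y = "biomarker score",
         colour = "status") +
    theme_minimal()
}

#' Render a plot to file deterministically
#'
#' @param plot A ggplot object.
#' @param path Output path; format from the extension (png, svg, pdf).
#' @param width,height,dpi Device settings.
#' @export
save_plot <- function(plot, path, width = 6, height = 5, dpi = 150) {
  ggsave(path, plot = plot, width = width, height = height, dpi = dpi)
  invisible(path)
}
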