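# shared fixture builders; everything is generated in code

toy_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_panel <- function(n_immune = 1, n_angio = 1, weighted = TRUE) {
  gene_panel(c(sprintf("imm%d", seq_len(n_immune)), sprintf("ang%d", seq_len(n_angio))),
             c(rep("immune", n_immune), rep("angiogenesis", n_angio)),
             weighted)
}

# hand-assembled model with explicit parameters
toy_model <- function(W1, b1 = c(0, 0), W2 = matrix(0, 2, 4), b2 = rep(0, 4),
                      genes = NULL, reference = NULL) {
  W1 <- as.matrix(W1)
  genes <- genes %||% rownames(W1) %||% sprintf("g%d", seq_len(nrow(W1)))
  rownames(W1) <- genes
  colnames(W1) <- c("neuron1", "neuron2")
  dimnames(W2) <- list(c("neuron1", "neuron2"), c("A", "IA", "ID", "IS"))
  names(b2) <- c("A", "IA", "ID", "IS")
  structure(list(
    hidden_weights = W1, hidden_biases = b1,
    output_weights = W2, output_biases = b2,
    class_order = c("A", "IA", "ID", "IS"), gene_order = genes,
    reference = reference,
    metadata = list(seed = 0L, l2 = 0, iterations = 0L, initial_loss = NA_real_,
                    final_loss = NA_real_, stopping_reason = "constructed",
                    cv_summary = NULL)
  ), class = "tme_model")
}

# subtype-call tibble from an explicit probability matrix
toy_calls <- function(P, sample_ids = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  cls <- c("A", "IA", "ID", "IS")
  tibble::tibble(
    sample_id = sample_ids %||% sprintf("s%d", seq_len(n)),
    p_A = P[, 1], p_IA = P[, 2], p_ID = P[, 3], p_IS = P[, 4],
    subtype = factor(cls[apply(P, 1, which.max)], levels = cls),
    neuron1 = 0, neuron2 = 0,
    max_probability = apply(P, 1, max)
  )
}

toy_clinical <- function(bor, sample_ids = NULL, ...) {
  as_clinical(tibble::tibble(
    sample_id = sample_ids %||% sprintf("s%d", seq_along(bor)),
    bor = bor, ...
  ))
}

# small trained model on a mixture-mode cohort, reused by several tests
trained_fixture <- function(seed = 42, n = 160, genes_per_axis = 12, noise_bg = 24) {
  sim <- simulate_cohort(sim_config(n_samples = n, n_genes_per_axis = genes_per_axis,
                                    n_noise_genes = noise_bg, seed = seed))
  lab <- label_cohort(sim$expression, sim$panel)
  ref <- fit_reference(sim$expression, sim$panel, seed = seed)
  feat <- map_to_reference(sim$expression, ref)
  model <- train_model(feat, lab, train_config(seed = seed), reference = ref)
  list(sim = sim, labels = lab, ref = ref, features = feat, model = model)
}
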