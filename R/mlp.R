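#' Training configuration for the subtype classifier
#'
#' @param tolerance Minimum loss improvement counted as progress (default
#'   1e-4).
#' @param patience Consecutive non-improving iterations tolerated before
#'   stopping (default 10).
#' @param max_iterations Hard iteration cap (default 1000).
#' @param l2 L2 regularization strength on the weights (default 1e-4).
#' @param init_scale Multiplier on the fan-in/fan-out scaled uniform weight
#'   initialization (default 1).
#' @param seed Integer seed for the weight initialization.
#' @param cv_repeats Repeats of the stratified k-fold loop (default 3).
#' @param cv_folds Folds per repeat (default 10).
#' @param grid Data frame of hyperparameter combinations for
#'   [cross_validate()]; columns must be `train_config` argument names
#'   (default a small ladder of `l2` values).
#' @return A list of class `train_config`.
#' @export
train_config <- function(tolerance = 1e-4, patience = 10, max_iterations = 1000,
                         l2 = 1e-4, init_scale = 1, seed = 1L,
                         cv_repeats = 3, cv_folds = 10,
                         grid = data.frame(l2 = c(1e-4, 1e-2, 1))) {
  if (tolerance <= 0) abort("tolerance must be > 0")
  if (cv_folds < 2) abort("cv_folds must be >= 2")
  structure(list(tolerance = tolerance, patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations), l2 = l2,
                 init_scale = init_scale, seed = as.integer(seed),
                 cv_repeats = as.integer(cv_repeats),
                 cv_folds = as.integer(cv_folds), grid = grid),
            class = "train_config")
}

# ---- parameter packing -----------------------------------------------------

mlp_unpack <- function(par, G) {
  K <- 4L; H <- 2L
  i <- 0
  W1 <- matrix(par[i + seq_len(G * H)], G, H); i <- i + G * H
  b1 <- par[i + seq_len(H)]; i <- i + H
  W2 <- matrix(par[i + seq_len(H * K)], H, K); i <- i + H * K
  b2 <- par[i + seq_len(K)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_pack <- function(W1, b1, W2, b2) c(as.vector(W1), b1, as.vector(W2), b2)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; X is samples x genes
mlp_forward <- function(X, W1, b1, W2, b2) {
  H <- tanh(sweep(X %*% W1, 2, b1, "+"))
  P <- softmax_rows(sweep(H %*% W2, 2, b2, "+"))
  list(H = H, P = P)
}

# multi-class cross-entropy + L2 on weights; Y is n x 4 one-hot
mlp_loss <- function(par, X, Y, l2) {
  th <- mlp_unpack(par, ncol(X))
  fw <- mlp_forward(X, th$W1, th$b1, th$W2, th$b2)
  n <- nrow(X)
  ce <- -sum(Y * log(pmax(fw$P, 1e-300))) / n
  ce + 0.5 * l2 * (sum(th$W1^2) + sum(th$W2^2))
}

mlp_grad <- function(par, X, Y, l2) {
  th <- mlp_unpack(par, ncol(X))
  fw <- mlp_forward(X, th$W1, th$b1, th$W2, th$b2)
  n <- nrow(X)
  dZ <- (fw$P - Y) / n
  dW2 <- crossprod(fw$H, dZ) + l2 * th$W2
  db2 <- colSums(dZ)
  dU <- (dZ %*% t(th$W2)) * (1 - fw$H^2)
  dW1 <- crossprod(X, dU) + l2 * th$W1
  db1 <- colSums(dU)
  mlp_pack(dW1, db1, dW2, db2)
}

mlp_init <- function(G, seed, init_scale) {
  with_sim_seed(seed, {
    s1 <- init_scale * sqrt(6 / (G + 2))
    s2 <- init_scale * sqrt(6 / (2 + 4))
    mlp_pack(matrix(stats::runif(G * 2, -s1, s1), G, 2),
             stats::runif(2, -s2, s2),
             matrix(stats::runif(2 * 4, -s2, s2), 2, 4),
             stats::runif(4, -s2, s2))
  })
}

coerce_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "subtype") %in% names(labels))) {
      abort("labels data frame needs sample_id and subtype columns")
    }
    labels <- as.character(labels$subtype[match(sample_ids, labels$sample_id)])
  } else {
    labels <- as.character(labels)
  }
  if (anyNA(labels)) abort("missing subtype label for some samples")
  bad <- setdiff(unique(labels), TME_SUBTYPES)
  if (length(bad)) abort(sprintf("unknown subtype label(s): %s", paste(bad, collapse = ", ")))
  labels
}

#' Train the TME subtype classifier
#'
#' Fits a multilayer perceptron with two tanh hidden neurons and a
#' four-class softmax output by minimizing the multi-class cross-entropy
#' loss (plus a small L2 penalty on the weights) with the L-BFGS solver.
#' Optimization runs in chunks of 10 iterations and stops when a chunk
#' improves the loss by less than `tolerance` (the patience rule at chunk
#' granularity), or at `max_iterations`.
#'
#' @param features Reference-normalized expression matrix (genes x samples);
#'   all values must be finite.
#' @param labels Subtype labels: either a tibble with `sample_id` and
#'   `subtype`, or a character/factor vector aligned to the feature columns.
#'   All four subtypes must be present.
#' @param cfg A [train_config()].
#' @param reference Optional `tme_reference` to embed so the model is
#'   self-contained for new cohorts (see [classify_samples()]).
#' @return An object of class `tme_model`.
#' @export
train_model <- function(features, labels, cfg = train_config(), reference = NULL) {
  assert_expression_matrix(features, "features")
  y <- coerce_labels(labels, colnames(features))
  missing_cls <- setdiff(TME_SUBTYPES, unique(y))
  if (length(missing_cls)) {
    abort(sprintf("class(es) absent from training labels: %s",
                  paste(missing_cls, collapse = ", ")))
  }
  n <- ncol(features)
  if (n < 5 * 4) abort("need at least 5 samples per class (n >= 20)")
  X <- t(features)
  G <- ncol(X)
  Y <- outer(y, TME_SUBTYPES, "==") * 1
  par <- mlp_init(G, cfg$seed, cfg$init_scale)
  initial_loss <- mlp_loss(par, X, Y, cfg$l2)
  loss <- initial_loss
  iters <- 0L
  reason <- "max_iterations"
  chunk <- cfg$patience
  while (iters < cfg$max_iterations) {
    res <- stats::optim(par, mlp_loss, mlp_grad, X = X, Y = Y, l2 = cfg$l2,
                        method = "L-BFGS-B",
                        control = list(maxit = chunk, factr = 10))
    iters <- iters + chunk
    improvement <- loss - res$value
    if (res$value <= loss) { par <- res$par; loss <- res$value }
    if (improvement < cfg$tolerance) {
      reason <- "patience"
      break
    }
  }
  th <- mlp_unpack(par, G)
  dimnames(th$W1) <- list(rownames(features), c("neuron1", "neuron2"))
  dimnames(th$W2) <- list(c("neuron1", "neuron2"), TME_SUBTYPES)
  names(th$b2) <- TME_SUBTYPES
  structure(list(
    hidden_weights = th$W1, hidden_biases = th$b1,
    output_weights = th$W2, output_biases = th$b2,
    class_order = TME_SUBTYPES, gene_order = rownames(features),
    reference = reference,
    metadata = list(seed = cfg$seed, l2 = cfg$l2, iterations = iters,
                    initial_loss = initial_loss, final_loss = loss,
                    stopping_reason = reason, cv_summary = NULL)
  ), class = "tme_model")
}

#' Predict subtype probabilities
#'
#' Deterministic forward pass: hidden activation `tanh(w . x + b)` per
#' neuron, then softmax over the four output neurons. The subtype is the
#' argmax, with ties broken by class order (A, IA, ID, IS); no minimum
#' probability is required for a call.
#'
#' @param model A `tme_model`.
#' @param features Reference-normalized matrix with exactly the model's
#'   genes (any row order).
#' @return Tibble: `sample_id`, `p_A`, `p_IA`, `p_ID`, `p_IS`, `subtype`,
#'   `neuron1`, `neuron2`, `max_probability`.
#' @export
predict_subtypes <- function(model, features) {
  stopifnot(inherits(model, "tme_model"))
  assert_expression_matrix(features, "features")
  extra <- setdiff(rownames(features), model$gene_order)
  missing <- setdiff(model$gene_order, rownames(features))
  if (length(missing) || length(extra)) {
    abort(sprintf("feature genes do not match the model: missing [%s], unexpected [%s]",
                  paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
  }
  X <- t(features[model$gene_order, , drop = FALSE])
  fw <- mlp_forward(X, model$hidden_weights, model$hidden_biases,
                    model$output_weights, model$output_biases)
  sub <- model$class_order[apply(fw$P, 1, which.max)]
  tibble::tibble(
    sample_id = colnames(features),
    p_A = unname(fw$P[, 1]), p_IA = unname(fw$P[, 2]),
    p_ID = unname(fw$P[, 3]), p_IS = unname(fw$P[, 4]),
    subtype = factor(sub, levels = model$class_order),
    neuron1 = unname(fw$H[, 1]), neuron2 = unname(fw$H[, 2]),
    max_probability = unname(apply(fw$P, 1, max))
  )
}

#' Hidden-layer (latent) coordinates
#'
#' The two tanh hidden activations per sample — the axes of the latent-space
#' plot. Identical to the intermediate values of [predict_subtypes()].
#'
#' @inheritParams predict_subtypes
#' @return Tibble: `sample_id`, `neuron1`, `neuron2` (each in (-1, 1)).
#' @export
latent_coordinates <- function(model, features) {
  predict_subtypes(model, features)[, c("sample_id", "neuron1", "neuron2")]
}

#' Normalize and classify a raw cohort in one step
#'
#' Maps the cohort onto the model's embedded frozen reference distribution
#' ([map_to_reference()]) and runs [predict_subtypes()].
#'
#' @param model A `tme_model` with an embedded reference.
#' @param expr Raw (log-scale) expression matrix containing all panel genes.
#' @return As [predict_subtypes()].
#' @export
classify_samples <- function(model, expr) {
  if (is.null(model$reference)) abort("model has no embedded reference distribution")
  predict_subtypes(model, map_to_reference(expr, model$reference))
}

# ---- cross validation ------------------------------------------------------

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Tune hyperparameters by repeated stratified k-fold cross-validation
#'
#' Evaluates every row of the hyperparameter grid with `cv_repeats` repeats
#' of stratified `cv_folds`-fold cross-validation and selects the grid point
#' with the highest mean validation accuracy; ties go to the smallest L2
#' strength (the less flexible model).
#'
#' @inheritParams train_model
#' @return List: `best` (one grid row), `results` (tibble of per-repeat,
#'   per-fold validation accuracy for every grid point), `summary` (mean
#'   accuracy per grid point).
#' @export
cross_validate <- function(features, labels, cfg = train_config()) {
  assert_expression_matrix(features, "features")
  y <- coerce_labels(labels, colnames(features))
  grid <- cfg$grid
  if (is.null(grid) || nrow(grid) == 0) abort("hyperparameter grid is empty")
  if (ncol(features) < cfg$cv_folds * 4) {
    abort("need at least cv_folds x 4 samples for stratified CV")
  }
  results <- with_sim_seed(cfg$seed, {
    purrr::map_dfr(seq_len(cfg$cv_repeats), function(rep_i) {
      fold <- stratified_folds(y, cfg$cv_folds)
      purrr::map_dfr(seq_len(cfg$cv_folds), function(k) {
        tr <- fold != k; va <- fold == k
        purrr::map_dfr(seq_len(nrow(grid)), function(g) {
          cfg_g <- cfg
          for (nm in names(grid)) cfg_g[[nm]] <- grid[[nm]][g]
          fit <- train_model(features[, tr, drop = FALSE], y[tr], cfg_g)
          pred <- predict_subtypes(fit, features[, va, drop = FALSE])
          tibble::tibble(grid_id = g, repeat_i = rep_i, fold = k,
                         accuracy = mean(as.character(pred$subtype) == y[va]))
        })
      })
    })
  })
  summ <- dplyr::summarise(dplyr::group_by(results, .data$grid_id),
                           mean_accuracy = mean(.data$accuracy), .groups = "drop")
  summ <- dplyr::bind_cols(summ, grid[summ$grid_id, , drop = FALSE])
  ord <- order(-summ$mean_accuracy,
               if ("l2" %in% names(summ)) summ$l2 else summ$grid_id)
  best <- summ[ord[1], , drop = FALSE]
  list(best = best, results = results, summary = summ)
}

# ---- interpretability ------------------------------------------------------

#' Neuron-to-axis alignment of the hidden weights
#'
#' Checks whether the trained hidden layer rediscovered the panel's two
#' biological axes. An axis's sign-alignment on its assigned neuron is the
#' fraction of panel genes whose hidden weight has the expected sign:
#' positive for the neuron's own axis genes and negative for the other
#' axis's genes (the contrast structure in which each neuron reads out one
#' biology and nets out the other). Because negating a hidden neuron's
#' weights together with its outgoing output weights leaves the network's
#' function unchanged, each neuron's orientation is arbitrary; the search
#' therefore covers both neuron-to-axis permutations and both orientations
#' per neuron, and reports the maximizing assignment with its orientations.
#' Random weights give alignment ~0.5; an aligned model approaches 1.
#'
#' @param model A `tme_model`.
#' @param panel [gene_panel()] with axis annotations covering the model's
#'   genes.
#' @return List: `assignment` (named character, neuron -> axis),
#'   `orientation` (named +1/-1 per neuron), `alignment` (tibble with
#'   per-axis sign-alignment fractions), `mean_alignment`, and
#'   `positive_fraction` (2 x 2 matrix, fraction of each axis's genes with
#'   positive raw weight per neuron).
#' @export
neuron_axis_alignment <- function(model, panel) {
  stopifnot(inherits(model, "tme_model"))
  assert_panel(panel)
  W <- model$hidden_weights
  ax <- panel$axis[match(rownames(W), panel$gene_id)]
  if (anyNA(ax)) abort("panel does not annotate every model gene")
  axes <- c("immune", "angiogenesis")
  pos_frac <- vapply(axes, function(a) colMeans(W[ax == a, , drop = FALSE] > 0),
                     numeric(2))  # neurons x axes
  sign_align <- function(w, axis) mean(c(w[ax == axis] > 0, w[ax != axis] < 0))
  best <- NULL
  for (perm in list(c("immune", "angiogenesis"), c("angiogenesis", "immune"))) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      al <- c(sign_align(s1 * W[, 1], perm[1]), sign_align(s2 * W[, 2], perm[2]))
      names(al) <- perm
      if (is.null(best) || mean(al) > best$mean) {
        best <- list(assignment = stats::setNames(perm, c("neuron1", "neuron2")),
                     orientation = c(neuron1 = s1, neuron2 = s2),
                     alignment = al, mean = mean(al))
      }
    }
  }
  list(
    assignment = best$assignment,
    orientation = best$orientation,
    alignment = tibble::tibble(axis = names(best$alignment),
                               sign_alignment = unname(best$alignment)),
    mean_alignment = best$mean,
    positive_fraction = pos_frac
  )
}

# ---- persistence -----------------------------------------------------------

#' Save / load a trained model as JSON
#'
#' The JSON document holds every model field (weights at full precision,
#' embedded reference distribution, training metadata) under a versioned
#' schema; save -> load -> predict reproduces probabilities to 1e-12.
#'
#' @param model A `tme_model`.
#' @param path Output path (`.json`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tme_model"))
  doc <- list(
    schema = "tme_model/1",
    gene_order = model$gene_order,
    class_order = model$class_order,
    hidden_weights = unname(model$hidden_weights),
    hidden_biases = model$hidden_biases,
    output_weights = unname(model$output_weights),
    output_biases = unname(model$output_biases),
    metadata = model$metadata,
    reference = if (!is.null(model$reference)) list(
      quantiles = model$reference$quantiles,
      gene_order = model$reference$gene_order,
      mean = unname(model$reference$mean),
      sd = unname(model$reference$sd),
      provenance = model$reference$provenance
    )
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @param path Path to a model JSON written by [save_model()].
#' @return A `tme_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "tme_model/1")) abort("unrecognized model schema")
  W1 <- matrix(doc$hidden_weights, ncol = 2,
               dimnames = list(doc$gene_order, c("neuron1", "neuron2")))
  W2 <- matrix(doc$output_weights, nrow = 2,
               dimnames = list(c("neuron1", "neuron2"), doc$class_order))
  ref <- NULL
  if (!is.null(doc$reference)) {
    ref <- structure(list(
      quantiles = doc$reference$quantiles,
      gene_order = doc$reference$gene_order,
      mean = stats::setNames(doc$reference$mean, doc$reference$gene_order),
      sd = stats::setNames(doc$reference$sd, doc$reference$gene_order),
      provenance = doc$reference$provenance
    ), class = "tme_reference")
  }
  structure(list(
    hidden_weights = W1, hidden_biases = doc$hidden_biases,
    output_weights = W2,
    output_biases = stats::setNames(doc$output_biases, doc$class_order),
    class_order = doc$class_order, gene_order = doc$gene_order,
    reference = ref, metadata = doc$metadata
  ), class = "tme_model")
}
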