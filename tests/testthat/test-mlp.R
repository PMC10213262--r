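test_that("a zero-parameter model returns uniform probabilities and origin latents", {
  model <- toy_model(matrix(0, 2, 2), genes = c("g1", "g2"))
  feats <- toy_expr(matrix(rnorm(10), 2, 5), genes = c("g1", "g2"))
  calls <- predict_subtypes(model, feats)
  expect_true(all(abs(as.matrix(calls[paste0("p_", c("A", "IA", "ID", "IS"))]) - 0.25) < 1e-12))
  expect_true(all(calls$neuron1 == 0 & calls$neuron2 == 0))
  # argmax ties resolve to the first class in (A, IA, ID, IS)
  expect_true(all(calls$subtype == "A"))
})

test_that("output biases shift probabilities per the softmax closed form", {
  model <- toy_model(matrix(0, 2, 2), b2 = c(log(2), 0, 0, 0), genes = c("g1", "g2"))
  calls <- predict_subtypes(model, toy_expr(matrix(1, 2, 1), genes = c("g1", "g2")))
  expect_equal(unlist(calls[1, c("p_A", "p_IA", "p_ID", "p_IS")], use.names = FALSE),
               c(0.4, 0.2, 0.2, 0.2), tolerance = 1e-12)
  expect_identical(as.character(calls$subtype), "A")
})

test_that("the forward pass matches a hand-computed tanh/softmax evaluation", {
  W1 <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2)
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(1, -1, 0.5, 0.25, -0.5, 2, 0, 1), 2, 4)
  b2 <- c(0.05, -0.05, 0.3, 0)
  model <- toy_model(W1, b1, W2, b2, genes = c("g1", "g2"))
  x <- c(g1 = 1.2, g2 = -0.7)
  calls <- predict_subtypes(model, toy_expr(matrix(x, 2, 1), genes = c("g1", "g2")))
  # independent scalar evaluation
  h <- tanh(c(sum(W1[, 1] * x) + b1[1], sum(W1[, 2] * x) + b1[2]))
  z <- as.vector(h %*% W2) + b2
  p <- exp(z) / sum(exp(z))
  expect_equal(unlist(calls[1, c("p_A", "p_IA", "p_ID", "p_IS")], use.names = FALSE),
               p, tolerance = 1e-9)
  expect_equal(c(calls$neuron1, calls$neuron2), h, tolerance = 1e-9)
  expect_equal(calls$max_probability, max(p))
})

test_that("the analytic gradient matches numerical differentiation", {
  set.seed(41)
  G <- 3; n <- 7
  X <- matrix(rnorm(n * G), n, G)
  y <- sample(c("A", "IA", "ID", "IS"), n, replace = TRUE)
  Y <- outer(y, c("A", "IA", "ID", "IS"), "==") * 1
  par <- rnorm(G * 2 + 2 + 8 + 4, sd = 0.5)
  g_an <- tmetyper:::mlp_grad(par, X, Y, l2 = 0.01)
  eps <- 1e-6
  g_num <- vapply(seq_along(par), function(i) {
    e <- rep(0, length(par)); e[i] <- eps
    (tmetyper:::mlp_loss(par + e, X, Y, 0.01) -
       tmetyper:::mlp_loss(par - e, X, Y, 0.01)) / (2 * eps)
  }, numeric(1))
  expect_equal(g_an, g_num, tolerance = 1e-6)
})

test_that("training is deterministic, reduces the loss, and validates labels", {
  fx <- trained_fixture(seed = 42)
  fx2 <- trained_fixture(seed = 42)
  expect_identical(fx$model$hidden_weights, fx2$model$hidden_weights)
  expect_identical(fx$model$output_weights, fx2$model$output_weights)
  expect_lt(fx$model$metadata$final_loss, fx$model$metadata$initial_loss)
  expect_true(fx$model$metadata$stopping_reason %in% c("patience", "max_iterations"))
  # a missing class is an error naming it
  three <- fx$labels
  three$subtype[three$subtype == "IS"] <- "IA"
  expect_error(train_model(fx$features, three, train_config(seed = 1)), "IS")
})

test_that("prediction is pure and rejects mismatched gene sets", {
  fx <- trained_fixture(seed = 42)
  c1 <- predict_subtypes(fx$model, fx$features)
  c2 <- predict_subtypes(fx$model, fx$features)
  expect_identical(c1, c2)
  probs <- as.matrix(c1[paste0("p_", c("A", "IA", "ID", "IS"))])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  expect_identical(as.character(c1$subtype),
                   c("A", "IA", "ID", "IS")[apply(probs, 1, which.max)])
  expect_true(all(abs(c1$neuron1) < 1) && all(abs(c1$neuron2) < 1))
  bad <- fx$features
  rownames(bad)[1] <- "intruder"
  expect_error(predict_subtypes(fx$model, bad), "intruder")
})

test_that("latent coordinates equal the hidden activations of prediction", {
  fx <- trained_fixture(seed = 42)
  lat <- latent_coordinates(fx$model, fx$features)
  calls <- predict_subtypes(fx$model, fx$features)
  expect_identical(lat$neuron1, calls$neuron1)
  expect_identical(lat$neuron2, calls$neuron2)
  # distance from the origin tracks call confidence
  d <- sqrt(calls$neuron1^2 + calls$neuron2^2)
  expect_gt(cor(d, calls$max_probability, method = "spearman"), 0.5)
})

test_that("model JSON round-trips to identical predictions", {
  fx <- trained_fixture(seed = 42)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fx$model, f)
  reloaded <- load_model(f)
  expect_equal(reloaded$hidden_weights, fx$model$hidden_weights, tolerance = 1e-15)
  p1 <- predict_subtypes(fx$model, fx$features)
  p2 <- predict_subtypes(reloaded, fx$features)
  expect_equal(as.matrix(p1[paste0("p_", c("A", "IA", "ID", "IS"))]),
               as.matrix(p2[paste0("p_", c("A", "IA", "ID", "IS"))]),
               tolerance = 1e-12)
  # the embedded reference also survives
  expect_equal(reloaded$reference$quantiles, fx$model$reference$quantiles)
  expect_identical(reloaded$metadata$seed, fx$model$metadata$seed)
})

test_that("classify_samples reproduces the manual normalize-then-predict path", {
  fx <- trained_fixture(seed = 42)
  direct <- classify_samples(fx$model, fx$sim$expression)
  manual <- predict_subtypes(fx$model, map_to_reference(fx$sim$expression, fx$ref))
  expect_identical(direct, manual)
})

test_that("stratified folds partition every class across folds", {
  y <- rep(c("A", "IA", "ID", "IS"), times = c(20, 15, 10, 5))
  set.seed(7)
  fold <- tmetyper:::stratified_folds(y, 5)
  expect_identical(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) >= floor(50 / 5)))
  for (cls in unique(y)) {
    expect_lte(diff(range(table(factor(fold[y == cls], levels = 1:5)))), 1)
  }
})

test_that("cross-validation returns a single-point grid unchanged and prefers
           lighter regularization when heavy shrinkage underfits", {
  sim <- simulate_cohort(sim_config(n_samples = 120, n_genes_per_axis = 8,
                                    n_noise_genes = 16, loading_effect = 3,
                                    seed = 51))
  lab <- label_cohort(sim$expression, sim$panel)
  ref <- fit_reference(sim$expression, sim$panel)
  feat <- map_to_reference(sim$expression, ref)
  one <- cross_validate(feat, lab,
                        train_config(seed = 51, cv_repeats = 1, cv_folds = 4,
                                     grid = data.frame(l2 = 0.01)))
  expect_equal(one$best$l2, 0.01)
  cv <- cross_validate(feat, lab,
                       train_config(seed = 51, cv_repeats = 1, cv_folds = 4,
                                    grid = data.frame(l2 = c(1e-3, 25))))
  expect_equal(cv$best$l2, 1e-3)
  expect_error(cross_validate(feat, lab, train_config(grid = data.frame())),
               "grid")
})

test_that("alignment reporting recovers a constructed axis structure", {
  genes <- sprintf("g%d", 1:8)
  panel <- gene_panel(genes, rep(c("immune", "angiogenesis"), each = 4))
  W1 <- cbind(ifelse(panel$axis == "immune", 1, -1),
              ifelse(panel$axis == "angiogenesis", -1, 1))
  model <- toy_model(W1, genes = genes)
  al <- neuron_axis_alignment(model, panel)
  expect_identical(unname(al$assignment["neuron1"]), "immune")
  expect_equal(al$alignment$sign_alignment[al$alignment$axis == "immune"], 1)
  # neuron2 reads the angiogenesis axis with inverted orientation; the
  # search flips it and reports a perfect contrast
  expect_identical(unname(al$orientation["neuron2"]), -1)
  expect_equal(al$alignment$sign_alignment[al$alignment$axis == "angiogenesis"], 1)
})
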