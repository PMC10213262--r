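test_that("the pooled reference is the sorted training values", {
  m <- toy_expr(matrix(c(1, 4, 2, 5, 6, 3), 2, 3), genes = c("a", "b"))
  panel <- gene_panel(c("a", "b"), c("immune", "angiogenesis"))
  ref <- fit_reference(m, panel)
  expect_identical(ref$quantiles, as.numeric(1:6))
  expect_identical(ref$gene_order, c("a", "b"))
})

test_that("per-gene scaling parameters match hand arithmetic on a toy matrix", {
  # genes a = (1,2,3), b = (4,5,6); within every sample a < b, so the
  # mapped value of a is always quantile(1:6, 0.25) = 2.25 and of b
  # quantile(1:6, 0.75) = 4.75 -> per-gene sd 0 -> rejected
  m <- toy_expr(matrix(c(1, 4, 2, 5, 3, 6), 2, 3), genes = c("a", "b"))
  panel <- gene_panel(c("a", "b"), c("immune", "angiogenesis"))
  expect_error(fit_reference(m, panel), "zero variance after reference mapping")
  # break the tie structure so ranks vary: swap ordering in sample 3
  m2 <- toy_expr(matrix(c(1, 4, 2, 5, 6, 3), 2, 3), genes = c("a", "b"))
  ref2 <- fit_reference(m2, panel)
  # hand-computed: plotting positions (0.25, 0.75) on pooled sorted 1..6
  lo <- 2.25; hi <- 4.75
  expect_equal(unname(ref2$mean["a"]), mean(c(lo, lo, hi)))
  expect_equal(unname(ref2$sd["a"]), sd(c(lo, lo, hi)))
  expect_equal(unname(ref2$mean["b"]), mean(c(hi, hi, lo)))
})

test_that("fitting demands panel genes present with variance", {
  m <- toy_expr(matrix(c(1, 4, 2, 5, 3, 6), 2, 3), genes = c("a", "b"))
  panel3 <- gene_panel(c("a", "b", "ghost"), c("immune", "angiogenesis", "immune"))
  expect_error(fit_reference(m, panel3), "ghost")
  m_const <- m; m_const["b", ] <- 7
  expect_error(fit_reference(m_const, gene_panel(c("a", "b"), c("immune", "angiogenesis"))),
               "b")
})

test_that("mapping the training data onto its own reference is near-identity", {
  sim <- simulate_cohort(sim_config(n_samples = 120, n_genes_per_axis = 10,
                                    n_noise_genes = 30, seed = 21))
  ref <- fit_reference(sim$expression, sim$panel)
  mapped <- map_to_reference(sim$expression, ref, zscale = FALSE)
  # within-sample ranks untouched
  for (j in c(1, 57, 120)) {
    expect_identical(rank(mapped[, j]), rank(sim$expression[, j]))
  }
  # quantile-domain distance between the mapped pool and the reference
  G <- nrow(sim$expression)
  pos <- (seq_len(G) - 0.5) / G
  ref_at <- quantile(ref$quantiles, probs = pos, names = FALSE)
  expect_lt(max(abs(apply(mapped, 2, sort) - ref_at)), 1e-6)
})

test_that("self-mapping leaves per-gene z-scores nearly unchanged at transcriptome scale", {
  # the per-sample map has rank resolution 1/G, so per-gene fidelity needs a
  # transcriptome-sized background, as in real data
  sim <- simulate_cohort(sim_config(n_samples = 120, n_genes_per_axis = 30,
                                    n_noise_genes = 1500, seed = 21))
  ref <- fit_reference(sim$expression, sim$panel)
  z_raw <- t(scale(t(sim$expression[ref$gene_order, ])))
  z_map <- map_to_reference(sim$expression, ref)
  expect_lt(sqrt(mean((z_map - z_raw)^2)), 0.1)
})

test_that("an affinely distorted copy maps back onto the reference", {
  sim <- simulate_cohort(sim_config(n_samples = 100, n_genes_per_axis = 10,
                                    n_noise_genes = 30, seed = 22))
  ref <- fit_reference(sim$expression, sim$panel)
  shifted <- 2 * sim$expression + 3
  mapped <- map_to_reference(shifted, ref, zscale = FALSE)
  ks <- suppressWarnings(ks.test(as.vector(mapped), ref$quantiles))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("mapping is monotone per sample and invariant to increasing transforms", {
  sim <- simulate_cohort(sim_config(n_samples = 30, n_genes_per_axis = 6,
                                    n_noise_genes = 10, seed = 23))
  ref <- fit_reference(sim$expression, sim$panel)
  new <- simulate_cohort(sim_config(n_samples = 25, n_genes_per_axis = 6,
                                    n_noise_genes = 10, seed = 24))$expression
  mapped_q <- map_to_reference(new, ref, zscale = FALSE)
  for (j in seq_len(ncol(new))) {
    ord <- order(new[, j])
    expect_true(all(diff(mapped_q[ord, j]) >= 0))
  }
  mapped <- map_to_reference(new, ref)
  # any strictly increasing transform of the input yields identical output
  expect_equal(map_to_reference(exp(new / 5), ref), mapped)
  expect_equal(map_to_reference(new^3, ref), mapped)
})

test_that("mapping reports missing panel genes by name", {
  sim <- simulate_cohort(sim_config(n_samples = 20, n_genes_per_axis = 4,
                                    n_noise_genes = 2, seed = 25))
  ref <- fit_reference(sim$expression, sim$panel)
  new <- sim$expression[rownames(sim$expression) != "IMM001", ]
  expect_error(map_to_reference(new, ref), "IMM001")
})
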