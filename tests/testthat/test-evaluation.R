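test_that("metrics from confusion counts reproduce the standard definitions", {
  m <- metrics_from_counts(tp = 11, fp = 21, fn = 2, tn = 39)
  r <- tidy(m, rounded = TRUE)
  expect_equal(r$accuracy, 0.68)
  expect_equal(r$f1, 0.49)
  expect_equal(r$sensitivity, 0.85)
  expect_equal(r$npv, 0.95)
  expect_equal(r$specificity, 0.65)
  expect_equal(r$ppv, 0.34)
  # unrounded fields stay exact fractions
  expect_equal(m$accuracy, 50 / 73)
  expect_equal(m$f1, 22 / 45)
  perfect <- tidy(metrics_from_counts(10, 0, 0, 10))
  expect_true(all(unlist(perfect[c("accuracy", "f1", "sensitivity",
                                   "specificity", "ppv", "npv")]) == 1))
})

test_that("comparator biomarker counts give their printed metrics", {
  pdl1 <- tidy(metrics_from_counts(12, 28, 1, 32), rounded = TRUE)
  expect_equal(pdl1$accuracy, 0.60)
  expect_equal(pdl1$sensitivity, 0.92)
  msi <- metrics_from_counts(5, 3, 8, 57)
  expect_equal(tidy(msi, rounded = TRUE)$accuracy, 0.85)
  expect_equal(msi$ppv, 5 / 8)
})

test_that("accuracy decomposes into class-conditional rates on random tables", {
  set.seed(71)
  for (i in 1:20) {
    cnt <- rmultinom(1, 60, rep(0.25, 4)) + 1
    m <- metrics_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    n_resp <- cnt[1] + cnt[3]; n_non <- cnt[2] + cnt[4]
    expect_equal(m$accuracy,
                 (m$sensitivity * n_resp + m$specificity * n_non) / m$n_evaluated)
    expect_equal(sum(m$counts), m$n_evaluated)
  }
})

test_that("confusion metrics exclude NE and demand both outcome classes", {
  cl <- suppressWarnings(toy_clinical(c("PR", "PD", "SD", "NE", "CR")))
  bm <- tibble::tibble(sample_id = cl$sample_id,
                       status = c("B+", "B+", "B-", "B+", "B-"))
  m <- confusion_metrics(bm, cl)
  expect_identical(m$n_excluded, 1L)
  expect_identical(m$n_evaluated, 4L)
  expect_error(confusion_metrics(bm, toy_clinical(rep("PD", 5))),
               "at least one responder")
})

test_that("rank-statistic AUROC equals brute-force pair counting", {
  brute <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(72)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), sample(0:2, 1)))  # coarse rounding forces ties
    expect_equal(auroc(s, y), brute(s, y), tolerance = 1e-12)
  }
  expect_equal(auroc(c(5, 4, 3, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_warning(a <- auroc(rep(2, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)))
  expect_equal(a, 0.5)
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.3, 0.7))
  y[1:2] <- c(TRUE, FALSE)
  s <- rnorm(40) + y
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("response-rate enrichment reproduces arm ratios", {
  mk <- function(tp, fp, fn, tn) {
    n <- tp + fp + fn + tn
    status <- c(rep("B+", tp + fp), rep("B-", fn + tn))
    bor <- c(rep("PR", tp), rep("PD", fp), rep("PR", fn), rep("PD", tn))
    list(bm = tibble::tibble(sample_id = sprintf("s%d", 1:n), status = status),
         cl = toy_clinical(bor))
  }
  g <- mk(11, 21, 2, 39)
  e <- orr_enrichment(g$bm, g$cl)
  expect_equal(e$orr_positive, 11 / 32)
  expect_equal(e$orr_negative, 2 / 41)
  expect_equal(round(2 * e$fold_enrichment) / 2, 7.0)
  ga <- mk(11, 11, 8, 18)
  expect_equal(tmetyper:::round_half_up(orr_enrichment(ga$bm, ga$cl)$fold_enrichment, 1), 1.6)
  eq <- mk(5, 5, 5, 5)
  expect_equal(orr_enrichment(eq$bm, eq$cl)$fold_enrichment, 1.0)
  none <- mk(3, 7, 0, 10)
  e0 <- orr_enrichment(none$bm, none$cl)
  expect_true(is.na(e0$fold_enrichment))
  expect_equal(e0$orr_positive, 0.3)
})

test_that("the analytic baseline satisfies its closed forms", {
  cl <- toy_clinical(c(rep("PR", 13), rep("PD", 60)))
  b <- baseline_null(cl, "analytic")
  p <- 13 / 73
  expect_equal(b$prevalence, p)
  expect_equal(b$sensitivity, p)
  expect_equal(b$ppv, p)
  expect_equal(b$f1, p)
  expect_equal(b$specificity, 1 - p)
  expect_equal(b$npv, 1 - p)
  expect_equal(b$accuracy, p^2 + (1 - p)^2)
  expect_equal(tmetyper:::round_half_up(b$specificity, 2), 0.82)
  even <- baseline_null(toy_clinical(c("PR", "PD")), "analytic")
  expect_equal(even$accuracy, 0.5)
  expect_error(baseline_null(toy_clinical(rep("PR", 4)), "analytic"), "prevalence")
})

test_that("Monte-Carlo baseline converges to the analytic closed forms", {
  cl <- toy_clinical(c(rep("PR", 13), rep("PD", 60)))
  an <- baseline_null(cl, "analytic")
  mc <- baseline_null(cl, "monte_carlo", reps = 20000, seed = 9)
  for (metric in c("accuracy", "sensitivity", "specificity", "npv")) {
    expect_lt(abs(mc[[metric]] - an[[metric]]), 0.01)
  }
  # PPV/F1 are ratio estimators: agreement within a few SE, not exact
  expect_lt(abs(mc$ppv - an$ppv), 0.02)
  # determinism under the seed
  mc2 <- baseline_null(cl, "monte_carlo", reps = 20000, seed = 9)
  expect_identical(mc, mc2)
})

test_that("subgroup metrics restrict and conserve the cohort", {
  cl <- toy_clinical(c(rep("PR", 5), rep("PD", 3), rep("PR", 2), rep("PD", 26)),
                     msi = c(rep("MSI-H", 8), rep("MSS", 28)))
  bm <- tibble::tibble(sample_id = cl$sample_id,
                       status = c(rep("B+", 5), rep("B-", 3), rep("B+", 6), rep("B-", 22)))
  sg <- subgroup_metrics(bm, cl, "msi")
  # constructed MSI-H arm: 5 responders of 8 -> ORR 62.5%
  msih <- sg[["MSI-H"]]
  expect_equal((msih$counts[["tp"]] + msih$counts[["fn"]]) / msih$n_evaluated, 0.625)
  expect_equal(sum(attr(sg, "sizes")), nrow(cl))
  # a single-level subgroup equals the unrestricted computation
  cl$all <- "yes"
  expect_equal(tidy(subgroup_metrics(bm, cl, "all")$yes), tidy(confusion_metrics(bm, cl)))
  expect_error(subgroup_metrics(bm, cl, "nope"), "nope")
})
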