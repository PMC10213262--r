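#' Confusion-matrix metrics of a binary biomarker against response
#'
#' Treats B+ as "predicted responder" and RECIST CR/PR as "actual
#' responder", then computes the standard metrics: accuracy, F1,
#' sensitivity (recall), specificity, PPV (precision), NPV, plus per-arm
#' objective response rates and their fold enrichment
#' `ORR(B+) / ORR(B-)`. Samples whose best response is NE (unevaluable) are
#' excluded and counted in `n_excluded`. All rates are stored as exact
#' fractions of the integer counts; rounding (half-up, 2 decimals for
#' rates, 1 for fold) happens only at presentation via [tidy()]/`print`.
#'
#' @param biomarker Tibble from [biomarker_call()] (or any data frame with
#'   `sample_id` and a `"B+"/"B-"` `status` column, or a logical `positive`
#'   column).
#' @param clinical Clinical tibble with `sample_id` and `responder`.
#' @return An object of class `tme_metrics`.
#' @export
confusion_metrics <- function(biomarker, clinical) {
  stopifnot("sample_id" %in% names(biomarker), "sample_id" %in% names(clinical))
  positive <- if ("status" %in% names(biomarker)) {
    biomarker$status == "B+"
  } else if ("positive" %in% names(biomarker)) {
    as.logical(biomarker$positive)
  } else {
    abort("biomarker needs a status (B+/B-) or logical positive column")
  }
  resp <- clinical$responder[match(biomarker$sample_id, clinical$sample_id)]
  if (anyNA(match(biomarker$sample_id, clinical$sample_id))) {
    abort("biomarker contains samples absent from the clinical table")
  }
  keep <- !is.na(resp)
  n_excluded <- sum(!keep)
  positive <- positive[keep]; resp <- resp[keep]
  if (!length(resp)) abort("no evaluable samples (all responses NE)")
  if (!any(resp) || all(resp)) {
    abort("need at least one responder and one non-responder after NE exclusion")
  }
  metrics_from_counts(tp = sum(positive & resp), fp = sum(positive & !resp),
                      fn = sum(!positive & resp), tn = sum(!positive & !resp),
                      n_excluded = n_excluded)
}

#' Metrics from explicit confusion counts
#'
#' @param tp,fp,fn,tn Integer counts (B+ responder, B+ non-responder,
#'   B- responder, B- non-responder).
#' @param n_excluded Count of NE samples excluded upstream.
#' @return An object of class `tme_metrics` with fields `counts`,
#'   `accuracy`, `f1`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `orr_positive`, `orr_negative`, `fold_enrichment` (NA when no B-
#'   responders exist), `n_evaluated`, `n_excluded`, and the rounding
#'   policy.
#' @export
metrics_from_counts <- function(tp, fp, fn, tn, n_excluded = 0L) {
  n <- tp + fp + fn + tn
  if (n == 0) abort("no evaluable samples")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  orr_pos <- rate(tp, tp + fp)
  orr_neg <- rate(fn, fn + tn)
  structure(list(
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
    accuracy = (tp + tn) / n,
    f1 = rate(2 * tp, 2 * tp + fp + fn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    orr_positive = orr_pos,
    orr_negative = orr_neg,
    fold_enrichment = if (!is.na(orr_neg) && orr_neg > 0) orr_pos / orr_neg else NA_real_,
    n_evaluated = as.integer(n),
    n_excluded = as.integer(n_excluded),
    rounding = list(rates_digits = 2, fold_digits = 1, mode = "half-up")
  ), class = "tme_metrics")
}

#' @method tidy tme_metrics
#' @export
tidy.tme_metrics <- function(x, rounded = FALSE, ...) {
  out <- tibble::tibble(
    tp = x$counts[["tp"]], fp = x$counts[["fp"]],
    fn = x$counts[["fn"]], tn = x$counts[["tn"]],
    accuracy = x$accuracy, f1 = x$f1, sensitivity = x$sensitivity,
    specificity = x$specificity, ppv = x$ppv, npv = x$npv,
    orr_positive = x$orr_positive, orr_negative = x$orr_negative,
    fold_enrichment = x$fold_enrichment,
    n_evaluated = x$n_evaluated, n_excluded = x$n_excluded
  )
  if (rounded) {
    rate_cols <- c("accuracy", "f1", "sensitivity", "specificity", "ppv",
                   "npv", "orr_positive", "orr_negative")
    out[rate_cols] <- lapply(out[rate_cols], round_half_up, digits = 2)
    out$fold_enrichment <- round_half_up(out$fold_enrichment, digits = 1)
  }
  out
}

#' @export
print.tme_metrics <- function(x, ...) {
  cat(sprintf("TME biomarker metrics (n = %d evaluable, %d NE excluded)\n",
              x$n_evaluated, x$n_excluded))
  cat(sprintf("  counts: TP %d  FP %d  FN %d  TN %d\n",
              x$counts[["tp"]], x$counts[["fp"]], x$counts[["fn"]], x$counts[["tn"]]))
  r2 <- function(v) formatC(round_half_up(v, 2), format = "f", digits = 2)
  cat(sprintf("  ACC %s  F1 %s  sens %s  spec %s  PPV %s  NPV %s\n",
              r2(x$accuracy), r2(x$f1), r2(x$sensitivity), r2(x$specificity),
              r2(x$ppv), r2(x$npv)))
  cat(sprintf("  ORR(B+) %s  ORR(B-) %s  enrichment %s-fold\n",
              r2(x$orr_positive), r2(x$orr_negative),
              if (is.na(x$fold_enrichment)) "NA" else
                formatC(round_half_up(x$fold_enrichment, 1), format = "f", digits = 1)))
  invisible(x)
}

#' AUROC by the Mann-Whitney rank statistic
#'
#' The probability that a randomly chosen responder outscores a randomly
#' chosen non-responder, ties counted one half — computed from midranks:
#' `AUROC = (sum of responder ranks - n1(n1+1)/2) / (n1 n0)`.
#'
#' @param scores Per-sample continuous score (higher = more
#'   responder-like); typically the biomarker `combined_probability`.
#' @param responder Logical vector aligned with `scores` (NA = NE,
#'   excluded).
#' @return AUROC in \[0, 1\]; all-tied scores return 0.5 with a warning.
#' @export
auroc <- function(scores, responder) {
  keep <- !is.na(responder) & !is.na(scores)
  scores <- scores[keep]; responder <- as.logical(responder[keep])
  n1 <- sum(responder); n0 <- sum(!responder)
  if (n1 == 0 || n0 == 0) abort("AUROC needs both responders and non-responders")
  if (length(unique(scores)) == 1) {
    warn("all scores identical; AUROC is 0.5 by convention")
    return(0.5)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[responder]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Objective response rates per biomarker arm
#'
#' @inheritParams confusion_metrics
#' @return Tibble: responders and totals per arm, `orr_positive`,
#'   `orr_negative`, `fold_enrichment` (NA when ORR(B-) is 0; the arm rates
#'   are still reported).
#' @export
orr_enrichment <- function(biomarker, clinical) {
  m <- confusion_metrics_relaxed(biomarker, clinical)
  tibble::tibble(
    n_positive = m$counts[["tp"]] + m$counts[["fp"]],
    responders_positive = m$counts[["tp"]],
    n_negative = m$counts[["fn"]] + m$counts[["tn"]],
    responders_negative = m$counts[["fn"]],
    orr_positive = m$orr_positive,
    orr_negative = m$orr_negative,
    fold_enrichment = m$fold_enrichment
  )
}

# like confusion_metrics but tolerates an all/none responder arm, since ORR
# per arm is still well-defined there
confusion_metrics_relaxed <- function(biomarker, clinical) {
  positive <- if ("status" %in% names(biomarker)) biomarker$status == "B+"
              else as.logical(biomarker$positive)
  resp <- clinical$responder[match(biomarker$sample_id, clinical$sample_id)]
  keep <- !is.na(resp)
  positive <- positive[keep]; resp <- resp[keep]
  if (!any(positive) || all(positive)) {
    abort("need at least one B+ and one B- evaluable sample")
  }
  metrics_from_counts(sum(positive & resp), sum(positive & !resp),
                      sum(!positive & resp), sum(!positive & !resp),
                      n_excluded = sum(!keep))
}

#' Prior-probability baseline (null) classifier
#'
#' The no-biomarker reference: a classifier that predicts "responder" with
#' probability equal to the cohort's responder prevalence p, independent of
#' the sample. In `analytic` mode the expected metrics have closed forms:
#' sensitivity = PPV = F1 = p, specificity = NPV = 1 - p, accuracy =
#' p^2 + (1-p)^2. In `monte_carlo` mode, `reps` random prediction vectors
#' are drawn and the metrics averaged (reps with an undefined PPV are
#' dropped from that metric's average).
#'
#' @param clinical Clinical tibble with `responder` (NE excluded).
#' @param mode `"analytic"` or `"monte_carlo"`.
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed Seed for the Monte-Carlo draws.
#' @return Tibble: `mode`, `prevalence`, `reps`, `seed`, `accuracy`, `f1`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
baseline_null <- function(clinical, mode = c("analytic", "monte_carlo"),
                          reps = 10000, seed = 1L) {
  mode <- match.arg(mode)
  resp <- clinical$responder[!is.na(clinical$responder)]
  n <- length(resp)
  p <- mean(resp)
  if (p <= 0 || p >= 1) abort("responder prevalence must be in (0, 1)")
  if (mode == "analytic") {
    return(tibble::tibble(mode = mode, prevalence = p, reps = NA_integer_,
                          seed = NA_integer_,
                          accuracy = p^2 + (1 - p)^2, f1 = p,
                          sensitivity = p, specificity = 1 - p,
                          ppv = p, npv = 1 - p))
  }
  # one reps x n prediction matrix; per-rep counts by row sums
  means <- with_sim_seed(seed, {
    pred <- matrix(stats::runif(reps * n) < p, nrow = reps)
    tp <- pred[, resp, drop = FALSE] |> rowSums()
    fp <- pred[, !resp, drop = FALSE] |> rowSums()
    fn <- sum(resp) - tp
    tn <- sum(!resp) - fp
    safe_mean <- function(num, den) mean(ifelse(den > 0, num / den, NA), na.rm = TRUE)
    tibble::tibble(
      accuracy = mean((tp + tn) / n),
      f1 = safe_mean(2 * tp, 2 * tp + fp + fn),
      sensitivity = mean(tp / sum(resp)),
      specificity = mean(tn / sum(!resp)),
      ppv = safe_mean(tp, tp + fp),
      npv = safe_mean(tn, tn + fn)
    )
  })
  dplyr::bind_cols(tibble::tibble(mode = mode, prevalence = p,
                                  reps = as.integer(reps), seed = as.integer(seed)),
                   means)
}

#' Biomarker metrics within clinical subgroups
#'
#' Recomputes [confusion_metrics()] restricted to each level of a clinical
#' grouping column (for example `msi`), reporting subgroup sizes.
#'
#' @inheritParams confusion_metrics
#' @param by Name of the clinical column to stratify on.
#' @return Named list of `tme_metrics`, one per subgroup level, with a
#'   `"sizes"` attribute (evaluable n per level).
#' @export
subgroup_metrics <- function(biomarker, clinical, by) {
  if (!by %in% names(clinical)) abort(sprintf("no column '%s' in clinical table", by))
  levels <- unique(stats::na.omit(clinical[[by]]))
  if (!length(levels)) abort("subgroup column is empty")
  out <- lapply(levels, function(lv) {
    sub <- clinical[!is.na(clinical[[by]]) & clinical[[by]] == lv, ]
    if (!nrow(sub)) abort(sprintf("empty subgroup: %s", lv))
    bm <- biomarker[biomarker$sample_id %in% sub$sample_id, , drop = FALSE]
    confusion_metrics_relaxed(bm, sub)
  })
  names(out) <- as.character(levels)
  attr(out, "sizes") <- vapply(out, function(m) m$n_evaluated, integer(1))
  out
}
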