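#' Define a mechanism-of-action biomarker rule
#'
#' A rule maps subtype probabilities to biomarker status. In `combined`
#' mode a sample is B+ when the summed probability of the positive subtypes
#' reaches `combined_threshold` (boundary inclusive: a combined probability
#' exactly at the threshold is B+, matching a signed score decision boundary
#' at 0). In `single_high` mode a sample is B+ when the probability of one
#' designated subtype reaches `single_high_threshold` (e.g. IA >= 0.90).
#'
#' @param name Rule name.
#' @param positive Character vector, a nonempty proper subset of
#'   `c("A","IA","ID","IS")` — the biomarker-positive subtypes.
#' @param combined_threshold Probability threshold for combined mode
#'   (default 0.5).
#' @param mode `"combined"` or `"single_high"`.
#' @param single_high_subtype,single_high_threshold The subtype and
#'   probability cutoff for `single_high` mode.
#' @return A list of class `biomarker_rule`.
#' @export
biomarker_rule <- function(name, positive, combined_threshold = 0.5,
                           mode = c("combined", "single_high"),
                           single_high_subtype = NULL,
                           single_high_threshold = 0.9) {
  mode <- match.arg(mode)
  bad <- setdiff(positive, TME_SUBTYPES)
  if (length(bad)) abort(sprintf("unknown subtype(s) in rule: %s", paste(bad, collapse = ", ")))
  if (length(positive) == 0 || length(positive) >= 4) {
    abort("positive subtypes must be a nonempty proper subset of the four subtypes")
  }
  if (combined_threshold <= 0 || combined_threshold >= 1) abort("combined_threshold must be in (0, 1)")
  if (mode == "single_high") {
    if (is.null(single_high_subtype) || !single_high_subtype %in% TME_SUBTYPES) {
      abort("single_high mode needs a valid single_high_subtype")
    }
    if (single_high_threshold <= 0 || single_high_threshold >= 1) {
      abort("single_high_threshold must be in (0, 1)")
    }
  }
  structure(list(name = name, positive = positive,
                 combined_threshold = combined_threshold, mode = mode,
                 single_high_subtype = single_high_subtype,
                 single_high_threshold = single_high_threshold),
            class = "biomarker_rule")
}

#' Standard mechanism-of-action rules
#'
#' The canonical therapy-class rules: anti-angiogenic agents target the
#' angiogenesis-high subtypes (A + IS); immune checkpoint inhibitors the
#' immune-high subtypes (IA + IS); TLR9-agonist combinations the immune
#' suppressed subtype (IS) alone.
#'
#' @param therapy One of `"anti-angio"`, `"immune"`, `"tlr9-combo"`.
#' @return A [biomarker_rule()].
#' @export
moa_rule <- function(therapy = c("anti-angio", "immune", "tlr9-combo")) {
  therapy <- match.arg(therapy)
  switch(therapy,
    "anti-angio" = biomarker_rule("anti-angio", c("A", "IS")),
    "immune" = biomarker_rule("immune", c("IA", "IS")),
    "tlr9-combo" = biomarker_rule("tlr9-combo", "IS")
  )
}

#' Apply a biomarker rule to subtype calls
#'
#' Computes each sample's combined probability over the rule's positive
#' subtypes, the signed biomarker score `2 x combined_probability - 1`
#' (so the B+/B- decision boundary sits at score 0 for a 0.5 threshold),
#' and the B+/B- status.
#'
#' @param calls Tibble from [predict_subtypes()].
#' @param rule A [biomarker_rule()].
#' @return Tibble: `sample_id`, `combined_probability`, `score`, `status`
#'   (`"B+"` / `"B-"`).
#' @export
biomarker_call <- function(calls, rule) {
  stopifnot(inherits(rule, "biomarker_rule"))
  prob_cols <- paste0("p_", TME_SUBTYPES)
  stopifnot(all(c("sample_id", prob_cols) %in% names(calls)))
  cp <- rowSums(as.matrix(calls[paste0("p_", rule$positive)]))
  status <- if (rule$mode == "combined") {
    cp >= rule$combined_threshold
  } else {
    calls[[paste0("p_", rule$single_high_subtype)]] >= rule$single_high_threshold
  }
  tibble::tibble(
    sample_id = calls$sample_id,
    combined_probability = cp,
    score = 2 * cp - 1,
    status = ifelse(status, "B+", "B-")
  )
}

#' Fraction of samples called with high confidence
#'
#' @param calls Tibble from [predict_subtypes()].
#' @param threshold Probability cutoff (default 0.8).
#' @return List: `fraction` (share of samples whose top subtype probability
#'   reaches the threshold), `by_subtype` (tibble with per-subtype counts
#'   and fractions), `threshold`, `n`.
#' @export
high_confidence_summary <- function(calls, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (nrow(calls) == 0) abort("no subtype calls supplied")
  hc <- calls$max_probability >= threshold
  by_sub <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(calls, high_confidence = hc), .data$subtype,
                    .drop = FALSE),
    n = dplyr::n(), n_high_confidence = sum(.data$high_confidence),
    fraction = ifelse(dplyr::n() > 0, mean(.data$high_confidence), NA_real_),
    .groups = "drop"
  )
  list(fraction = mean(hc), by_subtype = by_sub, threshold = threshold,
       n = nrow(calls))
}

#' Pre/post treatment subtype transition table
#'
#' Cross-tabulates matched pre- and post-treatment subtype calls. Every
#' `pair_id` in the clinical table must map to exactly one pre and one post
#' sample with calls available.
#'
#' @param pre_calls,post_calls Tibbles from [predict_subtypes()] for the
#'   pre- and post-treatment samples.
#' @param clinical Clinical tibble with `sample_id`, `pair_id`, `timepoint`.
#' @return A 4 x 4 integer matrix, rows = pre subtype, columns = post
#'   subtype; entries sum to the number of pairs.
#' @export
subtype_transitions <- function(pre_calls, post_calls, clinical) {
  if (!all(c("pair_id", "timepoint") %in% names(clinical))) {
    abort("clinical table needs pair_id and timepoint columns")
  }
  validate_pairing(clinical)
  paired <- clinical[!is.na(clinical$pair_id), ]
  pre_ids <- paired$sample_id[paired$timepoint == "pre"]
  post_ids <- paired$sample_id[paired$timepoint == "post"]
  miss_pre <- setdiff(pre_ids, pre_calls$sample_id)
  miss_post <- setdiff(post_ids, post_calls$sample_id)
  if (length(miss_pre) || length(miss_post)) {
    abort(sprintf("samples without subtype calls: %s",
                  paste(c(miss_pre, miss_post), collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(paired[, c("pair_id", "timepoint", "sample_id")],
                             names_from = "timepoint", values_from = "sample_id")
  pre_sub <- pre_calls$subtype[match(wide$pre, pre_calls$sample_id)]
  post_sub <- post_calls$subtype[match(wide$post, post_calls$sample_id)]
  table(pre = factor(pre_sub, levels = TME_SUBTYPES),
        post = factor(post_sub, levels = TME_SUBTYPES))
}
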