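#' Read a per-sample clinical table
#'
#' Expects a CSV with a `sample_id` column and a `bor` column (RECIST 1.1
#' best objective response: CR, PR, SD, PD, or NE). Optional columns:
#' `pdl1_cps` (nonnegative PD-L1 combined positive score), `msi` (MSI-H /
#' MSS / unknown), `pair_id` and `timepoint` (pre / post) for matched
#' longitudinal samples.
#'
#' Responders are CR or PR; SD and PD are non-responders. Unrecognized
#' response tokens are coerced to NE with a warning; NE samples carry
#' `responder = NA` and are excluded from response metrics downstream.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `sample_id`, `bor`, `responder`, plus any
#'   optional columns present.
#' @export
read_clinical_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  as_clinical(df)
}

#' Validate and normalize a clinical data frame
#'
#' @param df Data frame with at least `sample_id` and `bor`.
#' @return A validated tibble with a derived `responder` column.
#' @export
as_clinical <- function(df) {
  if (!"sample_id" %in% names(df)) abort("clinical table must have a sample_id column")
  if (!"bor" %in% names(df)) abort("clinical table must have a bor column")
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in clinical table")
  df <- tibble::as_tibble(df)
  bor <- toupper(trimws(as.character(df$bor)))
  known <- c("CR", "PR", "SD", "PD", "NE")
  unknown <- !(bor %in% known)
  if (any(unknown)) {
    warn(sprintf("%d unrecognized best-response token(s) coerced to NE: %s",
                 sum(unknown), paste(unique(df$bor[unknown]), collapse = ", ")))
    bor[unknown] <- "NE"
  }
  df$bor <- bor
  df$responder <- dplyr::case_when(
    bor %in% c("CR", "PR") ~ TRUE,
    bor %in% c("SD", "PD") ~ FALSE,
    TRUE ~ NA
  )
  if ("msi" %in% names(df)) {
    bad <- !(df$msi %in% c("MSI-H", "MSS", "unknown") | is.na(df$msi))
    if (any(bad)) abort(sprintf("unknown msi token(s): %s",
                                paste(unique(df$msi[bad]), collapse = ", ")))
  }
  if ("pdl1_cps" %in% names(df) && any(df$pdl1_cps < 0, na.rm = TRUE)) {
    abort("pdl1_cps must be nonnegative")
  }
  if ("pair_id" %in% names(df)) validate_pairing(df)
  df
}

validate_pairing <- function(df) {
  if (!"timepoint" %in% names(df)) abort("pair_id requires a timepoint column (pre/post)")
  paired <- df[!is.na(df$pair_id), ]
  if (!all(paired$timepoint %in% c("pre", "post"))) {
    abort("timepoint must be 'pre' or 'post' for paired samples")
  }
  counts <- dplyr::count(paired, .data$pair_id, .data$timepoint)
  bad <- dplyr::filter(dplyr::count(counts, .data$pair_id), .data$n != 2)
  bad2 <- dplyr::filter(counts, .data$n != 1)
  if (nrow(bad) || nrow(bad2)) {
    ids <- unique(c(bad$pair_id, bad2$pair_id))
    abort(sprintf("pair_id(s) without exactly one pre and one post sample: %s",
                  paste(ids, collapse = ", ")))
  }
  invisible(df)
}
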