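#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values are assumed to be on a
#' log scale (e.g. log2 RMA intensities or log2 CPM); set `log2_transform =
#' TRUE` for raw counts.
#'
#' Missing values (`NA` or empty cells) are handled by a fixed policy: a gene
#' with more than `max_missing` missing values (as a fraction of samples) is
#' dropped with a warning; remaining missing values are imputed with the
#' gene's observed median, since the downstream classifier requires complete
#' expression vectors.
#'
#' @param path Path to a TSV/CSV file (delimiter sniffed from the extension,
#'   override with `delim`).
#' @param delim Field delimiter; default `"\t"` for `.tsv`, `","` for `.csv`.
#' @param transpose If `TRUE` the file is samples x genes and is transposed
#'   on read.
#' @param log2_transform Apply `log2(x + 1)` after reading (for raw counts).
#' @param max_missing Maximum tolerated fraction of missing values per gene.
#' @return A numeric matrix, genes as rows, samples as columns.
#' @export
read_expression_matrix <- function(path, delim = NULL, transpose = FALSE,
                                   log2_transform = FALSE, max_missing = 0.2) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          na = c("", "NA"), progress = FALSE,
                          show_col_types = FALSE)
  if (ncol(df) < 2) abort("expression file needs an id column plus >= 1 sample column")
  ids <- as.character(df[[1]])
  vals <- df[-1]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    abort(sprintf("non-numeric expression column(s): %s",
                  paste(names(vals)[non_num], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("duplicate gene id(s): %s",
                  paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  }
  m <- apply_missing_policy(m, max_missing = max_missing)
  if (log2_transform) m <- log2(m + 1)
  inform(sprintf("read expression matrix: %d genes x %d samples", nrow(m), ncol(m)))
  assert_expression_matrix(m, "expression")
  m
}

apply_missing_policy <- function(m, max_missing = 0.2) {
  miss_frac <- rowMeans(is.na(m))
  drop <- miss_frac > max_missing
  if (any(drop)) {
    warn(sprintf("dropping %d gene(s) with > %.0f%% missing values: %s",
                 sum(drop), 100 * max_missing,
                 paste(utils::head(rownames(m)[drop], 5), collapse = ", ")))
    m <- m[!drop, , drop = FALSE]
  }
  if (anyNA(m)) {
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- med[idx[, 1]]
  }
  m
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]; round-trips values to within 1e-9
#' and preserves row/column order.
#'
#' @param x Numeric matrix, genes x samples.
#' @param path Output path (`.csv` writes comma-separated, else tab).
#' @export
write_expression_matrix <- function(x, path) {
  assert_expression_matrix(x)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tibble::as_tibble(x, rownames = "gene_id")
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}
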