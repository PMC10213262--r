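#' Construct a gene panel
#'
#' A gene panel is the classifier's feature set: gene identifiers annotated
#' with the biological axis they report on (`immune` or `angiogenesis`) and a
#' `weighted` flag. Weighted genes contribute to the population-dependent
#' axis scores used for training labels; unweighted genes are model features
#' only.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param axis Character vector, `"immune"` or `"angiogenesis"` per gene.
#' @param weighted Logical vector (recycled); default all `TRUE`.
#' @return A tibble with columns `gene_id`, `axis`, `weighted`.
#' @export
gene_panel <- function(gene_id, axis, weighted = TRUE) {
  panel <- tibble::tibble(
    gene_id = as.character(gene_id),
    axis = as.character(axis),
    weighted = rep_len(as.logical(weighted), length(gene_id))
  )
  assert_panel(panel)
  panel
}

#' Read a gene panel from JSON or YAML
#'
#' The file holds a list of entries, each with `gene_id`, `axis` and an
#' optional `weighted` flag (default true).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated panel tibble; axis counts are logged.
#' @export
read_gene_panel <- function(path) {
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.data.frame(entries)) {
    df <- entries
  } else {
    df <- purrr::map_dfr(entries, function(e) {
      tibble::tibble(gene_id = e$gene_id, axis = e$axis,
                     weighted = e$weighted %||% TRUE)
    })
  }
  if (!"weighted" %in% names(df)) df$weighted <- TRUE
  df$weighted[is.na(df$weighted)] <- TRUE
  panel <- gene_panel(df$gene_id, df$axis, df$weighted)
  cnt <- table(panel$axis)
  inform(sprintf("gene panel: %d genes (%s)", nrow(panel),
                 paste(sprintf("%s %d", names(cnt), cnt), collapse = ", ")))
  panel
}

#' Write a gene panel to YAML
#'
#' @param panel Panel tibble from [gene_panel()].
#' @param path Output path (`.yaml`).
#' @export
write_gene_panel <- function(panel, path) {
  assert_panel(panel)
  entries <- purrr::pmap(panel, function(gene_id, axis, weighted, ...) {
    list(gene_id = gene_id, axis = axis, weighted = weighted)
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
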