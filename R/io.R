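#' Read a gene-by-sample count or expression matrix from TSV
#'
#' The file must have a header row of sample labels and a first column of
#' gene identifiers. Comment lines starting with `#` are skipped (the writer
#' records the normalization state in such a line).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with a `gene_id` column followed by one numeric column
#'   per sample. The `normalization` attribute is restored from a
#'   `# normalization: <tag>` comment line when present.
#' @export
read_count_matrix <- function(path) {
  header <- readLines(path, n = 25L)
  tagline <- grep("^#\\s*normalization:", header, value = TRUE)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  m <- expr_to_matrix(x, basename(path))
  check_nonnegative(m, basename(path))
  if (length(tagline)) {
    x <- set_norm_tag(x, sub("^#\\s*normalization:\\s*", "", tagline[1]))
  }
  x
}

#' @rdname read_count_matrix
#' @export
read_expression_matrix <- read_count_matrix

#' Write an expression matrix as TSV with its normalization tag
#'
#' @param x Expression tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  writeLines(sprintf("# normalization: %s", norm_tag(x)), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read per-gene CDS lengths from a two-column TSV
#'
#' @param path TSV with columns gene_id and cds_length (header optional but
#'   recommended).
#' @return A tibble with columns `gene_id` and `cds_length`.
#' @export
read_cds_lengths <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2) abort("CDS-length file needs two columns: gene_id, cds_length.")
  out <- tibble(gene_id = as.character(x[[1]]), cds_length = as.numeric(x[[2]]))
  if (any(!is.finite(out$cds_length)) || any(out$cds_length <= 0)) {
    abort("All CDS lengths must be positive numbers.")
  }
  out
}

#' Read an isoform-to-gene map from a two-column TSV
#'
#' @param path TSV with columns isoform_id and gene_symbol.
#' @return A tibble with columns `isoform_id` and `gene_symbol`.
#' @export
read_isoform_map <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 2) abort("Isoform map needs two columns: isoform_id, gene_symbol.")
  tibble(isoform_id = as.character(x[[1]]), gene_symbol = as.character(x[[2]]))
}

#' Read a qPCR C_T plate from CSV or TSV
#'
#' Accepts either orientation: genes in rows (first column gene identifiers,
#' sample labels in the header) or samples in rows. Orientation is
#' auto-detected from the header: if the first header cell is `gene_id` (or
#' `gene`), rows are genes; otherwise rows are taken as samples and the
#' matrix is transposed so the returned tibble always has genes in rows.
#' Technical replicate wells (duplicated gene/sample labels) are aggregated
#' with `replicate_agg`.
#'
#' @param path CSV (`.csv`) or TSV file of threshold cycles.
#' @param replicate_agg How to aggregate replicate rows with the same label:
#'   `"mean"` (default) or `"median"`.
#' @return A C_T tibble: `gene_id` column plus one numeric column per sample.
#' @export
read_ct_matrix <- function(path, replicate_agg = c("mean", "median")) {
  replicate_agg <- match.arg(replicate_agg)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  x <- reader(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  first <- tolower(names(x)[1])
  genes_in_rows <- first %in% c("gene_id", "gene", "gene_symbol")
  agg <- match.fun(replicate_agg)
  x[[1]] <- as.character(x[[1]])
  if (anyDuplicated(x[[1]])) {
    x <- x |>
      dplyr::group_by(dplyr::across(1)) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), agg), .groups = "drop")
  }
  m <- expr_to_matrix(x, basename(path))
  if (!genes_in_rows) m <- t(m)
  if (anyNA(m)) abort(sprintf("Missing C_T values in %s are not allowed.", basename(path)))
  if (any(m <= 0)) abort(sprintf("Nonpositive C_T value in %s.", basename(path)))
  out <- matrix_to_tibble(m)
  set_norm_tag(out, "ct")
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path Text file; blank lines and `#` comments are ignored.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
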