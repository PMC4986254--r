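# Internal helpers shared across modules.
#
# An "expression table" throughout the package is a tibble whose first column
# (`gene_id`, character) identifies the gene and whose remaining columns are
# numeric per-sample values. The same layout is used for raw counts,
# normalized expression and qPCR C_T plates.

# Convert an expression tibble to a numeric matrix with gene_id rownames.
expr_to_matrix <- function(x, what = "expression table") {
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort(sprintf("`%s` must be a data frame with a gene_id column and at least one sample column.", what))
  }
  id <- as.character(x[[1]])
  if (anyDuplicated(id)) {
    abort(sprintf("Duplicate gene_id in %s: %s", what,
                  paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  vals <- x[-1]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("Non-numeric sample column(s) in %s: %s", what, paste(bad, collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- id
  m
}

matrix_to_tibble <- function(m, id_name = "gene_id") {
  ids <- rownames(m)
  vals <- m
  rownames(vals) <- NULL
  dplyr::bind_cols(tibble(!!id_name := ids),
                   as_tibble(vals, .name_repair = "minimal"))
}

# Normalization state travels as an attribute so writers can record it.
set_norm_tag <- function(x, tag) {
  attr(x, "normalization") <- tag
  x
}

norm_tag <- function(x) attr(x, "normalization") %||% "raw"

# cds_lengths may be a two-column data frame (gene_id, cds_length) or a
# named numeric vector; returns a named numeric vector.
as_length_vector <- function(cds_lengths) {
  if (is.data.frame(cds_lengths)) {
    if (ncol(cds_lengths) < 2) abort("`cds_lengths` data frame needs gene_id and cds_length columns.")
    v <- as.numeric(cds_lengths[[2]])
    names(v) <- as.character(cds_lengths[[1]])
  } else if (is.numeric(cds_lengths) && !is.null(names(cds_lengths))) {
    v <- cds_lengths
  } else {
    abort("`cds_lengths` must be a (gene_id, cds_length) data frame or a named numeric vector.")
  }
  if (anyDuplicated(names(v))) abort("Duplicate gene_id in `cds_lengths`.")
  v
}

check_nonnegative <- function(m, what) {
  if (anyNA(m)) abort(sprintf("Missing values are not allowed in %s.", what))
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Negative value in %s at gene %s, sample %s.",
                  what, rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  invisible(m)
}
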