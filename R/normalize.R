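#' Length- and depth-normalize a tag-count matrix
#'
#' Scales each count by the coding-sequence length of its gene and the
#' sequencing depth of its sample: the normalized value for gene g in sample
#' s is `1e9 * C[g,s] / (N[s] * L[g])`, where `C` is the raw tag count,
#' `N[s]` the total number of mappable tags in sample s, and `L[g]` the CDS
#' length in nucleotides. This is the tags-per-billion analogue of RPKM and
#' makes values comparable across genes of different lengths and libraries
#' of different depths.
#'
#' By default `N` is taken as the column totals of `counts`; when the matrix
#' is a gene subset of a larger experiment, pass the full-experiment totals
#' via `total_counts` so the depth term is not distorted by the subsetting.
#'
#' @param counts Count tibble: `gene_id` column plus numeric sample columns.
#'   Counts may be integers or non-negative reals (pre-normalized tags).
#' @param cds_lengths Per-gene CDS lengths: a (gene_id, cds_length) data
#'   frame (see [read_cds_lengths()]) or a named numeric vector.
#' @param total_counts Optional named numeric vector of per-sample mappable
#'   tag totals overriding the column sums.
#' @return An expression tibble of the same shape, with normalization
#'   attribute `"length_depth"`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("A", "B"), s1 = c(5, 15))
#' lens <- tibble::tibble(gene_id = c("A", "B"), cds_length = c(500, 1500))
#' normalize_length_depth(counts, lens)
#' @export
normalize_length_depth <- function(counts, cds_lengths, total_counts = NULL) {
  m <- expr_to_matrix(counts, "counts")
  check_nonnegative(m, "counts")
  L <- as_length_vector(cds_lengths)
  missing_len <- setdiff(rownames(m), names(L))
  if (length(missing_len)) {
    abort(sprintf("No CDS length for gene(s): %s", paste(missing_len, collapse = ", ")))
  }
  L <- L[rownames(m)]
  if (any(L <= 0)) {
    abort(sprintf("Nonpositive CDS length for gene(s): %s",
                  paste(rownames(m)[L <= 0], collapse = ", ")))
  }
  if (is.null(total_counts)) {
    N <- colSums(m)
  } else {
    missing_n <- setdiff(colnames(m), names(total_counts))
    if (length(missing_n)) {
      abort(sprintf("`total_counts` missing sample(s): %s", paste(missing_n, collapse = ", ")))
    }
    N <- as.numeric(total_counts[colnames(m)])
    names(N) <- colnames(m)
  }
  if (any(N <= 0)) {
    abort(sprintf("Sample(s) with zero total count: %s",
                  paste(colnames(m)[N <= 0], collapse = ", ")))
  }
  vals <- 1e9 * sweep(m / L, 2, N, "/")
  set_norm_tag(matrix_to_tibble(vals), "length_depth")
}

#' Collapse isoform counts onto one representative form per gene
#'
#' When tags were counted separately for several isoforms of the same gene,
#' the per-sample counts of the group are summed and allocated to the
#' isoform with the largest CDS, whose identifier and length are retained;
#' the other isoforms are dropped. Rows without a group assignment pass
#' through unchanged. This measures gene expression rather than isoform
#' expression.
#'
#' Equal maximal lengths within a group are resolved deterministically in
#' favour of the lexicographically smallest isoform identifier, with a
#' warning.
#'
#' @param counts Count tibble (`gene_id` holds isoform identifiers here).
#' @param isoform_groups An (isoform_id, gene_symbol) data frame (see
#'   [read_isoform_map()]) or a named character vector isoform -> gene.
#' @param cds_lengths Lengths for all isoforms, as in
#'   [normalize_length_depth()].
#' @return A list with elements `counts` (collapsed count tibble) and
#'   `cds_lengths` (tibble restricted to the retained rows).
#' @export
collapse_isoforms <- function(counts, isoform_groups, cds_lengths) {
  m <- expr_to_matrix(counts, "counts")
  check_nonnegative(m, "counts")
  L <- as_length_vector(cds_lengths)
  if (is.data.frame(isoform_groups)) {
    map <- setNames(as.character(isoform_groups[[2]]), as.character(isoform_groups[[1]]))
  } else if (is.character(isoform_groups) && !is.null(names(isoform_groups))) {
    map <- isoform_groups
  } else {
    abort("`isoform_groups` must be an (isoform_id, gene_symbol) data frame or named character vector.")
  }
  map <- map[names(map) %in% rownames(m)]
  if (!length(map)) abort("`isoform_groups` matches no row of `counts`.")
  missing_len <- setdiff(names(map), names(L))
  if (length(missing_len)) {
    abort(sprintf("No CDS length for isoform(s): %s", paste(missing_len, collapse = ", ")))
  }

  grouped <- split(names(map), unname(map))
  drop <- character(0)
  for (members in grouped) {
    members <- sort(members)            # lexicographic tie-break
    lens <- L[members]
    keep <- members[which.max(lens)]    # which.max takes the first, i.e. smallest id
    if (sum(lens == max(lens)) > 1) {
      warn(sprintf("Isoforms %s tie for largest CDS; keeping %s.",
                   paste(members[lens == max(lens)], collapse = ", "), keep))
    }
    if (length(members) > 1) {
      m[keep, ] <- colSums(m[members, , drop = FALSE])
      drop <- c(drop, setdiff(members, keep))
    }
  }
  m <- m[setdiff(rownames(m), drop), , drop = FALSE]
  list(
    counts = matrix_to_tibble(m),
    cds_lengths = tibble(gene_id = rownames(m),
                         cds_length = unname(L[rownames(m)]))
  )
}

#' Quantile-normalize an expression matrix
#'
#' Classic quantile normalization: each sample column is sorted, the mean of
#' each rank across samples is computed, and every value is replaced by the
#' rank-mean corresponding to its rank within its own column. Tied values
#' within a column receive the mean of the rank-means their positions span.
#' After the transform every sample shares the same value distribution
#' (identical column multisets), which makes independently generated
#' expression profiles directly comparable.
#'
#' @param x Expression tibble (`gene_id` + at least two sample columns).
#' @return Expression tibble with normalization attribute `"quantile"`.
#' @export
quantile_normalize <- function(x) {
  m <- expr_to_matrix(x, "expression")
  if (ncol(m) < 2) abort("Quantile normalization needs at least 2 samples.")
  if (anyNA(m)) abort("Missing values are not allowed in `x`.")
  rank_means <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    assigned <- numeric(length(col))
    assigned[order(col)] <- rank_means
    # ties within the column share the mean of the rank-means they span
    stats::ave(assigned, col, FUN = mean)
  })
  rownames(out) <- rownames(m)
  set_norm_tag(matrix_to_tibble(out), "quantile")
}
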