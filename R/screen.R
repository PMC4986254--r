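#' Proportion of samples in which a gene is not expressed
#'
#' The 0's proportion of a gene is the fraction of samples in which it shows
#' no expression. A value of 0 means the gene is expressed everywhere; 1
#' means it is expressed nowhere. "Not expressed" means a value of exactly 0
#' by default; a positive `min_expr` turns the rule into a detection floor
#' (values at or below the floor count as not expressed).
#'
#' @param values Non-negative per-sample expression vector.
#' @param min_expr Detection floor; default 0.
#' @return Fraction in \[0, 1\].
#' @examples
#' zeros_proportion(c(0, 3, 5, 0, 1, 2, 9, 4)) # 0.25
#' @export
zeros_proportion <- function(values, min_expr = 0) {
  if (!length(values)) abort("`values` must be non-empty.")
  if (anyNA(values)) abort("`values` must not contain NA.")
  if (any(values < 0)) abort("`values` must be non-negative.")
  mean(values <= min_expr)
}

#' Coefficient of variation, in percent
#'
#' The ratio of the sample standard deviation (denominator n - 1) to the
#' mean, times 100. The package's primary expression-stability statistic:
#' stably expressed genes have low CV.
#'
#' @param values Numeric vector, length >= 2, with non-zero mean.
#' @return CV as a percentage.
#' @examples
#' coefficient_of_variation(c(18.51, 16.45, 20.48, 15.66, 18.29)) # ~10.58
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) abort("CV needs at least 2 values.")
  if (anyNA(values)) abort("`values` must not contain NA.")
  mu <- mean(values)
  if (mu == 0) abort("CV is undefined for a zero-mean vector.")
  100 * sd(values) / mu
}

#' Score every gene for expression breadth and stability
#'
#' Computes, per gene: mean, standard deviation (n - 1), CV%, 0's
#' proportion, and eligibility for the housekeeping-gene candidate list.
#' A gene is eligible when it is expressed in every sample
#' (`zeros_proportion == 0`) and its CV is defined. Genes with zero mean
#' have an undefined CV (`NA`) and are marked excluded.
#'
#' @param x Expression tibble (`gene_id` + >= 2 numeric sample columns).
#' @param min_expr Detection floor passed to [zeros_proportion()].
#' @return A tibble with columns `gene_id`, `n_samples`, `mean`, `sd`,
#'   `cv_percent`, `zeros_proportion`, `eligible`, `exclusion_reason`.
#' @export
screen_genes <- function(x, min_expr = 0) {
  m <- expr_to_matrix(x, "expression")
  check_nonnegative(m, "expression")
  if (ncol(m) < 2) abort("Screening needs at least 2 samples.")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  zp <- apply(m, 1, zeros_proportion, min_expr = min_expr)
  cv <- ifelse(mu > 0, 100 * s / mu, NA_real_)
  reason <- dplyr::case_when(
    mu == 0        ~ "not expressed in any sample",
    zp > 0         ~ "zero expression in some samples",
    .default = NA_character_
  )
  tibble(
    gene_id = rownames(m),
    n_samples = ncol(m),
    mean = unname(mu),
    sd = unname(s),
    cv_percent = unname(cv),
    zeros_proportion = unname(zp),
    eligible = is.na(reason),
    exclusion_reason = reason
  )
}

#' Select the k most stably expressed candidate reference genes
#'
#' Among genes expressed in every sample, returns the `k` with the lowest
#' CV%, in ascending CV order (ties broken lexicographically by gene
#' identifier). Every dropped gene is recorded in the exclusion log with its
#' reason. If fewer than `k` genes are eligible, all eligible genes are
#' returned with a warning.
#'
#' @param stats A screen-statistics tibble from [screen_genes()].
#' @param k Number of candidates to keep (>= 1).
#' @return An object of class `hkg_candidates`: a list with elements
#'   `candidates` (ranked tibble of selected genes), `excluded` (gene_id +
#'   reason), `k`, and `n_eligible`. Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @export
select_candidates <- function(stats, k) {
  required <- c("gene_id", "cv_percent", "zeros_proportion", "eligible")
  if (!all(required %in% names(stats))) {
    abort("`stats` must come from screen_genes() (missing required columns).")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k)) {
    abort("`k` must be a single integer >= 1.")
  }
  eligible <- dplyr::filter(stats, .data$eligible)
  ranked <- dplyr::arrange(eligible, .data$cv_percent, .data$gene_id)
  if (nrow(ranked) < k) {
    warn(sprintf("Only %d eligible genes for k = %d; returning all of them.", nrow(ranked), k))
  }
  selected <- head(ranked, k)
  excluded <- dplyr::bind_rows(
    stats |>
      dplyr::filter(!.data$eligible) |>
      dplyr::select("gene_id", reason = "exclusion_reason"),
    ranked |>
      dplyr::slice(-seq_len(min(k, nrow(ranked)))) |>
      dplyr::transmute(.data$gene_id, reason = "CV rank above k")
  )
  structure(
    list(candidates = selected, excluded = excluded,
         k = as.integer(k), n_eligible = nrow(ranked)),
    class = "hkg_candidates"
  )
}

#' @export
print.hkg_candidates <- function(x, ...) {
  cat(sprintf("Housekeeping-gene candidate set: %d of %d eligible genes (k = %d)\n",
              nrow(x$candidates), x$n_eligible, x$k))
  print(x$candidates, ...)
  cat(sprintf("%d genes excluded; see $excluded for reasons.\n", nrow(x$excluded)))
  invisible(x)
}

#' @rdname select_candidates
#' @param x,object An `hkg_candidates` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hkg_candidates <- function(x, ...) {
  dplyr::mutate(x$candidates, rank = dplyr::row_number(), .before = 1)
}

#' @rdname select_candidates
#' @exportS3Method generics::glance
glance.hkg_candidates <- function(x, ...) {
  tibble(
    k = x$k,
    n_selected = nrow(x$candidates),
    n_eligible = x$n_eligible,
    n_excluded = nrow(x$excluded),
    mean_cv = mean(x$candidates$cv_percent),
    max_cv = max(x$candidates$cv_percent)
  )
}

#' @rdname select_candidates
#' @exportS3Method ggplot2::autoplot
autoplot.hkg_candidates <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$cv_percent),
    y = .data$cv_percent
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Coefficient of variation (%)",
                  title = "Candidate reference genes by expression stability") +
    ggplot2::theme_minimal()
}

#' Summarize a reference-gene panel's expression level and stability
#'
#' Unweighted arithmetic means of the per-gene expression means and
#' per-gene CV% values of a panel, plus the range of the means. Used to
#' contrast a novel candidate panel with a traditional housekeeping panel.
#'
#' @param stats Per-gene statistics tibble with columns `gene_id`, `mean`
#'   and `cv_percent` (e.g. from [screen_genes()]).
#' @param genes Optional character vector restricting the panel; default all
#'   rows of `stats`.
#' @return One-row tibble: `n_genes`, `mean_of_means`, `min_mean`,
#'   `max_mean`, `mean_of_cvs`.
#' @export
panel_summary <- function(stats, genes = NULL) {
  if (!all(c("gene_id", "mean", "cv_percent") %in% names(stats))) {
    abort("`stats` needs columns gene_id, mean and cv_percent.")
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, stats$gene_id)
    if (length(missing)) {
      abort(sprintf("Panel gene(s) absent from `stats`: %s", paste(missing, collapse = ", ")))
    }
    stats <- dplyr::filter(stats, .data$gene_id %in% genes)
  }
  if (!nrow(stats)) abort("Empty panel.")
  tibble(
    n_genes = nrow(stats),
    mean_of_means = mean(stats$mean),
    min_mean = min(stats$mean),
    max_mean = max(stats$mean),
    mean_of_cvs = mean(stats$cv_percent)
  )
}
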