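# Cohort-wide validation of reference-gene panels: persistence of
# expression across every sample of a large cohort, and per-gene
# distribution statistics mirroring a clinical summary table.

#' Is a gene expressed in every sample of a cohort?
#'
#' @param x Expression tibble (`gene_id` + numeric sample columns).
#' @param min_expr Detection floor: a gene counts as expressed in a sample
#'   when its value is strictly above `min_expr` (default 0).
#' @return Tibble: `gene_id`, `expressed_in_all`.
#' @export
expressed_in_all <- function(x, min_expr = 0) {
  m <- expr_to_matrix(x, "expression")
  if (!length(m)) abort("Empty expression matrix.")
  check_nonnegative(m, "expression")
  tibble(
    gene_id = rownames(m),
    expressed_in_all = unname(apply(m, 1, function(v) all(v > min_expr)))
  )
}

#' Per-gene distribution statistics over a cohort
#'
#' Order statistics (minimum, lower quartile, median, upper quartile,
#' maximum, by linear interpolation between order statistics), mean, sample
#' standard deviation (n - 1) and CV% for every gene of a cohort expression
#' matrix, plus the [expressed_in_all()] flag.
#'
#' @param x Expression tibble with at least 4 samples.
#' @param min_expr Detection floor for `expressed_in_all`.
#' @return Tibble: `gene_id`, `n_samples`, `min`, `q25`, `median`, `q75`,
#'   `max`, `mean`, `sd`, `cv_percent`, `expressed_in_all`. `cv_percent` is
#'   NA for all-zero genes.
#' @export
cohort_stats <- function(x, min_expr = 0) {
  m <- expr_to_matrix(x, "expression")
  check_nonnegative(m, "expression")
  if (ncol(m) < 4) abort("Cohort statistics need at least 4 samples (quartiles).")
  q <- t(apply(m, 1, quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
               type = 7, names = FALSE))
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  tibble(
    gene_id = rownames(m),
    n_samples = ncol(m),
    min = unname(q[, 1]), q25 = unname(q[, 2]), median = unname(q[, 3]),
    q75 = unname(q[, 4]), max = unname(q[, 5]),
    mean = unname(mu),
    sd = unname(s),
    cv_percent = unname(ifelse(mu > 0, 100 * s / mu, NA_real_)),
    expressed_in_all = unname(apply(m, 1, function(v) all(v > min_expr)))
  )
}

#' Compare the expression stability of two gene panels
#'
#' Unweighted mean of the per-gene CV% values of each panel and their
#' ratio. A ratio well above 1 means panel B is that many times more
#' variable than panel A across the cohort.
#'
#' @param stats Per-gene statistics with columns `gene_id` and `cv_percent`
#'   (from [cohort_stats()] or [screen_genes()]).
#' @param panel_a,panel_b Disjoint, non-empty character vectors of gene
#'   symbols present in `stats`.
#' @return One-row tibble: `mean_cv_a`, `mean_cv_b`, `ratio_b_over_a`.
#' @export
compare_panels <- function(stats, panel_a, panel_b) {
  if (!length(panel_a) || !length(panel_b)) abort("Panels must be non-empty.")
  if (length(intersect(panel_a, panel_b))) abort("Panels must be disjoint.")
  missing <- setdiff(c(panel_a, panel_b), stats$gene_id)
  if (length(missing)) {
    abort(sprintf("Panel gene(s) absent from `stats`: %s", paste(missing, collapse = ", ")))
  }
  cv_a <- stats$cv_percent[match(panel_a, stats$gene_id)]
  cv_b <- stats$cv_percent[match(panel_b, stats$gene_id)]
  tibble(
    mean_cv_a = mean(cv_a),
    mean_cv_b = mean(cv_b),
    ratio_b_over_a = mean(cv_b) / mean(cv_a)
  )
}
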