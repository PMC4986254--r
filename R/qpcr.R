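# Comparative-C_T stability analysis of reference-gene panels.
#
# C_T plates use the same tibble layout as expression matrices: gene_id
# column plus one numeric column of threshold cycles per sample. C_T is
# inversely related to transcript abundance, so expression comparisons use
# the 1/C_T transform while stability summaries work on raw C_T.

#' Convert a C_T plate to the 1/C_T expression scale
#'
#' @param ct C_T tibble (`gene_id` + positive numeric sample columns).
#' @return Expression tibble of reciprocal threshold cycles, normalization
#'   attribute `"reciprocal_ct"`.
#' @export
reciprocal_ct <- function(ct) {
  m <- expr_to_matrix(ct, "C_T matrix")
  if (anyNA(m)) abort("Missing C_T values are not allowed.")
  if (any(m <= 0)) {
    idx <- which(m <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Nonpositive C_T for gene %s, sample %s.",
                  rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  set_norm_tag(matrix_to_tibble(1 / m), "reciprocal_ct")
}

#' Per-gene threshold-cycle summaries
#'
#' For each gene: minimum, maximum, mean, sample standard deviation
#' (n - 1) and CV% of its C_T values across samples. Low C_T variation
#' across samples is the qPCR counterpart of low expression CV.
#'
#' @param ct C_T tibble with at least 2 sample columns.
#' @return Tibble: `gene_id`, `n_samples`, `min`, `max`, `mean`, `sd`,
#'   `cv_percent`.
#' @export
gene_ct_summary <- function(ct) {
  m <- expr_to_matrix(ct, "C_T matrix")
  if (ncol(m) < 2) abort("C_T summaries need at least 2 samples.")
  if (anyNA(m)) abort("Missing C_T values are not allowed.")
  tibble(
    gene_id = rownames(m),
    n_samples = ncol(m),
    min = unname(apply(m, 1, min)),
    max = unname(apply(m, 1, max)),
    mean = unname(rowMeans(m)),
    sd = unname(apply(m, 1, sd)),
    cv_percent = unname(apply(m, 1, coefficient_of_variation))
  )
}

#' Panel-level C_T aggregates
#'
#' The unweighted mean over all (gene, sample) C_T entries of a panel,
#' plus two dispersion readings whose definitions differ in what they
#' treat as the unit: `sd_gene_means` is the SD of the per-gene mean
#' C_T values, `sd_pooled` the SD of all individual entries (both n - 1).
#'
#' @param ct C_T tibble.
#' @param panel Character vector of panel gene symbols, all present in `ct`.
#' @return One-row tibble: `n_genes`, `n_values`, `mean_ct`,
#'   `sd_gene_means`, `sd_pooled`, `mean_inv_ct`.
#' @export
panel_mean_ct <- function(ct, panel) {
  if (!length(panel)) abort("Empty panel.")
  m <- expr_to_matrix(ct, "C_T matrix")
  missing <- setdiff(panel, rownames(m))
  if (length(missing)) {
    abort(sprintf("Panel gene(s) absent from the plate: %s", paste(missing, collapse = ", ")))
  }
  sub <- m[panel, , drop = FALSE]
  tibble(
    n_genes = length(panel),
    n_values = length(sub),
    mean_ct = mean(sub),
    sd_gene_means = if (length(panel) > 1) sd(rowMeans(sub)) else NA_real_,
    sd_pooled = sd(as.vector(sub)),
    mean_inv_ct = mean(1 / sub)
  )
}

#' Leave-one-out panel correlation
#'
#' For each gene of a panel, the Pearson correlation between its C_T
#' profile across samples and the per-sample mean C_T of the remaining
#' genes. Values near 1 indicate that each gene tracks the panel consensus,
#' i.e. the genes are interchangeable as internal controls.
#'
#' @param ct C_T tibble with >= 3 genes and >= 3 samples.
#' @return Tibble: `gene_id`, `r` (NA with a message when either vector has
#'   zero variance).
#' @export
loo_correlation <- function(ct) {
  m <- expr_to_matrix(ct, "C_T matrix")
  if (nrow(m) < 3) abort("Leave-one-out correlation needs at least 3 genes.")
  if (ncol(m) < 3) abort("Leave-one-out correlation needs at least 3 samples.")
  r <- vapply(rownames(m), function(gene) {
    own <- m[gene, ]
    rest <- colMeans(m[setdiff(rownames(m), gene), , drop = FALSE])
    if (sd(own) == 0 || sd(rest) == 0) {
      inform(sprintf("r undefined for %s (zero variance).", gene))
      return(NA_real_)
    }
    cor(own, rest)
  }, numeric(1))
  tibble(gene_id = rownames(m), r = unname(r))
}

#' Cross-platform concordance of RNA-seq and qPCR expression
#'
#' Fits the log-log relationship between per-gene mean normalized RNA-seq
#' expression and per-gene mean 1/C_T from qPCR, and reports the Pearson
#' correlation of the log10 values together with the least-squares line
#' (log10 RNA-seq as response, log10 qPCR as predictor) for extrapolating
#' results from one platform to the other. The correlation is invariant to
#' the log base; slope and intercept are on the base-10 scale.
#'
#' @param data Data frame with one row per gene.
#' @param rnaseq,qpcr Columns of `data` (tidy-eval) holding the positive
#'   per-gene RNA-seq means and qPCR mean 1/C_T values.
#' @return An object of class `cross_platform_fit` with elements `r`,
#'   `slope`, `intercept`, `n_genes`, `data` (log10 pairs) and `fit` (the
#'   underlying `lm`). Supports [tidy()], [glance()], [autoplot()].
#' @export
cross_platform_correlation <- function(data, rnaseq = rnaseq_mean, qpcr = qpcr_mean) {
  x <- dplyr::pull(data, {{ qpcr }})
  y <- dplyr::pull(data, {{ rnaseq }})
  if (length(x) < 3) abort("Need at least 3 genes.")
  if (any(x <= 0) || any(y <= 0)) abort("All expression values must be positive for the log-log fit.")
  d <- tibble(log10_qpcr = log10(x), log10_rnaseq = log10(y))
  fit <- lm(log10_rnaseq ~ log10_qpcr, data = d)
  structure(
    list(
      r = cor(d$log10_qpcr, d$log10_rnaseq),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      n_genes = nrow(d),
      data = d,
      fit = fit
    ),
    class = "cross_platform_fit"
  )
}

#' @export
print.cross_platform_fit <- function(x, ...) {
  cat(sprintf("Cross-platform concordance over %d genes: r = %.3f\n", x$n_genes, x$r))
  cat(sprintf("log10(RNA-seq) = %.3f + %.3f * log10(1/C_T)\n", x$intercept, x$slope))
  invisible(x)
}

#' @rdname cross_platform_correlation
#' @param x,object A `cross_platform_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cross_platform_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    std_error = unname(s[, 2])
  )
}

#' @rdname cross_platform_correlation
#' @exportS3Method generics::glance
glance.cross_platform_fit <- function(x, ...) {
  tibble(r = x$r, r_squared = x$r^2, slope = x$slope,
         intercept = x$intercept, n_genes = x$n_genes)
}

#' @rdname cross_platform_correlation
#' @exportS3Method ggplot2::autoplot
autoplot.cross_platform_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_qpcr, y = .data$log10_rnaseq)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2, color = "grey40") +
    ggplot2::labs(
      x = "log10 mean 1/C_T (qPCR)", y = "log10 mean expression (RNA-seq)",
      title = sprintf("Cross-platform concordance (r = %.3f)", object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Primer amplification efficiency from a dilution series
#'
#' Fits the standard curve C_T ~ log10(relative input) over a cDNA dilution
#' series (e.g. 1:100, 1:200, 1:400, 1:800) and converts its slope to an
#' amplification efficiency with the standard-curve convention
#' `E = 10^(-1/slope) - 1`; a perfectly doubling reaction has slope
#' -3.3219 and efficiency 1 (100%).
#'
#' @param dilutions Relative input amounts (> 0), at least 3 distinct
#'   values, e.g. `c(1/100, 1/200, 1/400, 1/800)`.
#' @param cts Matching observed C_T values.
#' @return One-row tibble: `slope`, `intercept`, `efficiency`, `r_squared`.
#' @export
primer_efficiency <- function(dilutions, cts) {
  if (length(dilutions) != length(cts)) abort("`dilutions` and `cts` must have equal length.")
  if (length(unique(dilutions)) < 3) abort("Need at least 3 distinct dilution points.")
  if (any(dilutions <= 0)) abort("Dilutions must be positive relative input amounts.")
  fit <- lm(cts ~ log10(dilutions))
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("Non-amplifying series: C_T does not decrease with input.")
  tibble(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    efficiency = 10^(-1 / slope) - 1,
    r_squared = 1 - sum(stats::residuals(fit)^2) / sum((cts - mean(cts))^2)
  )
}
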