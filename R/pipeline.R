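# End-to-end reference-gene identification pipeline: composition of the
# normalization, screening, network-filter and validation stages. The
# pipeline adds no computation of its own; every stage is an exported
# function that can be run on its own.

#' Assemble and validate a pipeline configuration
#'
#' @param counts Path to the count-matrix TSV (required).
#' @param cds_lengths Path to the gene_id/cds_length TSV (required).
#' @param k Number of candidate genes to select (>= 1).
#' @param isoform_map,edges,ct,cohort Optional paths: isoform-to-gene map,
#'   interactome edge list, qPCR C_T plate (CSV/TSV), cohort expression
#'   matrix.
#' @param tfs Transcription-factor names (character vector) or a path to a
#'   one-per-line list; used only when `edges` is given.
#' @param tf_aliases Optional YAML alias map path; defaults to the packaged
#'   map.
#' @param reference_panel Traditional reference-gene symbols (character
#'   vector or path).
#' @param min_expr Detection floor for the breadth screen.
#' @param qnorm Apply quantile normalization after length/depth
#'   normalization (default TRUE).
#' @param total_counts Optional named per-sample tag totals (see
#'   [normalize_length_depth()]).
#' @param replicate_agg Replicate aggregation for the C_T reader.
#' @param out_dir Optional directory for per-stage TSV outputs.
#' @return A validated list of class `hkg_run_config`.
#' @export
run_config <- function(counts, cds_lengths, k = 10,
                       isoform_map = NULL, edges = NULL, ct = NULL,
                       cohort = NULL, tfs = NULL, tf_aliases = NULL,
                       reference_panel = character(0),
                       min_expr = 0, qnorm = TRUE, total_counts = NULL,
                       replicate_agg = "mean", out_dir = NULL) {
  cfg <- as.list(environment())
  problems <- character(0)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k)) {
    problems <- c(problems, "k must be a single integer >= 1")
  }
  for (field in c("counts", "cds_lengths", "isoform_map", "edges", "ct", "cohort")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p)) {
      problems <- c(problems, sprintf("%s path does not exist: %s", field, p))
    }
  }
  if (length(problems)) {
    abort(paste0("Invalid pipeline config:\n", paste("-", problems, collapse = "\n")))
  }
  if (is.character(cfg$tfs) && length(cfg$tfs) == 1 && file.exists(cfg$tfs)) {
    cfg$tfs <- read_gene_list(cfg$tfs)
  }
  if (is.character(cfg$reference_panel) && length(cfg$reference_panel) == 1 &&
      file.exists(cfg$reference_panel)) {
    cfg$reference_panel <- read_gene_list(cfg$reference_panel)
  }
  structure(cfg, class = "hkg_run_config")
}

# Run one stage, rethrowing errors labelled with the stage name.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full reference-gene identification pipeline
#'
#' Executes normalize -> screen -> select -> network-filter ->
#' (optional) qPCR validation -> (optional) cohort validation and returns a
#' run report. When `out_dir` is configured, each stage also writes its
#' table as TSV. Re-running with the same config and inputs reproduces the
#' outputs exactly: every stage is deterministic.
#'
#' @param cfg An [run_config()] object, or a path to a YAML file with the
#'   same fields.
#' @return A list report: `expression` (normalized matrix),
#'   `screen_stats`, `candidates` ([select_candidates()] object),
#'   `coregulation` (tibble or NULL), `retained_panel` (character),
#'   `ct_summary`, `loo`, `panel_ct`, `cohort_stats`, `panel_comparison`
#'   (NULL when the stage was not configured).
#' @export
run_hkg_pipeline <- function(cfg) {
  if (is.character(cfg)) {
    cfg <- do.call(run_config, yaml::read_yaml(cfg))
  }
  stopifnot(inherits(cfg, "hkg_run_config"))
  out <- function(name, x) {
    if (!is.null(cfg$out_dir)) {
      if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
      readr::write_tsv(x, file.path(cfg$out_dir, paste0(name, ".tsv")), progress = FALSE)
    }
    x
  }

  counts <- run_stage("read", read_count_matrix(cfg$counts))
  lengths <- run_stage("read", read_cds_lengths(cfg$cds_lengths))
  if (!is.null(cfg$isoform_map)) {
    collapsed <- run_stage("collapse_isoforms",
                           collapse_isoforms(counts, read_isoform_map(cfg$isoform_map), lengths))
    counts <- collapsed$counts
    lengths <- collapsed$cds_lengths
  }
  expr <- run_stage("normalize",
                    normalize_length_depth(counts, lengths, total_counts = cfg$total_counts))
  if (isTRUE(cfg$qnorm)) expr <- run_stage("quantile_normalize", quantile_normalize(expr))
  out("expression", expr)

  stats <- run_stage("screen", screen_genes(expr, min_expr = cfg$min_expr))
  out("screen_stats", stats)
  candidates <- run_stage("select", select_candidates(stats, cfg$k))
  out("candidates", tidy(candidates))

  coreg <- NULL
  retained <- candidates$candidates$gene_id
  if (!is.null(cfg$edges)) {
    if (is.null(cfg$tfs)) abort("Pipeline stage 'network_filter' failed: `tfs` is required when `edges` is given.")
    g <- run_stage("network_filter", read_edge_list(cfg$edges))
    aliases <- if (is.null(cfg$tf_aliases)) default_tf_aliases() else read_tf_aliases(cfg$tf_aliases)
    coreg <- run_stage("network_filter",
                       flag_coregulated(candidates$candidates$gene_id,
                                        cfg$reference_panel, cfg$tfs, g, aliases))
    out("coregulation", coreg)
    retained <- coreg$gene_id[coreg$retained]
  }

  ct_summary <- loo <- panel_ct <- NULL
  if (!is.null(cfg$ct)) {
    plate <- run_stage("qpcr", read_ct_matrix(cfg$ct, replicate_agg = cfg$replicate_agg))
    ct_summary <- out("ct_summary", run_stage("qpcr", gene_ct_summary(plate)))
    if (nrow(plate) >= 3 && ncol(plate) >= 4) {
      loo <- out("loo_correlation", run_stage("qpcr", loo_correlation(plate)))
    }
    on_plate <- intersect(retained, plate$gene_id)
    if (length(on_plate)) {
      panel_ct <- out("panel_ct", run_stage("qpcr", panel_mean_ct(plate, on_plate)))
    }
  }

  cstats <- comparison <- NULL
  if (!is.null(cfg$cohort)) {
    cm <- run_stage("cohort", read_expression_matrix(cfg$cohort))
    cstats <- out("cohort_stats", run_stage("cohort", cohort_stats(cm, min_expr = cfg$min_expr)))
    ref <- intersect(cfg$reference_panel, cstats$gene_id)
    ret <- setdiff(intersect(retained, cstats$gene_id), ref)
    if (length(ref) && length(ret)) {
      comparison <- out("panel_comparison",
                        run_stage("cohort", compare_panels(cstats, ret, ref)))
    }
  }

  report <- list(
    expression = expr, screen_stats = stats, candidates = candidates,
    coregulation = coreg, retained_panel = retained,
    ct_summary = ct_summary, loo = loo, panel_ct = panel_ct,
    cohort_stats = cstats, panel_comparison = comparison
  )
  if (!is.null(cfg$out_dir)) {
    out("retained_panel", tibble(gene_id = retained))
  }
  report
}
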