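# Seeded synthetic-data generators with planted ground truth.
#
# The generators emulate the statistical structure the screening strategy
# assumes: a minority of stably expressed genes (low negative-binomial
# overdispersion), a majority of variable genes, a fraction of genes with
# structural zeros in some samples, a log-linear qPCR C_T response to
# expression, and an interactome dominated by transcription-factor hubs.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the emulated study conditions: 8 samples (one per cell
#' line), 200 genes of which 5% are planted as stable, negative-binomial
#' dispersions 0.005 (stable) vs 0.25 (variable), per-gene mean log2
#' expression uniform on \[6, 12\] (so overdispersion, not Poisson shot
#' noise, dominates each gene's CV and the stable/variable labels are
#' reflected in realized variability), 10% zero-inflated genes with per-sample
#' dropout probability 0.3, a C_T response of 40 - 1.6 * log2(expression)
#' cycles with 0.2 cycles of Gaussian noise, and a 100-node interactome
#' with 3 TF hubs of degree 10 over a 1% background edge density.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param seed Global seed; each generator derives its own substream from it
#'   so matrices, plates and interactomes are independently reproducible.
#' @param fraction_stable Fraction of genes planted as stable.
#' @param stable_dispersion,variable_dispersion Negative-binomial
#'   overdispersion (`1/size`); realized CV ~ `sqrt(1/mu + dispersion)`.
#' @param mean_log2_expr_range Range of per-gene mean log2 expression.
#' @param zero_gene_fraction Fraction of genes given structural zeros.
#' @param zero_prob Per-sample dropout probability for those genes.
#' @param ct_intercept,ct_slope,ct_noise_sd C_T model: cycles at log2
#'   expression 0, cycles lost per log2 unit, Gaussian noise SD (cycles).
#' @param cds_length_range CDS length range (nt), sampled uniformly.
#' @param net_n_nodes,net_n_tf_hubs,net_hub_degree,net_background_edge_prob
#'   Interactome size, number of TF hub nodes, edges per hub, and background
#'   edge probability for non-hub pairs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_samples = 8, seed = 1,
                       fraction_stable = 0.05,
                       stable_dispersion = 0.005, variable_dispersion = 0.25,
                       mean_log2_expr_range = c(6, 12),
                       zero_gene_fraction = 0.1, zero_prob = 0.3,
                       ct_intercept = 40, ct_slope = 1.6, ct_noise_sd = 0.2,
                       cds_length_range = c(300, 3000),
                       net_n_nodes = 100, net_n_tf_hubs = 3,
                       net_hub_degree = 10, net_background_edge_prob = 0.01) {
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_genes >= 2 && n_samples >= 2, "n_genes and n_samples must be >= 2")
  chk(fraction_stable >= 0 && fraction_stable <= 1, "fraction_stable must be in [0, 1]")
  chk(zero_gene_fraction >= 0 && zero_gene_fraction <= 1, "zero_gene_fraction must be in [0, 1]")
  chk(zero_prob >= 0 && zero_prob <= 1, "zero_prob must be in [0, 1]")
  chk(stable_dispersion > 0 && variable_dispersion > 0, "dispersions must be > 0")
  chk(length(mean_log2_expr_range) == 2 && diff(mean_log2_expr_range) >= 0,
      "mean_log2_expr_range must be an increasing pair")
  chk(ct_slope > 0, "ct_slope must be > 0")
  chk(ct_noise_sd >= 0, "ct_noise_sd must be >= 0")
  chk(length(cds_length_range) == 2 && all(cds_length_range > 0),
      "cds_length_range must be two positive lengths")
  chk(net_hub_degree < net_n_nodes, "net_hub_degree must be < net_n_nodes")
  chk(net_n_tf_hubs >= 0 && net_n_tf_hubs < net_n_nodes, "net_n_tf_hubs must be < net_n_nodes")
  chk(net_background_edge_prob >= 0 && net_background_edge_prob <= 1,
      "net_background_edge_prob must be in [0, 1]")
  if (length(problems)) {
    abort(paste0("Invalid simulation config:\n", paste("-", problems, collapse = "\n")))
  }
  structure(cfg, class = "sim_config")
}

# Derive a reproducible substream seed (< 2^31) from the global seed.
substream <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k) %% 2147483629)

#' Simulate a tag-count matrix with planted stable genes
#'
#' Counts are drawn gene-wise from a negative binomial with a per-gene mean
#' (log2-uniform over the configured range) and a label-specific
#' overdispersion, so stable genes have a low CV independent of their mean.
#' Zero-inflated genes additionally have each sample value zeroed with the
#' configured dropout probability. CDS lengths are uniform over the
#' configured range. Identical config and seed give identical output.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (count tibble), `cds_lengths` (tibble) and
#'   `truth` (tibble: `gene_id`, `label` in {stable, variable,
#'   zero_inflated}, `true_mean`, `dispersion`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(substream(cfg$seed, 1), {
    n <- cfg$n_genes
    genes <- sprintf("G%04d", seq_len(n))
    n_stable <- round(cfg$fraction_stable * n)
    n_zero <- round(cfg$zero_gene_fraction * n)
    if (n_stable + n_zero > n) abort("fraction_stable + zero_gene_fraction exceed 1.")
    label <- rep("variable", n)
    label[seq_len(n_stable)] <- "stable"
    if (n_zero > 0) label[n_stable + seq_len(n_zero)] <- "zero_inflated"
    mu <- 2^runif(n, cfg$mean_log2_expr_range[1], cfg$mean_log2_expr_range[2])
    disp <- ifelse(label == "stable", cfg$stable_dispersion, cfg$variable_dispersion)
    m <- t(vapply(seq_len(n), function(i) {
      v <- rnbinom(cfg$n_samples, mu = mu[i], size = 1 / disp[i])
      if (label[i] == "zero_inflated") {
        v <- v * (runif(cfg$n_samples) >= cfg$zero_prob)
      }
      as.numeric(v)
    }, numeric(cfg$n_samples)))
    rownames(m) <- genes
    colnames(m) <- sprintf("S%02d", seq_len(cfg$n_samples))
    lens <- round(runif(n, cfg$cds_length_range[1], cfg$cds_length_range[2]))
    list(
      counts = matrix_to_tibble(m),
      cds_lengths = tibble(gene_id = genes, cds_length = lens),
      truth = tibble(gene_id = genes, label = label,
                     true_mean = mu, dispersion = disp)
    )
  })
}

#' Simulate a qPCR C_T plate from an expression matrix
#'
#' Threshold cycles follow the standard log-linear qPCR response:
#' `ct = intercept - slope * log2(expression) + Normal(0, noise_sd)`,
#' truncated to stay positive. With the default slope of 1.6 cycles per
#' log2 unit, a doubling of expression lowers C_T by 1.6 cycles.
#'
#' @param expr Expression tibble with strictly positive values.
#' @param cfg A [sim_config()] (fields `ct_intercept`, `ct_slope`,
#'   `ct_noise_sd`, `seed`).
#' @return C_T tibble of the same shape as `expr`.
#' @export
simulate_ct <- function(expr, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- expr_to_matrix(expr, "expression")
  if (any(m <= 0)) abort("C_T simulation needs strictly positive expression values.")
  withr::with_seed(substream(cfg$seed, 2), {
    ct <- cfg$ct_intercept - cfg$ct_slope * log2(m) +
      rnorm(length(m), sd = cfg$ct_noise_sd)
    ct <- pmax(ct, .Machine$double.eps)
    set_norm_tag(matrix_to_tibble(ct), "ct")
  })
}

#' Simulate an interactome with transcription-factor hubs
#'
#' Each of the `net_n_tf_hubs` hub nodes is wired to `net_hub_degree`
#' distinct non-hub partners; every remaining unordered node pair receives
#' an edge independently with probability `net_background_edge_prob`. The
#' result is undirected and duplicate-free.
#'
#' @param cfg A [sim_config()].
#' @return List with `edges` (tibble `from`, `to`), `graph` (igraph) and
#'   `truth` (tibble: `node`, `role` in {tf_hub, other}).
#' @export
simulate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(substream(cfg$seed, 3), {
    n <- cfg$net_n_nodes
    n_hub <- cfg$net_n_tf_hubs
    hubs <- if (n_hub > 0) sprintf("TF%02d", seq_len(n_hub)) else character(0)
    others <- sprintf("N%03d", seq_len(n - n_hub))
    nodes <- c(hubs, others)
    hub_edges <- purrr::map(hubs, function(h) {
      tibble(from = h, to = sample(others, cfg$net_hub_degree))
    })
    pairs <- utils::combn(others, 2)
    keep <- runif(ncol(pairs)) < cfg$net_background_edge_prob
    bg_edges <- tibble(from = pairs[1, keep], to = pairs[2, keep])
    edges <- dplyr::bind_rows(hub_edges, bg_edges)
    g <- interaction_graph(edges, nodes = nodes)
    list(
      edges = edges,
      graph = g,
      truth = tibble(node = nodes,
                     role = ifelse(nodes %in% hubs, "tf_hub", "other"))
    )
  })
}

#' Write a full synthetic dataset to a directory
#'
#' Generates counts, CDS lengths, a C_T plate (from the length/depth
#' normalized expression of the non-zero genes), an interactome edge list
#' and the ground-truth labels, and writes them as plain-text files
#' (`counts.tsv`, `cds.tsv`, `ct.csv`, `edges.tsv`, `truth.tsv`).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_counts(cfg)
  readr::write_tsv(sim$counts, file.path(dir, "counts.tsv"), progress = FALSE)
  readr::write_tsv(sim$cds_lengths, file.path(dir, "cds.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  expr <- normalize_length_depth(sim$counts, sim$cds_lengths)
  m <- expr_to_matrix(expr, "expression")
  pos <- rownames(m)[apply(m, 1, function(v) all(v > 0))]
  ct <- simulate_ct(expr[expr$gene_id %in% pos, ], cfg)
  readr::write_csv(ct, file.path(dir, "ct.csv"), progress = FALSE)
  net <- simulate_interactome(cfg)
  readr::write_tsv(net$edges, file.path(dir, "edges.tsv"), col_names = FALSE,
                   progress = FALSE)
  invisible(dir)
}
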