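# Independent brute-force oracles and small fixture builders.

# Build an expression tibble from a named matrix.
expr_tbl <- function(m) {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m))
}

tbl_mat <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x[[1]]
  m
}

# Loop-based quantile normalization: sort each column, average across
# columns at each rank, reassign by rank; ties share the mean of the
# rank-means they span.
oracle_quantile_normalize <- function(m) {
  n <- nrow(m); k <- ncol(m)
  rank_means <- numeric(n)
  for (i in seq_len(n)) {
    at_rank <- numeric(k)
    for (j in seq_len(k)) at_rank[j] <- sort(m[, j])[i]
    rank_means[i] <- mean(at_rank)
  }
  out <- m
  for (j in seq_len(k)) {
    col <- m[, j]
    assigned <- numeric(n)
    assigned[order(col)] <- rank_means
    for (v in unique(col)) {
      idx <- which(col == v)
      assigned[idx] <- mean(assigned[idx])
    }
    out[, j] <- assigned
  }
  out
}

# Linear-interpolation quantile between order statistics.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Neighbor count from a raw edge data frame (either orientation, with
# possible duplicates).
oracle_degree <- function(edges, node) {
  nb <- c(edges$to[edges$from == node], edges$from[edges$to == node])
  length(unique(nb[nb != node]))
}

# The bundled five-cell-line plates.
plate_2dp <- function() example_ct_plate()
plate_precise <- function() example_ct_plate(precise = TRUE)
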