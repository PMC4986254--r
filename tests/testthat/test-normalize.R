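test_that("length/depth normalization applies 1e9*C/(N*L) with N from column totals", {
  # single gene, explicit totals: 1e9 * 10 / (1e6 * 1000) = 10
  x <- expr_tbl(matrix(10, 1, 1, dimnames = list("g1", "s1")))
  lens <- tibble::tibble(gene_id = "g1", cds_length = 1000)
  out <- normalize_length_depth(x, lens, total_counts = c(s1 = 1e6))
  expect_equal(out$s1, 10)

  # zero count stays zero regardless of N and L
  x2 <- expr_tbl(matrix(c(0, 7), 2, 1, dimnames = list(c("a", "b"), "s1")))
  l2 <- tibble::tibble(gene_id = c("a", "b"), cds_length = c(100, 700))
  expect_equal(normalize_length_depth(x2, l2)$s1[1], 0)

  # one sample, two genes, N = 20 from the column total: both 5e5
  x3 <- expr_tbl(matrix(c(5, 15), 2, 1, dimnames = list(c("a", "b"), "s1")))
  l3 <- tibble::tibble(gene_id = c("a", "b"), cds_length = c(500, 1500))
  out3 <- normalize_length_depth(x3, l3)
  expect_equal(out3$s1, c(5e5, 5e5))
  expect_identical(attr(out3, "normalization"), "length_depth")
})

test_that("length/depth normalization is invariant to rescaling one sample", {
  set.seed(11)
  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  lens <- tibble::tibble(gene_id = rownames(m), cds_length = sample(200:2000, 10))
  base <- normalize_length_depth(expr_tbl(m), lens)
  m2 <- m; m2[, 2] <- m2[, 2] * 7
  scaled <- normalize_length_depth(expr_tbl(m2), lens)
  expect_equal(scaled$s2, base$s2)
})

test_that("length/depth normalization errors name the offending sample or gene", {
  x <- expr_tbl(matrix(c(0, 0, 3, 4), 2, 2,
                       dimnames = list(c("a", "b"), c("empty", "ok"))))
  lens <- tibble::tibble(gene_id = c("a", "b"), cds_length = c(100, 100))
  expect_error(normalize_length_depth(x, lens), "empty")
  expect_error(
    normalize_length_depth(x, tibble::tibble(gene_id = "a", cds_length = 100)),
    "b"
  )
})

test_that("isoform collapsing sums group counts onto the longest form", {
  m <- matrix(c(4, 6, 9), 3, 1, dimnames = list(c("A1", "A2", "U"), "s1"))
  lens <- tibble::tibble(gene_id = c("A1", "A2", "U"), cds_length = c(300, 900, 100))
  map <- tibble::tibble(isoform_id = c("A1", "A2"), gene_symbol = c("A", "A"))
  out <- collapse_isoforms(expr_tbl(m), map, lens)
  expect_setequal(out$counts$gene_id, c("A2", "U"))
  expect_equal(out$counts$s1[out$counts$gene_id == "A2"], 10)
  expect_equal(out$cds_lengths$cds_length[out$cds_lengths$gene_id == "A2"], 900)
  # ungrouped gene untouched
  expect_equal(out$counts$s1[out$counts$gene_id == "U"], 9)

  # three-isoform group: middle-length loser, longest keeps the sum
  m3 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("B1", "B2", "B3"), "s1"))
  l3 <- tibble::tibble(gene_id = c("B1", "B2", "B3"), cds_length = c(200, 600, 400))
  out3 <- collapse_isoforms(expr_tbl(m3), c(B1 = "B", B2 = "B", B3 = "B"), l3)
  expect_identical(out3$counts$gene_id, "B2")
  expect_equal(out3$counts$s1, 6)
})

test_that("isoform collapsing conserves group totals and breaks length ties lexicographically", {
  set.seed(21)
  m <- matrix(rpois(12, 20), 6, 2,
              dimnames = list(paste0("I", 1:6), c("s1", "s2")))
  lens <- tibble::tibble(gene_id = rownames(m), cds_length = c(500, 500, 300, 800, 200, 900))
  map <- c(I1 = "X", I2 = "X", I3 = "X", I4 = "Y", I5 = "Y")
  expect_warning(out <- collapse_isoforms(expr_tbl(m), map, lens), "tie")
  # tie between I1 and I2 (both 500): lexicographically smallest wins... but
  # I3 is shorter, so the group max is the tied pair and I1 is kept
  expect_true("I1" %in% out$counts$gene_id)
  expect_false(any(c("I2", "I3") %in% out$counts$gene_id))
  expect_equal(out$counts$s1[out$counts$gene_id == "I1"], sum(m[c("I1", "I2", "I3"), "s1"]))
  expect_equal(out$counts$s2[out$counts$gene_id == "I4"], sum(m[c("I4", "I5"), "s2"]))
  # single-isoform "group" passes through
  single <- collapse_isoforms(expr_tbl(m), c(I6 = "Z"), lens)
  expect_equal(tbl_mat(single$counts), m)
})

test_that("quantile normalization matches the hand-rolled rank-mean procedure", {
  x <- expr_tbl(matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                       dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  out <- quantile_normalize(x)
  expect_equal(out$s1, c(2.5, 3.5, 4.5))
  expect_equal(out$s2, c(2.5, 3.5, 4.5))
  expect_identical(attr(out, "normalization"), "quantile")

  # random matrices against the independent oracle, including ties
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:10, 1); k <- sample(2:5, 1)
    m <- matrix(sample(0:5, n * k, replace = TRUE) + round(runif(n * k), 2),
                n, k, dimnames = list(paste0("g", 1:n), paste0("s", 1:k)))
    expect_equal(tbl_mat(quantile_normalize(expr_tbl(m))),
                 oracle_quantile_normalize(m), tolerance = 1e-12)
  }
})

test_that("quantile normalization equalizes columns, is idempotent and rank-preserving", {
  set.seed(41)
  m <- matrix(rexp(60, 0.1), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  q1 <- quantile_normalize(expr_tbl(m))
  mm <- tbl_mat(q1)
  # identical sorted multiset in every column, hence equal column means
  for (j in 2:5) expect_equal(unname(sort(mm[, j])), unname(sort(mm[, 1])))
  expect_equal(unname(colMeans(mm)), rep(mean(colMeans(apply(m, 2, sort))), 5))
  # rank order within columns preserved
  for (j in 1:5) expect_equal(order(mm[, j]), order(m[, j]))
  # idempotent
  expect_equal(tbl_mat(quantile_normalize(q1)), mm, tolerance = 1e-12)
  # a matrix whose columns already share one multiset is a fixed point
  fp <- matrix(c(1, 5, 9, 9, 1, 5), 3, 2,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(tbl_mat(quantile_normalize(expr_tbl(fp))), fp)
  expect_error(quantile_normalize(expr_tbl(m[, 1, drop = FALSE])), "2 samples")
})

test_that("quantile normalization agrees with limma's reference implementation", {
  skip_if_not_installed("limma")
  set.seed(51)
  m <- matrix(rexp(200, 0.05), 40, 5,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  ours <- tbl_mat(quantile_normalize(expr_tbl(m)))
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("matrices round-trip through the TSV reader/writer with their tag", {
  set.seed(61)
  m <- matrix(rpois(20, 30), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  lens <- tibble::tibble(gene_id = rownames(m), cds_length = rep(500, 5))
  expr <- normalize_length_depth(expr_tbl(m), lens)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(expr, path)
  back <- read_expression_matrix(path)
  expect_equal(tbl_mat(back), tbl_mat(expr))
  expect_identical(attr(back, "normalization"), "length_depth")
})
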