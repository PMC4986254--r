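test_that("reciprocal C_T transform inverts cycles elementwise", {
  m <- matrix(c(25, 20, 30, 10), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- reciprocal_ct(expr_tbl(m))
  expect_equal(tbl_mat(out), 1 / m)
  expect_equal(out$s1, c(1 / 25, 1 / 20))
  # monotone-decreasing cycles become monotone-increasing expression
  row <- expr_tbl(matrix(c(30, 25, 20), 1, 3, dimnames = list("g", paste0("s", 1:3))))
  expect_false(is.unsorted(as.numeric(unlist(reciprocal_ct(row)[1, -1]))))
  bad <- expr_tbl(matrix(c(25, 0), 1, 2, dimnames = list("g1", c("s1", "s2"))))
  expect_error(reciprocal_ct(bad), "g1.*s2")
})

test_that("per-gene C_T summaries report min/max/mean/sd/CV across samples", {
  plate <- plate_2dp()
  s <- gene_ct_summary(plate)
  gapdh <- s[s$gene_id == "GAPDH", ]
  expect_equal(gapdh$mean, 17.88, tolerance = 0.005 / 17.88)
  expect_equal(gapdh$sd, 1.892, tolerance = 0.002 / 1.892)
  expect_equal(gapdh$cv_percent, 10.58, tolerance = 0.005 / 10.58)
  ank <- s[s$gene_id == "ANKRD17", ]
  expect_equal(ank$mean, 28.72, tolerance = 0.01 / 28.72)
  expect_equal(ank$cv_percent, 6.66, tolerance = 0.01 / 6.66)
  # min/max come from the observed values
  expect_equal(gapdh$min, 15.66)
  expect_equal(gapdh$max, 20.48)
  # a constant gene degenerates cleanly
  const <- expr_tbl(matrix(22, 1, 4, dimnames = list("k", paste0("s", 1:4))))
  cs <- gene_ct_summary(const)
  expect_equal(cs$sd, 0)
  expect_equal(cs$cv_percent, 0)
  expect_equal(cs$min, cs$mean)
  expect_equal(cs$max, cs$mean)
  # shared CV definition with the screen module
  expect_equal(s$cv_percent[1],
               coefficient_of_variation(as.numeric(unlist(plate[1, -1]))))
})

test_that("panel C_T aggregates average all entries of the panel", {
  plate <- plate_2dp()
  one <- panel_mean_ct(plate, "GAPDH")
  expect_equal(one$mean_ct, mean(as.numeric(unlist(plate[plate$gene_id == "GAPDH", -1]))))
  expect_error(panel_mean_ct(plate, character(0)), "Empty")
  expect_error(panel_mean_ct(plate, c("GAPDH", "NOPE")), "NOPE")
})

test_that("leave-one-out correlation compares each gene to the rest-of-panel mean", {
  # identical vector plus distinct per-gene constants: r = 1 everywhere
  base <- c(25, 27, 24, 29, 26)
  m <- rbind(g1 = base + 1, g2 = base + 3, g3 = base - 2, g4 = base)
  colnames(m) <- paste0("s", 1:5)
  r <- loo_correlation(expr_tbl(m))
  expect_equal(r$r, rep(1, 4))
  # matches a direct computation on the bundled plate
  plate <- plate_precise()
  r2 <- loo_correlation(plate)
  mm <- tbl_mat(plate)
  for (g in rownames(mm)) {
    expect_equal(r2$r[r2$gene_id == g],
                 cor(mm[g, ], colMeans(mm[setdiff(rownames(mm), g), ])))
  }
  # zero-variance gene is reported as NA, not an error
  m2 <- m; m2["g2", ] <- 30
  expect_message(r3 <- loo_correlation(expr_tbl(m2)), "zero variance")
  expect_true(is.na(r3$r[r3$gene_id == "g2"]))
  expect_error(loo_correlation(expr_tbl(m[1:2, ])), "3 genes")
  expect_error(loo_correlation(expr_tbl(m[, 1:2])), "3 samples")
})

test_that("leave-one-out correlation is invariant to global and per-gene shifts", {
  plate <- plate_precise()
  r <- loo_correlation(plate)
  shifted <- plate
  shifted[-1] <- shifted[-1] + 5.5
  expect_equal(loo_correlation(shifted)$r, r$r)
  # Pearson affine invariance on random seeded cases
  set.seed(131)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(cor(a * x + b, y), cor(x, y))
  }
})

test_that("cross-platform concordance fits the log-log relationship", {
  # exactly log-linear pairs: r = 1; reversed pairing: r = -1
  qp <- 10^seq(-2, -1.4, by = 0.2)
  d <- tibble::tibble(rnaseq_mean = 10^(2 + 1.5 * log10(qp)), qpcr_mean = qp)
  fit <- cross_platform_correlation(d)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 1.5)
  expect_equal(fit$intercept, 2)
  d2 <- tibble::tibble(rnaseq_mean = rev(d$rnaseq_mean), qpcr_mean = qp)
  expect_equal(cross_platform_correlation(d2)$r, -1, tolerance = 1e-6)
  # r does not depend on the log base (base change is affine)
  set.seed(141)
  x <- rexp(15) + 0.01; y <- x^1.3 * exp(rnorm(15, sd = 0.2))
  fit3 <- cross_platform_correlation(tibble::tibble(rnaseq_mean = y, qpcr_mean = x))
  expect_equal(fit3$r, cor(log2(x), log2(y)))
  expect_error(cross_platform_correlation(
    tibble::tibble(rnaseq_mean = c(1, -1, 2), qpcr_mean = c(1, 2, 3))), "positive")
  g <- glance(fit3)
  expect_equal(g$r_squared, fit3$r^2)
  td <- tidy(fit3)
  expect_equal(td$estimate[td$term == "slope"], fit3$slope)
  expect_s3_class(autoplot(fit3), "ggplot")
})

test_that("primer efficiency follows the standard-curve convention", {
  dil <- c(1 / 100, 1 / 200, 1 / 400, 1 / 800)
  # perfect doubling: slope -log2(10)... i.e. C_T drops 1 per 2-fold input
  ct_perfect <- 20 - 3.3219 * log10(dil / max(dil))
  eff <- primer_efficiency(dil, ct_perfect)
  expect_equal(eff$slope, -3.3219, tolerance = 1e-6)
  expect_equal(eff$efficiency, 1, tolerance = 1e-4)
  ct_36 <- 20 - 3.6 * log10(dil / max(dil))
  expect_equal(primer_efficiency(dil, ct_36)$efficiency, 0.8957, tolerance = 1e-4)
  expect_error(primer_efficiency(dil[1:2], ct_36[1:2]), "3 distinct")
  # C_T rising with input is not an amplification curve
  expect_error(primer_efficiency(dil, rev(ct_36)), "Non-amplifying")
})

test_that("the C_T reader handles both orientations and replicate wells", {
  plate <- plate_2dp()
  # samples-in-rows orientation round-trips to the same matrix
  t_path <- withr::local_tempfile(fileext = ".csv")
  tm <- t(tbl_mat(plate))
  df <- data.frame(sample_id = rownames(tm), tm, check.names = FALSE)
  readr::write_csv(df, t_path)
  back <- read_ct_matrix(t_path)
  expect_equal(tbl_mat(back), tbl_mat(plate))
  # replicate gene rows aggregate by mean or median
  r_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "g1\t20\t22", "g1\t24\t26", "g2\t30\t30"), r_path)
  mean_agg <- read_ct_matrix(r_path)
  expect_equal(mean_agg$s1[mean_agg$gene_id == "g1"], 22)
  med_agg <- read_ct_matrix(r_path, replicate_agg = "median")
  expect_equal(med_agg$s2[med_agg$gene_id == "g1"], 24)
})
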