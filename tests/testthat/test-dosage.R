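make_bias_fixture <- function(mean_M, mean_F) {
  ann <- tiny_annotation()
  sheet <- sheet_mf(1)
  expr <- expr_tbl(cbind(mean_M, mean_F), c("gA", "gB", "gC")[seq_along(mean_M)],
                   sheet$sample_id)
  sex_bias_table(expr, sheet, ann, "gonad")
}

test_that("sex-bias records match their defining ratio examples", {
  b <- make_bias_fixture(c(4, 64, 3), c(2, 1, 3))
  expect_equal(b$log2_mf, c(1, 6, 0))
  expect_equal(b$amplitude, c(1, 6, 0))
  expect_equal(b$outlier, c(FALSE, TRUE, FALSE))
  expect_equal(b$position[1], (100L + 500L) %/% 2L)
})

test_that("features with a zero sex mean are excluded, not offset", {
  b <- make_bias_fixture(c(0.5, 2, 1), c(0, 2, 1))
  expect_false("gA" %in% b$feature_id)
  expect_equal(nrow(b), 2L)
})

test_that("features on excluded chromosomes are dropped", {
  ann <- tiny_annotation()
  sheet <- sheet_mf(1)
  expr <- expr_tbl(cbind(c(1, 1, 1), c(1, 1, 1)), c("gA", "gB", "gC"),
                   sheet$sample_id)
  b <- sex_bias_table(expr, sheet, ann, "gonad", exclude_chroms = "1")
  expect_false("gC" %in% b$feature_id)
})

test_that("unknown features raise an error listing ids", {
  sheet <- sheet_mf(1)
  expr <- expr_tbl(cbind(1, 1), "mystery", sheet$sample_id)
  expect_error(sex_bias_table(expr, sheet, tiny_annotation(), "gonad"),
               "mystery")
})

test_that("swapping sex labels negates log2_mf and preserves amplitude", {
  dat <- simulate_dataset(small_config(seed = 21))
  bias <- gene_bias_from(dat)
  flipped_sheet <- dat$samples
  flipped_sheet$sex <- ifelse(flipped_sheet$sex == "M", "F", "M")
  g <- aggregate_to_genes(dat$counts, dat$annotation)
  ref <- dat$annotation$genes$gene_id[dat$annotation$genes$chrom != "Z"]
  norm <- normalize_counts(g, method = "median_ratio",
                           reference_features = ref)
  flipped <- sex_bias_table(norm, flipped_sheet, dat$annotation, "gonad")
  m <- dplyr::inner_join(as.data.frame(bias), as.data.frame(flipped),
                         by = "feature_id")
  expect_equal(m$log2_mf.x, -m$log2_mf.y)
  expect_equal(m$amplitude.x, m$amplitude.y)
})

test_that("window scan matches its defining example and the brute force", {
  bias <- tibble::tibble(
    feature_id = c("a", "b"), chrom = "Z",
    position = c(5e5, 15e5), mean_M = 1, mean_F = 1,
    log2_mf = c(1, 3), amplitude = c(1, 3), outlier = FALSE
  )
  scan <- window_scan(bias, chrom_length = 6e6)
  expect_equal(scan$mean_log2_mf[1], 2)
  expect_equal(scan$mean_amplitude[1], 2)
  expect_equal(scan$window_end - scan$window_start,
               c(rep(3e6, 4), 2e6, 1e6))

  set.seed(51)
  for (i in 1:5) {
    n <- 40
    rb <- tibble::tibble(
      feature_id = paste0("g", 1:n), chrom = "Z",
      position = sample.int(2e7, n), mean_M = 1, mean_F = 1,
      log2_mf = rnorm(n), amplitude = NA, outlier = runif(n) < 0.1
    )
    rb$amplitude <- abs(rb$log2_mf)
    scan <- window_scan(rb, 2e7, window = 3e6, shift = 1e6)
    oracle <- oracle_window_scan(rb$position, rb$log2_mf, rb$outlier,
                                 2e7, 3e6, 1e6)
    expect_equal(scan$n_genes, oracle$n_genes)
    expect_equal(scan$mean_log2_mf, oracle$mean_log2_mf)
    expect_equal(scan$mean_amplitude, oracle$mean_amplitude)
  }
})

test_that("constant bias gives constant non-empty window means", {
  rb <- tibble::tibble(feature_id = paste0("g", 1:30), chrom = "Z",
                       position = seq(1e5, 9e6, length.out = 30),
                       mean_M = 2, mean_F = 1, log2_mf = 1, amplitude = 1,
                       outlier = FALSE)
  scan <- window_scan(rb, 1e7)
  expect_true(all(scan$mean_log2_mf[scan$n_genes > 0] == 1))
  expect_error(window_scan(rb, 1e7, window = 5e5, shift = 1e6), "window")
})

test_that("top region merges near-maximal overlapping windows", {
  scan <- tibble::tibble(
    chrom = "Z",
    window_start = c(30e6, 31e6, 32e6, 33e6),
    window_end = c(33e6, 34e6, 35e6, 36e6),
    n_genes = 5,
    mean_log2_mf = c(0.5, 2.0, 1.9, 0.5),
    mean_amplitude = c(0.5, 2.0, 1.9, 0.5)
  )
  class(scan) <- c("window_scan_tbl", class(scan))
  r <- top_region(scan)
  expect_equal(r$region_start, 31e6)
  expect_equal(r$region_end, 35e6)

  unimodal <- scan
  unimodal$mean_log2_mf <- c(0.1, 0.5, 2.0, 0.4)
  r2 <- top_region(unimodal)
  expect_equal(r2$region_start, 32e6)
  expect_equal(r2$region_end, 35e6)
  expect_equal(r2$n_windows, 1L)

  empty <- scan
  empty$mean_log2_mf <- NA_real_
  expect_error(top_region(empty), "empty")
})

test_that("the Z:AA pattern discriminates the sexes under simulated bias", {
  dat <- simulate_dataset(study_config(seed = 31))
  g <- aggregate_to_genes(dat$counts, dat$annotation)
  cpm <- normalize_counts(g)
  f <- z_aa_test(cpm, dat$samples, dat$annotation, "gonad", "F")
  m <- z_aa_test(cpm, dat$samples, dat$annotation, "gonad", "M")
  expect_lt(f$p_value, 0.01)
  expect_gt(m$p_value, 0.05)
  expect_lt(f$median_ratio, 1)
  td <- tidy(f)
  expect_equal(td$p.value, f$p_value)
})

test_that("a single Z feature dispatches the exact Wilcoxon mode", {
  sheet <- sheet_mf(1)
  ann <- tiny_annotation()
  expr <- expr_tbl(cbind(c(5, 1, 2), c(5, 1, 2)), c("gA", "gB", "gC"),
                   sheet$sample_id)
  ann2 <- ann
  ann2$genes$chrom[ann2$genes$gene_id == "gB"] <- "1"
  res <- z_aa_test(expr, sheet, ann2, "gonad", "M", exclude_chroms = character())
  expect_equal(res$mode, "exact")
  expect_equal(res$n_z, 1L)
})

test_that("fold summaries label the three fold conventions", {
  b <- make_bias_fixture(c(4, 8, 2), c(2, 2, 2))
  fs <- fold_summary(b)
  z <- fs[fs$group == "Z", ]
  expect_equal(z$fold_mean_of_ratios, 3)       # (2 + 4)/2
  expect_equal(z$fold_median_of_ratios, 3)
  expect_equal(z$fold_of_sums, 3)              # 12/4
})
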