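test_that("candidate filtering applies the length and exon rules strictly", {
  # len 200 exactly (2 exons of 100) must be excluded; > 200 kept
  exons <- dplyr::bind_rows(
    tibble::tibble(gene_id = "l1", transcript_id = "l1.t", chrom = "Z",
                   start = c(1000L, 1201L), end = c(1099L, 1300L),
                   strand = "+"),
    tibble::tibble(gene_id = "l2", transcript_id = "l2.t", chrom = "Z",
                   start = c(2000L, 2201L), end = c(2100L, 2300L),
                   strand = "+"),
    tibble::tibble(gene_id = "l3", transcript_id = "l3.t", chrom = "Z",
                   start = 5000L, end = 9999L, strand = "+")
  )
  ann <- genome_annotation(exons)
  cand <- filter_lncrna_candidates(ann, c("l1.t", "l2.t", "l3.t"))
  expect_equal(cand$transcript_id, "l2.t")  # l1 len 200, l3 single-exon
  strict <- filter_lncrna_candidates(ann, c("l1.t", "l2.t", "l3.t"),
                                     min_exons = 3)
  expect_equal(nrow(strict), 0L)
})

test_that("positional classes follow the precedence rules", {
  coding <- tibble::tibble(
    gene_id = "cg", transcript_id = "cg.t", chrom = "Z",
    start = c(50000L, 52001L, 54001L), end = c(50500L, 52500L, 54500L),
    strand = "+"
  )
  mk <- function(id, starts, ends, strand) {
    tibble::tibble(gene_id = id, transcript_id = paste0(id, ".t"),
                   chrom = "Z", start = as.integer(starts),
                   end = as.integer(ends), strand = strand)
  }
  ann <- genome_annotation(dplyr::bind_rows(
    coding,
    mk("linc", c(10000, 11000), c(10400, 11400), "+"),
    mk("anti", c(50300, 50800), c(50600, 51000), "-"),
    mk("sens", c(50300, 50800), c(50600, 51000), "+"),
    mk("intr", c(50700, 51100), c(50900, 51400), "+"),
    mk("oppintr", c(50700, 51100), c(50900, 51400), "-")
  ), gene_biotype = c(cg = "coding", linc = "noncoding_candidate",
                      anti = "noncoding_candidate",
                      sens = "noncoding_candidate",
                      intr = "noncoding_candidate",
                      oppintr = "noncoding_candidate"))
  ids <- c("linc.t", "anti.t", "sens.t", "intr.t", "oppintr.t")
  cand <- filter_lncrna_candidates(ann, ids)
  cl <- classify_lncrna(cand, ann)
  got <- setNames(cl$class, cl$transcript_id)
  expect_equal(unname(got[ids]),
               c("lincRNA", "antisense", "sense", "intronic", "antisense"))
  # strand-agnostic intronic config flips the last case
  cl2 <- classify_lncrna(cand, ann, intronic_any_strand = TRUE)
  expect_equal(cl2$class[cl2$transcript_id == "oppintr.t"], "intronic")
})

test_that("candidates on chromosomes without coding genes are lincRNA", {
  ann <- genome_annotation(dplyr::bind_rows(
    tibble::tibble(gene_id = "c", transcript_id = "c.t", chrom = "1",
                   start = 100L, end = 500L, strand = "+"),
    tibble::tibble(gene_id = "l", transcript_id = "l.t", chrom = "Z",
                   start = c(100L, 601L), end = c(400L, 900L), strand = "+")
  ), gene_biotype = c(c = "coding", l = "noncoding_candidate"))
  cl <- classify_lncrna(filter_lncrna_candidates(ann, "l.t"), ann)
  expect_equal(cl$class, "lincRNA")
})

test_that("target assignment honours the strict 100 kb gap bound", {
  mk_gene <- function(id, start, end) {
    tibble::tibble(gene_id = id, transcript_id = paste0(id, ".t"),
                   chrom = "Z", start = as.integer(start),
                   end = as.integer(end), strand = "+")
  }
  # lnc span 500000-501000; gaps 99999 (kept) and 100000 (dropped)
  ann <- genome_annotation(dplyr::bind_rows(
    mk_gene("near", 601000, 602000),    # gap = 601000-501000-1 = 99999
    mk_gene("far", 601001, 602001),     # gap = 100000
    mk_gene("olap", 500500, 502000),    # overlapping
    tibble::tibble(gene_id = "lnc", transcript_id = "lnc.t", chrom = "Z",
                   start = c(500000L, 500601L), end = c(500400L, 501000L),
                   strand = "+")
  ), gene_biotype = c(near = "coding", far = "coding", olap = "coding",
                      lnc = "noncoding_candidate"))
  lncs <- filter_lncrna_candidates(ann, "lnc.t")
  tg <- assign_lncrna_targets(lncs, ann)
  expect_setequal(tg$gene_id, c("near", "olap"))
  expect_equal(tg$distance[tg$gene_id == "near"], 99999L)
  expect_equal(tg$relation[tg$gene_id == "near"], "downstream")
  expect_equal(tg$distance[tg$gene_id == "olap"], 0L)
  expect_equal(tg$relation[tg$gene_id == "olap"], "overlapping")
})

test_that("upstream/downstream relations follow the lncRNA strand", {
  ann <- genome_annotation(dplyr::bind_rows(
    tibble::tibble(gene_id = "left", transcript_id = "left.t", chrom = "Z",
                   start = 100000L, end = 110000L, strand = "+"),
    tibble::tibble(gene_id = "lnc", transcript_id = "lnc.t", chrom = "Z",
                   start = c(200000L, 200601L), end = c(200400L, 201000L),
                   strand = "-")
  ), gene_biotype = c(left = "coding", lnc = "noncoding_candidate"))
  tg <- assign_lncrna_targets(filter_lncrna_candidates(ann, "lnc.t"), ann)
  expect_equal(tg$relation, "downstream")  # left of a '-' lncRNA
})

test_that("assignment matches the brute-force all-pairs scan", {
  dat <- simulate_annotation(small_config(seed = 111))
  cand <- filter_lncrna_candidates(dat$annotation,
                                   dat$truth$lncrnas$lncrna_id)
  tg <- assign_lncrna_targets(cand, dat$annotation)
  oracle <- oracle_targets(cand,
                           dat$annotation$genes[
                             dat$annotation$genes$biotype == "coding", ])
  expect_setequal(paste(tg$lncrna_id, tg$gene_id),
                  paste(oracle$lncrna_id, oracle$gene_id))
  # and the generator's own truth agrees
  expect_setequal(paste(tg$lncrna_id, tg$gene_id),
                  paste(dat$truth$lncrna_targets$lncrna_id,
                        dat$truth$lncrna_targets$gene_id))
})

test_that("male-bias calls use the strict positive log-ratio rule", {
  sheet <- sheet_mf(2)
  expr <- expr_tbl(rbind(c(2, 2, 1, 1), c(1, 1, 1, 1), c(0, 0, 2, 2)),
                   c("up", "flat", "zeroM"), sheet$sample_id)
  calls <- lncrna_bias(expr, sheet, "gonad")
  expect_equal(calls$male_biased, c(TRUE, FALSE, FALSE))
  expect_equal(calls$log2_mf[1], 1)
  expect_true(is.na(calls$log2_mf[3]))
})

test_that("lncRNA-target correlations behave at the extremes", {
  sheet <- sheet_mf(4)
  set.seed(121)
  base <- rlnorm(8)
  lnc <- expr_tbl(matrix(base, 1), "lnc1", sheet$sample_id)
  tgt <- expr_tbl(matrix(2 * base, 1), "g1", sheet$sample_id)
  pairs <- tibble::tibble(lncrna_id = "lnc1", gene_id = "g1")
  res <- correlate_lncrna_targets(lnc, tgt, pairs)
  expect_equal(res$spearman, 1)
  expect_equal(res$pearson, 1)

  flat <- expr_tbl(matrix(1, 1, 8), "g1", sheet$sample_id)
  res2 <- correlate_lncrna_targets(lnc, flat, pairs)
  expect_false(res2$defined)
  expect_true(is.na(res2$spearman))

  expect_error(correlate_lncrna_targets(
    expr_tbl(matrix(1, 1, 2), "lnc1", c("a", "b")),
    expr_tbl(matrix(1, 1, 2), "g1", c("a", "b")), pairs
  ), "3 shared samples")
})

test_that("independent pairs decorrelate and latent-factor pairs recover", {
  set.seed(122)
  n_pairs <- 200
  ids <- paste0("p", seq_len(n_pairs))
  sheet <- sheet_mf(8)
  lmat <- matrix(rnorm(n_pairs * 16), n_pairs)
  tmat_null <- matrix(rnorm(n_pairs * 16), n_pairs)
  shared <- matrix(rnorm(n_pairs * 16), n_pairs)
  a <- sqrt(0.8)  # loading giving pair correlation 0.8
  lmat_cor <- a * shared + sqrt(1 - a^2) * matrix(rnorm(n_pairs * 16), n_pairs)
  tmat_cor <- a * shared + sqrt(1 - a^2) * matrix(rnorm(n_pairs * 16), n_pairs)
  pairs <- tibble::tibble(lncrna_id = ids, gene_id = paste0("g", ids))
  null_res <- correlate_lncrna_targets(
    expr_tbl(lmat, ids, sheet$sample_id),
    expr_tbl(tmat_null, paste0("g", ids), sheet$sample_id), pairs
  )
  expect_lt(abs(mean(null_res$spearman)), 0.05)
  cor_res <- correlate_lncrna_targets(
    expr_tbl(lmat_cor, ids, sheet$sample_id),
    expr_tbl(tmat_cor, paste0("g", ids), sheet$sample_id), pairs
  )
  expect_gt(mean(cor_res$spearman), 0.6)
})
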