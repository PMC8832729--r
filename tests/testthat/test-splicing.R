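annot_from_exons <- function(...) {
  genome_annotation(dplyr::bind_rows(...))
}

tx_exons <- function(gene, tx, chrom, strand, starts, ends) {
  tibble::tibble(gene_id = gene, transcript_id = tx, chrom = chrom,
                 start = as.integer(starts), end = as.integer(ends),
                 strand = strand)
}

test_that("exon skipping and intron retention match their definitions", {
  ann <- annot_from_exons(
    tx_exons("g", "A", "Z", "+", c(1, 201, 401), c(100, 300, 500)),
    tx_exons("g", "B", "Z", "+", c(1, 401), c(100, 500))
  )
  ev <- classify_splice_events(ann)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "exon_skipping")
  expect_equal(c(ev$event_start, ev$event_end), c(201L, 300L))
  expect_equal(ev$inclusion[[1]], "A")
  expect_equal(ev$exclusion[[1]], "B")

  ann2 <- annot_from_exons(
    tx_exons("g", "A", "Z", "+", c(1, 201), c(100, 300)),
    tx_exons("g", "B", "Z", "+", 1, 300)
  )
  ev2 <- classify_splice_events(ann2)
  expect_equal(ev2$event_type, "intron_retention")
  expect_equal(c(ev2$event_start, ev2$event_end), c(101L, 200L))
  expect_equal(ev2$inclusion[[1]], "B")
})

test_that("alternative splice-site labels follow the strand", {
  for (strand in c("+", "-")) {
    # B extends the left exon 40 bp into the intron (shared intron end)
    ann <- annot_from_exons(
      tx_exons("g", "A", "Z", strand, c(1, 501), c(100, 700)),
      tx_exons("g", "B", "Z", strand, c(1, 501), c(140, 700))
    )
    ev <- classify_splice_events(ann)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$event_type, if (strand == "+") "alt_5ss" else "alt_3ss")
    expect_equal(c(ev$event_start, ev$event_end), c(101L, 140L))
    expect_equal(ev$inclusion[[1]], "B")
  }
})

test_that("mutually exclusive exons require gene-wide non-co-occurrence", {
  mxe <- annot_from_exons(
    tx_exons("g", "A", "Z", "+", c(1, 301, 901), c(100, 400, 1000)),
    tx_exons("g", "B", "Z", "+", c(1, 501, 901), c(100, 600, 1000))
  )
  ev <- classify_splice_events(mxe)
  expect_equal(ev$event_type, "mutually_exclusive_exons")
  expect_equal(c(ev$event_start, ev$event_end), c(301L, 600L))

  # a third isoform carrying both exons vetoes the MXE call
  both <- annot_from_exons(
    tx_exons("g", "A", "Z", "+", c(1, 301, 901), c(100, 400, 1000)),
    tx_exons("g", "B", "Z", "+", c(1, 501, 901), c(100, 600, 1000)),
    tx_exons("g", "C", "Z", "+", c(1, 301, 501, 901),
             c(100, 400, 600, 1000))
  )
  ev2 <- classify_splice_events(both)
  expect_false("mutually_exclusive_exons" %in% ev2$event_type)
})

test_that("classification is invariant to transcript input order", {
  dat <- simulate_annotation(small_config(seed = 61))
  ann <- dat$annotation
  rev_ann <- genome_annotation(
    ann$exons[rev(seq_len(nrow(ann$exons))), ],
    chromosomes = ann$chromosomes
  )
  a <- classify_splice_events(ann)
  b <- classify_splice_events(rev_ann)
  expect_equal(event_key(a), event_key(b))
})

test_that("detected events equal the generator's injected truth", {
  for (seed in c(71, 72)) {
    dat <- simulate_annotation(small_config(seed = seed))
    ev <- classify_splice_events(dat$annotation)
    expect_equal(
      event_key(ev),
      sort(paste(dat$truth$splice_events$event_type,
                 dat$truth$splice_events$event_start,
                 dat$truth$splice_events$event_end))
    )
  }
})

test_that("the classifier agrees with the brute-force enumerator", {
  dat <- simulate_annotation(small_config(seed = 81))
  ann <- dat$annotation
  multi <- ann$genes$gene_id[ann$genes$n_transcripts >= 2]
  ev <- classify_splice_events(ann)
  for (gid in multi) {
    ex <- ann$exons[ann$exons$gene_id == gid, ]
    byx <- split(as.data.frame(ex[c("start", "end")]), ex$transcript_id)
    oracle <- oracle_splice_events(byx, ann$genes$strand[ann$genes$gene_id == gid])
    expect_equal(event_key(ev[ev$gene_id == gid, ]), event_key(oracle),
                 label = gid)
  }
})

test_that("PSI follows the inclusion-ratio definition and flags zeros", {
  ev <- tibble::tibble(
    gene_id = "g", chrom = "Z", strand = "+", event_type = "exon_skipping",
    event_start = 1L, event_end = 10L,
    inclusion = list("A"), exclusion = list("B"),
    event_id = "g:es:1:10"
  )
  expr <- expr_tbl(rbind(c(3, 2, 0), c(1, 0, 0)), c("A", "B"),
                   c("s1", "s2", "s3"))
  p <- splice_psi(ev, expr)
  expect_equal(p$psi, c(0.75, 1, NA))
  expect_equal(p$defined, c(TRUE, TRUE, FALSE))
  expect_error(splice_psi(ev, expr_tbl(matrix(1, 1), "A", "s1")), "absent")
})

test_that("defined PSI values stay within [0, 1] on simulated data", {
  dat <- simulate_dataset(small_config(seed = 91))
  ev <- classify_splice_events(dat$annotation)
  expr <- normalize_counts(dat$counts)
  p <- splice_psi(ev, expr)
  expect_true(all(p$psi[p$defined] >= 0 & p$psi[p$defined] <= 1))
})

test_that("differential splicing applies the delta and FDR rules", {
  sheet <- sheet_mf(4)
  mk_psi <- function(event_id, m, f) {
    tibble::tibble(event_id = event_id, gene_id = event_id,
                   event_type = "exon_skipping",
                   sample_id = sheet$sample_id, psi = c(m, f),
                   defined = TRUE)
  }
  flat <- mk_psi("null", rep(0.5, 4), rep(0.5, 4))
  res0 <- suppressWarnings(differential_splicing(flat, sheet, "gonad"))
  expect_equal(res0$delta_psi, 0)
  expect_false(res0$significant)

  strong <- mk_psi("strong", c(0.92, 0.9, 0.91, 0.9), c(0.1, 0.12, 0.11, 0.1))
  res1 <- differential_splicing(strong, sheet, "gonad")
  expect_equal(res1$p_value, 2 / 70)
  expect_equal(res1$delta_psi, 0.8, tolerance = 0.01)
  expect_true(res1$significant)

  # delta below 0.10 is never significant, whatever the p-value
  small <- mk_psi("small", c(0.55, 0.56, 0.55, 0.56), c(0.5, 0.5, 0.51, 0.5))
  res2 <- differential_splicing(small, sheet, "gonad")
  expect_false(res2$significant)

  # one sex with < 2 defined replicates is skipped with a reason
  und <- mk_psi("und", c(0.9, NA, NA, NA), c(0.1, 0.1, 0.1, 0.2))
  und$defined <- !is.na(und$psi)
  res3 <- differential_splicing(und, sheet, "gonad")
  expect_true(res3$skipped)
  expect_match(res3$skip_reason, "fewer than 2")
})

test_that("BH adjustment matches the brute-force step-up", {
  set.seed(101)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("unique transcripts partition correctly across groups", {
  sheet <- dplyr::bind_rows(sheet_mf(2, "gonad"), sheet_mf(2, "skin"))
  sheet$sample_id <- paste0(sheet$sample_id, "_", sheet$tissue)
  # t1 only in (M, gonad); t2 everywhere; t3 nowhere
  mat <- rbind(c(5, 5, 0, 0, 0, 0, 0, 0),
               c(1, 1, 1, 1, 1, 1, 1, 1),
               c(0, 0, 0, 0, 0, 0, 0, 0))
  expr <- expr_tbl(mat, c("t1", "t2", "t3"), sheet$sample_id)
  res <- unique_transcripts(expr, sheet)
  expect_equal(res$membership$unique_group,
               c("M_gonad", NA, NA))
  expect_equal(res$unique_counts$n_unique[res$unique_counts$group == "M_gonad"],
               1L)
  expect_equal(res$patterns$n[res$patterns$pattern ==
                                "M_gonad&F_gonad&M_skin&F_skin"], 1L)

  # brute-force membership check on a random fixture
  set.seed(102)
  mat2 <- matrix(rpois(20 * 8, 0.7), 20)
  expr2 <- expr_tbl(mat2, paste0("x", 1:20), sheet$sample_id)
  res2 <- unique_transcripts(expr2, sheet)
  for (i in c(1, 7, 20)) {
    for (g in seq_len(nrow(res2$unique_counts))) {
      grp <- res2$unique_counts$group[g]
      ids <- sheet$sample_id[paste(sheet$sex, sheet$tissue, sep = "_") == grp]
      expect_equal(res2$membership[[grp]][i], mean(mat2[i, match(ids, sheet$sample_id)]) > 0)
    }
  }
})
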