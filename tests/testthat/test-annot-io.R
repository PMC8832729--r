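test_that("a single-record GTF round-trips with correct grouping and length", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'Z\tsrc\tgene\t100\t200\t.\t+\t.\tgene_id "g1";',
    'Z\tsrc\ttranscript\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'Z\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";'
  ), gtf)
  ann <- read_gtf(gtf)
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(nrow(ann$transcripts), 1L)
  expect_equal(ann$transcripts$length, 101L)
  expect_equal(ann$transcripts$n_exons, 1L)
})

test_that("two transcripts sharing gene_id group under one gene", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'Z\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'Z\tsrc\texon\t100\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'
  ), gtf)
  ann <- read_gtf(gtf)
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(ann$genes$n_transcripts, 2L)
})

test_that("malformed GTF lines produce errors naming the line", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'Z\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "Z\tsrc\texon\t100\t200"
  ), bad)
  expect_error(read_gtf(bad), "line 2")

  no_tx <- tempfile(fileext = ".gtf")
  writeLines('Z\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1";', no_tx)
  expect_error(read_gtf(no_tx), "transcript_id")

  olap <- tempfile(fileext = ".gtf")
  writeLines(c(
    'Z\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'Z\tsrc\texon\t150\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), olap)
  expect_error(read_gtf(olap), "overlapping")

  dup <- tempfile(fileext = ".gtf")
  writeLines(rep(
    'Z\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";', 2
  ), dup)
  expect_equal(nrow(read_gtf(dup)$exons), 1L)  # identical duplicates collapse
})

test_that("GTF writing then reading is identity on content", {
  dat <- simulate_annotation(small_config(seed = 5))
  path <- tempfile(fileext = ".gtf")
  write_gtf(dat$annotation, path)
  back <- read_gtf(path, chrom_sizes = tibble::tibble(
    chrom = c("1", "Z"), length = c(2e7, 2e7)
  ))
  for (tb in c("genes", "transcripts", "exons")) {
    a <- dat$annotation[[tb]]
    a$biotype <- NULL  # biotype is external to the GTF dialect
    b <- back[[tb]]
    b$biotype <- NULL
    a <- dplyr::arrange(a, dplyr::across(dplyr::everything()))
    b <- dplyr::arrange(b, dplyr::across(dplyr::everything()))
    expect_equal(as.data.frame(a)[names(b)], as.data.frame(b),
                 ignore_attr = TRUE)
  }
})

test_that("the GTF reader agrees with rtracklayer on a fixture", {
  skip_if_not_installed("rtracklayer")
  dat <- simulate_annotation(small_config(seed = 7))
  path <- tempfile(fileext = ".gtf")
  write_gtf(dat$annotation, path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ours <- dat$annotation$exons
  expect_equal(length(gr), nrow(ours))
  key_ref <- sort(paste(GenomicRanges::seqnames(gr),
                        GenomicRanges::start(gr), GenomicRanges::end(gr),
                        GenomicRanges::strand(gr), gr$transcript_id))
  key_ours <- sort(paste(ours$chrom, ours$start, ours$end, ours$strand,
                         ours$transcript_id))
  expect_equal(key_ours, key_ref)
})

test_that("count matrix reading enforces the sample schema", {
  sheet <- sheet_mf(2)
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(expr_tbl(matrix(1:8, 2), c("f1", "f2"),
                            sheet$sample_id, unit = NULL), path)
  cnt <- read_counts(path, sheet)
  expect_equal(dim(cnt), c(2L, 5L))
  expect_equal(attr(cnt, "unit"), "raw_counts")

  extra <- readr::read_tsv(path, show_col_types = FALSE)
  extra$mystery <- 1
  path2 <- tempfile(fileext = ".tsv")
  readr::write_tsv(extra, path2)
  expect_error(read_counts(path2, sheet), "unknown column")

  expect_error(read_counts(path, sheet_mf(3)), "missing sample column")

  neg <- readr::read_tsv(path, show_col_types = FALSE)
  neg$M1[1] <- -1
  path3 <- tempfile(fileext = ".tsv")
  readr::write_tsv(neg, path3)
  expect_error(read_counts(path3, sheet), "negative")
})

test_that("count matrices written by the generator round-trip value-exactly", {
  dat <- simulate_dataset(small_config(seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_counts(dat$counts, path)
  back <- read_counts(path, dat$samples)
  expect_equal(as.data.frame(back), as.data.frame(dat$counts),
               ignore_attr = TRUE)
})

test_that("poly(A) BED-like I/O converts 0-based starts and round-trips", {
  path <- tempfile(fileext = ".tsv")
  writeLines("Z\t99\t100\tr1\t.\t+\tg1\tM1", path)
  ends <- read_polya_ends(path)
  expect_equal(ends$position, 100L)

  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(read_polya_ends(empty)), 0L)

  dat <- simulate_dataset(small_config(seed = 3))
  rt <- tempfile(fileext = ".tsv")
  write_polya_ends(dat$polya_ends, rt)
  back <- read_polya_ends(rt, dat$annotation)
  expect_equal(nrow(back), nrow(dat$polya_ends))
  expect_equal(dplyr::arrange(as.data.frame(back), read_id),
               dplyr::arrange(as.data.frame(dat$polya_ends), read_id))
})

test_that("out-of-range poly(A) positions are a validation error", {
  ann <- tiny_annotation()
  path <- tempfile(fileext = ".tsv")
  writeLines("Z\t10050\t10051\tr1\t.\t+\tgA\tM1", path)
  expect_error(read_polya_ends(path, ann), "outside chromosome length")
})

test_that("annotation invariants are enforced", {
  expect_error(genome_annotation(tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "Z",
    start = 10L, end = 5L, strand = "+"
  )), "start > end")
  expect_error(genome_annotation(tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "Z",
    start = 10L, end = 50L, strand = "*"
  )), "strand")
  expect_error(genome_annotation(
    tibble::tibble(gene_id = "g", transcript_id = "t", chrom = "Z",
                   start = 10L, end = 50L, strand = "+"),
    chromosomes = tibble::tibble(chrom = "Z", length = 20L)
  ), "beyond chromosome length")
})
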