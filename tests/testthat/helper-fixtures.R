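# Shared fixture builders (everything is generated in code at test time).

# tiny hand-built annotation: two genes on chromosome Z, one on chromosome 1
tiny_annotation <- function() {
  exons <- tibble::tribble(
    ~gene_id, ~transcript_id, ~chrom, ~start, ~end, ~strand,
    "gA", "gA.t1", "Z", 100L, 200L, "+",
    "gA", "gA.t1", "Z", 401L, 500L, "+",
    "gA", "gA.t2", "Z", 100L, 200L, "+",
    "gA", "gA.t2", "Z", 301L, 350L, "+",
    "gA", "gA.t2", "Z", 401L, 500L, "+",
    "gB", "gB.t1", "Z", 5000L, 5999L, "-",
    "gC", "gC.t1", "1", 100L, 600L, "+"
  )
  genome_annotation(exons, chromosomes = tibble::tibble(
    chrom = c("Z", "1"), length = c(10000L, 10000L)
  ))
}

# wide expression tibble from a matrix
expr_tbl <- function(mat, feature_ids, sample_ids, unit = "per_scale") {
  colnames(mat) <- sample_ids
  out <- dplyr::bind_cols(tibble::tibble(feature_id = feature_ids),
                          tibble::as_tibble(mat))
  attr(out, "unit") <- unit
  out
}

# minimal sample sheet: n replicates per sex for one tissue
sheet_mf <- function(n = 4, tissue = "gonad") {
  tibble::tibble(
    sample_id = c(paste0("M", seq_len(n)), paste0("F", seq_len(n))),
    sex = rep(c("M", "F"), each = n),
    tissue = tissue,
    replicate = rep(seq_len(n), 2)
  )
}

# small simulation config used by several suites
small_config <- function(seed = 1, lncrna_n = 12L, ...) {
  sim_config(
    seed = seed,
    chromosomes = tibble::tibble(
      chrom = c("1", "Z"), length = c(2e7, 2e7),
      is_z = c(FALSE, TRUE), n_genes = c(25L, 25L)
    ),
    lncrna_n = lncrna_n, tissues = "gonad",
    hotspot = NULL, ...
  )
}

# read 3'-end fixture rows for APA tests
mk_ends <- function(pos, gene = "g1", sample = "M1") {
  tibble::tibble(gene_id = gene, sample_id = sample, chrom = "Z",
                 position = as.integer(pos), strand = "+",
                 read_id = paste0("r", seq_along(pos)))
}

# study-scale config: 1000 autosomal + 200 Z genes, single-isoform
study_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    chromosomes = tibble::tibble(
      chrom = c("1", "2", "Z"), length = c(1e8, 1e8, 8e7),
      is_z = c(FALSE, FALSE, TRUE), n_genes = c(500L, 500L, 200L)
    ),
    isoform_probs = c("1" = 1), lncrna_n = 0L, hotspot = NULL,
    tissues = "gonad", ...
  )
}

# dosage-ready gene-level tables from a simulated dataset
gene_bias_from <- function(dat, method = "median_ratio") {
  g <- aggregate_to_genes(dat$counts, dat$annotation)
  ref <- dat$annotation$genes$gene_id[dat$annotation$genes$chrom != "Z"]
  norm <- normalize_counts(g, method = method, reference_features = ref)
  sex_bias_table(norm, dat$samples, dat$annotation, "gonad")
}
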