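# Expression and poly(A)-end simulation on top of the generated annotation.

#' Simulate a transcript-level count matrix and its sample sheet
#'
#' Per-transcript counts are negative binomial with
#' `mean = gene baseline x isoform usage x sex factor x library factor`.
#' Autosomal genes have sex factor 1 for both sexes; for Z-linked genes males
#' sit at the baseline and females at `baseline / true_fold`, so the
#' male:female fold equals the configured fold while male Z:AA stays near 1.
#' Gene baselines are log-normal, isoform usage is Dirichlet, library factors
#' are log-normal around 1.
#'
#' @param annotation A [genome_annotation()] from [simulate_annotation()].
#' @param truth Matching ground-truth list.
#' @param config The [sim_config()] used to generate them.
#' @param sex_usage_shift Optional tibble (`transcript_id`, `sex`,
#'   `multiplier`) multiplying isoform usage for one sex; used to induce
#'   sex-dependent splicing (true non-zero delta PSI) in calibration studies.
#' @param usage Optional named numeric vector (`transcript_id` -> weight)
#'   replacing the random Dirichlet isoform usage.
#' @return `list(counts, samples)`: a wide count tibble (`feature_id` +
#'   sample columns, transcript level) and the sample sheet.
#' @export
simulate_expression <- function(annotation, truth, config,
                                sex_usage_shift = NULL, usage = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    samples <- tidyr::expand_grid(
      sex = c("M", "F"), tissue = config$tissues,
      replicate = seq_len(config$n_replicates)
    ) |>
      mutate(sample_id = paste(.data$sex, .data$tissue, .data$replicate,
                               sep = "_")) |>
      select("sample_id", "sex", "tissue", "replicate")

    tx <- annotation$transcripts |>
      left_join(truth$genes[c("gene_id", "true_fold", "is_z")], by = "gene_id")

    gene_ids <- unique(tx$gene_id)
    baseline <- setNames(
      rlnorm(length(gene_ids), config$baseline_meanlog, config$baseline_sdlog),
      gene_ids
    )
    # Dirichlet(5) usage within each gene unless overridden
    if (is.null(usage)) {
      usage <- rgamma(nrow(tx), shape = 5, rate = 1)
    } else {
      if (!all(tx$transcript_id %in% names(usage))) {
        abort("usage override must name every transcript")
      }
      usage <- unname(usage[tx$transcript_id])
    }
    tot <- tapply(usage, tx$gene_id, sum)
    usage <- usage / as.numeric(tot[tx$gene_id])

    base_mu <- baseline[tx$gene_id] * usage
    lib <- rlnorm(nrow(samples), 0, config$library_sdlog)

    n_tx <- nrow(tx)
    counts <- matrix(0, nrow = n_tx, ncol = nrow(samples))
    for (s in seq_len(nrow(samples))) {
      sexfac <- if (samples$sex[s] == "F") {
        ifelse(tx$is_z, 1 / tx$true_fold, 1)
      } else {
        rep(1, n_tx)
      }
      shift <- rep(1, n_tx)
      if (!is.null(sex_usage_shift)) {
        hit <- sex_usage_shift[sex_usage_shift$sex == samples$sex[s], ]
        m <- match(tx$transcript_id, hit$transcript_id)
        shift[!is.na(m)] <- hit$multiplier[m[!is.na(m)]]
      }
      mu <- base_mu * sexfac * shift * lib[s]
      counts[, s] <- if (config$nb_dispersion < 1e-8) {
        rpois(n_tx, mu)
      } else {
        rnbinom(n_tx, mu = mu, size = 1 / config$nb_dispersion)
      }
    }
    colnames(counts) <- samples$sample_id
    out <- bind_cols(tibble(feature_id = tx$transcript_id),
                     as_tibble(counts))
    attr(out, "unit") <- "raw_counts"
    list(counts = out, samples = samples)
  })
}

#' Simulate poly(A) read 3'-end records
#'
#' For every gene, sample and true site, `Poisson(polya_reads_per_site)` read
#' ends are drawn and jittered by integer offsets in
#' `[-polya_jitter, +polya_jitter]`.
#'
#' @inheritParams simulate_expression
#' @param samples Sample sheet (from [simulate_expression()]).
#' @return Tibble with columns `gene_id`, `sample_id`, `chrom`, `position`,
#'   `strand`, `read_id`; empty when `polya_reads_per_site = 0`.
#' @export
simulate_polya_ends <- function(annotation, truth, config, samples) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 2L, {
    sites <- truth$polya_sites
    empty <- tibble(gene_id = character(), sample_id = character(),
                    chrom = character(), position = integer(),
                    strand = character(), read_id = character())
    if (nrow(sites) == 0L || config$polya_reads_per_site <= 0) return(empty)
    grid <- tidyr::expand_grid(site = seq_len(nrow(sites)),
                               sample_id = samples$sample_id)
    n_reads <- rpois(nrow(grid), config$polya_reads_per_site)
    keep <- n_reads > 0L
    if (!any(keep)) return(empty)
    grid <- grid[keep, ]
    n_reads <- n_reads[keep]
    idx <- rep(seq_len(nrow(grid)), n_reads)
    jit <- sample(seq(-config$polya_jitter, config$polya_jitter),
                  length(idx), replace = TRUE)
    s <- sites[grid$site[idx], ]
    lens <- setNames(annotation$chromosomes$length,
                     annotation$chromosomes$chrom)
    out <- tibble(
      gene_id = s$gene_id,
      sample_id = grid$sample_id[idx],
      chrom = s$chrom,
      position = pmin(pmax(s$position + jit, 1L),
                      as.integer(lens[s$chrom])),
      strand = s$strand,
      read_id = sprintf("read%07d", seq_along(idx))
    )
    arrange(out, .data$gene_id, .data$sample_id, .data$position)
  })
}

#' Generate a complete synthetic dataset, optionally writing it to disk
#'
#' Runs [simulate_annotation()], [simulate_expression()] and
#' [simulate_polya_ends()] under one configuration. With `outdir` set, writes
#' `genome.gtf`, `chrom.sizes`, `counts.tsv`, `samples.tsv`,
#' `polya_ends.tsv` and `truth.json`. Outputs are a pure function of the
#' configuration: the same config (and seed) reproduces every file
#' byte-identically.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return `list(annotation, truth, counts, samples, polya_ends)`, invisibly
#'   when writing.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  sim <- simulate_annotation(config)
  expr <- simulate_expression(sim$annotation, sim$truth, config)
  ends <- simulate_polya_ends(sim$annotation, sim$truth, config,
                              expr$samples)
  out <- list(annotation = sim$annotation, truth = sim$truth,
              counts = expr$counts, samples = expr$samples,
              polya_ends = ends)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_gtf(sim$annotation, file.path(outdir, "genome.gtf"))
    write_chrom_sizes(sim$annotation, file.path(outdir, "chrom.sizes"))
    write_counts(expr$counts, file.path(outdir, "counts.tsv"))
    readr::write_tsv(expr$samples, file.path(outdir, "samples.tsv"))
    write_polya_ends(ends, file.path(outdir, "polya_ends.tsv"))
    truth_json <- sim$truth
    truth_json$hotspot <- truth_json$hotspot %||% NULL
    jsonlite::write_json(truth_json, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(out))
  }
  out
}
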