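# End-to-end orchestration: simulate (or load) -> quantify -> dosage ->
# splicing -> lncRNA -> APA, with on-disk TSV/BED artifacts, a
# machine-readable summary and content checksums for integrity checks.

write_stage_tsv <- function(x, path, params) {
  # drop list columns (transcript sets) by collapsing to comma strings
  is_list <- map_lgl(x, is.list)
  for (nm in names(x)[is_list]) {
    x[[nm]] <- map_chr(x[[nm]], function(v) paste(v, collapse = ","))
  }
  readr::write_lines(paste0("# zdosage ", params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_stage_tsv <- function(path, col_types = NULL) {
  if (!file.exists(path)) {
    abort(paste0("missing pipeline table: ", basename(path)))
  }
  readr::read_tsv(path, comment = "#", progress = FALSE, col_types = col_types,
                  show_col_types = FALSE)
}

#' Run the full analysis pipeline
#'
#' Either generates a synthetic dataset from `config` or loads the four
#' input files, then runs the enabled stages in dependency order, writing
#' every result table (with a parameter header comment) plus `summary.json`
#' to `outdir`. The summary is recomputed from the written tables via
#' [summarize_run()], guaranteeing the tables are self-sufficient. A fixed
#' config (and seed) reproduces every artifact byte-identically.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [sim_config()], or `NULL` when `gtf`/`counts`/`samples`
#'   paths are given.
#' @param gtf,chrom_sizes,counts,samples,polya_ends Input file paths
#'   (ignored when `config` is given; `polya_ends` optional).
#' @param noncoding Character vector of noncoding transcript ids; defaults
#'   to the simulation truth when simulating.
#' @param stages Character subset of
#'   `c("dosage", "splicing", "lncrna", "apa")`.
#' @param scale,z_chrom,exclude_chroms,window,shift,merge_dist,min_support,max_dist
#'   Stage parameters (see the stage functions).
#' @param norm_method Normalization for cross-sample ratio analyses:
#'   `"median_ratio"` (default; size factors anchored on autosomal
#'   features, robust to the compositional shift a biased Z introduces into
#'   column totals), `"cpm"` or `"tmm"`.
#' @return The run summary (list), invisibly.
#' @export
run_pipeline <- function(outdir, config = NULL, gtf = NULL,
                         chrom_sizes = NULL, counts = NULL, samples = NULL,
                         polya_ends = NULL, noncoding = NULL,
                         stages = c("dosage", "splicing", "lncrna", "apa"),
                         scale = 1e6, z_chrom = "Z",
                         exclude_chroms = c("W", "31", "33"),
                         window = 3e6, shift = 1e6,
                         merge_dist = 24, min_support = 2,
                         max_dist = 100000, norm_method = "median_ratio") {
  simulated <- !is.null(config)
  if (simulated == !is.null(counts)) {
    abort("provide exactly one of `config` or input file paths")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- "inputs"
  result <- tryCatch({
    if (simulated) {
      dat <- simulate_dataset(config, outdir = outdir)
      annotation <- dat$annotation
      cnt <- dat$counts
      sheet <- dat$samples
      ends <- dat$polya_ends
      noncoding <- noncoding %||% dat$truth$lncrnas$lncrna_id
      cfg_json <- config[setdiff(names(config), "chromosomes")]
      cfg_json$chromosomes <- as.data.frame(config$chromosomes)
    } else {
      annotation <- read_gtf(gtf, chrom_sizes = chrom_sizes)
      sheet <- read_sample_sheet(samples)
      cnt <- read_counts(counts, sheet)
      ends <- if (!is.null(polya_ends)) {
        read_polya_ends(polya_ends, annotation)
      } else NULL
      cfg_json <- list(gtf = gtf, counts = counts, samples = samples,
                       polya_ends = polya_ends)
    }
    jsonlite::write_json(
      c(cfg_json, list(stages = stages, scale = scale, z_chrom = z_chrom,
                       exclude_chroms = exclude_chroms, window = window,
                       shift = shift, merge_dist = merge_dist,
                       min_support = min_support, max_dist = max_dist,
                       norm_method = norm_method)),
      file.path(outdir, "config.json"), auto_unbox = TRUE, digits = NA,
      null = "null"
    )
    tissues <- unique(sheet$tissue)

    stage <- "quantify"
    # median-ratio factors are anchored on autosomal coding features so the
    # Z-linked shift cannot leak into the library-size estimate
    aut_genes <- annotation$genes$gene_id[
      annotation$genes$chrom != z_chrom &
        !annotation$genes$chrom %in% exclude_chroms &
        annotation$genes$biotype == "coding"]
    aut_tx <- annotation$transcripts$transcript_id[
      annotation$transcripts$gene_id %in% aut_genes]
    tx_norm <- normalize_counts(cnt, scale = scale, method = norm_method,
                                reference_features = aut_tx)
    gene_counts <- aggregate_to_genes(cnt, annotation)
    gene_norm <- normalize_counts(gene_counts, scale = scale,
                                  method = norm_method,
                                  reference_features = aut_genes)
    gene_cpm <- normalize_counts(gene_counts, scale = scale, method = "cpm")
    qparams <- paste0("quantify scale=", scale, " method=", norm_method)
    write_stage_tsv(tx_norm, file.path(outdir, "norm_transcripts.tsv"), qparams)
    write_stage_tsv(gene_norm, file.path(outdir, "norm_genes.tsv"), qparams)
    inform(paste0("quantify: ", nrow(cnt), " transcripts, ",
                  nrow(gene_counts), " genes, ", nrow(sheet), " samples"))

    if ("dosage" %in% stages) {
      stage <- "dosage"
      dparams <- paste0("dosage z_chrom=", z_chrom, " exclude=",
                        paste(exclude_chroms, collapse = ","),
                        " window=", window, " shift=", shift,
                        " norm=", norm_method)
      bias_all <- map_dfr(tissues, function(ti) {
        b <- sex_bias_table(gene_norm, sheet, annotation, ti,
                            exclude_chroms = exclude_chroms)
        inform(paste0("dosage/", ti, ": ", nrow(b), " of ", nrow(gene_norm),
                      " genes expressed in both sexes"))
        mutate(b, tissue = ti)
      })
      zaa_all <- map_dfr(tissues, function(ti) {
        map_dfr(c("F", "M"), function(sx) {
          tidy(z_aa_test(gene_cpm, sheet, annotation, ti, sx,
                         z_chrom = z_chrom,
                         exclude_chroms = exclude_chroms))
        })
      })
      zlen <- annotation$chromosomes$length[
        annotation$chromosomes$chrom == z_chrom]
      if (length(zlen) == 0L) abort(paste0("no chromosome named ", z_chrom))
      scan_all <- map_dfr(tissues, function(ti) {
        b <- bias_all[bias_all$tissue == ti & bias_all$chrom == z_chrom, ]
        mutate(window_scan(b, zlen, window = window, shift = shift),
               tissue = ti)
      })
      region_all <- map_dfr(tissues, function(ti) {
        mutate(top_region(scan_all[scan_all$tissue == ti, ]), tissue = ti)
      })
      write_stage_tsv(bias_all, file.path(outdir, "sex_bias.tsv"), dparams)
      write_stage_tsv(zaa_all, file.path(outdir, "zaa_tests.tsv"), dparams)
      write_stage_tsv(scan_all, file.path(outdir, "window_scan.tsv"), dparams)
      bed <- tibble(chrom = region_all$chrom,
                    start = format(region_all$region_start, scientific = FALSE),
                    end = format(region_all$region_end, scientific = FALSE),
                    name = paste0("top_region_", region_all$tissue))
      readr::write_tsv(bed, file.path(outdir, "top_region.bed"),
                       col_names = FALSE)
    }

    if ("splicing" %in% stages) {
      stage <- "splicing"
      sparams <- "splicing modes=5 min_delta=0.1 max_fdr=0.05"
      events <- classify_splice_events(annotation)
      inform(paste0("splicing: ", sum(events$event_type != "complex"),
                    " events (", sum(events$event_type == "complex"),
                    " complex) in ",
                    length(unique(events$gene_id)), " genes"))
      psi <- splice_psi(events, tx_norm)
      diffs <- map_dfr(tissues, function(ti) {
        differential_splicing(psi, sheet, ti)
      })
      uniq <- unique_transcripts(tx_norm, sheet)
      write_stage_tsv(events, file.path(outdir, "splice_events.tsv"), sparams)
      write_stage_tsv(psi, file.path(outdir, "psi.tsv"), sparams)
      write_stage_tsv(diffs, file.path(outdir, "diff_splice.tsv"), sparams)
      write_stage_tsv(uniq$membership,
                      file.path(outdir, "unique_transcripts.tsv"), sparams)
    }

    if ("lncrna" %in% stages) {
      stage <- "lncrna"
      if (is.null(noncoding)) {
        abort("lncrna stage requires noncoding labels")
      }
      lparams <- paste0("lncrna min_len=200 min_exons=2 max_dist=", max_dist)
      cand <- filter_lncrna_candidates(annotation, noncoding)
      inform(paste0("lncrna: ", nrow(cand), " of ", length(noncoding),
                    " labelled transcripts pass the candidate filter"))
      classes <- classify_lncrna(cand, annotation)
      targets <- assign_lncrna_targets(classes, annotation,
                                       max_dist = max_dist)
      lnc_expr <- tx_norm[tx_norm$feature_id %in% cand$transcript_id, ]
      bias_lnc <- map_dfr(tissues, function(ti) {
        lncrna_bias(lnc_expr, sheet, ti)
      })
      corr <- correlate_lncrna_targets(lnc_expr, gene_norm, targets)
      write_stage_tsv(classes, file.path(outdir, "lnc_classes.tsv"), lparams)
      write_stage_tsv(targets, file.path(outdir, "lnc_targets.tsv"), lparams)
      write_stage_tsv(bias_lnc, file.path(outdir, "lnc_bias.tsv"), lparams)
      write_stage_tsv(corr, file.path(outdir, "lnc_target_corr.tsv"), lparams)
    }

    if ("apa" %in% stages && !is.null(ends) && nrow(ends) > 0) {
      stage <- "apa"
      aparams <- paste0("apa merge_dist=", merge_dist, " min_support=",
                        min_support, " by=sex_tissue")
      sites <- cluster_polya_sites(ends, sheet, merge_dist = merge_dist,
                                   min_support = min_support)
      summ <- polya_sites_per_gene(sites)
      inform(paste0("apa: ", nrow(sites), " sites in ",
                    length(unique(sites$gene_id)), " genes"))
      sex_tests <- map_dfr(tissues, function(ti) {
        tidy(compare_polya_sex(summ$per_gene, ti))
      })
      write_stage_tsv(sites, file.path(outdir, "apa_sites.tsv"), aparams)
      write_stage_tsv(summ$per_gene, file.path(outdir, "apa_per_gene.tsv"),
                      aparams)
      write_stage_tsv(sex_tests, file.path(outdir, "apa_sex_test.tsv"),
                      aparams)
    }
    TRUE
  }, error = function(e) {
    writeLines(paste0("stage ", stage, " failed: ", conditionMessage(e)),
               failed_marker)
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)), parent = e)
  })

  summary <- summarize_run(outdir)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

#' Recompute the run summary from on-disk tables
#'
#' Reads only the pipeline's written tables (never in-memory state) and
#' recomputes per-stage record counts, key statistics and per-table MD5
#' checksums. Missing tables for stages that ran are an error naming the
#' table.
#'
#' @param outdir A [run_pipeline()] output directory.
#' @return A named list (the run summary).
#' @export
summarize_run <- function(outdir) {
  cfg_path <- file.path(outdir, "config.json")
  if (!file.exists(cfg_path)) abort("missing pipeline table: config.json")
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  stages <- cfg$stages
  summary <- list(
    package_version = as.character(utils::packageVersion("zdosage")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = stages
  )

  if ("dosage" %in% stages) {
    bias <- read_stage_tsv(file.path(outdir, "sex_bias.tsv"))
    zaa <- read_stage_tsv(file.path(outdir, "zaa_tests.tsv"))
    scan <- read_stage_tsv(file.path(outdir, "window_scan.tsv"))
    zc <- cfg$z_chrom
    per_tissue <- bias |>
      filter(!.data$outlier) |>
      group_by(.data$tissue) |>
      summarise(
        n_features = dplyr::n(),
        mean_z_log2_mf = mean(.data$log2_mf[.data$chrom == zc]),
        z_fold = 2^mean(.data$log2_mf[.data$chrom == zc]),
        mean_autosomal_log2_mf = mean(.data$log2_mf[.data$chrom != zc]),
        .groups = "drop"
      )
    summary$dosage <- list(
      per_tissue = as.data.frame(per_tissue),
      zaa = as.data.frame(zaa[c("tissue", "sex", "p.value", "median_ratio")]),
      top_region = as.data.frame(
        scan |>
          group_by(.data$tissue) |>
          group_modify(function(d, k) top_region(d)) |>
          ungroup() |>
          select("tissue", "chrom", "region_start", "region_end", "max_stat")
      )
    )
  }

  if ("splicing" %in% stages) {
    events <- read_stage_tsv(file.path(outdir, "splice_events.tsv"))
    diffs <- read_stage_tsv(file.path(outdir, "diff_splice.tsv"))
    tallies <- events |> count(.data$event_type, name = "n")
    five <- tallies[tallies$event_type != "complex", ]
    summary$splicing <- list(
      event_tallies = as.data.frame(tallies),
      pct_exon_skipping = 100 *
        sum(five$n[five$event_type == "exon_skipping"]) / sum(five$n),
      n_significant = sum(diffs$significant, na.rm = TRUE),
      n_tested = sum(!diffs$skipped)
    )
  }

  if ("lncrna" %in% stages) {
    classes <- read_stage_tsv(file.path(outdir, "lnc_classes.tsv"))
    bias_lnc <- read_stage_tsv(file.path(outdir, "lnc_bias.tsv"))
    targets <- read_stage_tsv(file.path(outdir, "lnc_targets.tsv"))
    summary$lncrna <- list(
      n_candidates = nrow(classes),
      class_percent = as.data.frame(
        classes |> count(.data$class) |>
          mutate(percent = 100 * .data$n / sum(.data$n))
      ),
      n_targets = nrow(targets),
      male_biased_per_tissue = as.data.frame(
        bias_lnc |> group_by(.data$tissue) |>
          summarise(n_male_biased = sum(.data$male_biased), .groups = "drop")
      )
    )
  }

  if ("apa" %in% stages &&
      file.exists(file.path(outdir, "apa_per_gene.tsv"))) {
    per_gene <- read_stage_tsv(file.path(outdir, "apa_per_gene.tsv"))
    sex_tests <- read_stage_tsv(file.path(outdir, "apa_sex_test.tsv"))
    summary$apa <- list(
      frac_multi = as.data.frame(
        per_gene |> group_by(.data$group) |>
          summarise(n_genes = dplyr::n(),
                    frac_multi = mean(.data$n_sites >= 2), .groups = "drop")
      ),
      sex_test = as.data.frame(sex_tests)
    )
  }

  tables <- sort(setdiff(list.files(outdir, pattern = "\\.(tsv|bed|gtf|json)$"),
                         c("summary.json")))
  md5 <- tools::md5sum(file.path(outdir, tables))
  summary$table_md5 <- as.list(setNames(unname(md5), tables))
  summary
}

#' Verify the integrity of a pipeline output directory
#'
#' Recomputes the summary (including per-table checksums) from disk and
#' compares it with the stored `summary.json`. Any edited table changes its
#' checksum and fails the check.
#'
#' @param outdir A [run_pipeline()] output directory.
#' @return `TRUE` if the stored summary matches the recomputed one.
#' @export
verify_run <- function(outdir) {
  stored_path <- file.path(outdir, "summary.json")
  if (!file.exists(stored_path)) abort("missing summary.json")
  stored <- jsonlite::read_json(stored_path, simplifyVector = TRUE)
  fresh <- jsonlite::parse_json(
    jsonlite::toJSON(summarize_run(outdir), auto_unbox = TRUE, digits = NA,
                     null = "null"),
    simplifyVector = TRUE
  )
  isTRUE(all.equal(stored, fresh, tolerance = 1e-12))
}
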