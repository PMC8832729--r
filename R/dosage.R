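# Sex-bias ratio statistics, Z:AA comparisons and the sliding-window scan.

#' Per-feature sex-bias table
#'
#' One record per feature expressed in both sexes (`mean > 0` in each) within
#' the tissue, positioned at the feature's span midpoint. `log2_mf` is
#' computed without pseudocount (zero-expression features are already
#' excluded); `amplitude = |log2_mf|`; features with amplitude above
#' `outlier_cutoff` are flagged, retained in the table, and excluded from
#' window means downstream.
#'
#' @param expr Wide normalized expression tibble (gene- or transcript-level).
#' @param samples Sample sheet.
#' @param annotation A [genome_annotation()] providing positions.
#' @param tissue Tissue label.
#' @param exclude_chroms Chromosomes dropped from the analysis
#'   (default `c("W", "31", "33")`).
#' @param outlier_cutoff Amplitude above which a record is flagged
#'   (default 5).
#' @param level `"gene"` or `"transcript"`: which annotation table the
#'   feature ids refer to.
#' @return Tibble of class `sex_bias_tbl` with columns `feature_id`, `chrom`,
#'   `position`, `mean_M`, `mean_F`, `log2_mf`, `amplitude`, `outlier`.
#' @export
sex_bias_table <- function(expr, samples, annotation, tissue,
                           exclude_chroms = c("W", "31", "33"),
                           outlier_cutoff = 5, level = c("gene", "transcript")) {
  level <- match.arg(level)
  feats <- if (level == "gene") {
    annotation$genes |> select(feature_id = "gene_id", "chrom", "start", "end")
  } else {
    annotation$transcripts |>
      select(feature_id = "transcript_id", "chrom", "start", "end")
  }
  missing_ids <- setdiff(expr$feature_id, feats$feature_id)
  if (length(missing_ids) > 0) {
    abort(paste0("feature(s) in expression matrix missing from annotation: ",
                 paste(head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) " ..." else ""))
  }
  gm <- group_means(expr, samples, tissue)
  out <- gm |>
    left_join(feats, by = "feature_id") |>
    filter(!.data$chrom %in% exclude_chroms,
           .data$mean_M > 0, .data$mean_F > 0) |>
    mutate(
      position = (.data$start + .data$end) %/% 2L,
      log2_mf = log2(.data$mean_M / .data$mean_F),
      amplitude = abs(.data$log2_mf),
      outlier = .data$amplitude > outlier_cutoff
    ) |>
    select("feature_id", "chrom", "position", "mean_M", "mean_F",
           "log2_mf", "amplitude", "outlier")
  class(out) <- c("sex_bias_tbl", class(out))
  out
}

#' Z-versus-autosome expression comparison within one sex
#'
#' Compares per-feature `log2(normalized + offset)` expression (mean over the
#' sex's replicates in the tissue) between Z-linked and autosomal features
#' with [wilcoxon_rank_sum()]. Within-sample comparisons are invariant to the
#' library-size normalization method.
#'
#' @inheritParams sex_bias_table
#' @param sex `"M"` or `"F"`.
#' @param z_chrom Name of the Z chromosome (default `"Z"`).
#' @param offset Added inside the log (default 1), admitting zeros.
#' @param mode Wilcoxon mode passed through.
#' @return A list of class `zaa_test`: `tissue`, `sex`, `n_z`, `n_aa`,
#'   `statistic`, `p_value`, `median_z`, `median_aa`, `median_ratio`
#'   (of the back-transformed medians).
#' @export
z_aa_test <- function(expr, samples, annotation, tissue, sex, z_chrom = "Z",
                      exclude_chroms = c("W", "31", "33"), offset = 1,
                      mode = "auto", level = c("gene", "transcript")) {
  level <- match.arg(level)
  feats <- if (level == "gene") {
    annotation$genes |> select(feature_id = "gene_id", "chrom")
  } else {
    annotation$transcripts |> select(feature_id = "transcript_id", "chrom")
  }
  samples <- validate_sample_sheet(samples)
  sel <- samples[samples$tissue == tissue & samples$sex == sex, ]
  if (nrow(sel) == 0L) abort("no samples for that sex/tissue")
  vals <- tibble(
    feature_id = expr$feature_id,
    value = log2(rowMeans(as.matrix(expr[, sel$sample_id, drop = FALSE])) +
                   offset)
  ) |>
    left_join(feats, by = "feature_id") |>
    filter(!.data$chrom %in% exclude_chroms)
  z_vals <- vals$value[vals$chrom == z_chrom]
  aa_vals <- vals$value[vals$chrom != z_chrom]
  if (length(z_vals) == 0L) abort("empty Z-linked feature set")
  if (length(aa_vals) == 0L) abort("empty autosomal feature set")
  ht <- wilcoxon_rank_sum(z_vals, aa_vals, mode = mode)
  med_z <- median(z_vals)
  med_aa <- median(aa_vals)
  out <- list(
    tissue = tissue, sex = sex, n_z = length(z_vals), n_aa = length(aa_vals),
    statistic = ht$statistic, p_value = ht$p_value, mode = ht$mode,
    median_z = med_z, median_aa = med_aa,
    median_ratio = (2^med_z - offset) / (2^med_aa - offset)
  )
  class(out) <- "zaa_test"
  out
}

#' @export
print.zaa_test <- function(x, ...) {
  cat("Z:AA comparison - tissue ", x$tissue, ", sex ", x$sex, "\n",
      "  n(Z) = ", x$n_z, ", n(AA) = ", x$n_aa, "\n",
      "  median log2 expr: Z = ", round(x$median_z, 3),
      ", AA = ", round(x$median_aa, 3), "\n",
      "  Wilcoxon W = ", format(x$statistic), ", p = ",
      format.pval(x$p_value), " (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Tidiers for test objects
#'
#' `tidy()` returns the per-test statistics as a one-row tibble; `glance()`
#' is an alias for the test objects in this package.
#'
#' @param x A `rank_sum_test`, `zaa_test` or `polya_sex_test` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.zaa_test <- function(x, ...) {
  tibble(tissue = x$tissue, sex = x$sex, n_z = x$n_z, n_aa = x$n_aa,
         statistic = x$statistic, p.value = x$p_value,
         median_z = x$median_z, median_aa = x$median_aa,
         median_ratio = x$median_ratio, mode = x$mode)
}

#' @rdname tidiers
#' @export
glance.zaa_test <- function(x, ...) tidy.zaa_test(x)

#' Sliding-window scan of sex bias along one chromosome
#'
#' Windows of `window` bp tile `[0, chrom_len)` every `shift` bp (half-open;
#' the final windows may be partial). A feature belongs to every window
#' containing its midpoint. Outlier-flagged records are excluded from window
#' means; empty windows carry `NA` means.
#'
#' @param bias A [sex_bias_table()] restricted to one chromosome (rows on
#'   other chromosomes are an error).
#' @param chrom_length Length of the chromosome in bp.
#' @param window Window size in bp (default 3e6).
#' @param shift Step size in bp (default 1e6); must not exceed `window`.
#' @return Tibble of class `window_scan_tbl` with columns `chrom`,
#'   `window_start`, `window_end` (0-based half-open), `n_genes`,
#'   `mean_log2_mf`, `mean_amplitude`.
#' @export
window_scan <- function(bias, chrom_length, window = 3e6, shift = 1e6) {
  if (window < shift) abort("window must be >= shift")
  chroms <- unique(bias$chrom)
  if (length(chroms) > 1L) {
    abort("window_scan expects records from a single chromosome")
  }
  starts <- seq(0, max(chrom_length - 1, 0), by = shift)
  ends <- pmin(starts + window, chrom_length)
  chrom <- if (length(chroms) == 1L) chroms else NA_character_
  used <- bias[!bias$outlier, ]
  rows <- map_dfr(seq_along(starts), function(i) {
    inw <- used$position > starts[i] & used$position <= ends[i]
    n <- sum(inw)
    tibble(
      chrom = chrom, window_start = starts[i], window_end = ends[i],
      n_genes = n,
      mean_log2_mf = if (n > 0) mean(used$log2_mf[inw]) else NA_real_,
      mean_amplitude = if (n > 0) mean(used$amplitude[inw]) else NA_real_
    )
  })
  class(rows) <- c("window_scan_tbl", class(rows))
  rows
}

#' Top sex-biased region of a window scan
#'
#' Takes the window maximising the chosen statistic and merges it with
#' adjacent overlapping windows whose statistic is within `within` (a
#' fraction of the maximum's absolute value) of the maximum; ties are broken
#' by leftmost start.
#'
#' @param scan A [window_scan()] result.
#' @param stat `"mean_log2_mf"` or `"mean_amplitude"`.
#' @param within Merge tolerance as a fraction of `|max|` (default 0.1).
#' @return One-row tibble: `chrom`, `region_start`, `region_end`, `stat`,
#'   `max_stat`, `n_windows`.
#' @export
top_region <- function(scan, stat = c("mean_log2_mf", "mean_amplitude"),
                       within = 0.1) {
  stat <- match.arg(stat)
  vals <- scan[[stat]]
  if (all(is.na(vals))) abort("all windows are empty")
  mx <- max(vals, na.rm = TRUE)
  thr <- mx - within * abs(mx)
  best <- which(vals == mx)[1]  # leftmost on ties (scan is start-ordered)
  cand <- which(!is.na(vals) & vals >= thr)
  # connected run of overlapping candidate windows containing the argmax
  run <- best
  i <- best
  while (TRUE) {
    nxt <- cand[cand > i & scan$window_start[cand] < scan$window_end[i]]
    if (length(nxt) == 0) break
    i <- min(nxt)
    run <- c(run, i)
  }
  i <- best
  while (TRUE) {
    prv <- cand[cand < i & scan$window_end[cand] > scan$window_start[i]]
    if (length(prv) == 0) break
    i <- max(prv)
    run <- c(run, i)
  }
  run <- sort(unique(run))
  tibble(
    chrom = scan$chrom[best],
    region_start = min(scan$window_start[run]),
    region_end = max(scan$window_end[run]),
    stat = stat, max_stat = mx, n_windows = length(run)
  )
}

#' Chromosome-level fold summaries of a sex-bias table
#'
#' Reports, per chromosome group (Z vs autosomes), three labelled versions of
#' the male:female fold: mean and median of per-feature ratios, and the ratio
#' of aggregate (summed) expression. Outlier-flagged records are excluded.
#'
#' @param bias A [sex_bias_table()].
#' @param z_chrom Name of the Z chromosome.
#' @return Tibble with one row per group and columns `group`, `n`,
#'   `mean_log2_mf`, `fold_mean_of_ratios`, `fold_median_of_ratios`,
#'   `fold_of_sums`.
#' @export
fold_summary <- function(bias, z_chrom = "Z") {
  bias |>
    filter(!.data$outlier) |>
    mutate(group = ifelse(.data$chrom == z_chrom, "Z", "autosome")) |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      mean_log2_mf = mean(.data$log2_mf),
      fold_mean_of_ratios = mean(.data$mean_M / .data$mean_F),
      fold_median_of_ratios = median(.data$mean_M / .data$mean_F),
      fold_of_sums = sum(.data$mean_M) / sum(.data$mean_F),
      .groups = "drop"
    )
}
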