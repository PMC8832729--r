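# Normalization and group summaries.

#' Library-size normalization of a count matrix
#'
#' `method = "cpm"` divides each column by its sum and multiplies by `scale`
#' (counts per million with the default `scale = 1e6`; the per-10,000-reads
#' convention is `scale = 1e4`). `method = "median_ratio"` uses
#' median-of-ratios size factors computed on a reference feature set
#' (default: all features), rescaled so columns stay on the `scale` scale on
#' average; anchoring the reference on autosomal features keeps unbiased
#' features centred when a large feature subset is systematically shifted in
#' one sex (the compositional bias of total-count scaling under incomplete
#' dosage compensation). `method = "tmm"` uses trimmed-mean-of-M effective
#' library sizes (edgeR). With non-CPM methods columns no longer sum exactly
#' to `scale`. An all-zero column yields an all-zero output column.
#'
#' @param counts Wide count tibble (`feature_id` + one numeric column per
#'   sample).
#' @param scale Positive scale constant (default 1e6).
#' @param method `"cpm"`, `"median_ratio"` or `"tmm"`.
#' @param reference_features Feature ids anchoring the `median_ratio` size
#'   factors (ignored otherwise).
#' @return Tibble of the same shape with attribute `unit = "per_scale"`.
#' @export
normalize_counts <- function(counts, scale = 1e6,
                             method = c("cpm", "median_ratio", "tmm"),
                             reference_features = NULL) {
  method <- match.arg(method)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    abort("scale must be a single positive number")
  }
  unit <- attr(counts, "unit")
  if (!is.null(unit) && !identical(unit, "raw_counts")) {
    abort("normalize_counts expects raw counts (unit 'raw_counts')")
  }
  mat <- as.matrix(counts[, -1])
  if (any(mat < 0)) abort("negative counts")
  lib <- colSums(mat)
  if (method == "tmm" && any(lib > 0)) {
    nf <- edgeR::calcNormFactors(mat[, lib > 0, drop = FALSE], method = "TMM")
    lib[lib > 0] <- lib[lib > 0] * nf
  } else if (method == "median_ratio" && any(lib > 0)) {
    sf <- size_factors_median_ratio(counts, reference_features)
    # rescale factors to the library-size scale so `scale` keeps its meaning
    pos <- lib > 0
    lib[pos] <- sf[pos] * mean(lib[pos] / sf[pos])
  }
  div <- ifelse(lib > 0, lib, 1)  # all-zero column stays all-zero
  out_mat <- sweep(mat, 2, div, "/") * scale
  out <- bind_cols(counts[, 1], as_tibble(out_mat))
  attr(out, "unit") <- "per_scale"
  out
}

#' Median-of-ratios size factors
#'
#' Per sample, the median ratio of counts to the per-feature geometric mean
#' across samples, computed over `reference_features` (features with a zero
#' in any sample are dropped from the reference, as usual for geometric-mean
#' references).
#'
#' @param counts Wide count tibble.
#' @param reference_features Feature ids to anchor on (default all).
#' @return Named numeric vector of size factors (one per sample).
#' @export
size_factors_median_ratio <- function(counts, reference_features = NULL) {
  mat <- as.matrix(counts[, -1])
  rownames(mat) <- counts$feature_id
  if (!is.null(reference_features)) {
    mat <- mat[rownames(mat) %in% reference_features, , drop = FALSE]
  }
  keep <- rowSums(mat == 0) == 0
  if (sum(keep) < 10L) {
    abort("fewer than 10 all-positive reference features for median-ratio size factors")
  }
  ref <- mat[keep, , drop = FALSE]
  gm <- exp(rowMeans(log(ref)))
  apply(ref, 2, function(col) median(col / gm))
}

#' Sum transcript-level counts to gene level
#'
#' @param counts Wide transcript-level count tibble.
#' @param annotation A [genome_annotation()] providing the
#'   transcript-to-gene map.
#' @return Wide gene-level tibble (same unit attribute).
#' @export
aggregate_to_genes <- function(counts, annotation) {
  map <- annotation$transcripts[c("transcript_id", "gene_id")]
  missing_tx <- setdiff(counts$feature_id, map$transcript_id)
  if (length(missing_tx) > 0) {
    abort(paste0("feature(s) absent from annotation: ",
                 paste(head(missing_tx, 5), collapse = ", ")))
  }
  long <- counts |>
    left_join(map, by = c(feature_id = "transcript_id")) |>
    select(-"feature_id") |>
    group_by(feature_id = .data$gene_id) |>
    summarise(across(where(is.numeric), sum), .groups = "drop")
  attr(long, "unit") <- attr(counts, "unit")
  long
}

#' Per-feature mean expression by sex within one tissue
#'
#' Arithmetic mean of (normalized) values over the replicates of each sex.
#'
#' @param expr Wide expression tibble.
#' @param samples Sample sheet.
#' @param tissue Tissue label to restrict to.
#' @return Tibble with columns `feature_id`, `mean_M`, `mean_F`.
#' @export
group_means <- function(expr, samples, tissue) {
  samples <- validate_sample_sheet(samples)
  sel <- samples[samples$tissue == tissue, ]
  if (nrow(sel) == 0L) abort(paste0("tissue not in sample sheet: ", tissue))
  for (sx in c("M", "F")) {
    if (!any(sel$sex == sx)) {
      abort(paste0("tissue ", tissue, " has no ", sx, " samples"))
    }
  }
  missing_cols <- setdiff(sel$sample_id, names(expr))
  if (length(missing_cols) > 0) {
    abort(paste0("expression matrix lacks sample column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  m_cols <- sel$sample_id[sel$sex == "M"]
  f_cols <- sel$sample_id[sel$sex == "F"]
  tibble(
    feature_id = expr$feature_id,
    mean_M = rowMeans(as.matrix(expr[, m_cols, drop = FALSE])),
    mean_F = rowMeans(as.matrix(expr[, f_cols, drop = FALSE]))
  )
}

#' Expressed-feature filter
#'
#' The default rule `both_sexes` keeps a feature iff both sex means exceed
#' the threshold (the "expressed in both sexes" convention used for ratio
#' analyses, threshold 0). `any`/`all` apply the threshold across individual
#' samples instead.
#'
#' @param expr Wide normalized expression tibble.
#' @param samples Sample sheet.
#' @param tissue Tissue label.
#' @param threshold Expression threshold (strict `>`).
#' @param rule One of `"both_sexes"`, `"any"`, `"all"`.
#' @return Logical vector along the rows of `expr`.
#' @export
expressed_features <- function(expr, samples, tissue, threshold = 0,
                               rule = c("both_sexes", "any", "all")) {
  rule <- match.arg(rule)
  samples <- validate_sample_sheet(samples)
  sel <- samples[samples$tissue == tissue, ]
  mat <- as.matrix(expr[, sel$sample_id, drop = FALSE])
  if (rule == "both_sexes") {
    gm <- group_means(expr, samples, tissue)
    return(gm$mean_M > threshold & gm$mean_F > threshold)
  }
  if (rule == "any") return(apply(mat > threshold, 1, any))
  apply(mat > threshold, 1, all)
}
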