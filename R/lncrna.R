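# lncRNA candidate filtering, positional classification, cis-target
# assignment, sex-bias calls and lncRNA-target correlation.
#
# Classification is purely positional relative to the protein-coding
# annotation; coding-potential scoring and base-complementarity target
# models are out of scope (noncoding labels are supplied externally).

#' Filter lncRNA candidate transcripts
#'
#' Keeps transcripts with spliced length strictly greater than `min_len`,
#' at least `min_exons` exons, and an external noncoding label. The default
#' exon rule is the standard multi-exon filter (`min_exons = 2`); the
#' stricter more-than-two-exons reading is `min_exons = 3`.
#'
#' @param annotation A [genome_annotation()].
#' @param noncoding Character vector of noncoding transcript ids, or a
#'   tibble with columns `transcript_id` and a logical `noncoding`.
#' @param min_len Minimum spliced length in nt, exclusive (default 200).
#' @param min_exons Minimum exon count, inclusive (default 2).
#' @return Tibble of candidate transcripts (`transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `n_exons`, `length`).
#' @export
filter_lncrna_candidates <- function(annotation, noncoding, min_len = 200,
                                     min_exons = 2) {
  if (is.data.frame(noncoding)) {
    noncoding <- noncoding$transcript_id[noncoding$noncoding]
  }
  annotation$transcripts |>
    filter(.data$transcript_id %in% noncoding,
           .data$length > min_len,
           .data$n_exons >= min_exons)
}

# introns of every transcript of one gene, as a tibble
gene_introns <- function(annotation, gene_id) {
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  split(ex, ex$transcript_id) |>
    map_dfr(function(e) transcript_introns(e$start, e$end))
}

#' Positional classification of lncRNA candidates
#'
#' Each candidate receives exactly one class by precedence:
#' (1) no overlap with any coding gene span -> `lincRNA`;
#' (2) exonic overlap with a coding exon on the opposite strand ->
#' `antisense`; (3) exonic overlap with a coding exon on the same strand ->
#' `sense`; (4) fully contained in a coding transcript's intron (same strand
#' unless `intronic_any_strand`) with no exonic overlap -> `intronic`;
#' remaining span-overlap cases resolve to `intronic` when the strand rule
#' admits them, else `antisense`. Candidates on chromosomes without coding
#' genes are `lincRNA`.
#'
#' @param candidates Tibble from [filter_lncrna_candidates()].
#' @param annotation A [genome_annotation()]; only genes with biotype
#'   `"coding"` are used as the reference.
#' @param intronic_any_strand Accept opposite-strand intronic containment
#'   (default `FALSE`: same strand required).
#' @return `candidates` with an added `class` column.
#' @export
classify_lncrna <- function(candidates, annotation,
                            intronic_any_strand = FALSE) {
  coding <- annotation$genes |> filter(.data$biotype == "coding")
  coding_tx <- annotation$transcripts |>
    filter(.data$gene_id %in% coding$gene_id)
  coding_ex <- annotation$exons |>
    filter(.data$gene_id %in% coding$gene_id)

  classify_one <- function(tid, chrom, strand, start, end) {
    g <- coding[coding$chrom == chrom &
                coding$start <= end & coding$end >= start, ]
    if (nrow(g) == 0L) return("lincRNA")
    lex <- annotation$exons[annotation$exons$transcript_id == tid, ]
    cex <- coding_ex[coding_ex$gene_id %in% g$gene_id, ]
    ex_olap <- function(target_strand) {
      hit <- cex[cex$strand == target_strand, ]
      if (nrow(hit) == 0L) return(FALSE)
      any(map_lgl(seq_len(nrow(lex)), function(i) {
        any(hit$start <= lex$end[i] & hit$end >= lex$start[i])
      }))
    }
    opp <- if (strand == "+") "-" else "+"
    if (ex_olap(opp)) return("antisense")
    if (ex_olap(strand)) return("sense")
    # intronic: whole span inside one intron of a coding transcript
    host_tx <- coding_tx[coding_tx$gene_id %in% g$gene_id, ]
    if (!intronic_any_strand) host_tx <- host_tx[host_tx$strand == strand, ]
    for (gid in unique(host_tx$gene_id)) {
      intr <- gene_introns(annotation, gid)
      if (nrow(intr) > 0 && any(intr$start <= start & intr$end >= end)) {
        return("intronic")
      }
    }
    "antisense"
  }
  candidates |>
    mutate(class = purrr::pmap_chr(
      list(.data$transcript_id, .data$chrom, .data$strand,
           .data$start, .data$end),
      classify_one
    ))
}

#' Assign cis target genes to lncRNAs by proximity
#'
#' Every coding gene whose span lies strictly within `max_dist` bp of the
#' lncRNA span is a target (gap distance between spans; overlap = 0). The
#' upstream/downstream relation is judged in the lncRNA's strand
#' orientation; the reported `distance` is signed (negative upstream,
#' positive downstream, 0 overlapping).
#'
#' @param lncs Tibble of lncRNAs (`transcript_id`, `chrom`, `strand`,
#'   `start`, `end`), e.g. from [classify_lncrna()].
#' @param annotation A [genome_annotation()] (coding genes used).
#' @param max_dist Strict distance bound in bp (default 1e5).
#' @return Tibble with columns `lncrna_id`, `gene_id`, `distance`,
#'   `relation`.
#' @export
assign_lncrna_targets <- function(lncs, annotation, max_dist = 100000) {
  coding <- annotation$genes |> filter(.data$biotype == "coding")
  rows <- map_dfr(seq_len(nrow(lncs)), function(i) {
    cand <- coding[coding$chrom == lncs$chrom[i], ]
    if (nrow(cand) == 0L) return(NULL)
    gap <- pmax(0L, pmax(cand$start, lncs$start[i]) -
                     pmin(cand$end, lncs$end[i]) - 1L)
    hit <- which(gap < max_dist)
    if (length(hit) == 0L) return(NULL)
    cand <- cand[hit, ]
    gap <- gap[hit]
    overlapping <- cand$start <= lncs$end[i] & cand$end >= lncs$start[i]
    gene_is_left <- cand$end < lncs$start[i]
    # in lncRNA orientation: on '+', left = upstream; on '-', left = downstream
    plus <- lncs$strand[i] == "+"
    relation <- dplyr::case_when(
      overlapping ~ "overlapping",
      gene_is_left == plus ~ "upstream",
      TRUE ~ "downstream"
    )
    tibble(
      lncrna_id = lncs$transcript_id[i],
      gene_id = cand$gene_id,
      distance = as.integer(ifelse(relation == "upstream", -gap, gap)),
      relation = relation
    )
  })
  if (nrow(rows) == 0L) {
    return(tibble(lncrna_id = character(), gene_id = character(),
                  distance = integer(), relation = character()))
  }
  arrange(rows, .data$lncrna_id, .data$gene_id)
}

#' Male-bias calls for lncRNAs
#'
#' `log2_mf` per lncRNA via the sex-bias conventions (means over replicates
#' of normalized expression within the tissue); `male_biased` iff
#' `log2_mf > 0` with both sex means positive.
#'
#' @param expr Wide normalized lncRNA expression tibble (transcript-level).
#' @param samples Sample sheet.
#' @param tissue Tissue label.
#' @return Tibble with columns `lncrna_id`, `tissue`, `mean_M`, `mean_F`,
#'   `log2_mf`, `male_biased`.
#' @export
lncrna_bias <- function(expr, samples, tissue) {
  gm <- group_means(expr, samples, tissue)
  gm |>
    mutate(
      tissue = tissue,
      log2_mf = ifelse(.data$mean_M > 0 & .data$mean_F > 0,
                       log2(.data$mean_M / .data$mean_F), NA_real_),
      male_biased = !is.na(.data$log2_mf) & .data$log2_mf > 0
    ) |>
    select(lncrna_id = "feature_id", "tissue", "mean_M", "mean_F",
           "log2_mf", "male_biased")
}

#' Correlate lncRNA expression with assigned target genes
#'
#' Rank (Spearman) and linear (Pearson) correlation across all shared
#' samples for every (lncRNA, target) pair. Pairs with a zero-variance
#' vector are flagged and carry `NA` correlations.
#'
#' @param lnc_expr Wide lncRNA expression tibble (`feature_id` = lncRNA ids).
#' @param target_expr Wide gene-level expression tibble.
#' @param pairs Tibble with columns `lncrna_id`, `gene_id` (e.g. from
#'   [assign_lncrna_targets()]).
#' @return `pairs` with added `spearman`, `pearson`, `defined`.
#' @export
correlate_lncrna_targets <- function(lnc_expr, target_expr, pairs) {
  shared <- intersect(names(lnc_expr)[-1], names(target_expr)[-1])
  if (length(shared) < 3L) abort("need at least 3 shared samples")
  lmat <- as.matrix(lnc_expr[, shared])
  rownames(lmat) <- lnc_expr$feature_id
  tmat <- as.matrix(target_expr[, shared])
  rownames(tmat) <- target_expr$feature_id
  res <- pairs |>
    mutate(
      spearman = NA_real_, pearson = NA_real_, defined = FALSE
    )
  for (i in seq_len(nrow(res))) {
    if (!res$lncrna_id[i] %in% rownames(lmat) ||
        !res$gene_id[i] %in% rownames(tmat)) next
    a <- lmat[res$lncrna_id[i], ]
    b <- tmat[res$gene_id[i], ]
    if (sd(a) == 0 || sd(b) == 0) next
    res$spearman[i] <- cor(a, b, method = "spearman")
    res$pearson[i] <- cor(a, b, method = "pearson")
    res$defined[i] <- TRUE
  }
  res
}
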