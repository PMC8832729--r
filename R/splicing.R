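# Alternative-splicing event classification among a gene's isoforms, PSI
# computation, differential splicing and group-unique transcripts.
#
# Events are defined on pairs of intron chains and merged across pairs by
# (type, coordinates). Only the five canonical modes are emitted as events;
# pairwise structural differences that fit none of them are reported with
# event_type "complex". Terminal-exon differences are not splicing events.

# pairwise comparison of two transcripts; returns rows with event_type,
# event_start, event_end, inclusion/exclusion transcript ids, and (for MXE
# candidates) the two exon intervals for the gene-level co-occurrence check
pair_events <- function(ex1, ex2, id1, id2, strand) {
  i1 <- transcript_introns(ex1$start, ex1$end)
  i2 <- transcript_introns(ex2$start, ex2$end)
  key1 <- paste(i1$start, i1$end)
  key2 <- paste(i2$start, i2$end)
  u1 <- which(!key1 %in% key2)
  u2 <- which(!key2 %in% key1)
  if (length(u1) == 0L && length(u2) == 0L) return(NULL)

  rows <- list()
  used1 <- logical(nrow(i1))
  used2 <- logical(nrow(i2))

  add <- function(type, s, e, incl, excl, x1s = NA_integer_,
                  x1e = NA_integer_, x2s = NA_integer_, x2e = NA_integer_) {
    rows[[length(rows) + 1L]] <<- tibble(
      event_type = type, event_start = as.integer(s), event_end = as.integer(e),
      inclusion = incl, exclusion = excl,
      mxe_a_start = x1s, mxe_a_end = x1e, mxe_b_start = x2s, mxe_b_end = x2e
    )
  }

  # intron retention: one chain lacks an intron of the other while covering
  # it exonically (flanking bases included); the retainer is the inclusion
  ir_scan <- function(iu, ia, ib, exb, ida, idb, useda, usedb) {
    for (k in iu) {
      s <- ia$start[k]; e <- ia$end[k]
      if (any(ib$start <= e & ib$end >= s)) next
      if (any(exb$start <= s - 1L & exb$end >= e + 1L)) {
        add("intron_retention", s, e, incl = idb, excl = ida)
        useda[k] <- TRUE
      }
    }
    useda
  }
  used1 <- ir_scan(u1, i1, i2, ex2, id1, id2, used1, used2)
  used2 <- ir_scan(u2, i2, i1, ex1, id2, id1, used2, used1)

  # exon skipping: an exon of one chain strictly inside an intron of the
  # other, with both flanking splice sites shared
  es_scan <- function(iu, ia, ib, exb, ida, idb, useda) {
    for (k in iu) {
      a <- ia$start[k]; b <- ia$end[k]
      inside <- which(exb$start > a & exb$end < b)
      for (x in inside) {
        left_ok <- any(ib$start == a & ib$end == exb$start[x] - 1L)
        right_ok <- any(ib$start == exb$end[x] + 1L & ib$end == b)
        if (left_ok && right_ok) {
          add("exon_skipping", exb$start[x], exb$end[x],
              incl = idb, excl = ida)
          useda[k] <- TRUE
        }
      }
    }
    useda
  }
  used1 <- es_scan(u1, i1, i2, ex2, id1, id2, used1)
  used2 <- es_scan(u2, i2, i1, ex1, id2, id1, used2)
  # mark the two flanking introns of a detected skipped exon as consumed
  consume_flanks <- function(used, introns, key_other, rows) {
    for (r in rows) {
      if (is.null(r) || r$event_type[1] != "exon_skipping") next
      used[introns$end == r$event_start[1] - 1L |
           introns$start == r$event_end[1] + 1L] <- TRUE
    }
    used
  }
  used1 <- consume_flanks(used1, i1, key2, rows)
  used2 <- consume_flanks(used2, i2, key1, rows)

  # alternative 5'/3' splice sites: two introns sharing one boundary; the
  # variable region must lie within the adjacent exon of the longer-exon
  # (inclusion) transcript
  region_in_exon <- function(ex, s, e) any(ex$start <= s & ex$end >= e)
  for (k in u1) {
    for (l in u2) {
      s1 <- i1$start[k]; e1 <- i1$end[k]
      s2 <- i2$start[l]; e2 <- i2$end[l]
      if (e1 == e2 && s1 != s2) {
        rs <- min(s1, s2); re <- max(s1, s2) - 1L
        incl_is_1 <- s1 > s2  # later intron start = longer exon
        exi <- if (incl_is_1) ex1 else ex2
        if (!region_in_exon(exi, rs, re)) next
        type <- if (strand == "+") "alt_5ss" else "alt_3ss"
        add(type, rs, re,
            incl = if (incl_is_1) id1 else id2,
            excl = if (incl_is_1) id2 else id1)
        used1[k] <- TRUE; used2[l] <- TRUE
      } else if (s1 == s2 && e1 != e2) {
        rs <- min(e1, e2) + 1L; re <- max(e1, e2)
        incl_is_1 <- e1 < e2  # earlier intron end = longer exon
        exi <- if (incl_is_1) ex1 else ex2
        if (!region_in_exon(exi, rs, re)) next
        type <- if (strand == "+") "alt_3ss" else "alt_5ss"
        add(type, rs, re,
            incl = if (incl_is_1) id1 else id2,
            excl = if (incl_is_1) id2 else id1)
        used1[k] <- TRUE; used2[l] <- TRUE
      }
    }
  }

  # mutually exclusive exons: internal exons X1 (t1 only) and X2 (t2 only),
  # non-overlapping, inside the same pair of shared outer splice sites;
  # the gene-level never-co-occur condition is checked by the caller
  internal <- function(ex) which(seq_len(nrow(ex)) > 1L &
                                 seq_len(nrow(ex)) < nrow(ex))
  exkey1 <- paste(ex1$start, ex1$end)
  exkey2 <- paste(ex2$start, ex2$end)
  for (xi in internal(ex1)) {
    if (exkey1[xi] %in% exkey2) next
    a1 <- ex1$end[xi - 1L] + 1L; b1 <- ex1$start[xi + 1L] - 1L
    for (xj in internal(ex2)) {
      if (exkey2[xj] %in% exkey1) next
      a2 <- ex2$end[xj - 1L] + 1L; b2 <- ex2$start[xj + 1L] - 1L
      if (a1 != a2 || b1 != b2) next
      if (ex1$end[xi] >= ex2$start[xj] && ex2$end[xj] >= ex1$start[xi]) next
      s <- min(ex1$start[xi], ex2$start[xj])
      e <- max(ex1$end[xi], ex2$end[xj])
      first_is_1 <- ex1$start[xi] < ex2$start[xj]
      add("mutually_exclusive_exons", s, e,
          incl = if (first_is_1) id1 else id2,
          excl = if (first_is_1) id2 else id1,
          x1s = ex1$start[xi], x1e = ex1$end[xi],
          x2s = ex2$start[xj], x2e = ex2$end[xj])
      used1[i1$start == a1 | i1$end == b1] <- TRUE
      used2[i2$start == a2 | i2$end == b2] <- TRUE
    }
  }

  # unmatched unique introns are pairwise-complex residue
  for (k in u1[!used1[u1]]) {
    add("complex", i1$start[k], i1$end[k], incl = id2, excl = id1)
  }
  for (k in u2[!used2[u2]]) {
    add("complex", i2$start[k], i2$end[k], incl = id1, excl = id2)
  }
  bind_rows(rows)
}

#' Classify alternative-splicing events within genes
#'
#' Compares every unordered pair of isoforms per gene and classifies their
#' structural differences into the five canonical modes (exon skipping,
#' intron retention, alternative 5'/3' splice site - donor/acceptor resolved
#' by strand - and mutually exclusive exons). Events found in several pairs
#' are merged by (type, coordinates), accumulating inclusion and exclusion
#' transcript sets. Differences matching none of the five modes are returned
#' with `event_type = "complex"`. Single-transcript genes yield no events.
#'
#' @param annotation A [genome_annotation()].
#' @param gene_ids Optional subset of gene ids.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `event_type`,
#'   `event_start`, `event_end` (1-based inclusive), `inclusion`,
#'   `exclusion` (list columns of transcript ids), `event_id`.
#' @export
classify_splice_events <- function(annotation, gene_ids = NULL) {
  tx <- annotation$transcripts
  ex <- annotation$exons
  genes <- annotation$genes
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids, ]
  genes <- genes[genes$n_transcripts >= 2L, ]
  empty <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    event_type = character(), event_start = integer(), event_end = integer(),
    inclusion = list(), exclusion = list(), event_id = character()
  )
  if (nrow(genes) == 0L) return(empty)

  ex_by_tx <- split(ex[c("start", "end")], ex$transcript_id)
  out <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    strand <- genes$strand[g]
    tids <- tx$transcript_id[tx$gene_id == gid]
    exs <- ex_by_tx[tids]
    pairs <- combn(length(tids), 2L)
    rows <- list()
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      pe <- pair_events(exs[[a]], exs[[b]], tids[a], tids[b], strand)
      if (!is.null(pe) && nrow(pe) > 0) rows[[length(rows) + 1L]] <- pe
    }
    if (length(rows) == 0L) next
    evs <- bind_rows(rows)

    # gene-level MXE condition: the two exons never co-occur in any isoform
    if (any(evs$event_type == "mutually_exclusive_exons")) {
      exkeys <- lapply(exs, function(e) paste(e$start, e$end))
      keep <- map_lgl(seq_len(nrow(evs)), function(i) {
        if (evs$event_type[i] != "mutually_exclusive_exons") return(TRUE)
        ka <- paste(evs$mxe_a_start[i], evs$mxe_a_end[i])
        kb <- paste(evs$mxe_b_start[i], evs$mxe_b_end[i])
        !any(map_lgl(exkeys, function(k) ka %in% k && kb %in% k))
      })
      evs <- evs[keep, ]
    }
    if (nrow(evs) == 0L) next

    merged <- evs |>
      group_by(.data$event_type, .data$event_start, .data$event_end) |>
      summarise(
        inclusion = list(sort(unique(.data$inclusion))),
        exclusion = list(sort(unique(.data$exclusion))),
        .groups = "drop"
      ) |>
      mutate(gene_id = gid, chrom = genes$chrom[g], strand = strand)
    out[[g]] <- merged
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty)
  res <- res |>
    mutate(event_id = paste(.data$gene_id, .data$event_type,
                            .data$event_start, .data$event_end, sep = ":")) |>
    select("gene_id", "chrom", "strand", "event_type", "event_start",
           "event_end", "inclusion", "exclusion", "event_id") |>
    arrange(.data$gene_id, .data$event_start)
  res
}

#' Per-sample inclusion levels (PSI) of splicing events
#'
#' `psi = sum(expr over inclusion isoforms) / sum(expr over inclusion and
#' exclusion isoforms)` per sample, from transcript-level normalized
#' expression (isoform-abundance PSI, the natural definition for full-length
#' long-read quantification). A zero denominator yields `NA` with
#' `defined = FALSE`.
#'
#' @param events Output of [classify_splice_events()]; `"complex"` rows are
#'   ignored.
#' @param expr Wide transcript-level normalized expression tibble.
#' @return Tibble with columns `event_id`, `gene_id`, `event_type`,
#'   `sample_id`, `psi`, `defined`.
#' @export
splice_psi <- function(events, expr) {
  events <- events[events$event_type != "complex", ]
  sample_ids <- names(expr)[-1]
  all_tx <- unique(c(unlist(events$inclusion), unlist(events$exclusion)))
  missing_tx <- setdiff(all_tx, expr$feature_id)
  if (length(missing_tx) > 0) {
    abort(paste0("transcript(s) in events absent from expression matrix: ",
                 paste(head(missing_tx, 5), collapse = ", ")))
  }
  mat <- as.matrix(expr[, -1])
  rownames(mat) <- expr$feature_id
  rows <- map_dfr(seq_len(nrow(events)), function(i) {
    inc <- unname(colSums(mat[events$inclusion[[i]], , drop = FALSE]))
    exc <- unname(colSums(mat[events$exclusion[[i]], , drop = FALSE]))
    den <- inc + exc
    tibble(
      event_id = events$event_id[i], gene_id = events$gene_id[i],
      event_type = events$event_type[i], sample_id = sample_ids,
      psi = ifelse(den > 0, inc / den, NA_real_),
      defined = den > 0
    )
  })
  rows
}

#' Differential splicing between sexes within one tissue
#'
#' Per event, a Wilcoxon rank-sum test on replicate PSI values (M vs F),
#' Benjamini-Hochberg FDR across all tested events in the tissue, and the
#' significance rule `|delta_psi| >= min_delta & fdr < max_fdr`
#' (`delta_psi = mean PSI(M) - mean PSI(F)`). Events with fewer than two
#' defined replicate PSIs in either sex are skipped with a reason.
#'
#' @param psi Output of [splice_psi()].
#' @param samples Sample sheet.
#' @param tissue Tissue label.
#' @param min_delta Minimum absolute PSI change (default 0.10).
#' @param max_fdr FDR threshold (default 0.05).
#' @param mode Wilcoxon mode.
#' @return Tibble with columns `event_id`, `gene_id`, `event_type`, `tissue`,
#'   `mean_psi_M`, `mean_psi_F`, `delta_psi`, `p_value`, `fdr`,
#'   `significant`, `skipped`, `skip_reason`.
#' @export
differential_splicing <- function(psi, samples, tissue, min_delta = 0.10,
                                  max_fdr = 0.05, mode = "auto") {
  samples <- validate_sample_sheet(samples)
  sel <- samples[samples$tissue == tissue, ]
  dat <- psi |>
    inner_join(sel[c("sample_id", "sex")], by = "sample_id") |>
    filter(.data$defined)
  per_event <- dat |>
    group_by(.data$event_id, .data$gene_id, .data$event_type) |>
    summarise(
      n_M = sum(.data$sex == "M"), n_F = sum(.data$sex == "F"),
      psi_M = list(.data$psi[.data$sex == "M"]),
      psi_F = list(.data$psi[.data$sex == "F"]),
      .groups = "drop"
    )
  res <- per_event |>
    mutate(
      tissue = tissue,
      skipped = .data$n_M < 2L | .data$n_F < 2L,
      skip_reason = ifelse(.data$skipped,
                           "fewer than 2 defined PSI replicates in a sex",
                           NA_character_),
      mean_psi_M = map_dbl(.data$psi_M, mean),
      mean_psi_F = map_dbl(.data$psi_F, mean),
      delta_psi = .data$mean_psi_M - .data$mean_psi_F,
      p_value = ifelse(
        .data$skipped, NA_real_,
        map2_dbl(.data$psi_M, .data$psi_F, function(m, f) {
          suppressWarnings(wilcoxon_rank_sum(m, f, mode = mode)$p_value)
        })
      )
    )
  res$fdr <- NA_real_
  tested <- !res$skipped
  res$fdr[tested] <- p.adjust(res$p_value[tested], method = "BH")
  res$significant <- !res$skipped & abs(res$delta_psi) >= min_delta &
    res$fdr < max_fdr
  res |>
    select("event_id", "gene_id", "event_type", "tissue", "mean_psi_M",
           "mean_psi_F", "delta_psi", "p_value", "fdr", "significant",
           "skipped", "skip_reason")
}

#' Group-unique transcripts and overlap structure
#'
#' A transcript is "expressed" in a (sex, tissue) group iff its mean
#' normalized expression over the group's replicates exceeds `threshold`;
#' it is unique to a group iff expressed there and in no other group.
#'
#' @param expr Wide transcript-level normalized expression tibble.
#' @param samples Sample sheet.
#' @param threshold Expression threshold (strict `>`, default 0).
#' @return List of three tibbles: `membership` (`feature_id` + one logical
#'   column per group + `n_groups` + `unique_group`), `unique_counts`
#'   (`group`, `n_unique`), and `patterns` (group-membership pattern counts).
#' @export
unique_transcripts <- function(expr, samples, threshold = 0) {
  samples <- validate_sample_sheet(samples)
  groups <- samples |> distinct(.data$sex, .data$tissue) |>
    mutate(group = paste(.data$sex, .data$tissue, sep = "_"))
  memb <- tibble(feature_id = expr$feature_id)
  for (i in seq_len(nrow(groups))) {
    ids <- samples$sample_id[samples$sex == groups$sex[i] &
                             samples$tissue == groups$tissue[i]]
    memb[[groups$group[i]]] <-
      rowMeans(as.matrix(expr[, ids, drop = FALSE])) > threshold
  }
  flags <- as.matrix(memb[, -1])
  memb$n_groups <- rowSums(flags)
  memb$unique_group <- ifelse(
    memb$n_groups == 1L,
    groups$group[apply(flags, 1, function(z) which(z)[1])],
    NA_character_
  )
  unique_counts <- groups |>
    mutate(n_unique = map_int(.data$group, function(g) {
      sum(!is.na(memb$unique_group) & memb$unique_group == g)
    })) |>
    select("group", "n_unique")
  memb$pattern <- apply(flags, 1, function(z) {
    if (!any(z)) NA_character_ else paste(groups$group[z], collapse = "&")
  })
  patterns <- memb |>
    filter(!is.na(.data$pattern)) |>
    count(.data$pattern, name = "n")
  list(membership = memb, unique_counts = unique_counts, patterns = patterns)
}
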