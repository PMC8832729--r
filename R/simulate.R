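# Seeded synthetic-data generator. Produces an annotated toy genome with
# known ground truth: Z-linked male-biased expression (incomplete dosage
# compensation), an optional regional hotspot, multi-isoform genes whose
# isoforms differ by exactly one injected splicing event, positionally placed
# lncRNAs of the four classes, and per-gene poly(A) cleavage sites.

#' Simulation configuration
#'
#' All randomness downstream is a pure function of this object (including its
#' seed). Defaults encode the study conditions the analysis assumes: two
#' tissues x two sexes x four replicates, negative-binomial counts, a
#' constant male:female fold on Z-linked features, and lncRNA class
#' proportions matching the four positional classes' reported shares.
#'
#' @param seed Integer seed.
#' @param chromosomes Tibble with columns `chrom`, `length` (bp), `is_z`
#'   (logical), `n_genes` (coding genes to place).
#' @param isoform_probs Named probabilities over isoform counts `"1".."5"`.
#' @param event_probs Named probabilities over the five splicing modes used
#'   when deriving additional isoforms.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression mean.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); values below 1e-8 fall back to Poisson.
#' @param z_male_fold Expected male:female fold for Z-linked features (> 0).
#'   Males sit at the autosomal baseline and females at baseline / fold, so
#'   the male Z:AA ratio stays near 1 while the female Z:AA ratio drops.
#' @param fold_jitter_sd Standard deviation (log2 scale) of optional per-gene
#'   fold jitter around `z_male_fold`; 0 gives a constant fold.
#' @param hotspot `NULL`, or `list(chrom, start, end, extra_fold)`: genes
#'   whose midpoint falls in the interval get `extra_fold` on top of
#'   `z_male_fold`.
#' @param lncrna_n Number of lncRNAs to place.
#' @param lncrna_class_probs Named probabilities over
#'   `lincRNA`, `antisense`, `sense`, `intronic`.
#' @param polya_site_probs Named probabilities over poly(A) site counts
#'   `"1".."5"` per gene.
#' @param polya_reads_per_site Mean Poisson read support per site per sample.
#' @param polya_jitter Maximum absolute integer jitter of read 3' ends around
#'   the true site (default 5 bp, below the default merge distance).
#' @param tissues Tissue labels.
#' @param n_replicates Replicates per sex x tissue.
#' @param library_sdlog Log-normal sd of per-sample library-size factors.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = tibble(
                         chrom = c("1", "2", "Z"),
                         length = c(4e7, 4e7, 8e7),
                         is_z = c(FALSE, FALSE, TRUE),
                         n_genes = c(60L, 60L, 80L)
                       ),
                       isoform_probs = c("1" = 0.4, "2" = 0.3, "3" = 0.15,
                                         "4" = 0.1, "5" = 0.05),
                       event_probs = c(exon_skipping = 0.5538,
                                       intron_retention = 0.15,
                                       alt_5ss = 0.12, alt_3ss = 0.12,
                                       mutually_exclusive_exons = 0.0562),
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       nb_dispersion = 0.1,
                       z_male_fold = 1.75, fold_jitter_sd = 0,
                       hotspot = list(chrom = "Z", start = 31e6, end = 36e6,
                                      extra_fold = 1.5),
                       lncrna_n = 40L,
                       lncrna_class_probs = c(lincRNA = 0.7616,
                                              antisense = 0.1192,
                                              sense = 0.0066,
                                              intronic = 0.1126),
                       polya_site_probs = c("1" = 0.28, "2" = 0.30, "3" = 0.20,
                                            "4" = 0.12, "5" = 0.10),
                       polya_reads_per_site = 8,
                       polya_jitter = 5L,
                       tissues = c("gonad", "head_skin"),
                       n_replicates = 4L,
                       library_sdlog = 0.1) {
  cfg <- list(
    seed = as.integer(seed), chromosomes = as_tibble(chromosomes),
    isoform_probs = isoform_probs, event_probs = event_probs,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    nb_dispersion = nb_dispersion, z_male_fold = z_male_fold,
    fold_jitter_sd = fold_jitter_sd, hotspot = hotspot,
    lncrna_n = as.integer(lncrna_n), lncrna_class_probs = lncrna_class_probs,
    polya_site_probs = polya_site_probs,
    polya_reads_per_site = polya_reads_per_site,
    polya_jitter = as.integer(polya_jitter),
    tissues = tissues, n_replicates = as.integer(n_replicates),
    library_sdlog = library_sdlog
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0(what, " must be non-negative and sum to 1 (within 1e-9)"))
    }
  }
  chk_probs(cfg$isoform_probs, "isoform_probs")
  chk_probs(cfg$event_probs, "event_probs")
  chk_probs(cfg$lncrna_class_probs, "lncrna_class_probs")
  chk_probs(cfg$polya_site_probs, "polya_site_probs")
  if (cfg$z_male_fold <= 0) abort("z_male_fold must be > 0")
  if (!is.null(cfg$hotspot) && cfg$hotspot$extra_fold <= 0) {
    abort("hotspot extra_fold must be > 0")
  }
  if (cfg$nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  req <- c("chrom", "length", "is_z", "n_genes")
  if (length(setdiff(req, names(cfg$chromosomes))) > 0) {
    abort("chromosomes needs columns chrom, length, is_z, n_genes")
  }
  cfg
}

# ---- gene and isoform construction -----------------------------------------

# internal-exon slots spaced >= 2 apart so injected events never share or
# abut a region; returns event slot indices (exon index i; the event may also
# use intron i and exon i+1)
choose_slots <- function(n_exons, n_events) {
  if (n_events == 0L) return(integer())
  base <- seq(2L, by = 2L, length.out = n_events)
  room <- (n_exons - 2L) - base[n_events]
  shift <- if (room > 0L) sample.int(room + 1L, 1L) - 1L else 0L
  base + shift
}

# base exon chain for one gene starting at `at`; returns list(starts, ends)
base_exons <- function(at, n_exons) {
  widths <- sample(150:400, n_exons, replace = TRUE)
  introns <- sample(800:2500, max(n_exons - 1L, 0L), replace = TRUE)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- at
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + widths[i] - 1L
    pos <- ends[i] + 1L + if (i < n_exons) introns[i] else 0L
  }
  list(starts = starts, ends = ends)
}

# derive one alternative isoform from the base chain by a single event at
# `slot`; returns list(starts, ends, event = tibble row)
inject_event <- function(base, slot, type, strand) {
  s <- base$starts
  e <- base$ends
  i <- slot
  intron_start <- e[i] + 1L
  intron_end <- s[i + 1L] - 1L
  intron_len <- intron_end - intron_start + 1L
  if (type == "exon_skipping") {
    keep <- setdiff(seq_along(s), i)
    ev <- tibble(event_type = type, event_start = s[i], event_end = e[i])
    return(list(starts = s[keep], ends = e[keep], event = ev))
  }
  if (type == "intron_retention") {
    ns <- s[-(i + 1L)]
    ne <- e[-i]
    ev <- tibble(event_type = type, event_start = intron_start,
                 event_end = intron_end)
    return(list(starts = ns, ends = ne, event = ev))
  }
  if (type %in% c("alt_5ss", "alt_3ss")) {
    d <- sample(15:60, 1L)
    # donor side is the intron start on '+', the intron end on '-'
    extend_right <- (type == "alt_5ss") == (strand == "+")
    if (extend_right) {
      e[i] <- e[i] + d
      ev <- tibble(event_type = type, event_start = intron_start,
                   event_end = intron_start + d - 1L)
    } else {
      s[i + 1L] <- s[i + 1L] - d
      ev <- tibble(event_type = type, event_start = intron_end - d + 1L,
                   event_end = intron_end)
    }
    return(list(starts = s, ends = e, event = ev))
  }
  if (type == "mutually_exclusive_exons") {
    w2 <- sample(120:300, 1L)
    f1 <- sample(30:(intron_len - w2 - 30L), 1L)
    e2s <- intron_start + f1
    e2e <- e2s + w2 - 1L
    ns <- s
    ne <- e
    ns[i] <- e2s
    ne[i] <- e2e
    ev <- tibble(event_type = type, event_start = s[i], event_end = e2e)
    return(list(starts = ns, ends = ne, event = ev))
  }
  abort(paste0("unknown event type: ", type))
}

# non-overlapping gene start positions given span lengths on one chromosome
place_spans <- function(chrom_len, spans, min_gap = 3000L) {
  n <- length(spans)
  need <- sum(spans) + (n + 1L) * min_gap
  if (need > chrom_len) {
    abort(paste0("chromosome too short to place ", n,
                 " genes without overlap; needs >= ", need,
                 " bp - increase the chromosome length"))
  }
  free <- chrom_len - need
  u <- runif(n + 1L)
  extra <- as.integer(floor(free * u / sum(u)))
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + min_gap + extra[i]
    starts[i] <- pos
    pos <- pos + spans[i]
  }
  starts
}

# ---- annotation + truth -----------------------------------------------------

#' Generate the annotated toy genome and its ground truth
#'
#' Coding genes are placed uniformly and non-overlapping per chromosome; each
#' gene receives `k` isoforms (drawn from `isoform_probs`), and every
#' additional isoform differs from the base isoform by exactly one splicing
#' event of a randomly chosen mode in its own region of the gene. lncRNAs are
#' constructed to realise their assigned positional class exactly and all
#' satisfy spliced length > 200 nt with >= 2 exons.
#'
#' @param config A [sim_config()].
#' @return `list(annotation, truth)` where `annotation` is a
#'   [genome_annotation()] and `truth` a list with elements `genes`
#'   (`gene_id`, `chrom`, `true_fold`, `in_hotspot`), `splice_events`,
#'   `lncrnas`, `lncrna_targets`, `polya_sites` and `hotspot`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_annotation_impl(config))
}

simulate_annotation_impl <- function(config) {
  exon_rows <- list()
  event_rows <- list()
  gene_rows <- list()
  gene_counter <- 0L

  for (ci in seq_len(nrow(config$chromosomes))) {
    chrom <- config$chromosomes$chrom[ci]
    chrom_len <- config$chromosomes$length[ci]
    n_genes <- config$chromosomes$n_genes[ci]
    if (n_genes == 0L) next

    k_iso <- as.integer(sample(names(config$isoform_probs), n_genes,
                               replace = TRUE, prob = config$isoform_probs))
    n_events <- k_iso - 1L
    n_exons <- pmax(sample(5:8, n_genes, replace = TRUE), 2L * n_events + 3L)
    # span upper bound: widths <= 400, introns <= 2500
    spans <- vapply(seq_len(n_genes), function(g) {
      400L * n_exons[g] + 2500L * (n_exons[g] - 1L)
    }, integer(1))
    # spans are realised below; reserve the upper bound for placement
    starts_at <- place_spans(chrom_len, spans)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)

    for (g in seq_len(n_genes)) {
      gene_counter <- gene_counter + 1L
      gid <- sprintf("G%05d", gene_counter)
      base <- base_exons(starts_at[g], n_exons[g])
      slots <- choose_slots(n_exons[g], n_events[g])
      types <- if (n_events[g] > 0L) {
        sample(names(config$event_probs), n_events[g], replace = TRUE,
               prob = config$event_probs)
      } else character()
      txs <- vector("list", k_iso[g])
      txs[[1]] <- base
      free_introns <- rep(TRUE, n_exons[g] - 1L)
      for (j in seq_len(n_events[g])) {
        alt <- inject_event(base, slots[j], types[j], strands[g])
        txs[[j + 1L]] <- alt[c("starts", "ends")]
        event_rows[[length(event_rows) + 1L]] <- mutate(
          alt$event, gene_id = gid, chrom = chrom,
          alt_transcript = sprintf("%s.t%d", gid, j + 1L)
        )
        touched <- intersect(seq_len(n_exons[g] - 1L),
                             (slots[j] - 1L):(slots[j] + 1L))
        free_introns[touched] <- FALSE
      }
      for (j in seq_len(k_iso[g])) {
        exon_rows[[length(exon_rows) + 1L]] <- tibble(
          gene_id = gid, transcript_id = sprintf("%s.t%d", gid, j),
          chrom = chrom, start = txs[[j]]$starts, end = txs[[j]]$ends,
          strand = strands[g]
        )
      }
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        gene_id = gid, chrom = chrom, strand = strands[g],
        start = base$starts[1], end = base$ends[n_exons[g]],
        is_z = config$chromosomes$is_z[ci],
        base_starts = list(base$starts), base_ends = list(base$ends),
        free_introns = list(free_introns)
      )
    }
  }

  genes <- bind_rows(gene_rows)
  lnc <- place_lncrnas(config, genes)
  exons <- bind_rows(c(exon_rows, list(lnc$exons)))

  biotype <- c(
    setNames(rep("coding", nrow(genes)), genes$gene_id),
    setNames(rep("noncoding_candidate", length(unique(lnc$exons$gene_id))),
             unique(lnc$exons$gene_id))
  )
  annotation <- genome_annotation(
    exons,
    chromosomes = config$chromosomes[c("chrom", "length")],
    gene_biotype = biotype
  )

  truth_genes <- annotation$genes |>
    left_join(config$chromosomes[c("chrom", "is_z")], by = "chrom") |>
    mutate(
      midpoint = (.data$start + .data$end) %/% 2L,
      in_hotspot = !is.null(config$hotspot) &
        .data$chrom == (config$hotspot$chrom %||% "") &
        .data$midpoint >= (config$hotspot$start %||% 0) &
        .data$midpoint <= (config$hotspot$end %||% 0),
      true_fold = ifelse(.data$is_z, config$z_male_fold, 1) *
        ifelse(.data$is_z & .data$in_hotspot,
               config$hotspot$extra_fold %||% 1, 1)
    )
  if (config$fold_jitter_sd > 0) {
    jit <- 2^rnorm(nrow(truth_genes), 0, config$fold_jitter_sd)
    truth_genes$true_fold <- ifelse(truth_genes$is_z,
                                    truth_genes$true_fold * jit,
                                    truth_genes$true_fold)
  }
  truth_genes <- truth_genes |>
    select("gene_id", "chrom", "biotype", "midpoint", "is_z", "in_hotspot",
           "true_fold")

  splice_events <- if (length(event_rows) > 0) {
    bind_rows(event_rows) |>
      select("gene_id", "chrom", "event_type", "event_start", "event_end",
             "alt_transcript")
  } else {
    tibble(gene_id = character(), chrom = character(),
           event_type = character(), event_start = integer(),
           event_end = integer(), alt_transcript = character())
  }

  targets <- lnc_truth_targets(lnc$exons, genes)
  polya <- truth_polya_sites(genes, config)

  truth <- list(
    genes = truth_genes,
    splice_events = splice_events,
    lncrnas = lnc$lncrnas,
    lncrna_targets = targets,
    polya_sites = polya,
    hotspot = config$hotspot
  )
  list(annotation = annotation, truth = truth)
}

# construct lncRNAs realising each assigned class; returns exon rows and a
# truth table
place_lncrnas <- function(config, genes) {
  n <- config$lncrna_n
  empty <- list(
    exons = tibble(gene_id = character(), transcript_id = character(),
                   chrom = character(), start = integer(), end = integer(),
                   strand = character()),
    lncrnas = tibble(lncrna_id = character(), gene_id = character(),
                     chrom = character(), class = character(),
                     host_gene = character())
  )
  if (n == 0L) return(empty)
  classes <- sample(names(config$lncrna_class_probs), n, replace = TRUE,
                    prob = config$lncrna_class_probs)
  exon_rows <- list()
  truth_rows <- list()
  flip <- c("+" = "-", "-" = "+")
  chrom_tbl <- config$chromosomes

  # intergenic gaps per chromosome, recomputed once (lncRNAs may share gaps;
  # only coding overlap matters for classification)
  gaps <- genes |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    reframe(gap_start = c(1L, .data$end + 2L),
            gap_end = c(.data$start - 2L,
                        chrom_tbl$length[match(.data$chrom[1], chrom_tbl$chrom)])) |>
    filter(.data$gap_end - .data$gap_start + 1L >= 1500L)

  for (i in seq_len(n)) {
    lid <- sprintf("LNC%04d", i)
    cls <- classes[i]
    if (cls == "lincRNA") {
      g <- gaps[sample.int(nrow(gaps), 1L), ]
      w1 <- sample(150:300, 1L)
      w2 <- sample(150:300, 1L)
      gap_intr <- sample(200:500, 1L)
      span <- w1 + gap_intr + w2
      room <- (g$gap_end - g$gap_start + 1L) - span
      at <- g$gap_start + if (room > 0L) sample.int(room, 1L) - 1L else 0L
      starts <- c(at, at + w1 + gap_intr)
      ends <- c(at + w1 - 1L, at + w1 + gap_intr + w2 - 1L)
      strand <- sample(c("+", "-"), 1L)
      host <- NA_character_
      chrom <- g$chrom
    } else if (cls %in% c("antisense", "sense")) {
      # overlap the first exon of a host gene; second exon downstream in the
      # host's first intron region
      cand <- genes |> filter(purrr::map_int(.data$base_starts, length) >= 3L)
      h <- cand[sample.int(nrow(cand), 1L), ]
      hs <- h$base_starts[[1]]
      he <- h$base_ends[[1]]
      w1 <- min(150L, he[1] - hs[1] + 1L)
      e1s <- he[1] - w1 + 1L        # overlaps host exon 1
      e1e <- he[1] + 60L            # extends into intron 1
      e2s <- e1e + 150L
      e2e <- e2s + 149L
      # keep the second exon inside intron 1 so no other host exon is touched
      if (e2e >= hs[2]) {
        e2e <- hs[2] - 30L
        e2s <- max(e1e + 50L, e2e - 149L)
      }
      starts <- c(e1s, e2s)
      ends <- c(e1e, e2e)
      strand <- if (cls == "antisense") flip[[h$strand]] else h$strand
      host <- h$gene_id
      chrom <- h$chrom
    } else { # intronic
      ok <- FALSE
      for (try in 1:50) {
        h <- genes[sample.int(nrow(genes), 1L), ]
        hs <- h$base_starts[[1]]
        he <- h$base_ends[[1]]
        free <- h$free_introns[[1]]
        ilen <- hs[-1] - he[-length(he)] - 1L
        usable <- which(free & ilen >= 500L)
        if (length(usable) > 0L) { ok <- TRUE; break }
      }
      if (!ok) abort("no intron wide enough for an intronic lncRNA; increase gene sizes")
      ii <- usable[sample.int(length(usable), 1L)]
      is0 <- he[ii] + 1L
      ie0 <- hs[ii + 1L] - 1L
      w <- 120L
      gap_intr <- 100L
      span <- 2L * w + gap_intr
      room <- (ie0 - is0 + 1L) - span - 20L
      at <- is0 + 10L + if (room > 0L) sample.int(room, 1L) - 1L else 0L
      starts <- c(at, at + w + gap_intr)
      ends <- c(at + w - 1L, at + w + gap_intr + w - 1L)
      strand <- h$strand
      host <- h$gene_id
      chrom <- h$chrom
    }
    exon_rows[[i]] <- tibble(
      gene_id = lid, transcript_id = paste0(lid, ".t1"), chrom = chrom,
      start = starts, end = ends, strand = strand
    )
    truth_rows[[i]] <- tibble(
      lncrna_id = paste0(lid, ".t1"), gene_id = lid, chrom = chrom,
      class = cls, host_gene = host
    )
  }
  list(exons = bind_rows(exon_rows), lncrnas = bind_rows(truth_rows))
}

# ground-truth cis targets: coding genes whose span gap to the lncRNA span is
# strictly below 100 kb (inline all-pairs scan, independent of the
# assignment module)
lnc_truth_targets <- function(lnc_exons, genes, max_dist = 100000L) {
  empty <- tibble(lncrna_id = character(), gene_id = character(),
                  gap = integer())
  if (nrow(lnc_exons) == 0L) return(empty)
  spans <- lnc_exons |>
    group_by(lncrna_id = .data$transcript_id, chrom = .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  rows <- list()
  for (i in seq_len(nrow(spans))) {
    cand <- genes[genes$chrom == spans$chrom[i], ]
    if (nrow(cand) == 0L) next
    gap <- pmax(0L, pmax(cand$start, spans$start[i]) -
                     pmin(cand$end, spans$end[i]) - 1L)
    hit <- which(gap < max_dist)
    if (length(hit) > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        lncrna_id = spans$lncrna_id[i], gene_id = cand$gene_id[hit],
        gap = as.integer(gap[hit])
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  bind_rows(rows)
}

truth_polya_sites <- function(genes, config) {
  ks <- as.integer(sample(names(config$polya_site_probs), nrow(genes),
                          replace = TRUE, prob = config$polya_site_probs))
  rows <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    k <- ks[g]
    spacing <- sample(200:400, max(k - 1L, 0L), replace = TRUE)
    offs <- c(0L, cumsum(spacing))
    pos <- if (genes$strand[g] == "+") genes$end[g] - offs
           else genes$start[g] + offs
    rows[[g]] <- tibble(gene_id = genes$gene_id[g], chrom = genes$chrom[g],
                        strand = genes$strand[g], position = as.integer(pos))
  }
  bind_rows(rows)
}
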