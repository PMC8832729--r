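# Annotation and tabular I/O: GTF, chrom.sizes, count matrix, sample sheet,
# poly(A) 3'-end records. GTF coordinates are 1-based inclusive; BED-like
# poly(A) input is 0-based half-open and converted on load.

#' Construct a genome annotation from an exon table
#'
#' The annotation container used throughout the package. It is a list of four
#' tibbles (`chromosomes`, `genes`, `transcripts`, `exons`); gene and
#' transcript spans are derived from the exons. Coordinates are 1-based
#' inclusive.
#'
#' @param exons Tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param chromosomes Tibble with columns `chrom`, `length`, or `NULL` to
#'   infer each chromosome length as the maximum exon end observed on it.
#' @param gene_biotype Optional named character vector (`gene_id` ->
#'   `"coding"` or `"noncoding_candidate"`). Genes not named default to
#'   `"coding"`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(exons, chromosomes = NULL, gene_biotype = NULL) {
  required <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  exons <- as_tibble(exons)[required]
  exons$chrom <- as.character(exons$chrom)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(!exons$strand %in% c("+", "-"))) {
    abort("exon strand must be '+' or '-'")
  }
  if (any(exons$start > exons$end)) {
    abort("exon start > end")
  }
  if (any(exons$start < 1L)) {
    abort("exon coordinates must be >= 1 (1-based inclusive)")
  }
  exons <- distinct(exons) |> arrange(.data$transcript_id, .data$start)

  # per-transcript validation: one chrom/strand, non-overlapping exons
  tx <- exons |>
    group_by(.data$transcript_id, .data$gene_id) |>
    summarise(
      one_chrom = length(unique(.data$chrom)) == 1L,
      one_strand = length(unique(.data$strand)) == 1L,
      n_exons = dplyr::n(),
      length = sum(.data$end - .data$start + 1L),
      overlapping = dplyr::n() > 1L &&
        any(.data$start[-1] <= cummax(.data$end)[-dplyr::n()]),
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
  if (any(!tx$one_chrom) || any(!tx$one_strand)) {
    bad <- tx$transcript_id[!tx$one_chrom | !tx$one_strand]
    abort(paste0("transcript(s) with mixed chrom/strand: ", paste(bad, collapse = ", ")))
  }
  if (any(tx$overlapping)) {
    bad <- tx$transcript_id[tx$overlapping]
    abort(paste0("overlapping exons within transcript(s): ", paste(bad, collapse = ", ")))
  }
  dup_tx <- tx |> count(.data$transcript_id) |> filter(.data$n > 1L)
  if (nrow(dup_tx) > 0) {
    abort(paste0("transcript_id(s) mapped to multiple genes: ",
                 paste(dup_tx$transcript_id, collapse = ", ")))
  }
  tx <- tx |> select("transcript_id", "gene_id", "chrom", "strand",
                     "start", "end", "n_exons", "length")

  genes <- tx |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = min(.data$start),
      end = max(.data$end),
      n_transcripts = dplyr::n(),
      .groups = "drop"
    )
  biotype <- rep("coding", nrow(genes))
  if (!is.null(gene_biotype)) {
    hit <- match(genes$gene_id, names(gene_biotype))
    biotype[!is.na(hit)] <- unname(gene_biotype[hit[!is.na(hit)]])
  }
  genes$biotype <- biotype

  if (is.null(chromosomes)) {
    chromosomes <- exons |>
      group_by(chrom = .data$chrom) |>
      summarise(length = max(.data$end), .groups = "drop")
  }
  chromosomes <- as_tibble(chromosomes)[c("chrom", "length")]
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.integer(chromosomes$length)

  missing_chr <- setdiff(genes$chrom, chromosomes$chrom)
  if (length(missing_chr) > 0) {
    abort(paste0("gene(s) on chromosome(s) absent from sizes: ",
                 paste(missing_chr, collapse = ", ")))
  }
  span_check <- genes |> left_join(chromosomes, by = "chrom")
  if (any(span_check$end > span_check$length)) {
    bad <- span_check$gene_id[span_check$end > span_check$length]
    abort(paste0("gene(s) extend beyond chromosome length: ",
                 paste(bad, collapse = ", ")))
  }

  structure(
    list(chromosomes = chromosomes, genes = genes, transcripts = tx,
         exons = arrange(exons, .data$chrom, .data$start)),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ",
      nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$genes), " gene(s), ",
      nrow(x$transcripts), " transcript(s), ",
      nrow(x$exons), " exon(s)\n", sep = "")
  invisible(x)
}

#' Read a chromosome sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp, no header.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  sizes <- readr::read_tsv(path, col_names = c("chrom", "length"),
                           col_types = "ci", progress = FALSE)
  if (any(is.na(sizes$length)) || any(sizes$length <= 0)) {
    abort("chrom.sizes: lengths must be positive integers")
  }
  sizes
}

#' Read a GTF file into a genome annotation
#'
#' Minimal GTF dialect: 9 tab-separated columns; only `exon` feature rows are
#' used to build transcript models and each must carry `gene_id` and
#' `transcript_id` attributes. All other attributes and feature types are
#' ignored. Identical duplicate exon rows are collapsed; exons that overlap
#' within one transcript are a validation error.
#'
#' @param path GTF file path.
#' @param chrom_sizes Optional tibble (`chrom`, `length`) or path to a
#'   chrom.sizes file. When absent, chromosome lengths are inferred from the
#'   annotation itself.
#' @return A [genome_annotation()].
#' @export
read_gtf <- function(path, chrom_sizes = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) abort("GTF contains no feature lines")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1]]
    abort(paste0("malformed GTF line ", bad, ": expected 9 tab-separated fields, got ",
                 nf[which(nf != 9L)[1]]))
  }
  mat <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  feature <- mat[, 3]
  ex <- mat[feature == "exon", , drop = FALSE]
  ex_lines <- idx[feature == "exon"]
  if (nrow(ex) == 0) abort("GTF contains no exon features")

  start <- suppressWarnings(as.integer(ex[, 4]))
  end <- suppressWarnings(as.integer(ex[, 5]))
  bad_coord <- which(is.na(start) | is.na(end))
  if (length(bad_coord) > 0) {
    abort(paste0("malformed GTF line ", ex_lines[bad_coord[1]],
                 ": non-numeric coordinates"))
  }
  strand <- ex[, 7]
  bad_strand <- which(!strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(paste0("malformed GTF line ", ex_lines[bad_strand[1]],
                 ": strand must be '+' or '-'"))
  }
  attr_field <- ex[, 9]
  gene_id <- stringr::str_match(attr_field, 'gene_id\\s+"([^"]+)"')[, 2]
  transcript_id <- stringr::str_match(attr_field, 'transcript_id\\s+"([^"]+)"')[, 2]
  if (anyNA(transcript_id)) {
    abort(paste0("GTF line ", ex_lines[which(is.na(transcript_id))[1]],
                 ": exon without transcript_id attribute"))
  }
  if (anyNA(gene_id)) {
    abort(paste0("GTF line ", ex_lines[which(is.na(gene_id))[1]],
                 ": exon without gene_id attribute"))
  }

  if (!is.null(chrom_sizes) && is.character(chrom_sizes)) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  genome_annotation(
    tibble(gene_id = gene_id, transcript_id = transcript_id,
           chrom = ex[, 1], start = start, end = end, strand = strand),
    chromosomes = chrom_sizes
  )
}

#' Write a genome annotation as GTF
#'
#' Emits `gene`, `transcript` and `exon` rows with `gene_id`/`transcript_id`
#' attributes, 1-based inclusive coordinates, sorted by chromosome and start.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  fmt <- function(chrom, feature, start, end, strand, attrs) {
    paste(chrom, "zdosage", feature, start, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  g <- annotation$genes
  t <- annotation$transcripts
  e <- annotation$exons
  gene_rows <- tibble(
    chrom = g$chrom, start = g$start,
    line = fmt(g$chrom, "gene", g$start, g$end, g$strand,
               sprintf('gene_id "%s";', g$gene_id)),
    rank = 1L
  )
  tx_rows <- tibble(
    chrom = t$chrom, start = t$start,
    line = fmt(t$chrom, "transcript", t$start, t$end, t$strand,
               sprintf('gene_id "%s"; transcript_id "%s";', t$gene_id, t$transcript_id)),
    rank = 2L
  )
  ex_rows <- tibble(
    chrom = e$chrom, start = e$start,
    line = fmt(e$chrom, "exon", e$start, e$end, e$strand,
               sprintf('gene_id "%s"; transcript_id "%s";', e$gene_id, e$transcript_id)),
    rank = 3L
  )
  out <- bind_rows(gene_rows, tx_rows, ex_rows) |>
    arrange(.data$chrom, .data$start, .data$rank)
  readr::write_lines(out$line, path)
  invisible(path)
}

#' Write a chromosome sizes file
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(annotation, path) {
  readr::write_tsv(annotation$chromosomes, path, col_names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `sex` (M/F), `tissue`,
#' `replicate`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", sex = "c", tissue = "c", replicate = "i"
  ), progress = FALSE)
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "sex", "tissue", "replicate")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) abort("sample sheet: duplicate sample_id")
  if (any(!sheet$sex %in% c("M", "F"))) abort("sample sheet: sex must be 'M' or 'F'")
  if (any(sheet$replicate < 1)) abort("sample sheet: replicate must be >= 1")
  as_tibble(sheet)
}

#' Read a feature-by-sample count matrix
#'
#' Tab-separated, first column `feature_id`, one column per sample. The header
#' must contain exactly the sample sheet's `sample_id`s (strict schema).
#'
#' @param path File path.
#' @param samples Sample sheet tibble (see [read_sample_sheet()]).
#' @return Wide tibble (`feature_id` + one numeric column per sample) with
#'   attribute `unit = "raw_counts"`.
#' @export
read_counts <- function(path, samples) {
  samples <- validate_sample_sheet(samples)
  mat <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = "c", .default = "d"
  ), progress = FALSE)
  if (names(mat)[1] != "feature_id") {
    abort("count matrix: first column must be 'feature_id'")
  }
  have <- names(mat)[-1]
  missing_ids <- setdiff(samples$sample_id, have)
  if (length(missing_ids) > 0) {
    abort(paste0("count matrix: missing sample column(s): ",
                 paste(missing_ids, collapse = ", ")))
  }
  extra <- setdiff(have, samples$sample_id)
  if (length(extra) > 0) {
    abort(paste0("count matrix: unknown column(s) not in sample sheet: ",
                 paste(extra, collapse = ", ")))
  }
  vals <- as.matrix(mat[, -1])
  if (anyNA(vals)) abort("count matrix: missing values")
  if (any(vals < 0)) abort("count matrix: negative values")
  out <- mat[c("feature_id", samples$sample_id)]
  attr(out, "unit") <- "raw_counts"
  out
}

#' Write a feature-by-sample matrix as TSV
#' @param expr Wide expression tibble (`feature_id` + sample columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read poly(A) read 3'-end records
#'
#' BED6-like TSV with two extra columns, no header:
#' `chrom start end read_id score strand gene_id sample_id`. Positions are
#' 0-based half-open on disk and converted to 1-based on load
#' (`position = start + 1`).
#'
#' @param path File path.
#' @param annotation Optional [genome_annotation()]; when given, positions are
#'   validated against chromosome lengths.
#' @return Tibble with columns `gene_id`, `sample_id`, `chrom`, `position`
#'   (1-based), `strand`, `read_id`. Empty file yields an empty tibble.
#' @export
read_polya_ends <- function(path, annotation = NULL) {
  cols <- c("chrom", "start", "end", "read_id", "score", "strand",
            "gene_id", "sample_id")
  empty <- tibble(gene_id = character(), sample_id = character(),
                  chrom = character(), position = integer(),
                  strand = character(), read_id = character())
  if (file.size(path) == 0) return(empty)
  bed <- readr::read_tsv(path, col_names = cols,
                         col_types = "ciiccccc", progress = FALSE)
  if (nrow(bed) == 0) return(empty)
  out <- tibble(
    gene_id = bed$gene_id, sample_id = bed$sample_id, chrom = bed$chrom,
    position = bed$start + 1L, strand = bed$strand, read_id = bed$read_id
  )
  if (!is.null(annotation)) {
    lens <- setNames(annotation$chromosomes$length, annotation$chromosomes$chrom)
    known <- out$chrom %in% names(lens)
    if (any(!known)) {
      abort(paste0("poly(A) ends on unknown chromosome(s): ",
                   paste(unique(out$chrom[!known]), collapse = ", ")))
    }
    if (any(out$position < 1L | out$position > lens[out$chrom])) {
      abort("poly(A) end position outside chromosome length")
    }
  }
  out
}

#' Write poly(A) read 3'-end records as BED6-like TSV
#'
#' Inverse of [read_polya_ends()]: 1-based positions are written 0-based
#' half-open (`start = position - 1`, `end = position`).
#'
#' @param ends Tibble as returned by [read_polya_ends()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_polya_ends <- function(ends, path) {
  bed <- tibble(
    chrom = ends$chrom, start = ends$position - 1L, end = ends$position,
    read_id = ends$read_id, score = ".", strand = ends$strand,
    gene_id = ends$gene_id, sample_id = ends$sample_id
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

# introns of one transcript from its sorted exon table; zero-row tibble for
# single-exon transcripts
transcript_introns <- function(exon_start, exon_end) {
  n <- length(exon_start)
  if (n < 2L) {
    return(tibble(start = integer(), end = integer()))
  }
  tibble(start = exon_end[-n] + 1L, end = exon_start[-1] - 1L)
}
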