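# Alternative polyadenylation: cluster read 3'-end positions into poly(A)
# sites, summarise sites per gene, and compare site-count distributions
# between sexes.

#' Cluster read 3'-end positions into poly(A) sites
#'
#' Single-linkage clustering of sorted positions within each
#' (gene, group): consecutive ends at most `merge_dist` bp apart join one
#' cluster; clusters supported by fewer than `min_support` reads are
#' discarded. The representative position is the most frequent member
#' position (ties broken by the smallest).
#'
#' @param ends Tibble of read 3' ends (`gene_id`, `sample_id`, `chrom`,
#'   `position`, `strand`), e.g. from [read_polya_ends()] or
#'   [simulate_polya_ends()].
#' @param samples Sample sheet; required for `by = "sex_tissue"`.
#' @param merge_dist Maximum gap joining consecutive ends (default 24).
#' @param min_support Minimum reads per retained site (default 2).
#' @param by `"sex_tissue"` (pool replicates within sex x tissue, the
#'   four-group convention) or `"sample"`.
#' @return Tibble with columns `gene_id`, `group`, `chrom`, `strand`,
#'   `position` (representative), `cluster_start`, `cluster_end`,
#'   `n_reads`.
#' @export
cluster_polya_sites <- function(ends, samples = NULL, merge_dist = 24,
                                min_support = 2,
                                by = c("sex_tissue", "sample")) {
  by <- match.arg(by)
  empty <- tibble(gene_id = character(), group = character(),
                  chrom = character(), strand = character(),
                  position = integer(), cluster_start = integer(),
                  cluster_end = integer(), n_reads = integer())
  if (nrow(ends) == 0L) return(empty)
  if (by == "sex_tissue") {
    if (is.null(samples)) abort("samples sheet required for by = 'sex_tissue'")
    samples <- validate_sample_sheet(samples)
    ends <- ends |>
      inner_join(samples[c("sample_id", "sex", "tissue")], by = "sample_id") |>
      mutate(group = paste(.data$sex, .data$tissue, sep = "_"))
  } else {
    ends <- mutate(ends, group = .data$sample_id)
  }
  ends |>
    group_by(.data$gene_id, .data$group, .data$chrom, .data$strand) |>
    arrange(.data$position, .by_group = TRUE) |>
    reframe({
      pos <- .data$position
      cl <- cumsum(c(1L, as.integer(diff(pos) > merge_dist)))
      map_dfr(split(pos, cl), function(p) {
        tb <- table(p)
        rep_pos <- as.integer(names(tb)[which.max(tb)])  # ties -> smallest
        tibble(position = rep_pos,
               cluster_start = min(p), cluster_end = max(p),
               n_reads = length(p))
      })
    }) |>
    filter(.data$n_reads >= min_support) |>
    select("gene_id", "group", "chrom", "strand", "position",
           "cluster_start", "cluster_end", "n_reads")
}

#' Poly(A) sites per gene and the site-count distribution
#'
#' Counts surviving sites per gene per group and bins them into the
#' categories 1, 2, 3, 4, >=5. Only genes with at least one surviving site
#' appear (genes "with evidence of a poly(A) site").
#'
#' @param sites Output of [cluster_polya_sites()].
#' @return List of two tibbles: `per_gene` (`gene_id`, `group`, `n_sites`,
#'   `category`) and `distribution` (`group`, `category`, `n_genes`,
#'   `fraction`, plus the per-group fraction of genes with >= 2 sites as
#'   attribute column `frac_multi`).
#' @export
polya_sites_per_gene <- function(sites) {
  cats <- c("1", "2", "3", "4", ">=5")
  per_gene <- sites |>
    group_by(.data$gene_id, .data$group) |>
    summarise(n_sites = dplyr::n(), .groups = "drop") |>
    mutate(category = factor(ifelse(.data$n_sites >= 5L, ">=5",
                                    as.character(.data$n_sites)),
                             levels = cats))
  distribution <- per_gene |>
    group_by(.data$group, .data$category, .drop = FALSE) |>
    summarise(n_genes = dplyr::n(), .groups = "drop_last") |>
    mutate(fraction = .data$n_genes / sum(.data$n_genes)) |>
    ungroup()
  frac_multi <- per_gene |>
    group_by(.data$group) |>
    summarise(frac_multi = mean(.data$n_sites >= 2L), .groups = "drop")
  distribution <- left_join(distribution, frac_multi, by = "group")
  list(per_gene = per_gene, distribution = distribution)
}

#' Compare poly(A) site-count distributions between sexes
#'
#' Chi-square test of independence on the sex x site-count-category
#' contingency table of gene counts within one tissue. Categories with an
#' expected count below 1 are pooled into their lower neighbour.
#'
#' @param per_gene `per_gene` tibble from [polya_sites_per_gene()] computed
#'   with `by = "sex_tissue"` grouping.
#' @param tissue Tissue label.
#' @return List of class `polya_sex_test`: `tissue`, `table`, `statistic`,
#'   `df`, `p_value`.
#' @export
compare_polya_sex <- function(per_gene, tissue) {
  dat <- per_gene |>
    tidyr::separate_wider_delim("group", "_", names = c("sex", "tissue"),
                                too_many = "merge") |>
    filter(.data$tissue == !!tissue)
  for (sx in c("M", "F")) {
    if (!any(dat$sex == sx)) {
      abort(paste0("no genes with poly(A) sites for sex ", sx,
                   " in tissue ", tissue))
    }
  }
  tab <- table(dat$sex, as.character(dat$category))
  ord <- intersect(c("1", "2", "3", "4", ">=5"), colnames(tab))
  tab <- tab[, ord, drop = FALSE]
  # pool sparse categories (expected < 1) into the lower neighbour
  repeat {
    if (ncol(tab) <= 1L) break
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- which(apply(expected, 2, min) < 1)
    if (length(bad) == 0L) break
    j <- max(bad)
    k <- if (j > 1L) j - 1L else j + 1L
    tab[, k] <- tab[, k] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  if (ncol(tab) == 1L) {
    out <- list(tissue = tissue, table = tab, statistic = 0,
                df = 0L, p_value = 1)
  } else if (all(tab == tab[rep(1L, nrow(tab)), , drop = FALSE])) {
    # identical rows: no dependence by construction
    out <- list(tissue = tissue, table = tab, statistic = 0,
                df = as.integer((nrow(tab) - 1) * (ncol(tab) - 1)),
                p_value = 1)
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    out <- list(tissue = tissue, table = tab,
                statistic = unname(ht$statistic),
                df = as.integer(unname(ht$parameter)),
                p_value = unname(ht$p.value))
  }
  class(out) <- "polya_sex_test"
  out
}

#' @export
print.polya_sex_test <- function(x, ...) {
  cat("Poly(A) site-count distribution, M vs F - tissue ", x$tissue, "\n",
      sep = "")
  print(x$table)
  cat("chi-square = ", round(x$statistic, 4), ", df = ", x$df,
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.polya_sex_test <- function(x, ...) {
  tibble(tissue = x$tissue, statistic = x$statistic, df = x$df,
         p.value = x$p_value)
}

#' @rdname tidiers
#' @export
glance.polya_sex_test <- function(x, ...) tidy.polya_sex_test(x)
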