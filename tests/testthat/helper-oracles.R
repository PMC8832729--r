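# Independent brute-force oracles used across tests. Each is written
# directly from the operation's definition and shares no code with the
# package implementation.

# exact two-sided Wilcoxon p by full enumeration of group assignments
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  ws <- combn(length(pooled), n1, function(idx) sum(r[idx]))
  eps <- 1e-8
  min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
}

# Benjamini-Hochberg step-up from first principles
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# transitive-closure single-linkage clustering of integer positions
oracle_cluster <- function(pos, merge_dist) {
  n <- length(pos)
  if (n == 0) return(list())
  cl <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (i in seq_along(cl)) {
      for (j in seq_along(cl)) {
        if (j <= i) next
        gap <- min(abs(outer(pos[cl[[i]]], pos[cl[[j]]], "-")))
        if (gap <= merge_dist) {
          cl[[i]] <- c(cl[[i]], cl[[j]])
          cl[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  lapply(cl, function(idx) sort(pos[idx]))
}

# window scan by an explicit double loop over (window, gene)
oracle_window_scan <- function(position, log2_mf, outlier, chrom_len,
                               window, shift) {
  starts <- seq(0, max(chrom_len - 1, 0), by = shift)
  res <- NULL
  for (ws in starts) {
    we <- min(ws + window, chrom_len)
    vals <- c()
    for (i in seq_along(position)) {
      if (!outlier[i] && position[i] > ws && position[i] <= we) {
        vals <- c(vals, log2_mf[i])
      }
    }
    res <- rbind(res, data.frame(
      window_start = ws, window_end = we, n_genes = length(vals),
      mean_log2_mf = if (length(vals)) mean(vals) else NA_real_,
      mean_amplitude = if (length(vals)) mean(abs(vals)) else NA_real_
    ))
  }
  res
}

# all-pairs lncRNA-target scan from span coordinates
oracle_targets <- function(lncs, genes, max_dist = 100000) {
  out <- NULL
  for (i in seq_len(nrow(lncs))) {
    for (j in seq_len(nrow(genes))) {
      if (lncs$chrom[i] != genes$chrom[j]) next
      gap <- max(0, max(lncs$start[i], genes$start[j]) -
                    min(lncs$end[i], genes$end[j]) - 1)
      if (gap < max_dist) {
        out <- rbind(out, data.frame(lncrna_id = lncs$transcript_id[i],
                                     gene_id = genes$gene_id[j]))
      }
    }
  }
  out
}

# brute-force splicing-event enumerator for one gene: checks every
# candidate sub-interval relation between each pair of isoforms directly
# against the five definitions
oracle_splice_events <- function(exons_by_tx, strand) {
  tx_ids <- names(exons_by_tx)
  introns_of <- function(e) {
    e <- e[order(e$start), ]
    n <- nrow(e)
    if (n < 2) return(data.frame(start = integer(), end = integer()))
    data.frame(start = e$end[-n] + 1, end = e$start[-1] - 1)
  }
  has_intron <- function(it, s, e) any(it$start == s & it$end == e)
  has_exon <- function(ex, s, e) any(ex$start == s & ex$end == e)
  found <- NULL
  emit <- function(type, s, e) {
    found <<- rbind(found, data.frame(event_type = type, event_start = s,
                                      event_end = e))
  }
  for (a in seq_along(tx_ids)) {
    for (b in seq_along(tx_ids)) {
      if (b <= a) next
      for (dir in 1:2) {
        e1 <- exons_by_tx[[if (dir == 1) a else b]]
        e2 <- exons_by_tx[[if (dir == 1) b else a]]
        e1 <- e1[order(e1$start), ]; e2 <- e2[order(e2$start), ]
        i1 <- introns_of(e1); i2 <- introns_of(e2)
        # exon skipping: exon of e2 strictly inside an intron of e1 whose
        # boundaries match e2's flanking introns
        for (k in seq_len(nrow(i1))) {
          for (x in seq_len(nrow(e2))) {
            if (e2$start[x] > i1$start[k] && e2$end[x] < i1$end[k] &&
                has_intron(i2, i1$start[k], e2$start[x] - 1) &&
                has_intron(i2, e2$end[x] + 1, i1$end[k])) {
              emit("exon_skipping", e2$start[x], e2$end[x])
            }
          }
        }
        # intron retention: intron of e1 absent from e2, covered exonically
        for (k in seq_len(nrow(i1))) {
          overlapping <- nrow(i2) > 0 &&
            any(i2$start <= i1$end[k] & i2$end >= i1$start[k])
          covered <- any(e2$start <= i1$start[k] - 1 &
                         e2$end >= i1$end[k] + 1)
          if (!overlapping && covered &&
              !has_intron(i2, i1$start[k], i1$end[k])) {
            emit("intron_retention", i1$start[k], i1$end[k])
          }
        }
        if (dir == 2) next  # boundary/MXE relations are symmetric; run once
        # alternative boundaries: intron pairs sharing exactly one end,
        # with the variable region contained in the longer exon
        for (k in seq_len(nrow(i1))) {
          for (l in seq_len(nrow(i2))) {
            s1 <- i1$start[k]; f1 <- i1$end[k]
            s2 <- i2$start[l]; f2 <- i2$end[l]
            if (f1 == f2 && s1 != s2) {
              rs <- min(s1, s2); re <- max(s1, s2) - 1
              longer <- if (s1 > s2) e1 else e2
              if (any(longer$start <= rs & longer$end >= re)) {
                emit(if (strand == "+") "alt_5ss" else "alt_3ss", rs, re)
              }
            }
            if (s1 == s2 && f1 != f2) {
              rs <- min(f1, f2) + 1; re <- max(f1, f2)
              longer <- if (f1 < f2) e1 else e2
              if (any(longer$start <= rs & longer$end >= re)) {
                emit(if (strand == "+") "alt_3ss" else "alt_5ss", rs, re)
              }
            }
          }
        }
        # mutually exclusive exons
        for (xi in seq_len(nrow(e1))) {
          if (xi == 1 || xi == nrow(e1)) next
          for (xj in seq_len(nrow(e2))) {
            if (xj == 1 || xj == nrow(e2)) next
            a1 <- e1$end[xi - 1] + 1; b1 <- e1$start[xi + 1] - 1
            a2 <- e2$end[xj - 1] + 1; b2 <- e2$start[xj + 1] - 1
            if (a1 != a2 || b1 != b2) next
            if (has_exon(e2, e1$start[xi], e1$end[xi])) next
            if (has_exon(e1, e2$start[xj], e2$end[xj])) next
            if (e1$end[xi] >= e2$start[xj] && e2$end[xj] >= e1$start[xi]) next
            both <- any(vapply(exons_by_tx, function(e) {
              has_exon(e, e1$start[xi], e1$end[xi]) &&
                has_exon(e, e2$start[xj], e2$end[xj])
            }, logical(1)))
            if (!both) {
              emit("mutually_exclusive_exons",
                   min(e1$start[xi], e2$start[xj]),
                   max(e1$end[xi], e2$end[xj]))
            }
          }
        }
      }
    }
  }
  if (is.null(found)) {
    return(data.frame(event_type = character(), event_start = integer(),
                      event_end = integer()))
  }
  unique(found[order(found$event_type, found$event_start), ])
}

# compact event table for comparisons: one row per (type, start, end)
event_key <- function(df) {
  df <- df[df$event_type != "complex", ]
  sort(paste(df$event_type, df$event_start, df$event_end))
}
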