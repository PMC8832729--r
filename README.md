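# zdosage

Sex-chromosome dosage-effect analysis for long-read transcriptomes.

Birds have ZZ males and ZW females and no chromosome-wide dosage
compensation, so Z-linked genes are typically male-biased. `zdosage` is an
R package for characterising that bias from a transcript-level count matrix
and a GTF annotation, together with the post-transcriptional layers that
shape it. It computes:

- **Sex-bias statistics** — per-gene log₂ M:F = log₂(x̄_M / x̄_F) of
  normalized expression (no pseudocount; features must be expressed in both
  sexes), amplitude |log₂ M:F|, and outlier flags (|log₂ FC| > 5).
- **Z:AA comparisons** — within one sex, per-feature log₂(CPM + 1) of
  Z-linked versus autosomal features, tested with a Wilcoxon rank-sum test
  (exact enumeration when a group is small, tie- and continuity-corrected
  normal approximation otherwise).
- **Sliding-window scans** — 3 Mb windows every 1 Mb along a chromosome,
  averaging fold-change and amplitude per window, with merged top-region
  extraction.
- **Alternative splicing** — classification of isoform differences into
  the five canonical modes (exon skipping, intron retention, alternative
  5′/3′ splice sites, mutually exclusive exons), isoform-based PSI per
  sample, and differential splicing at |ΔPSI| ≥ 0.10 with BH FDR < 0.05.
- **lncRNA analysis** — candidate filtering (> 200 nt, ≥ 2 exons,
  external noncoding labels), positional classification into
  lincRNA / antisense / sense / intronic, cis-target assignment within a
  strict 100 kb span gap, male-bias calls (log₂ M:F > 0), and
  lncRNA–target correlations.
- **Alternative polyadenylation** — single-linkage clustering of read 3′
  ends (24 nt merge distance, ≥ 2 supporting reads), per-gene site-count
  distributions (1/2/3/4/≥5), and a between-sex chi-square comparison.

A seeded synthetic-data generator (`sim_config()`, `simulate_dataset()`)
builds an annotated toy genome — autosomes plus a Z chromosome, 2 tissues ×
2 sexes × 4 replicates, negative-binomial counts with configurable Z-linked
male bias and a regional hotspot, multi-isoform genes with known injected
splicing events, positionally constructed lncRNAs, and per-gene poly(A)
read ends — so every stage can be verified against ground truth.

## Worked example

```r
library(zdosage)
library(dplyr)

cfg <- sim_config(seed = 7)          # defaults: 1.75-fold Z bias, 31-36 Mb hotspot
dat <- simulate_dataset(cfg)
dat$annotation
#> <genome_annotation> 3 chromosome(s), 240 gene(s), 464 transcript(s), 3270 exon(s)

genes <- aggregate_to_genes(dat$counts, dat$annotation)
aut   <- dat$annotation$genes$gene_id[dat$annotation$genes$chrom != "Z"]
norm  <- normalize_counts(genes, method = "median_ratio",
                          reference_features = aut)
bias  <- sex_bias_table(norm, dat$samples, dat$annotation, "gonad")
fold_summary(bias)
#> # A tibble: 2 × 6
#>   group        n mean_log2_mf fold_mean_of_ratios fold_median_of_ratios
#> 1 Z           96       0.873                 1.88                  1.83
#> 2 autosome   144      -0.0162                1.01                  1.00
```

The Z-linked genes sit near the simulated 1.75-fold male bias (the mean is
pulled slightly above it by the hotspot genes), while autosomal genes stay
centred at log₂ M:F ≈ 0 — the package anchors its size factors on
autosomal genes precisely so that the Z-linked shift cannot leak into the
library-size estimate.

```r
cpm <- normalize_counts(genes)       # plain CPM; Z:AA is within-sample
z_aa_test(cpm, dat$samples, dat$annotation, "gonad", "F")
#> Z:AA comparison - tissue gonad, sex F
#>   n(Z) = 96, n(AA) = 144
#>   median log2 expr: Z = 10.809, AA = 11.665
#>   Wilcoxon W = 9650, p = 0.00027353 (normal)

top_region(window_scan(bias[bias$chrom == "Z", ], 8e7))
#> # A tibble: 1 × 6
#>   chrom region_start region_end stat         max_stat n_windows
#> 1 Z         31000000   36000000 mean_log2_mf     1.39         3
```

The female Z expression is significantly below the autosomal level (the
male comparison, not shown, is non-significant), and the window scan
relocalises the injected 31–36 Mb hotspot exactly.

```r
ev <- classify_splice_events(dat$annotation)
count(filter(ev, event_type != "complex"), event_type, sort = TRUE)
#> # A tibble: 5 × 2
#>   event_type                   n
#> 1 exon_skipping              136
#> 2 intron_retention            32
#> 3 alt_3ss                     20
#> 4 alt_5ss                     19
#> 5 mutually_exclusive_exons    17
```

Exon skipping dominates the event tally (136 / 224 ≈ 61% here), matching
the generator's configured mode weights. `run_pipeline(outdir, config =
cfg)` chains every stage, writes all result tables (with parameter header
comments) plus `summary.json`, and is byte-reproducible under a fixed
seed; `summarize_run(outdir)` recomputes the summary purely from the
written tables and `verify_run(outdir)` checks their integrity.

Plot helpers (`plot_sex_bias()`, `plot_window_scan()` /
`autoplot()`, `plot_splice_modes()`, `plot_lncrna_classes()`,
`plot_polya_distribution()`) return ggplot objects; test objects support
broom-style `tidy()` / `glance()`.

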