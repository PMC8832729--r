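---
title: "Methods: Z-chromosome dosage-effect analysis on synthetic long-read transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Z-chromosome dosage-effect analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdosage)
```

## The problem

Birds carry ZZ males and ZW females and lack a chromosome-wide dosage
compensation mechanism, so Z-linked genes tend to be expressed more highly
in males. `zdosage` implements the statistics used to characterise this
*dosage effect* in a bulk long-read transcriptome: per-gene male:female
expression ratios, within-sex comparisons of Z-linked versus autosomal
expression, a sliding-window scan that localises regionally concentrated
bias, and the three post-transcriptional layers that modulate it —
alternative splicing, positionally classified lncRNAs with cis targets, and
alternative polyadenylation.

Because the real sequencing data behind such a study is not required here,
the package ships a seeded generator that builds a toy genome with the
statistical structure the analysis assumes, with full ground truth. Every
analysis stage is therefore testable against construction rather than
against a frozen result file.

## The expression model and its statistics

Counts are modelled negative-binomially: for transcript $t$ of gene $g$ in
sample $s$,

$$K_{ts} \sim \mathrm{NB}\!\left(\mu_{ts},\ \phi\right),\qquad
\mu_{ts} = \beta_g\, u_t\, f_g(\mathrm{sex}_s)\, \ell_s,$$

with gene baseline $\beta_g$ log-normal, isoform usage $u_t$ Dirichlet
within the gene, library factor $\ell_s$ log-normal around 1 and dispersion
$\phi$ (variance $\mu + \phi\mu^2$). The sex factor encodes incomplete
dosage compensation: autosomal genes have $f_g \equiv 1$; for Z-linked
genes **males sit at the autosomal baseline and females at
$\beta_g / \rho$**, where $\rho$ is the configured male:female fold
(default 1.75). This parameterisation was chosen deliberately over the
alternative (females at baseline, males boosted): only the female-reduced
form yields the empirically observed pattern in which the male Z:AA ratio
is near 1 (non-significant) while the female Z:AA ratio is significantly
below 1. Both forms give the same M:F fold, so nothing else changes.

Per gene (or transcript) the central statistic is
$\log_2 \mathrm{M{:}F} = \log_2(\bar x_M / \bar x_F)$, the log-ratio of sex
means of normalized expression, computed without pseudocount: features with
a zero mean in either sex are excluded ("expressed in both sexes") rather
than offset, because an arbitrary offset distorts ratios of
lowly-expressed features. The *amplitude* is $|\log_2 \mathrm{M{:}F}|$;
records with amplitude above 5 are flagged as outliers, kept in tables, and
excluded from window and chromosome means. An optional pseudocount exists
for sensitivity checks only.

The Z:AA comparison is within-sex: per feature, the mean over the sex's
replicates of $\log_2(\mathrm{CPM} + 1)$, compared between Z-linked and
autosomal features with a Wilcoxon rank-sum test. The offset of 1 admits
zeros, which cannot be excluded sex-symmetrically in a single-sex analysis;
since the comparison is within samples, it is invariant to the
normalization method.

## Normalization: why ratio analyses are anchored on autosomes

`normalize_counts()` defaults to plain CPM (column sums; `scale = 1e6`,
with `scale = 1e4` available for the per-10,000-reads convention — ratios
are scale-invariant, so the choice never affects results). CPM is, however,
compositional: if 200 of 1,200 genes are Z-linked and 1.75-fold reduced in
females, female column totals shrink by $\approx 8\%$ and *every* autosomal
$\log_2 \mathrm{M{:}F}$ acquires a spurious $\approx -0.11$ shift. Robust
trimming (TMM, RLE) does not rescue this at realistic dispersion: with
$\phi = 0.1$ the per-gene M-value noise (SD $\approx 0.7$ log2) exceeds the
0.8 log2 Z shift, so trimmed means absorb a weighted share of it — we
verified the factors stay within 2% of 1 on constructed fixtures.

The pipeline therefore computes median-of-ratios size factors **anchored on
autosomal coding features** (`method = "median_ratio"`,
`reference_features =` autosomes): the scientific question is "Z relative
to autosomes, between sexes", which makes autosomes the natural invariant
set, and a median over $\ge 1000$ reference genes is insensitive to
per-gene noise. This restores autosomal centering to within about
$\pm 0.015$ and Z-fold recovery to within a few percent. Within-sample
analyses (Z:AA, PSI) are unaffected by the choice.

## Wilcoxon rank-sum modes

`wilcoxon_rank_sum()` reports the midrank sum of the first group and a
two-sided p-value. *Exact* mode enumerates all
$\binom{n_1+n_2}{n_1}$ assignments (valid under ties via midranks) and
doubles the smaller tail, capping at 1. *Normal* mode uses the
tie-corrected variance with a 0.5 continuity correction. *Auto* picks exact
when $\min(n_1,n_2) \le 8$ **and** the enumeration stays below $5\times
10^5$ combinations — the second condition matters for one-versus-many
splits (1 vs 1000 enumerates 1001 assignments; 8 vs 1000 cannot be
enumerated and falls back to the approximation).

A caution documented here because it is easy to over-trust the
approximation: no closed-form continuous approximation is uniformly
accurate at tiny sizes. Against exact enumeration over all achievable
statistics, the continuity-corrected normal approximation errs by up to
0.088 at $n = (2,2)$; an Edgeworth correction using the exact excess
kurtosis $\gamma_2 = -\tfrac{6}{5}\,(n_1^2+n_2^2+n_1 n_2+n_1+n_2)/(n_1 n_2
(n+1))$ still errs by 0.065, and a moment-matched Pearson-II fit by 0.085.
The errors concentrate at the central atoms of the discrete null
distribution. This is why auto mode insists on exact enumeration at small
sizes; the normal mode is adequate from roughly $\min(n) \ge 10$.

## Sliding-window scan and top region

Windows of 3 Mb tile $[0, L)$ every 1 Mb (half-open; trailing windows may
be partial). A gene belongs to every window containing its span midpoint —
the midpoint is symmetric and strand-free, and at 3 Mb resolution the
distinction from TSS-anchoring is immaterial. Windows average
$\log_2 \mathrm{M{:}F}$ and amplitude with equal gene weights (expression
weighting would let single high expressors dominate a window). Empty
windows carry `NA`. `top_region()` takes the maximal window (leftmost on
ties) and merges adjacent overlapping windows whose statistic is within 10%
of the maximum — a single window boundary should not split a contiguous
biased region.

## Splicing events, PSI and differential splicing

Isoform structures are compared pairwise on their intron chains and
classified into the five canonical modes: exon skipping (an exon of one
chain strictly inside an intron of the other, both flanking splice sites
shared), intron retention (an intron absent and exonically covered,
flanking bases included), alternative 5'/3' splice sites (intron pairs
sharing exactly one boundary, the variable region contained in the
longer-exon transcript's flanking exon; donor/acceptor labels resolved by
strand), and mutually exclusive exons (two internal exons, one per chain,
non-overlapping, inside the same shared outer splice sites, and — checked
gene-wide — never co-occurring in any isoform). Events found in several
pairs are merged by (type, coordinates) with inclusion/exclusion transcript
sets accumulated. Structural differences matching none of the five modes
are reported as `"complex"` and excluded from mode tallies; terminal-exon
differences (alternative first/last exons, APA-driven 3' ends) are not
splicing events. Unstranded transcripts are rejected because the 5'/3'
labels would be undefined.

PSI is isoform-based — inclusion expression over inclusion-plus-exclusion
expression per sample — which is the natural definition when
quantifications are full-length long reads rather than junction counts.
A zero denominator yields an undefined (flagged) PSI. Differential
splicing uses the rank-sum test on replicate PSIs per event (no
distributional assumption survives 4-vs-4 PSIs), Benjamini–Hochberg FDR
across the tissue's events, and the significance rule
$|\Delta\mathrm{PSI}| \ge 0.10$ **and** FDR $< 0.05$. Events with fewer
than two defined replicate PSIs in a sex are skipped with a recorded
reason, not silently dropped.

## lncRNA classification and cis targets

Candidates must have spliced length strictly greater than 200 nt, at least
2 exons, and an external noncoding label (the package does no
coding-potential scoring; the generator's truth supplies labels in
synthetic runs). The default exon rule is the standard multi-exon filter
($\ge 2$); the stricter more-than-two reading is available via
`min_exons = 3`. Classification is total and deterministic by precedence:
no span overlap with coding genes → lincRNA; exonic overlap opposite
strand → antisense; exonic overlap same strand → sense; full containment
in a coding intron (same strand by default) → intronic; residual
span-overlap cases resolve to antisense unless the strand-agnostic intronic
option admits them. Exonic-overlap tests run before the intronic test
because an exon-touching transcript is not "inside" an intron in any
useful sense.

Targets are positional only: every coding gene whose span gap to the
lncRNA span is strictly below 100 kb, symmetric by construction (gap
distance, not TSS anchoring), with upstream/downstream judged in the
lncRNA's orientation and overlap reported as distance 0. Rank and linear
correlations across all shared samples accompany each pair; zero-variance
vectors are flagged rather than propagated as NaN.

## Poly(A) site clustering

Read 3' ends are clustered per gene within (sex, tissue) groups —
replicates pooled, matching the four-group display convention; per-sample
mode is available. Clustering is single-linkage on sorted positions with a
24 nt merge distance: the typical span of poly(A)-site microheterogeneity,
safely above the generator's ±5 nt jitter and exposed as a flag. Clusters
need at least 2 supporting reads; the representative position is the modal
member (smallest on ties, a deterministic tie-break). Site counts per gene
are binned 1/2/3/4/≥5 and sexes are compared per tissue with a chi-square
test of independence on the gene-count table, pooling categories with
expected counts below 1 into their lower neighbour. When both sexes
recover identical distributions — which happens by design when read
support is ample and recovery exact — the statistic is 0 and p is 1.

## What the generator emulates, and what it does not

It emulates: non-overlapping gene loci placed uniformly per chromosome;
5–11-exon genes with 1–5 isoforms, each additional isoform differing from
the base by exactly one event in its own region (regions kept ≥ 2 exon
slots apart so injected events never interact); lncRNAs constructed to
realise their class exactly, with class proportions configurable (defaults
follow the four classes' reported shares: 76.16 / 11.92 / 0.66 / 11.26%);
per-gene poly(A) sites 200–400 bp apart near the 3' end with Poisson read
support (mean 8 per site per sample) and ±5 bp jitter; an optional hotspot
interval whose genes get an extra fold. The default poly(A) site-count
distribution (0.28 / 0.30 / 0.20 / 0.12 / 0.10 over 1–5 sites) puts 72% of
genes at ≥ 2 sites, the multi-site fraction a long-read survey of a
Z chromosome reports.

It does not emulate: raw reads or basecalling error, mapping and collapsing
artifacts, fusion transcripts, W-linked sequence (the W chromosome is
excluded from the ratio figures this analysis style produces, so it is not
simulated), genuinely novel event grammars beyond the five modes,
expression-coupled splicing, or biased coverage along transcripts. Passing
tests therefore certify the statistics and algorithms, not robustness to
upstream artefacts of real long-read data.

One open modelling choice: no effect-size distribution across Z genes is
established for this system, so the generator defaults to a constant fold
with an optional per-gene log-normal jitter (`fold_jitter_sd`), defaulting
to 0.

## Problem sizes used by the test suite

The bias-recovery and Z:AA analyses run on 1,000 autosomal + 200 Z-linked
single-isoform genes (dispersion 0.1, 4+4 replicates); the Z:AA
significance pattern and the hotspot relocalisation are each evaluated over
100 simulation seeds; the splicing classifier is checked against injected
truth on 500 multi-isoform genes and against a brute-force enumerator on
every generated ≤ 5-exon gene; differential-splicing calibration uses 300
null and 150 true-effect two-isoform genes; lncRNA construction fidelity
runs 20 seeds with balanced class proportions; poly(A) clustering is
compared with a transitive-closure oracle on 200 random end-sets at four
merge distances. These sizes give stable Monte-Carlo margins for every
threshold asserted.

## Known limitations

- The five-mode grammar is pairwise; nested or chained events in one
  region are reported as `complex`, not decomposed.
- PSI from isoform abundances inherits quantification error of
  low-expressed isoforms; junction-level PSI is out of scope.
- Target assignment is proximity-only; it deliberately over-reports
  relative to mechanistic (base-pairing or perturbation) evidence.
- The chi-square APA comparison treats genes as independent observations
  within a group.
- The normal Wilcoxon mode should not be trusted below $\min(n) \approx
  10$; auto mode exists precisely to route such calls to enumeration.
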