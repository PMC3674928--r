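---
title: "Genomic-context categorisation and comparison: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-context categorisation and comparison: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcontext)
```

## The seven-category model

Sets of genomic loci produced by ChIP profiling (transcription-factor
binding peaks, histone-mark domains, methylation loci) are routinely
interpreted through their position relative to gene annotation. peakcontext
formalises this by partitioning *every base* of the genome into exactly one
of seven exhaustive, mutually exclusive categories:

| category     | definition                                                          |
|--------------|---------------------------------------------------------------------|
| `exon`       | inside an exon of any gene                                          |
| `intron`     | inside a gene body but not one of its exons                         |
| `five_near`  | within the near limit upstream of a gene 5' end (promoter side)     |
| `three_near` | within the near limit downstream of a gene 3' end                   |
| `five_far`   | between the near and far limits upstream of a 5' end                |
| `three_far`  | between the near and far limits downstream of a 3' end              |
| `distant`    | everything else                                                     |

Overlapping annotation is resolved by a fixed precedence order — the table
order above, `exon` highest — so a base that is, say, intronic in one gene
and promoter-proximal to another is `intron`. Within one tier, membership
from *any* gene suffices; the map is a merged, gene-anonymous partition.
Because the categories tile the genome exactly once, category counts over a
locus set form a well-defined multinomial, which is what makes the
between-set statistics below valid.

Two tunable distances control the flank tiers: the **near limit** (default
5000 bp) and the **far limit** (default 25000 bp), with
`0 < near <= far`. Setting them equal simply abolishes the far tiers. For
compact genomes, or to mirror analyses phrased in terms of "promoter =
1 kb", both can be lowered (e.g. near 1000 / far 3000). Flanks are
truncated at chromosome ends, never wrapped. When no chromosome sizes are
supplied, each chromosome is taken to end `far_limit` bp past its last
annotated coordinate, which keeps the partition well defined without a
genome download.

Gene models are gene-level: all transcripts of a gene are merged (span =
union span, exons = union of exons with overlaps merged). The model does
not distinguish UTR from CDS exons, and it includes every gene record in
the input regardless of biotype; filtering, if wanted, belongs upstream.

## Locus-level context

A locus (BED interval) is categorised at its **midpoint**
(`floor((start+end)/2)` in 0-based coordinates). A wide peak can straddle
several categories; the midpoint rule keeps one category per locus, which
the homogeneity test's "mutually exclusive categories" assumption requires.

The **nearest gene** minimises the point-to-interval distance from the
midpoint to the gene span on the half-open line
(`max(0, start - mid, mid - end)`, 0 inside the span). Ties break
deterministically: smallest chromosome name, then smallest gene start, then
lexicographic gene id. Signed distances to the nearest gene's 5' and 3'
ends are measured **along the direction of transcription**: positive means
the midpoint lies 3'-ward of that end, negative upstream of it. A midpoint
inside the gene thus has `dist_5prime >= 0` and `dist_3prime <= 0`, and the
two distances always differ by the span length. Loci on chromosomes with no
genes keep a nearest gene (the global tie-break winner) but `NA` distances;
loci on chromosomes absent from the annotation are counted as `distant` and
logged, never dropped silently.

One numerical subtlety: because the midpoint is a base but the span
boundaries are half-open coordinates, mirroring the genome
(`x -> L - x`, strands flipped) preserves every category exactly but can
shift signed distances by one base. The test-suite asserts categories
exactly and distances to within 1 bp under mirroring.

Distance histograms default to a ±100 kb range in 5 kb half-open bins —
a scale at which promoter-proximal structure is visible for typical
vertebrate peak sets; values outside the range (and undefined distances)
are tallied separately rather than clipped into edge bins.

## Comparing two category distributions

Given a foreground (the set under study) and a background (its reference)
with totals $n_1$, $n_2$, $n = n_1 + n_2$ and per-category counts
$n_{1i}$, $n_{2i}$, the homogeneity of the two multinomials is tested with
the Brandt–Snedecor computational form of the chi-square test of
homogeneity for $k$ binomial proportions:

$$\chi^2 = \frac{n^2}{n_1 n_2}\left[\sum_{i=1}^{k}
\frac{n_{1i}^2}{n_{1i}+n_{2i}} - \frac{n_1^2}{n}\right],
\qquad p = P\!\left(\chi^2_{k-1} \ge \chi^2\right).$$

This is algebraically identical to the Pearson statistic on the
$2 \times k$ table (the suite verifies agreement to $10^{-9}$ on random
tables); identical distributions give statistic 0 and p-value 1. Categories
empty in both sets are dropped and the degrees of freedom reduced, since
the statistic's denominator is undefined for them; fewer than two non-empty
categories is an error.

Assumptions — independent observations, a background at least twice the
foreground, exhaustive mutually exclusive categories — are surfaced as
warnings (including expected cells below 5), never as errors. In
particular, comparing a subset against its superset is allowed, as counts
are used as-is with no overlap bookkeeping. Users should know what that
costs: if the foreground is a uniform subsample of fraction $f$ of the
background's loci, the statistic is deflated by roughly $(1-f)/(1+f)$, so
the test is *conservative* for subset comparisons (at $f = 1/4$ the
nominal 5% level rejects about 1% of the time). The suite asserts
conservativeness for the subset case and proper calibration (5% ± 1.5%
over 2000 replicates at $n_1 = 500$, $n_2 = 1000$) for independent
samples.

Per-category effects use the log-likelihood **G-test of independence** on
the $2 \times 2$ table of each category against the union of the others,
$G = 2\sum O \ln(O/E)$ with margin-based expectations, empty cells
contributing 0, and no Williams or Yates correction. Enrichment is
reported as the foreground/background frequency ratio (undefined when the
background count is 0). Both raw and Bonferroni-adjusted (over the seven
categories) p-values are reported; significance stars
(`*** < 0.001`, `** < 0.01`, `* < 0.05`) follow the *adjusted* values —
the conservative, transparent choice. P-values below double precision
print as `< 2.2e-16`.

## GO over-representation of nearest genes

The foreground's nearest-gene set is tested against the background's
nearest-gene set term for term: annotations are first propagated to all
`is_a` ancestors (the smallest defensible closure; `part_of` is
deliberately ignored), then each term with at least one population hit gets
a one-sided hypergeometric p-value for observing at least the foreground's
hit count, Benjamini–Hochberg adjusted across tested terms. Terms are
tested independently of the GO graph; no parent–child conditioning or
model-based scoring is attempted. Inputs are a two-column gene→term TSV
plus an OBO 1.2 file, so any species — indeed any ontology — is usable.
When the study set is not a subset of the population, stray study genes
are dropped with a warning.

## The synthetic-data generator

`synthetic_spec()` / `synth_annotation()` / `synth_loci()` generate a
seeded, fully reproducible test genome: by default 2 chromosomes of 1 Mb
carrying 40 non-overlapping genes of 2–10 kb with 1–5 exons each and random
strands, written as GTF plus a sizes file. Loci are drawn
**category-first**: a category from the target probabilities (defaults
weight intergenic space most heavily — 10% exon, 15% intron, 15/10% near
flanks, 10/10% far flanks, 30% distant), then a uniform base within that
category's territory, emitted as midpoint ± 25 bp. This makes the true
category of every locus known by construction, so the whole pipeline can be
checked for exact recovery (within multinomial sampling error: the suite
and the end-to-end check use 2000 loci and a 3-standard-error band per
category).

What the generator emulates: strand-annotated multi-exon genes, overlapping
flank geometry, all seven categories populated, BED/GTF round-trips. What
it does not: overlapping genes and nested transcripts, chromosome-scale
length heterogeneity, biased peak widths, and any sequence-level signal.
Passing tests therefore validate the geometry and the statistics, not
robustness to pathological real-world annotation, which is exercised only
by the parser-level tests (multi-chromosome genes, malformed lines).

## Problem sizes and numerical choices

The test-suite runs entirely on synthetic data at desk scale: 1 Mb × 2
chromosome genomes, hundreds to 2000 loci, 2000-replicate null
calibrations, 200 random tables against the independent Pearson oracle,
and 500–1000 random-base comparisons against a brute-force per-gene
precedence scan. The statistic guards against tiny negative rounding at
the null (`max(chi2, 0)`); category maps are asserted disjoint and
gap-free by construction checks rather than floating-point tolerance,
as all coordinates are integers.

## Limitations

* Categories are gene-relative only; regulatory-feature tracks enter as
  boolean overlap flags, not as categories of their own, because no
  defensible precedence against the gene tiers exists.
* No UTR/CDS distinction, no transcript-level categories.
* The G-test is asymptotic; with very small categories the per-category
  p-values inherit the usual chi-square small-count caveats (flagged by the
  assumption checks).
* Enrichment analysis is term-for-term; GO graph dependence between terms
  is ignored by design.
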