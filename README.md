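# peakcontext

Genomic-context categorisation and statistical comparison of locus sets.

ChIP profiling (ChIP-seq, ChIP-on-chip, methylation mapping) yields sets of
genomic loci whose first-pass interpretation is positional: where do the
sites sit relative to genes, and does one set of sites — say, a subset of
binding sites lacking a cofactor — sit *differently* from another?
peakcontext answers both questions for anyone with a BED file of loci and a
gene annotation (GTF, GFF3 or BED12), offline and reproducibly.

## What it computes

**Categorisation.** Every base of the genome is assigned exactly one of
seven exhaustive, mutually exclusive categories — `exon`, `intron`,
`five_near`, `three_near`, `five_far`, `three_far`, `distant` — by
flattening the (possibly overlapping) gene annotation under a fixed
precedence order, with user-chosen near/far flank limits (defaults 5 kb and
25 kb). Each locus is categorised at its midpoint and annotated with its
nearest gene, the direction of transcription, and signed strand-aware
distances to the gene's 5' and 3' ends.

**Comparison.** Two locus sets (foreground = the set under study,
background = its reference) are compared with the Brandt–Snedecor
chi-square test of homogeneity for k binomial distributions,

```
chi2 = n^2/(n1*n2) * [ sum_i n1i^2/(n1i+n2i) - n1^2/n ],   df = k-1
```

(the computational form of the Pearson homogeneity statistic), plus a
per-category log-likelihood G-test of each category against the union of
the others, with enrichment ratios, Bonferroni-adjusted p-values and
significance stars.

**Extras.** Distance histograms, TSS-in-window counts, element-track
overlap flags (CpG islands, ESTs, ...), reference sequence retrieval,
term-for-term GO over-representation of the nearest genes (hypergeometric,
BH-adjusted, from a gene→term TSV plus an OBO file), SVG report plots, and
a seeded synthetic annotation/locus generator with known category
structure.

## Worked example

Generate a synthetic genome, draw a promoter/exon-biased foreground of 600
loci and a background of 2000 loci with the default mix, and compare:

```r
library(peakcontext)

ann_spec <- synthetic_spec(seed = 42L)
ann <- synth_annotation(ann_spec, dir = "example")
map <- flatten_categories(ann$genes)          # near = 5 kb, far = 25 kb

bg_spec <- ann_spec                           # background: the default mix
fg_spec <- synthetic_spec(seed = 43L, n_loci = 600L,
                          target_category_probs = c(0.25, 0.15, 0.30, 0.05,
                                                    0.05, 0.05, 0.15))
bg <- synth_loci(bg_spec, map)
fg <- synth_loci(fg_spec, map)

report <- compare_distributions(
  summarize_categories(annotate_loci(fg, ann$genes, map), "promoter-biased"),
  summarize_categories(annotate_loci(bg, ann$genes, map), "background"))
print(report)
```

```
Comparison: promoter-biased (foreground, n = 600) vs background (background, n = 2000)
Brandt-Snedecor homogeneity test: chi2 = 243.3, df = 6, p = < 2.2e-16 (n1 = 600, n2 = 2000)
  category         fg       bg  fg_freq  bg_freq   ratio         G          p      p_adj stars
  exon            163      222   0.2717   0.1110   2.447     84.37  < 2.2e-16  < 2.2e-16 ***
  intron           81      303   0.1350   0.1515   0.891     1.016     0.3136          1
  five_near       190      294   0.3167   0.1470   2.154     80.03  < 2.2e-16  < 2.2e-16 ***
  three_near       36      179   0.0600   0.0895   0.670     5.661    0.01734     0.1214
  five_far         28      203   0.0467   0.1015   0.460     19.51  1.001e-05  7.006e-05 ***
  three_far        25      191   0.0417   0.0955   0.436     20.18  7.064e-06  4.945e-05 ***
  distant          77      608   0.1283   0.3040   0.422     81.85  < 2.2e-16  < 2.2e-16 ***
```

Reading it: the homogeneity test says the two distributions differ
overall (p < 2.2e-16). Per category, the foreground is ~2.4-fold enriched
in exons and ~2.2-fold in promoter-proximal (`five_near`) positions, and
depleted everywhere distal — exactly the bias it was drawn with; `intron`
and `three_near` show no significant difference after Bonferroni
adjustment. The same analysis runs from the shell:

```sh
./exec/peakcontext fixtures --seed 42 --out example
./exec/peakcontext compare fg.bed bg.bed example/synthetic_annotation.gtf \
    --sizes example/synthetic_annotation.sizes --near 5000 --far 25000 --out results
```

which writes `comparison.tsv` and the SVG report (pie chart, side-by-side
frequency barplot, star-annotated ratio barplot, distance histograms).

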