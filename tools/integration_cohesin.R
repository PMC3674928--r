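#!/usr/bin/env Rscript
# Optional integration run on real data: compares a subset of cohesin ChIP
# binding sites lacking CTCF (foreground) against all cohesin sites
# (background) with near = 1000 bp and far = 3000 bp, and checks the expected
# direction pattern: over-representation of five_near and exon, and
# under-representation of the 3' categories.
#
# Requires files the repository does not ship (a human gene annotation in
# GTF/GFF3 and the two BED files of binding sites):
#   Rscript tools/integration_cohesin.R no_CTCF_cohesin.bed cohesin.bed \
#       Homo_sapiens.gtf [chrom.sizes]

suppressPackageStartupMessages(library(peakcontext))
args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 3) stop("usage: integration_cohesin.R fg.bed bg.bed annotation [sizes]")

sizes <- if (length(args) >= 4) read_chrom_sizes(args[4]) else NULL
genes <- read_gene_models(args[3], chrom_lengths = sizes)
map <- flatten_categories(genes, near_limit = 1000, far_limit = 3000)
fg <- summarize_categories(annotate_loci(read_bed(args[1]), genes, map), "no-CTCF cohesin")
bg <- summarize_categories(annotate_loci(read_bed(args[2]), genes, map), "all cohesin")
rep <- compare_distributions(fg, bg)
print(rep)

dir_of <- function(cat) rep$per_category$direction[rep$per_category$category == cat]
ok <- rep$homogeneity$p_value < 2.2e-16 &&
  dir_of("five_near") == "over" && dir_of("exon") == "over" &&
  dir_of("three_near") == "under" && dir_of("three_far") == "under"
cat(sprintf("\ndirection pattern %s\n", if (ok) "CONFIRMED" else "NOT confirmed"))
quit(status = if (ok) 0 else 1)
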