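# Shared fixtures and independent oracles for the test suite.
# Coordinates in these helpers are BED convention (0-based half-open),
# matching the worked examples they encode.

# Toy annotation: chr1 of 10 kb; G1 forward [1000,2000) with exons
# [1000,1200) and [1800,2000); G2 reverse [4000,5000), single exon.
toy_gene_models <- function() {
  df <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                   start = c(1000, 4000), end = c(2000, 5000),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  df$exons <- list(rbind(c(1000, 1200), c(1800, 2000)),
                   rbind(c(4000, 5000)))
  gene_models_from_df(df, chrom_lengths = c(chr1 = 10000L))
}

# A width-1 locus whose midpoint is the 0-based base b0.
point_locus <- function(chrom, b0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(b0 + 1L, width = 1L))
}

# A locus from BED coordinates.
bed_locus <- function(chrom, start0, end0, strand = "*", name = NA_character_) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                         strand = strand, name = name, score = NA_real_)
}

# Random annotation as a plain data.frame (0-based), independent of the
# package's own generator, for oracle-based property tests.
random_genes_df <- function(seed, n_chroms = 2L, chrom_len = 50000L,
                            genes_per_chrom = 6L) {
  set.seed(seed)
  rows <- list()
  for (ci in seq_len(n_chroms)) {
    chrom <- paste0("rchr", ci)
    for (gi in seq_len(genes_per_chrom)) {
      len <- sample(500:3000, 1)
      s <- sample(0:(chrom_len - len - 1), 1)
      n_ex <- sample(1:3, 1)
      if (n_ex == 1L) {
        ex <- rbind(c(s, s + len))
      } else {
        cuts <- sort(sample(seq_len(len - 1), 2L * n_ex - 2L))
        bounds <- c(0, cuts, len) + s
        idx <- seq(1, 2L * n_ex - 1L, by = 2)
        ex <- cbind(bounds[idx], bounds[idx + 1])
      }
      rows[[length(rows) + 1L]] <-
        list(gene_id = sprintf("R%d_%d", ci, gi), chrom = chrom,
             start = s, end = s + len,
             strand = sample(c("+", "-"), 1), exons = ex)
    }
  }
  df <- data.frame(gene_id = vapply(rows, `[[`, "", "gene_id"),
                   chrom = vapply(rows, `[[`, "", "chrom"),
                   start = vapply(rows, `[[`, 0, "start"),
                   end = vapply(rows, `[[`, 0, "end"),
                   strand = vapply(rows, `[[`, "", "strand"),
                   stringsAsFactors = FALSE)
  df$exons <- lapply(rows, `[[`, "exons")
  df
}

# Brute-force per-gene precedence scan at a single 0-based base: the
# independent oracle for the flattened category map. Works directly on the
# data.frame representation, not on any package data structure.
oracle_category <- function(df, chrom, b0, near, far) {
  tiers <- c("exon", "intron", "five_near", "three_near",
             "five_far", "three_far")
  hit <- setNames(rep(FALSE, 6), tiers)
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] != chrom) next
    s <- df$start[i]; e <- df$end[i]
    fwd <- df$strand[i] == "+"
    ex <- df$exons[[i]]
    if (any(b0 >= ex[, 1] & b0 < ex[, 2])) hit["exon"] <- TRUE
    if (b0 >= s && b0 < e) hit["intron"] <- TRUE
    up_near <- if (fwd) b0 >= s - near && b0 < s else b0 >= e && b0 < e + near
    dn_near <- if (fwd) b0 >= e && b0 < e + near else b0 >= s - near && b0 < s
    up_far <- if (fwd) b0 >= s - far && b0 < s - near else b0 >= e + near && b0 < e + far
    dn_far <- if (fwd) b0 >= e + near && b0 < e + far else b0 >= s - far && b0 < s - near
    if (up_near) hit["five_near"] <- TRUE
    if (dn_near) hit["three_near"] <- TRUE
    if (up_far) hit["five_far"] <- TRUE
    if (dn_far) hit["three_far"] <- TRUE
  }
  # intron tier means "inside a gene body but not its exon"; across genes the
  # merged semantics make any body base at least intron, and exon anywhere wins
  if (hit["exon"]) return("exon")
  if (hit["intron"]) return("intron")
  for (t in tiers[3:6]) if (hit[t]) return(t)
  "distant"
}

# Write a small file from lines; returns the path.
write_lines_tmp <- function(lines, ext) {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
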