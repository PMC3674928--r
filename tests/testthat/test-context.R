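toy_setup <- function(near = 100, far = 500) {
  gm <- toy_gene_models()
  list(gm = gm, map = flatten_categories(gm, near, far))
}

test_that("loci are categorised at their midpoint", {
  s <- toy_setup()
  got <- function(s0, e0) {
    as.character(categorize(bed_locus("chr1", s0, e0), s$map))
  }
  expect_equal(got(1090, 1110), "exon")       # midpoint 1100
  expect_equal(got(2290, 2310), "three_far")  # midpoint 2300
  expect_equal(got(6990, 7010), "distant")
  # a wide locus straddling categories still gets exactly one, by midpoint
  expect_equal(got(900, 2100), "intron")      # midpoint 1500
})

test_that("loci on unknown chromosomes are reported distant with a warning", {
  s <- toy_setup()
  expect_warning(cat <- categorize(bed_locus("chrUn", 100, 200), s$map),
                 "absent from the annotation")
  expect_equal(as.character(cat), "distant")
})

test_that("nearest gene and signed distances follow the strand-aware convention", {
  s <- toy_setup()
  ctx <- annotate_loci(c(point_locus("chr1", 1500), point_locus("chr1", 4500),
                         point_locus("chr1", 3000)),
                       s$gm, s$map)
  # midpoint 1500 inside forward G1 (TSS 1000, TES 2000)
  expect_equal(ctx$nearest_gene[1], "G1")
  expect_equal(ctx$dist_5prime[1], 500)
  expect_equal(ctx$dist_3prime[1], -500)
  # midpoint 4500 inside reverse G2 (5' end 5000, 3' end 4000)
  expect_equal(ctx$nearest_gene[2], "G2")
  expect_equal(ctx$dist_5prime[2], 500)
  expect_equal(ctx$dist_3prime[2], -500)
  # midpoint 3000 equidistant from both spans: smaller gene start wins
  expect_equal(ctx$nearest_gene[3], "G1")
  # inside the span the 5' distance is non-negative and the 3' non-positive
  expect_true(all(ctx$dist_5prime[1:2] >= 0 & ctx$dist_3prime[1:2] <= 0))
})

test_that("mirroring the annotation and loci preserves categories and signed distances", {
  L <- 50000L
  df <- random_genes_df(11, n_chroms = 1L, chrom_len = L)
  mirror <- df
  mirror$start <- L - df$end
  mirror$end <- L - df$start
  mirror$strand <- ifelse(df$strand == "+", "-", "+")
  mirror$exons <- lapply(df$exons, function(ex) {
    m <- cbind(L - ex[, 2], L - ex[, 1])
    m[rev(seq_len(nrow(m))), , drop = FALSE]
  })
  gm <- gene_models_from_df(df, chrom_lengths = c(rchr1 = L))
  gmm <- gene_models_from_df(mirror, chrom_lengths = c(rchr1 = L))
  map <- flatten_categories(gm, 300, 1200)
  mapm <- flatten_categories(gmm, 300, 1200)
  set.seed(33)
  mids <- sample(0:(L - 1L), 300)
  ctx <- annotate_loci(point_locus("rchr1", mids), gm, map)
  # the mirror image of base b is L - 1 - b
  ctxm <- annotate_loci(point_locus("rchr1", L - 1L - mids), gmm, mapm)
  expect_equal(as.character(ctxm$category), as.character(ctx$category))
  # mirroring flips coordinates and strands, so gene-oriented distances are
  # preserved up to the one-base asymmetry of the half-open convention
  expect_true(all(abs(ctxm$dist_5prime - ctx$dist_5prime) <= 1))
  expect_true(all(abs(ctxm$dist_3prime - ctx$dist_3prime) <= 1))
})

test_that("5' and 3' distances always differ by the nearest gene's span length", {
  s <- toy_setup()
  set.seed(4)
  mids <- sample(0:9999, 200)
  ctx <- annotate_loci(point_locus("chr1", mids), s$gm, s$map)
  span <- ifelse(ctx$nearest_gene == "G1", 1000, 1000)
  expect_equal(abs(ctx$dist_5prime - ctx$dist_3prime), span)
})

test_that("summaries conserve totals and handle empty input", {
  empty <- summarize_categories(factor(character(0), levels = pc_categories()))
  expect_equal(empty$total, 0L)
  expect_true(all(empty$counts == 0L))
  expect_equal(names(empty$counts), pc_categories())

  d <- summarize_categories(c("exon", "exon", "exon", "distant"), label = "x")
  expect_equal(d$counts[["exon"]], 3L)
  expect_equal(d$counts[["distant"]], 1L)
  expect_equal(d$total, 4L)
  expect_equal(d$total, sum(d$counts))
})

test_that("every locus on an annotated chromosome receives exactly one category", {
  s <- toy_setup()
  set.seed(5)
  mids <- sample(0:9999, 500, replace = TRUE)
  cats <- categorize(point_locus("chr1", mids), s$map)
  expect_false(any(is.na(cats)))
  expect_equal(summarize_categories(cats)$total, 500L)
})

test_that("distance histograms bin half-open and track out-of-range loci", {
  ctx <- data.frame(nearest_gene = c("G", "G", "G", "G"),
                    dist_5prime = c(500, -1000, 1000, 250),
                    dist_3prime = c(0, 0, 0, 0))
  h <- distance_histogram(ctx, "5prime", bin_width = 500, range = c(-1000, 1000))
  # bins [-1000,-500) [-500,0) [0,500) [500,1000); 1000 itself is out of range
  expect_equal(h$counts, c(1L, 0L, 1L, 1L))
  expect_equal(h$n_out_of_range, 1L)
  expect_equal(sum(h$counts) + h$n_out_of_range, 4L)

  none <- distance_histogram(ctx[0, ], "3prime", bin_width = 500, range = c(-1000, 1000))
  expect_true(all(none$counts == 0L))
  expect_error(distance_histogram(ctx, "5prime", bin_width = 0), "bin_width")
  expect_error(distance_histogram(ctx, "5prime", range = c(10, 10)), "range")
})

test_that("TSS-in-window counts gene 5' ends around midpoints", {
  gm <- toy_gene_models()   # TSSs at 1000 (forward G1) and 5000 (reverse G2)
  count <- function(mid, w) tss_in_window(point_locus("chr1", mid), gm, w)
  expect_equal(count(1500, 1000), 1L)
  expect_equal(count(7000, 1000), 0L)
  expect_equal(count(3000, 2000), 2L)   # both endpoints inclusive
  expect_error(tss_in_window(point_locus("chr1", 1), gm, -1), "window")
})

test_that("sequence extraction respects strand and bounds", {
  fa <- write_lines_tmp(c(">chr1 test sequence", "ACGTACGT"), ".fa")
  expect_equal(unname(extract_sequences(bed_locus("chr1", 0, 4), fa)), "ACGT")
  expect_equal(unname(extract_sequences(bed_locus("chr1", 1, 5, strand = "-"), fa)),
               "TACG")
  full <- unname(extract_sequences(bed_locus("chr1", 0, 8), fa))
  expect_equal(nchar(full), 8L)
  expect_error(extract_sequences(bed_locus("chrX", 0, 4), fa), "chrX")
  expect_error(extract_sequences(bed_locus("chr1", 0, 9), fa), "beyond")
})

test_that("element overlap is half-open intersection", {
  tr <- structure(list(name = "t",
                       intervals = bed_locus("chr1", 150, 300)),
                  class = "element_track")
  expect_true(overlap_elements(bed_locus("chr1", 100, 200), tr))
  expect_false(overlap_elements(bed_locus("chr1", 100, 150), tr))  # abutting
  expect_false(overlap_elements(bed_locus("chr1", 300, 400), tr))
  empty <- structure(list(name = "e", intervals = GenomicRanges::GRanges()),
                     class = "element_track")
  expect_false(overlap_elements(bed_locus("chr1", 100, 200), empty))
})
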