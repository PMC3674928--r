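#' Specification for the synthetic annotation and locus generator
#'
#' Describes a small genome with strand-annotated multi-exon genes and a
#' locus set drawn from a controlled category distribution; used throughout
#' the test-suite and by the \code{fixtures} CLI subcommand. All randomness
#' flows from the single \code{seed}.
#'
#' The default genome (2 chromosomes of 1 Mb, 40 genes of 2-10 kb with 1-5
#' exons each) is small enough to flatten instantly but dense enough that,
#' with the default 5 kb/25 kb limits, all seven categories occupy
#' appreciable genomic territory. The default target category probabilities
#' weight intergenic space most heavily, as in mammalian genomes.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Total number of genes, spread evenly over chromosomes.
#' @param exons_per_gene Integer range \code{c(min, max)} of exons per gene.
#' @param gene_length Range \code{c(min, max)} of gene span lengths (bp).
#' @param target_category_probs Numeric vector of 7 probabilities (summing
#'   to 1) over the categories in precedence order; loci are drawn
#'   category-first from these.
#' @param n_loci Number of loci to generate.
#' @param seed Integer seed driving every random choice.
#' @return List of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_chroms = 2L, chrom_length = 1e6, n_genes = 40L,
                           exons_per_gene = c(1L, 5L),
                           gene_length = c(2000L, 10000L),
                           target_category_probs = c(exon = 0.10, intron = 0.15,
                                                     five_near = 0.15, three_near = 0.10,
                                                     five_far = 0.10, three_far = 0.10,
                                                     distant = 0.30),
                           n_loci = 2000L, seed = 1L) {
  p <- target_category_probs
  if (length(p) != 7L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    pc_stop("target_category_probs must be 7 non-negative values summing to 1")
  names(p) <- pc_categories()
  if (gene_length[1] < 2 * exons_per_gene[2])
    pc_stop("minimum gene_length too small for the requested exon count")
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 gene_length = as.integer(gene_length),
                 target_category_probs = p,
                 n_loci = as.integer(n_loci), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes with random strands and exon structures on
#' the synthetic genome and (optionally) writes them as GTF plus a
#' chromosome-sizes file. Deterministic for a fixed seed: running twice
#' yields byte-identical files.
#'
#' @param spec A \code{synthetic_spec}.
#' @param dir Output directory; when \code{NULL} nothing is written.
#' @return List: \code{genes} (a \code{gene_models}), \code{gtf} and
#'   \code{sizes} (paths or \code{NULL}).
#' @export
synth_annotation <- function(spec, dir = NULL) {
  if (spec$gene_length[2] > spec$chrom_length)
    pc_stop("gene_length exceeds chrom_length: annotation infeasible")
  chroms <- sprintf("chrS%d", seq_len(spec$n_chroms))
  lens <- stats::setNames(rep(spec$chrom_length, spec$n_chroms), chroms)
  per_chrom <- diff(round(seq(0, spec$n_genes, length.out = spec$n_chroms + 1L)))
  rows <- with_seed(spec$seed, {
    out <- list()
    gi <- 0L
    for (ci in seq_len(spec$n_chroms)) {
      spans <- .place_genes(per_chrom[ci], spec$chrom_length, spec$gene_length)
      for (j in seq_len(nrow(spans))) {
        gi <- gi + 1L
        s0 <- spans[j, 1]; e0 <- spans[j, 2]
        n_ex <- sample(seq(spec$exons_per_gene[1], spec$exons_per_gene[2]), 1L)
        ex <- .split_exons(s0, e0, n_ex)
        out[[gi]] <- list(gene_id = sprintf("SYNG%04d", gi), chrom = chroms[ci],
                          start = s0, end = e0,
                          strand = sample(c("+", "-"), 1L), exons = ex)
      }
    }
    out
  })
  df <- data.frame(gene_id = vapply(rows, `[[`, "", "gene_id"),
                   chrom = vapply(rows, `[[`, "", "chrom"),
                   start = vapply(rows, `[[`, 0, "start"),
                   end = vapply(rows, `[[`, 0, "end"),
                   strand = vapply(rows, `[[`, "", "strand"),
                   stringsAsFactors = FALSE)
  df$exons <- lapply(rows, `[[`, "exons")
  genes <- gene_models_from_df(df, chrom_lengths = lens)
  gtf_path <- sizes_path <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gtf_path <- file.path(dir, "synthetic_annotation.gtf")
    sizes_path <- file.path(dir, "synthetic_annotation.sizes")
    writeLines(.gtf_lines(rows), gtf_path)
    writeLines(sprintf("%s\t%d", names(lens), lens), sizes_path)
  }
  list(genes = genes, gtf = gtf_path, sizes = sizes_path)
}

# n non-overlapping spans (0-based half-open) on [0, len); errors when they
# cannot fit.
.place_genes <- function(n, len, gene_length) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  widths <- sample(seq(gene_length[1], gene_length[2]), n, replace = TRUE)
  gap_total <- len - sum(widths)
  if (gap_total < n + 1L)
    pc_stop("cannot fit %d genes of total %d bp on a %d bp chromosome", n, sum(widths), len)
  # n+1 gaps (before, between, after) drawn uniformly over compositions
  cuts <- sort(sample(seq_len(gap_total - 1L), n))
  gaps <- diff(c(0L, cuts))
  starts <- cumsum(gaps) + cumsum(c(0L, widths[-n]))
  cbind(starts, starts + widths)
}

# split span [s0, e0) into n_ex exons separated by introns, all >= 1 bp;
# returns a 2-column matrix of 0-based half-open exon intervals.
.split_exons <- function(s0, e0, n_ex) {
  w <- e0 - s0
  n_seg <- 2L * n_ex - 1L
  if (n_seg == 1L) return(matrix(c(s0, e0), ncol = 2))
  cuts <- sort(sample(seq_len(w - 1L), n_seg - 1L))
  bounds <- c(0L, cuts, w) + s0
  idx <- seq(1L, n_seg, by = 2L)        # odd segments are exons
  cbind(bounds[idx], bounds[idx + 1L])
}

.gtf_lines <- function(rows) {
  unlist(lapply(rows, function(r) {
    attr_g <- sprintf('gene_id "%s"; transcript_id "%s.1";', r$gene_id, r$gene_id)
    c(sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
              r$chrom, r$start + 1L, r$end, r$strand, r$gene_id),
      sprintf("%s\tsynth\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              r$chrom, r$start + 1L, r$end, r$strand, attr_g),
      sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s",
              r$chrom, r$exons[, 1] + 1L, r$exons[, 2], r$strand, attr_g))
  }))
}

#' Generate synthetic loci with a controlled category distribution
#'
#' Loci are sampled category-first: a category is drawn from
#' \code{target_category_probs}, then a base uniformly within that
#' category's runs in \code{map}, and the locus is written as the midpoint
#' +/- 25 bp (shrunk symmetrically near chromosome edges so the midpoint is
#' preserved). Deterministic for a fixed seed.
#'
#' @param spec A \code{synthetic_spec}.
#' @param map \code{category_map} built from the matching annotation.
#' @param path Optional BED output path.
#' @return \code{GRanges} of loci (with \code{name} metadata); written to
#'   \code{path} as BED when given.
#' @export
synth_loci <- function(spec, map, path = NULL) {
  probs <- spec$target_category_probs
  bp <- category_bp(map)
  absent <- names(probs)[probs > 0 & bp == 0]
  if (length(absent))
    pc_stop("category absent from the map but requested with nonzero probability: %s",
            paste(absent, collapse = ", "))
  run_cat <- as.character(S4Vectors::mcols(map$runs)$category)
  run_w <- GenomicRanges::width(map$runs)
  lens <- map$chrom_lengths
  run_chrom <- as.character(GenomeInfoDb::seqnames(map$runs))
  run_s0 <- GenomicRanges::start(map$runs) - 1L
  dat <- with_seed(spec$seed + 1L, {
    cats <- sample(names(probs), spec$n_loci, replace = TRUE, prob = probs)
    mids <- integer(spec$n_loci)
    chroms <- character(spec$n_loci)
    for (i in seq_len(spec$n_loci)) {
      ri <- which(run_cat == cats[i])
      pick <- if (length(ri) == 1L) ri else
        sample(ri, 1L, prob = run_w[ri])
      mids[i] <- run_s0[pick] + sample.int(run_w[pick], 1L) - 1L
      chroms[i] <- run_chrom[pick]
    }
    list(cats = cats, mids = mids, chroms = chroms)
  })
  half <- pmin(25L, dat$mids, unname(lens[dat$chroms]) - dat$mids - 1L)
  half <- pmax(half, 0L)
  s0 <- dat$mids - half
  e0 <- pmax(dat$mids + half, dat$mids + 1L)
  loci <- GenomicRanges::GRanges(dat$chroms, IRanges::IRanges(s0 + 1L, e0),
                                 strand = "*",
                                 name = sprintf("locus%05d", seq_len(spec$n_loci)))
  if (!is.null(path)) write_bed(loci, path)
  loci
}
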