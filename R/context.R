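#' Annotate loci with genomic context
#'
#' For each locus this computes the context category at its midpoint, the
#' nearest gene, signed strand-aware distances from the midpoint to that
#' gene's 5' and 3' ends, the nearest gene's transcription direction, and
#' (optionally) overlap flags against element tracks.
#'
#' The nearest gene minimises the unsigned distance from the locus midpoint
#' to the gene span (0 when the midpoint lies inside the span). Ties are
#' broken deterministically: smallest chromosome name, then smallest gene
#' start, then lexicographic gene id. Loci on chromosomes without genes are
#' assigned the first gene under the same ordering, with \code{NA} distances.
#'
#' Distance sign convention: a distance is positive when the midpoint lies
#' 3'-ward (in the direction of transcription) of the reference gene end and
#' negative when it lies 5'-ward of it. A midpoint inside the gene therefore
#' has \code{dist_5prime >= 0} and \code{dist_3prime <= 0}.
#'
#' @param loci \code{GRanges} of loci (from \code{\link{read_bed}}).
#' @param genes A \code{gene_models} object.
#' @param map A \code{category_map} built from the same annotation.
#' @param tracks Optional list of \code{element_track} objects; each adds a
#'   logical overlap column named after the track.
#' @return A data.frame of class \code{locus_context} with columns
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open, BED
#'   convention), \code{name}, \code{midpoint}, \code{category},
#'   \code{nearest_gene}, \code{gene_strand}, \code{dist_5prime},
#'   \code{dist_3prime}, plus one logical column per element track.
#' @export
annotate_loci <- function(loci, genes, map, tracks = NULL) {
  n <- length(loci)
  mids <- locus_midpoints(loci)
  category <- categorize(loci, map)
  nm <- S4Vectors::mcols(loci)$name
  if (is.null(nm)) nm <- rep(NA_character_, n)
  ctx <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(loci)),
    start = GenomicRanges::start(loci) - 1L,
    end = GenomicRanges::end(loci),
    name = as.character(nm),
    midpoint = mids,
    category = category,
    nearest_gene = NA_character_,
    gene_strand = NA_character_,
    dist_5prime = NA_real_,
    dist_3prime = NA_real_,
    stringsAsFactors = FALSE)

  ng <- .nearest_genes(ctx$chrom, mids, genes)
  ctx$nearest_gene <- ng$gene_id
  ctx$gene_strand <- ng$strand
  ctx$dist_5prime <- ng$dist_5prime
  ctx$dist_3prime <- ng$dist_3prime

  for (tr in tracks) {
    ctx[[tr$name]] <- overlap_elements(loci, tr)
  }
  class(ctx) <- c("locus_context", "data.frame")
  ctx
}

# Nearest gene per (chrom, 0-based midpoint). Unsigned distance is the
# point-to-interval distance on the half-open line:
# d = max(0, gene_start - mid, mid - gene_end).
.nearest_genes <- function(chrom, mids, genes) {
  n <- length(mids)
  out <- list(gene_id = rep(NA_character_, n), strand = rep(NA_character_, n),
              dist_5prime = rep(NA_real_, n), dist_3prime = rep(NA_real_, n))
  g <- genes$genes
  if (length(g) == 0L || n == 0L) return(out)
  g_chrom <- as.character(GenomeInfoDb::seqnames(g))
  g_s0 <- GenomicRanges::start(g) - 1L     # 0-based half-open span
  g_e0 <- GenomicRanges::end(g)
  g_id <- S4Vectors::mcols(g)$gene_id
  g_strand <- as.character(GenomicRanges::strand(g))
  g_strand[g_strand == "*"] <- "+"
  # genes are stored sorted by (chrom, start, gene_id), so index order is the
  # tie-break order and which.min resolves ties deterministically
  for (ch in unique(chrom)) {
    li <- which(chrom == ch)
    gi <- which(g_chrom == ch)
    if (length(gi) == 0L) {
      # geneless chromosome: every gene is equally (un)reachable; the global
      # tie-break picks gene 1, distances stay NA
      out$gene_id[li] <- g_id[1L]
      out$strand[li] <- g_strand[1L]
      next
    }
    m <- mids[li]
    # distance matrix genes x loci
    d <- pmax(outer(g_s0[gi], m, "-"), outer(-g_e0[gi], m, "+"))
    d[d < 0] <- 0
    best <- gi[apply(d, 2L, which.min)]
    out$gene_id[li] <- g_id[best]
    out$strand[li] <- g_strand[best]
    fwd <- g_strand[best] == "+"
    out$dist_5prime[li] <- ifelse(fwd, m - g_s0[best], g_e0[best] - m)
    out$dist_3prime[li] <- ifelse(fwd, m - g_e0[best], g_s0[best] - m)
  }
  out
}

#' Summarise locus contexts into a category distribution
#'
#' @param contexts A \code{locus_context} data.frame (or a factor/character
#'   vector of categories).
#' @param label Label for the locus set (used in reports and plots).
#' @return An object of class \code{category_distribution}: list with
#'   \code{counts} (named integer vector over all seven categories),
#'   \code{total} and \code{label}.
#' @export
summarize_categories <- function(contexts, label = "loci") {
  cats <- pc_categories()
  x <- if (is.data.frame(contexts)) contexts$category else contexts
  x <- factor(as.character(x), levels = cats)
  counts <- stats::setNames(as.integer(table(x)), cats)
  structure(list(counts = counts, total = sum(counts), label = label),
            class = "category_distribution")
}

#' Build a category distribution from explicit counts
#'
#' @param counts Named (or ordered) integer vector over the seven categories;
#'   shorter unnamed vectors are padded with zeros.
#' @param label Label for the set.
#' @return A \code{category_distribution}.
#' @export
category_distribution <- function(counts, label = "set") {
  cats <- pc_categories()
  if (is.null(names(counts))) {
    counts <- stats::setNames(c(as.integer(counts),
                                rep(0L, max(0L, 7L - length(counts))))[1:7], cats)
  } else {
    unknown <- setdiff(names(counts), cats)
    if (length(unknown)) pc_stop("unknown categories: %s", paste(unknown, collapse = ", "))
    full <- stats::setNames(integer(7), cats)
    full[names(counts)] <- as.integer(counts)
    counts <- full
  }
  if (any(counts < 0)) pc_stop("counts must be non-negative")
  structure(list(counts = counts, total = sum(counts), label = label),
            class = "category_distribution")
}

#' @export
print.category_distribution <- function(x, ...) {
  cat(sprintf("category_distribution '%s' (n = %d)\n", x$label, x$total))
  freq <- if (x$total > 0) x$counts / x$total else rep(0, 7)
  for (cat in pc_categories())
    cat(sprintf("  %-10s %7d  %6.2f%%\n", cat, x$counts[[cat]], 100 * freq[[cat]]))
  invisible(x)
}

#' Histogram of signed distances to gene 5' or 3' ends
#'
#' Distances are binned into half-open bins \code{[edge_i, edge_{i+1})};
#' distances outside the range (including the upper edge itself) are counted
#' in \code{n_out_of_range}, as are loci whose nearest gene lies on another
#' chromosome (undefined distance). The defaults, +/-100 kb in 5 kb bins,
#' suit typical ChIP peak sets against vertebrate annotation.
#'
#' @param contexts A \code{locus_context} data.frame.
#' @param end Which gene end to measure from: \code{"5prime"} or
#'   \code{"3prime"}.
#' @param bin_width Bin width in bp (> 0).
#' @param range Numeric length-2 \code{c(lo, hi)} with \code{lo < hi}.
#' @return An object of class \code{distance_histogram}: list with
#'   \code{end}, \code{bin_edges}, \code{counts}, \code{n_out_of_range}.
#' @export
distance_histogram <- function(contexts, end = c("5prime", "3prime"),
                               bin_width = 5000, range = c(-1e5, 1e5)) {
  end <- match.arg(end)
  if (bin_width <= 0) pc_stop("bin_width must be > 0")
  if (length(range) != 2L || range[1] >= range[2])
    pc_stop("range must be c(lo, hi) with lo < hi")
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  nbins <- length(edges) - 1L
  d <- contexts[[paste0("dist_", end)]]
  d <- d[!is.na(contexts$nearest_gene)]
  n_na <- sum(is.na(d))
  d <- d[!is.na(d)]
  inside <- d >= range[1] & d < range[2]
  idx <- findInterval(d[inside], edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = nbins)
  structure(list(end = end, bin_edges = edges, counts = counts,
                 n_out_of_range = sum(!inside) + n_na),
            class = "distance_histogram")
}

#' Count transcription start sites around locus midpoints
#'
#' Counts gene 5' ends whose coordinate lies within \code{window} bp of each
#' locus midpoint (inclusive on both sides), on the locus chromosome.
#'
#' @param loci \code{GRanges} of loci.
#' @param genes A \code{gene_models} object.
#' @param window Half-width of the window in bp (>= 0).
#' @return Integer vector of TSS counts, parallel to \code{loci}.
#' @export
tss_in_window <- function(loci, genes, window) {
  if (window < 0) pc_stop("window must be >= 0")
  g <- genes$genes
  n <- length(loci)
  if (length(g) == 0L || n == 0L) return(integer(n))
  strand <- as.character(GenomicRanges::strand(g))
  # TSS as a 0-based coordinate: span start on the forward strand, span end
  # (half-open) on the reverse strand
  tss0 <- ifelse(strand == "-", GenomicRanges::end(g),
                 GenomicRanges::start(g) - 1L)
  g_chrom <- as.character(GenomeInfoDb::seqnames(g))
  mids <- locus_midpoints(loci)
  chrom <- as.character(GenomeInfoDb::seqnames(loci))
  vapply(seq_len(n), function(i) {
    t <- tss0[g_chrom == chrom[i]]
    sum(t >= mids[i] - window & t <= mids[i] + window)
  }, integer(1))
}

#' Extract reference sequences for loci
#'
#' Returns the sequence of each locus interval, reverse-complemented for loci
#' on the reverse strand.
#'
#' @param loci \code{GRanges} of loci.
#' @param fasta Path to a (multi-)FASTA reference, or a
#'   \code{Biostrings::DNAStringSet}.
#' @return Named character vector of sequences (names from locus names or
#'   \code{chrom:start-end}).
#' @export
extract_sequences <- function(loci, fasta) {
  ref <- if (inherits(fasta, "DNAStringSet")) fasta else {
    if (!file.exists(fasta)) pc_stop("FASTA file not found: %s", fasta)
    Biostrings::readDNAStringSet(fasta)
  }
  names(ref) <- sub("\\s.*$", "", names(ref))
  chrom <- as.character(GenomeInfoDb::seqnames(loci))
  missing <- setdiff(unique(chrom), names(ref))
  if (length(missing))
    pc_stop("chromosome(s) missing from the reference: %s",
            paste(missing, collapse = ", "))
  s <- GenomicRanges::start(loci)
  e <- GenomicRanges::end(loci)
  too_long <- e > Biostrings::width(ref)[match(chrom, names(ref))]
  if (any(too_long))
    pc_stop("%d locus/loci extend beyond the reference sequence end", sum(too_long))
  seqs <- vapply(seq_along(loci), function(i) {
    as.character(Biostrings::subseq(ref[[chrom[i]]], start = s[i], end = e[i]))
  }, character(1))
  rev <- as.character(GenomicRanges::strand(loci)) == "-"
  if (any(rev)) {
    seqs[rev] <- vapply(seqs[rev], function(x) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    }, character(1), USE.NAMES = FALSE)
  }
  nm <- S4Vectors::mcols(loci)$name
  default <- sprintf("%s:%d-%d", chrom, s - 1L, e)
  names(seqs) <- if (is.null(nm)) default else ifelse(is.na(nm) | nm == "", default, nm)
  seqs
}

#' Flag loci overlapping an element track
#'
#' A locus overlaps a track when its interval shares at least one base with
#' any track interval (half-open intersection).
#'
#' @param loci \code{GRanges} of loci.
#' @param track An \code{element_track}.
#' @return Logical vector parallel to \code{loci}.
#' @export
overlap_elements <- function(loci, track) {
  if (length(track$intervals) == 0L) return(rep(FALSE, length(loci)))
  GenomicRanges::countOverlaps(loci, track$intervals, ignore.strand = TRUE) > 0L
}
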