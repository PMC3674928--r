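#' Flatten gene models into an exhaustive category partition of the genome
#'
#' Every base of every chromosome is assigned exactly one of the seven
#' context categories. Where a base qualifies for several (overlapping genes,
#' overlapping flanks), the highest-precedence label wins:
#' exon > intron > five_near > three_near > five_far > three_far > distant.
#' Within one precedence tier, membership from any gene suffices; the map
#' does not track which gene contributed a flank.
#'
#' Flank geometry is strand aware: the 5' flanks sit upstream of each gene's
#' transcription start (promoter side) and the 3' flanks downstream of its
#' transcription end, \code{near_limit} bp for the near tiers and from
#' \code{near_limit} to \code{far_limit} bp for the far tiers. Flanks are
#' truncated at chromosome boundaries, never wrapped.
#'
#' @param genes A \code{gene_models} object (see \code{\link{read_gene_models}}).
#' @param near_limit,far_limit Distance thresholds in bp; defaults 5000 and
#'   25000. Must satisfy \code{0 < near_limit <= far_limit}.
#' @param chrom_lengths Named integer vector of chromosome lengths. Falls
#'   back to the lengths stored on \code{genes}; chromosomes still missing a
#'   length default to the maximum annotated coordinate plus
#'   \code{far_limit}, which keeps the partition well-defined without a
#'   sizes file.
#' @return An object of class \code{category_map}: list with
#'   \describe{
#'     \item{runs}{\code{GRanges} sorted within chromosome, tiling every
#'       chromosome exactly, with metadata column \code{category} (factor
#'       over the seven categories).}
#'     \item{chrom_lengths}{Named integer vector actually used.}
#'     \item{near_limit, far_limit}{The thresholds the map was built with.}
#'   }
#' @export
flatten_categories <- function(genes, near_limit = 5000L, far_limit = 25000L,
                               chrom_lengths = NULL) {
  if (!inherits(genes, "gene_models")) pc_stop("genes must be a gene_models object")
  near_limit <- as.integer(near_limit)
  far_limit <- as.integer(far_limit)
  if (is.na(near_limit) || near_limit <= 0L)
    pc_stop("near_limit must be a positive number of bp")
  if (is.na(far_limit) || near_limit > far_limit)
    pc_stop("near_limit must not exceed far_limit")

  g <- genes$genes
  lens <- .resolve_chrom_lengths(genes, chrom_lengths, far_limit)

  cats <- pc_categories()
  tiers <- .category_tiers(genes, near_limit, far_limit, lens)

  # Successive subtraction in precedence order yields the partition directly.
  all_chroms <- GenomicRanges::GRanges(names(lens),
                                       IRanges::IRanges(1L, unname(lens)))
  covered <- GenomicRanges::GRanges()
  pieces <- list()
  for (cat in cats[cats != "distant"]) {
    tier <- tiers[[cat]]
    if (length(tier) == 0L) next
    tier <- GenomicRanges::setdiff(tier, covered, ignore.strand = TRUE)
    if (length(tier) == 0L) next
    covered <- GenomicRanges::reduce(c(covered, GenomicRanges::granges(tier)),
                                     ignore.strand = TRUE)
    S4Vectors::mcols(tier)$category <- cat
    pieces[[cat]] <- tier
  }
  distant <- GenomicRanges::setdiff(all_chroms, covered, ignore.strand = TRUE)
  if (length(distant)) {
    S4Vectors::mcols(distant)$category <- "distant"
    pieces[["distant"]] <- distant
  }
  runs <- if (length(pieces)) do.call(c, unname(pieces)) else all_chroms
  runs <- GenomicRanges::sort(runs, ignore.strand = TRUE)
  S4Vectors::mcols(runs)$category <- factor(S4Vectors::mcols(runs)$category,
                                            levels = cats)
  structure(list(runs = runs, chrom_lengths = lens,
                 near_limit = near_limit, far_limit = far_limit),
            class = "category_map")
}

.resolve_chrom_lengths <- function(genes, chrom_lengths, far_limit) {
  g <- genes$genes
  lens <- if (!is.null(chrom_lengths)) chrom_lengths else genes$chrom_lengths
  if (is.null(lens)) lens <- integer(0)
  lens <- stats::setNames(as.integer(lens), names(lens))
  if (length(g)) {
    chroms <- as.character(GenomeInfoDb::seqnames(g))
    missing <- setdiff(unique(chroms), names(lens))
    if (length(missing)) {
      fallback <- vapply(missing, function(ch) {
        max(GenomicRanges::end(g[chroms == ch])) + as.integer(far_limit)
      }, integer(1))
      lens <- c(lens, fallback)
    }
  }
  if (!length(lens)) pc_stop("no chromosomes: supply chrom_lengths or a non-empty annotation")
  lens
}

# Raw (pre-precedence) interval set for each of the six gene-derived tiers,
# clipped to chromosome bounds and merged across genes.
.category_tiers <- function(genes, near_limit, far_limit, lens) {
  g <- genes$genes
  empty <- GenomicRanges::GRanges()
  if (length(g) == 0L) {
    return(stats::setNames(rep(list(empty), 6),
                           pc_categories()[1:6]))
  }
  exon <- GenomicRanges::reduce(unlist(genes$exons), ignore.strand = TRUE)
  body <- GenomicRanges::reduce(g, ignore.strand = TRUE)
  five_near_raw <- GenomicRanges::flank(g, near_limit, start = TRUE)
  three_near_raw <- GenomicRanges::flank(g, near_limit, start = FALSE)
  width_far <- far_limit - near_limit
  if (width_far > 0L) {
    five_far_raw <- GenomicRanges::flank(five_near_raw, width_far, start = TRUE)
    three_far_raw <- GenomicRanges::flank(three_near_raw, width_far, start = FALSE)
  } else {
    five_far_raw <- empty
    three_far_raw <- empty
  }
  tidy <- function(gr) {
    if (length(gr) == 0L) return(empty)
    gr <- clip_granges(gr, lens)
    GenomicRanges::reduce(gr, ignore.strand = TRUE)
  }
  list(exon = tidy(exon),
       intron = tidy(body),      # precedence subtraction removes the exons
       five_near = tidy(five_near_raw),
       three_near = tidy(three_near_raw),
       five_far = tidy(five_far_raw),
       three_far = tidy(three_far_raw))
}

#' @export
print.category_map <- function(x, ...) {
  bp <- tapply(GenomicRanges::width(x$runs),
               S4Vectors::mcols(x$runs)$category, sum, default = 0L)
  cat(sprintf("category_map: %d chromosome(s), near=%d bp, far=%d bp\n",
              length(x$chrom_lengths), x$near_limit, x$far_limit))
  for (cat in pc_categories())
    cat(sprintf("  %-10s %12.0f bp\n", cat, bp[[cat]]))
  invisible(x)
}

#' Total bp per category in a category map
#'
#' @param map A \code{category_map}.
#' @return Named numeric vector over the seven categories (bp).
#' @export
category_bp <- function(map) {
  cats <- pc_categories()
  bp <- tapply(as.numeric(GenomicRanges::width(map$runs)),
               S4Vectors::mcols(map$runs)$category, sum, default = 0)
  stats::setNames(as.numeric(bp[cats]), cats)
}

#' Category at locus midpoints
#'
#' Each locus is categorised at its midpoint, \code{floor((start+end)/2)} in
#' 0-based coordinates, which keeps the seven categories mutually exclusive
#' per locus even for wide peaks. Loci on chromosomes absent from the map are
#' reported as \code{distant} with a warning.
#'
#' @param loci \code{GRanges} of loci (1-based internally; see
#'   \code{\link{read_bed}}).
#' @param map A \code{category_map}.
#' @return Factor of categories, parallel to \code{loci}.
#' @export
categorize <- function(loci, map) {
  cats <- pc_categories()
  if (length(loci) == 0L) return(factor(character(0), levels = cats))
  mids <- locus_midpoints(loci)
  pts <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(loci),
                                IRanges::IRanges(mids + 1L, width = 1L))
  res <- factor(rep("distant", length(loci)), levels = cats)
  known <- as.character(GenomeInfoDb::seqnames(pts)) %in% names(map$chrom_lengths)
  if (any(!known)) {
    pc_warn("%d locus/loci on chromosome(s) absent from the annotation treated as distant",
            sum(!known))
  }
  if (any(known)) {
    hits <- GenomicRanges::findOverlaps(pts[known], map$runs, ignore.strand = TRUE,
                                        select = "first")
    got <- !is.na(hits)
    idx <- which(known)[got]
    res[idx] <- as.character(S4Vectors::mcols(map$runs)$category[hits[got]])
  }
  res
}

# 0-based midpoint of each locus: floor((start0 + end0) / 2).
locus_midpoints <- function(loci) {
  s0 <- GenomicRanges::start(loci) - 1L
  e0 <- GenomicRanges::end(loci)
  as.integer(floor((as.numeric(s0) + as.numeric(e0)) / 2))
}
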