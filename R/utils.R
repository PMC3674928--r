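#' The seven genomic context categories, in precedence order
#'
#' Every base of an annotated genome belongs to exactly one of seven
#' exhaustive, mutually exclusive categories. When a position qualifies for
#' several, the highest-precedence label wins, in the order
#' exon > intron > five_near > three_near > five_far > three_far > distant.
#'
#' @return Character vector of the seven category names, highest precedence
#'   first.
#' @export
pc_categories <- function() {
  c("exon", "intron", "five_near", "three_near",
    "five_far", "three_far", "distant")
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Clip a GRanges to [1, seqlength] per chromosome, dropping emptied ranges.
# Works without requiring seqlengths to be set on the object itself.
clip_granges <- function(gr, chrom_lengths) {
  if (length(gr) == 0L) return(gr)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  len <- unname(chrom_lengths[chr])
  s <- pmax(GenomicRanges::start(gr), 1L)
  e <- GenomicRanges::end(gr)
  e <- ifelse(is.na(len), e, pmin(e, len))
  keep <- s <= e
  gr <- gr[keep]
  if (length(gr) == 0L) return(gr)
  GenomicRanges::ranges(gr) <- IRanges::IRanges(start = s[keep], end = e[keep])
  gr
}

# Format a p-value the way the report tables print it: 4 significant digits
# in scientific notation, with values below double precision reported as a
# bound rather than a misleading zero.
format_pvalue <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 2.2e-16, "< 2.2e-16", sprintf("%.4g", p)))
}

pc_warn <- function(...) warning(sprintf(...), call. = FALSE)

pc_stop <- function(...) stop(sprintf(...), call. = FALSE)
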