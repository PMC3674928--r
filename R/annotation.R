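#' Read gene models from GTF, GFF3 or BED12
#'
#' Parses a gene annotation file and merges all transcripts of each gene into
#' a single gene model: the gene span is the union span of its transcripts and
#' the exons are the union of all transcript exons (overlapping exons merged).
#' Internally coordinates live in \pkg{GenomicRanges} objects (1-based,
#' closed); BED input is converted on read, GTF/GFF3 already use that
#' convention.
#'
#' Genes whose features fall on more than one chromosome or strand are
#' rejected with a warning and parsing continues.
#'
#' @param path Path to the annotation file.
#' @param format One of \code{"gtf"}, \code{"gff3"}, \code{"bed12"}. Guessed
#'   from the file extension when \code{NULL}.
#' @param chrom_lengths Optional named integer vector of chromosome lengths
#'   (e.g. from \code{\link{read_chrom_sizes}}); recorded on the result.
#' @return An object of class \code{gene_models}: a list with
#'   \describe{
#'     \item{genes}{\code{GRanges}, one range per gene (the merged span) with
#'       metadata columns \code{gene_id} and \code{biotype}.}
#'     \item{exons}{\code{GRangesList} parallel to \code{genes}, the merged
#'       exon intervals of each gene.}
#'     \item{chrom_lengths}{Named integer vector, possibly empty.}
#'   }
#' @export
read_gene_models <- function(path, format = NULL, chrom_lengths = NULL) {
  if (!file.exists(path)) pc_stop("annotation file not found: %s", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     gtf = "gtf", gff = "gff3", gff3 = "gff3", bed = "bed12",
                     pc_stop("cannot guess annotation format from '%s'; pass format=", path))
  }
  format <- match.arg(format, c("gtf", "gff3", "bed12"))
  raw <- switch(format,
    gtf   = rtracklayer::import(path, format = "gtf"),
    gff3  = rtracklayer::import(path, format = "gff3"),
    bed12 = rtracklayer::import(path, format = "bed"))

  if (format == "bed12") {
    exon_gr <- .bed12_exons(raw)
  } else {
    exon_gr <- .gxf_exons(raw, format)
  }
  models <- .merge_gene_models(exon_gr)

  lens <- chrom_lengths
  if (is.null(lens)) {
    sl <- GenomeInfoDb::seqlengths(raw)
    sl <- sl[!is.na(sl)]
    lens <- if (length(sl)) sl else integer(0)
  }
  models$chrom_lengths <- lens
  models
}

# Exon-level GRanges (mcols: gene_id, biotype) from a GTF/GFF3 import.
.gxf_exons <- function(raw, format) {
  mc <- S4Vectors::mcols(raw)
  type <- as.character(mc$type)
  if (format == "gtf") {
    gid <- as.character(mc$gene_id)
    biotype <- if ("gene_biotype" %in% names(mc)) as.character(mc$gene_biotype) else NA_character_
  } else {
    # GFF3: exon rows carry Parent=transcript; resolve through the ID/Parent
    # chain to the top-level feature, whose ID is the gene identifier.
    id <- as.character(mc$ID)
    parent <- mc$Parent
    first_parent <- vapply(parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                           character(1))
    parent_of <- stats::setNames(first_parent, id)
    parent_of <- parent_of[!is.na(names(parent_of)) & names(parent_of) != ""]
    resolve <- function(p) {
      seen <- character(0)
      while (!is.na(p) && p %in% names(parent_of) && !is.na(parent_of[[p]]) &&
             !(p %in% seen)) {
        seen <- c(seen, p)
        p <- parent_of[[p]]
      }
      p
    }
    gid <- vapply(seq_along(raw), function(i) {
      p <- first_parent[i]
      if (is.na(p)) {
        if (!is.na(id[i])) id[i] else NA_character_
      } else resolve(p)
    }, character(1))
    biotype <- if ("biotype" %in% names(mc)) as.character(mc$biotype) else NA_character_
  }
  is_exon <- !is.na(type) & type == "exon"
  if (any(is_exon)) {
    keep <- is_exon & !is.na(gid)
    dropped <- is_exon & is.na(gid)
    if (any(dropped))
      pc_warn("%d exon records without a resolvable gene id were skipped", sum(dropped))
  } else {
    # Annotation without exon features: treat each gene/transcript record as a
    # single-exon gene.
    keep <- !is.na(gid) & type %in% c("gene", "transcript", "mRNA")
    if (!any(keep)) pc_stop("no exon, gene or transcript features found")
  }
  out <- raw[keep]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gid[keep],
    biotype = if (length(biotype) == 1L) rep(biotype, sum(keep)) else biotype[keep])
  out
}

# Exon-level GRanges from a BED12 import (blocks are 1-based, range-relative).
.bed12_exons <- function(raw) {
  mc <- S4Vectors::mcols(raw)
  gid <- if ("name" %in% names(mc)) as.character(mc$name) else sprintf("bed_%d", seq_along(raw))
  gid[is.na(gid) | gid == ""] <- sprintf("bed_%d", which(is.na(gid) | gid == ""))
  if ("blocks" %in% names(mc)) {
    blocks <- mc$blocks
    abs_blocks <- IRanges::shift(blocks, GenomicRanges::start(raw) - 1L)
    n_per <- S4Vectors::elementNROWS(abs_blocks)
    out <- GenomicRanges::GRanges(
      seqnames = rep(GenomeInfoDb::seqnames(raw), n_per),
      ranges = unlist(abs_blocks, use.names = FALSE),
      strand = rep(GenomicRanges::strand(raw), n_per))
    S4Vectors::mcols(out)$gene_id <- rep(gid, n_per)
  } else {
    out <- raw
    S4Vectors::mcols(out) <- NULL
    S4Vectors::mcols(out)$gene_id <- gid
  }
  S4Vectors::mcols(out)$biotype <- NA_character_
  out
}

# Merge exon-level records into one model per gene; reject genes spanning
# several chromosomes or strands.
.merge_gene_models <- function(exon_gr) {
  if (length(exon_gr) == 0L) {
    return(structure(list(genes = GenomicRanges::GRanges(),
                          exons = GenomicRanges::GRangesList(),
                          chrom_lengths = integer(0)),
                     class = "gene_models"))
  }
  gid <- S4Vectors::mcols(exon_gr)$gene_id
  chrom <- as.character(GenomeInfoDb::seqnames(exon_gr))
  strand <- as.character(GenomicRanges::strand(exon_gr))
  strand[strand == "*"] <- "+"

  n_chrom <- tapply(chrom, gid, function(x) length(unique(x)))
  n_strand <- tapply(strand, gid, function(x) length(unique(x)))
  bad <- names(n_chrom)[n_chrom > 1L | n_strand > 1L]
  if (length(bad)) {
    pc_warn("rejecting %d gene(s) with features on multiple chromosomes or strands: %s",
            length(bad), paste(utils::head(bad, 5), collapse = ", "))
    keep <- !(gid %in% bad)
    exon_gr <- exon_gr[keep]
    gid <- gid[keep]
  }
  if (length(exon_gr) == 0L) {
    return(structure(list(genes = GenomicRanges::GRanges(),
                          exons = GenomicRanges::GRangesList(),
                          chrom_lengths = integer(0)),
                     class = "gene_models"))
  }
  exons_by_gene <- S4Vectors::split(exon_gr, gid)
  exons_merged <- GenomicRanges::reduce(exons_by_gene)
  genes <- unlist(range(exons_merged))
  ord <- order(as.character(GenomeInfoDb::seqnames(genes)),
               GenomicRanges::start(genes), names(genes), method = "radix")
  genes <- genes[ord]
  exons_merged <- exons_merged[names(genes)]
  biotype <- tapply(as.character(S4Vectors::mcols(exon_gr)$biotype), gid,
                    function(x) x[1L])
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = names(genes),
    biotype = unname(biotype[names(genes)]))
  structure(list(genes = genes, exons = exons_merged,
                 chrom_lengths = integer(0)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s) on %d chromosome(s)\n",
              length(x$genes),
              length(unique(as.character(GenomeInfoDb::seqnames(x$genes))))))
  invisible(x)
}

#' Build a gene_models object from explicit coordinates
#'
#' Convenience constructor used by the synthetic generator and tests. All
#' coordinates are BED convention (0-based, half-open) and converted
#' internally.
#'
#' @param df data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} and list-column \code{exons}
#'   (each a 2-column matrix of 0-based half-open intervals; defaults to the
#'   full span).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A \code{gene_models} object.
#' @export
gene_models_from_df <- function(df, chrom_lengths = integer(0)) {
  if (nrow(df) == 0L) {
    m <- .merge_gene_models(GenomicRanges::GRanges())
    m$chrom_lengths <- chrom_lengths
    return(m)
  }
  exon_rows <- lapply(seq_len(nrow(df)), function(i) {
    ex <- if (!is.null(df$exons)) df$exons[[i]] else NULL
    if (is.null(ex)) ex <- matrix(c(df$start[i], df$end[i]), ncol = 2)
    data.frame(chrom = df$chrom[i], start0 = ex[, 1], end0 = ex[, 2],
               strand = df$strand[i], gene_id = df$gene_id[i],
               stringsAsFactors = FALSE)
  })
  flat <- do.call(rbind, exon_rows)
  exon_gr <- GenomicRanges::GRanges(flat$chrom,
                                    IRanges::IRanges(start = flat$start0 + 1L,
                                                     end = flat$end0),
                                    strand = flat$strand,
                                    gene_id = flat$gene_id,
                                    biotype = NA_character_)
  m <- .merge_gene_models(exon_gr)
  m$chrom_lengths <- chrom_lengths
  m
}

#' Read a chromosome sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length in bp.
#' @return Named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$length, tab$chrom)
}

#' Read an element track (e.g. CpG islands, ESTs) from BED
#'
#' Malformed lines are rejected with a warning; intervals are returned sorted
#' by (chromosome, start).
#'
#' @param path BED file (3+ columns).
#' @param name Track name used for the overlap flag column.
#' @return An object of class \code{element_track}: list with \code{name} and
#'   \code{intervals} (a sorted \code{GRanges}).
#' @export
read_element_track <- function(path, name) {
  gr <- read_bed(path, allow_empty = TRUE)
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  structure(list(name = name, intervals = gr), class = "element_track")
}
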