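#' Read a BED file of loci
#'
#' Accepts 3-6 column BED; \code{track}, \code{browser} and \code{#} comment
#' lines are skipped. Lines with non-numeric coordinates or
#' \code{start >= end} are rejected with a warning and parsing continues.
#' BED coordinates (0-based half-open) are converted to the internal 1-based
#' closed \code{GRanges} convention on read.
#'
#' @param path Path to the BED file.
#' @param allow_empty Return an empty \code{GRanges} instead of erroring
#'   when no valid line remains.
#' @return \code{GRanges} with metadata columns \code{name} and \code{score}
#'   where present.
#' @export
read_bed <- function(path, allow_empty = FALSE) {
  if (!file.exists(path)) pc_stop("BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    if (allow_empty) return(GenomicRanges::GRanges())
    pc_stop("no data lines in BED file: %s", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  get <- function(i, j) if (length(fields[[i]]) >= j) fields[[i]][j] else NA_character_
  n <- length(fields)
  chrom <- vapply(seq_len(n), get, "", j = 1L)
  start <- suppressWarnings(as.numeric(vapply(seq_len(n), get, "", j = 2L)))
  end <- suppressWarnings(as.numeric(vapply(seq_len(n), get, "", j = 3L)))
  bad <- short | is.na(start) | is.na(end) | start >= end | start < 0
  if (any(bad))
    pc_warn("rejected %d malformed BED line(s) in %s", sum(bad), path)
  keep <- which(!bad)
  if (!length(keep)) {
    if (allow_empty) return(GenomicRanges::GRanges())
    pc_stop("no valid BED lines in %s", path)
  }
  nm <- vapply(keep, get, "", j = 4L)
  score <- suppressWarnings(as.numeric(vapply(keep, get, "", j = 5L)))
  strand <- vapply(keep, get, "", j = 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(chrom[keep],
                         IRanges::IRanges(start[keep] + 1, end[keep]),
                         strand = strand,
                         name = nm, score = score)
}

#' Write loci as BED
#'
#' @param loci \code{GRanges}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(loci, path) {
  nm <- S4Vectors::mcols(loci)$name
  if (is.null(nm)) nm <- sprintf("locus%05d", seq_along(loci))
  nm[is.na(nm) | nm == ""] <- "."
  score <- S4Vectors::mcols(loci)$score
  if (is.null(score)) score <- rep(0, length(loci))
  score[is.na(score)] <- 0
  strand <- as.character(GenomicRanges::strand(loci))
  strand[strand == "*"] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     as.character(GenomeInfoDb::seqnames(loci)),
                     GenomicRanges::start(loci) - 1L,
                     GenomicRanges::end(loci),
                     nm, score, strand),
             path)
  invisible(path)
}

#' Write a locus-context table
#'
#' Tab-separated, one header line starting \code{#}; coordinates in BED
#' convention (0-based half-open).
#'
#' @param contexts \code{locus_context} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_context_table <- function(contexts, path) {
  df <- as.data.frame(contexts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a locus-context table
#'
#' @param path Path written by \code{\link{write_context_table}}.
#' @return \code{locus_context} data.frame.
#' @export
read_context_table <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, na.strings = "NA",
                          stringsAsFactors = FALSE, comment.char = "")
  df$category <- factor(df$category, levels = pc_categories())
  class(df) <- c("locus_context", "data.frame")
  df
}

#' Write a comparison report as a statistics table
#'
#' One comment line with the homogeneity summary, one header line starting
#' \code{#}, then one row per category. P-values are printed with 4
#' significant digits; values below double precision print as
#' \code{"< 2.2e-16"}.
#'
#' @param report A \code{comparison_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_comparison_table <- function(report, path) {
  h <- report$homogeneity
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("## homogeneity chi2=%.6g df=%d p=%s n1=%d n2=%d",
                     h$chi2, h$df, format_pvalue(h$p_value), h$n1, h$n2), con)
  for (w in report$warnings) writeLines(paste0("## warning: ", w), con)
  writeLines(paste0("#", paste(c("category", "fg_count", "bg_count", "fg_freq",
                                 "bg_freq", "ratio", "g_statistic", "p_value",
                                 "p_adjusted", "direction", "stars"),
                               collapse = "\t")), con)
  tab <- report$per_category
  writeLines(sprintf("%s\t%.0f\t%.0f\t%.6g\t%.6g\t%s\t%.6g\t%s\t%s\t%s\t%s",
                     as.character(tab$category), tab$fg_count, tab$bg_count,
                     tab$fg_freq, tab$bg_freq,
                     ifelse(is.na(tab$ratio), "NA", sprintf("%.6g", tab$ratio)),
                     tab$g_statistic, format_pvalue(tab$p_value),
                     format_pvalue(tab$p_adjusted), tab$direction, tab$stars),
             con)
  invisible(path)
}

#' Write GO term results as a table
#'
#' @param results data.frame from \code{\link{term_for_term}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_term_table <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(results), collapse = "\t")), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write extracted sequences as FASTA
#'
#' @param seqs Named character vector from \code{\link{extract_sequences}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}
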