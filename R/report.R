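#' Render SVG report plots
#'
#' Produces the standard report figures as SVG files in \code{out_dir}:
#' a pie chart of the foreground category shares; when a background is
#' given, a side-by-side barplot of the two relative frequency
#' distributions; when a comparison report is given, a barplot of
#' foreground/background enrichment ratios annotated with significance
#' stars; and one histogram per supplied distance histogram. The numeric
#' series drawn in each plot are exactly the corresponding distribution and
#' report fields.
#'
#' @param fg \code{category_distribution} of the foreground set (total > 0).
#' @param bg Optional \code{category_distribution} of the background set.
#' @param report Optional \code{comparison_report} for the ratio plot.
#' @param histograms Optional list of \code{distance_histogram} objects.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the SVG file paths written.
#' @export
render_report <- function(fg, bg = NULL, report = NULL, histograms = NULL,
                          out_dir = ".") {
  if (!inherits(fg, "category_distribution")) pc_stop("fg must be a category_distribution")
  if (fg$total == 0L) pc_stop("foreground distribution is empty: nothing to plot")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) pc_stop("cannot create output directory: %s", out_dir)
  }
  cats <- pc_categories()
  cols <- c("#e31a1c", "#ff7f00", "#1f78b4", "#a6cee3",
            "#33a02c", "#b2df8a", "#bdbdbd")
  paths <- character(0)
  emit <- function(name, width, height, draw) {
    p <- file.path(out_dir, name)
    grDevices::svg(p, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    tryCatch(draw(), finally = NULL)
    paths <<- c(paths, p)
  }

  emit("pie_categories.svg", 7, 6, function() {
    share <- fg$counts / fg$total
    lab <- sprintf("%s (%.1f%%)", cats, 100 * share)
    lab[fg$counts == 0] <- NA
    graphics::pie(fg$counts[fg$counts > 0],
                  labels = lab[fg$counts > 0],
                  col = cols[fg$counts > 0],
                  main = sprintf("Genomic distribution: %s (n = %d)", fg$label, fg$total))
  })

  if (!is.null(bg)) {
    emit("barplot_frequencies.svg", 8, 5, function() {
      m <- rbind(fg$counts / fg$total, bg$counts / bg$total)
      graphics::barplot(m, beside = TRUE, names.arg = cats, las = 2,
                        col = c("#e31a1c", "#737373"),
                        ylab = "relative frequency",
                        main = "Category frequencies, foreground vs background",
                        legend.text = c(fg$label, bg$label))
    })
  }

  if (!is.null(report)) {
    emit("barplot_ratio.svg", 8, 5, function() {
      tab <- report$per_category
      r <- tab$ratio
      ylim <- c(0, max(1.3, r * 1.25, na.rm = TRUE))
      bp <- graphics::barplot(ifelse(is.na(r), 0, r),
                              names.arg = as.character(tab$category), las = 2,
                              col = cols, ylim = ylim,
                              ylab = "foreground / background frequency ratio",
                              main = "Enrichment ratio per category")
      graphics::abline(h = 1, lty = 2)
      graphics::text(bp, ifelse(is.na(r), 0, r), labels = tab$stars, pos = 3)
    })
  }

  for (h in histograms) {
    emit(sprintf("hist_%s.svg", h$end), 7, 5, function() {
      mids <- (utils::head(h$bin_edges, -1) + utils::tail(h$bin_edges, -1)) / 2
      graphics::barplot(h$counts, names.arg = sprintf("%g", mids / 1000),
                        las = 2, col = "#1f78b4", space = 0,
                        xlab = sprintf("signed distance to gene %s end (kb)", h$end),
                        ylab = "loci",
                        main = sprintf("Distances to %s ends (%d out of range)",
                                       h$end, h$n_out_of_range))
    })
  }
  paths
}
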