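#' Brandt-Snedecor chi-square test of homogeneity
#'
#' Tests whether two locus sets draw their category counts from the same
#' underlying distribution over the k context categories. With totals
#' \eqn{n_1}, \eqn{n_2}, \eqn{n = n_1 + n_2} and per-category counts
#' \eqn{n_{1i}}, \eqn{n_{2i}}, the statistic is
#' \deqn{\chi^2 = \frac{n^2}{n_1 n_2}\left[\sum_{i=1}^{k}
#'       \frac{n_{1i}^2}{n_{1i}+n_{2i}} - \frac{n_1^2}{n}\right]}
#' which is algebraically identical to the Pearson chi-square statistic on
#' the 2 x k contingency table but cheaper to evaluate. The p-value is the
#' upper tail of the chi-square distribution with \eqn{k_{eff} - 1} degrees
#' of freedom, where \eqn{k_{eff}} counts categories with a nonzero combined
#' count (empty categories are dropped; the statistic's denominator is
#' undefined for them). Identical distributions give statistic 0 and
#' p-value 1.
#'
#' @param fg,bg \code{category_distribution} objects (foreground = the set
#'   under study, background = the reference set) over the same categories.
#' @return List of class \code{homogeneity_result}: \code{chi2}, \code{df},
#'   \code{p_value}, \code{k_eff}, \code{n1}, \code{n2}, \code{n}.
#' @export
brandt_snedecor <- function(fg, bg) {
  x <- .aligned_counts(fg, bg)
  n1 <- sum(x$fg); n2 <- sum(x$bg)
  if (n1 == 0L || n2 == 0L) pc_stop("both distributions must have a positive total")
  keep <- (x$fg + x$bg) > 0L
  k_eff <- sum(keep)
  if (k_eff < 2L) pc_stop("fewer than 2 non-empty categories: no comparison possible")
  n1i <- as.numeric(x$fg[keep]); n2i <- as.numeric(x$bg[keep])
  n <- n1 + n2
  chi2 <- (n^2 / (n1 * n2)) * (sum(n1i^2 / (n1i + n2i)) - n1^2 / n)
  chi2 <- max(chi2, 0)          # guard tiny negative rounding at the null
  df <- k_eff - 1L
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
                 k_eff = k_eff, n1 = n1, n2 = n2, n = n),
            class = "homogeneity_result")
}

.aligned_counts <- function(fg, bg) {
  if (!inherits(fg, "category_distribution")) fg <- category_distribution(fg, "fg")
  if (!inherits(bg, "category_distribution")) bg <- category_distribution(bg, "bg")
  list(fg = fg$counts, bg = bg$counts)
}

#' Per-category G-tests of independence
#'
#' For each category i, tests the 2 x 2 table pitting that category against
#' the union of the other categories in the two sets:
#' \preformatted{[[n1i, n1 - n1i], [n2i, n2 - n2i]]}
#' with the log-likelihood statistic \eqn{G = 2\sum O \ln(O/E)} over the four
#' cells (expected counts from the margins; empty cells contribute 0) and a
#' chi-square upper-tail p-value at 1 degree of freedom. No Williams or
#' Yates correction is applied. Enrichment ratio is foreground frequency over
#' background frequency (\code{NA} when the background count is 0);
#' p-values are Bonferroni-adjusted over the seven categories and stars are
#' assigned from the adjusted values.
#'
#' @inheritParams brandt_snedecor
#' @return data.frame with one row per category: counts, frequencies, ratio,
#'   \code{g_statistic}, \code{p_value}, \code{p_adjusted},
#'   \code{direction} (over/under/none by frequency comparison) and
#'   \code{stars}.
#' @export
per_category_gtest <- function(fg, bg) {
  x <- .aligned_counts(fg, bg)
  n1 <- sum(x$fg); n2 <- sum(x$bg)
  if (n1 == 0L || n2 == 0L) pc_stop("both distributions must have a positive total")
  cats <- names(x$fg)
  res <- lapply(cats, function(cat) {
    n1i <- as.numeric(x$fg[[cat]]); n2i <- as.numeric(x$bg[[cat]])
    tab <- matrix(c(n1i, n1 - n1i, n2i, n2 - n2i), nrow = 2, byrow = TRUE)
    g <- g_statistic(tab)
    fg_freq <- n1i / n1; bg_freq <- n2i / n2
    data.frame(
      category = cat, fg_count = n1i, bg_count = n2i,
      fg_freq = fg_freq, bg_freq = bg_freq,
      ratio = if (n2i > 0) fg_freq / bg_freq else NA_real_,
      g_statistic = g,
      p_value = stats::pchisq(g, df = 1, lower.tail = FALSE),
      direction = if (fg_freq > bg_freq) "over" else if (fg_freq < bg_freq) "under" else "none",
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "bonferroni")
  res$stars <- vapply(res$p_adjusted, significance_stars, character(1))
  res$category <- factor(res$category, levels = pc_categories())
  res
}

#' Log-likelihood G statistic of a contingency table
#'
#' \eqn{G = 2\sum O \ln(O/E)} with expected counts from the table margins and
#' the convention that empty cells contribute 0.
#'
#' @param tab Numeric matrix of observed counts.
#' @return The G statistic (non-negative).
#' @export
g_statistic <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / n
  o <- as.numeric(tab); e <- as.numeric(e)
  nz <- o > 0
  g <- 2 * sum(o[nz] * log(o[nz] / e[nz]))
  max(g, 0)
}

#' Check the assumptions of the homogeneity comparison
#'
#' The test assumes independent observations, a background at least twice
#' the size of the foreground, and exhaustive mutually exclusive categories.
#' This reports warnings (never errors) when the background is smaller than
#' twice the foreground or when any expected cell count of the 2 x k table
#' (empty categories dropped) falls below 5, where the chi-square
#' approximation weakens.
#'
#' @inheritParams brandt_snedecor
#' @return Character vector of warning messages (possibly empty).
#' @export
check_assumptions <- function(fg, bg) {
  x <- .aligned_counts(fg, bg)
  n1 <- sum(x$fg); n2 <- sum(x$bg)
  w <- character(0)
  if (n2 < 2 * n1)
    w <- c(w, sprintf("background total (%d) is less than twice the foreground total (%d)", n2, n1))
  keep <- (x$fg + x$bg) > 0L
  if (any(keep)) {
    tab <- rbind(as.numeric(x$fg[keep]), as.numeric(x$bg[keep]))
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(e < 5))
      w <- c(w, sprintf("%d expected cell count(s) below 5; chi-square approximation may be poor",
                        sum(e < 5)))
  }
  w
}

#' Significance stars for a p-value
#'
#' \code{"***"} for p < 0.001, \code{"**"} for p < 0.01, \code{"*"} for
#' p < 0.05, otherwise the empty string.
#'
#' @param p A p-value in [0, 1].
#' @return Character string of stars.
#' @export
significance_stars <- function(p) {
  if (is.na(p) || p < 0 || p > 1) pc_stop("p must be in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Full comparison of two category distributions
#'
#' Runs the Brandt-Snedecor homogeneity test over all categories, the
#' per-category G-tests, and the assumption checks, bundled into one report.
#'
#' @inheritParams brandt_snedecor
#' @return List of class \code{comparison_report}: \code{homogeneity}
#'   (\code{homogeneity_result}), \code{per_category} (data.frame),
#'   \code{warnings} (character), \code{fg_label}, \code{bg_label}.
#' @export
compare_distributions <- function(fg, bg) {
  if (!inherits(fg, "category_distribution")) fg <- category_distribution(fg, "foreground")
  if (!inherits(bg, "category_distribution")) bg <- category_distribution(bg, "background")
  structure(list(homogeneity = brandt_snedecor(fg, bg),
                 per_category = per_category_gtest(fg, bg),
                 warnings = check_assumptions(fg, bg),
                 fg_label = fg$label, bg_label = bg$label),
            class = "comparison_report")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("Brandt-Snedecor homogeneity test: chi2 = %.4g, df = %d, p = %s (n1 = %d, n2 = %d)\n",
              x$chi2, x$df, format_pvalue(x$p_value), x$n1, x$n2))
  invisible(x)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison: %s (foreground, n = %d) vs %s (background, n = %d)\n",
              x$fg_label, x$homogeneity$n1, x$bg_label, x$homogeneity$n2))
  print(x$homogeneity)
  tab <- x$per_category
  cat(sprintf("  %-10s %8s %8s %8s %8s %7s %9s %10s %10s %s\n",
              "category", "fg", "bg", "fg_freq", "bg_freq", "ratio", "G",
              "p", "p_adj", "stars"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-10s %8.0f %8.0f %8.4f %8.4f %7s %9.4g %10s %10s %s\n",
                as.character(tab$category[i]), tab$fg_count[i], tab$bg_count[i],
                tab$fg_freq[i], tab$bg_freq[i],
                ifelse(is.na(tab$ratio[i]), "NA", sprintf("%.3f", tab$ratio[i])),
                tab$g_statistic[i], format_pvalue(tab$p_value[i]),
                format_pvalue(tab$p_adjusted[i]), tab$stars[i]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
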