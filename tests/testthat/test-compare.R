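test_that("identical category proportions give statistic 0 and p-value 1", {
  r <- brandt_snedecor(category_distribution(c(10, 20, 30)),
                       category_distribution(c(20, 40, 60)))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2L)
  expect_equal(r$n, r$n1 + r$n2)
})

test_that("the homogeneity statistic matches its closed-form value on a worked table", {
  # fg (10,20,30) vs bg (40,40,40): chi2 = 4.5 * (2 + 400/60 + 900/70 - 20)
  r <- brandt_snedecor(category_distribution(c(10, 20, 30)),
                       category_distribution(c(40, 40, 40)))
  expect_equal(r$chi2, (180^2 / (60 * 120)) * (100 / 50 + 400 / 60 + 900 / 70 - 3600 / 180),
               tolerance = 1e-12)
  expect_equal(r$chi2, 6.857, tolerance = 1e-3)
  # at df = 2 the chi-square upper tail has the closed form exp(-x/2)
  expect_equal(r$p_value, exp(-r$chi2 / 2), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0324, tolerance = 1e-2)
})

test_that("categories empty in both sets are dropped and reduce the degrees of freedom", {
  r <- brandt_snedecor(category_distribution(c(10, 0, 30)),
                       category_distribution(c(20, 0, 60)))
  expect_equal(r$k_eff, 2L)
  expect_equal(r$df, 1L)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
})

test_that("the shortcut statistic equals an independent Pearson chi-square on random tables", {
  set.seed(91)
  for (rep in 1:200) {
    k <- sample(2:7, 1)
    fg <- sample(1:500, k, replace = TRUE)
    bg <- sample(1:500, k, replace = TRUE)
    r <- brandt_snedecor(category_distribution(fg), category_distribution(bg))
    pearson <- suppressWarnings(
      stats::chisq.test(rbind(fg, bg), correct = FALSE))
    expect_equal(r$chi2, unname(pearson$statistic), tolerance = 1e-9)
    expect_equal(r$df, unname(pearson$parameter))
    expect_equal(r$p_value, unname(pearson$p.value), tolerance = 1e-9)
  }
})

test_that("swapping foreground and background preserves chi2 and G, and inverts ratios", {
  fg <- category_distribution(c(12, 40, 9, 30, 5, 1, 80))
  bg <- category_distribution(c(50, 60, 30, 31, 25, 9, 120))
  a <- brandt_snedecor(fg, bg); b <- brandt_snedecor(bg, fg)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
  ga <- per_category_gtest(fg, bg); gb <- per_category_gtest(bg, fg)
  expect_equal(ga$g_statistic, gb$g_statistic, tolerance = 1e-12)
  expect_equal(ga$ratio, 1 / gb$ratio, tolerance = 1e-12)
})

test_that("chi2 scales linearly with counts and p is non-increasing for a non-null table", {
  fg0 <- c(10, 25, 30); bg0 <- c(30, 40, 80)
  prev_p <- Inf
  base <- brandt_snedecor(category_distribution(fg0), category_distribution(bg0))
  for (c in c(1, 2, 5, 10)) {
    r <- brandt_snedecor(category_distribution(fg0 * c), category_distribution(bg0 * c))
    expect_equal(r$chi2, base$chi2 * c, tolerance = 1e-9)
    expect_lte(r$p_value, prev_p)
    prev_p <- r$p_value
  }
})

test_that("degenerate comparisons are rejected", {
  expect_error(brandt_snedecor(category_distribution(c(0, 0, 0)),
                               category_distribution(c(1, 2, 3))), "positive total")
  expect_error(brandt_snedecor(category_distribution(c(5, 0, 0)),
                               category_distribution(c(7, 0, 0))),
               "fewer than 2")
})

test_that("per-category G matches direct log-likelihood evaluation", {
  fg <- category_distribution(c(exon = 10, intron = 50), label = "fg")
  bg <- category_distribution(c(exon = 40, intron = 80), label = "bg")
  res <- per_category_gtest(fg, bg)
  exon <- res[res$category == "exon", ]
  # direct 2*sum(O*ln(O/E)) on [[10,50],[40,80]]
  o <- c(10, 50, 40, 80)
  e <- c(60 * 50, 60 * 130, 120 * 50, 120 * 130) / 180
  expect_equal(exon$g_statistic, 2 * sum(o * log(o / e)), tolerance = 1e-9)
  expect_equal(exon$g_statistic, 5.873, tolerance = 1e-3)
  expect_equal(exon$p_value, 0.0154, tolerance = 1e-2)
  expect_equal(exon$direction, "under")
  expect_equal(exon$ratio, 0.5)
})

test_that("identical proportions and empty categories give G = 0", {
  fg <- category_distribution(c(exon = 10, intron = 50))
  bg <- category_distribution(c(exon = 20, intron = 100))
  res <- per_category_gtest(fg, bg)
  expect_equal(res$g_statistic[res$category == "exon"], 0, tolerance = 1e-12)
  expect_equal(res$p_value[res$category == "exon"], 1)
  expect_equal(res$direction[res$category == "exon"], "none")
  expect_equal(res$ratio[res$category == "exon"], 1)
  # category empty in both sets
  empty <- res[res$category == "five_far", ]
  expect_equal(empty$g_statistic, 0)
  expect_equal(empty$p_value, 1)
  expect_true(is.na(empty$ratio))
})

test_that("assumption checks warn on small backgrounds and small expected counts", {
  d <- function(x) category_distribution(x)
  expect_length(check_assumptions(d(c(20, 20, 20)), d(c(40, 40, 40))), 0L)
  expect_match(check_assumptions(d(c(20, 20, 20)), d(c(30, 35, 35)))[1],
               "twice the foreground")
  expect_match(check_assumptions(d(c(1, 1, 58)), d(c(2, 2, 116)))[1],
               "below 5")
})

test_that("stars follow the 0.001/0.01/0.05 thresholds", {
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.5), "")
  expect_equal(significance_stars(0.05), "")   # boundary is strict
  expect_error(significance_stars(1.5), "\\[0, 1\\]")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
})

test_that("a full comparison report covers all seven categories once", {
  fg <- summarize_categories(rep(c("exon", "distant", "intron"), c(30, 50, 20)), "fg")
  bg <- summarize_categories(rep(c("exon", "distant", "intron"), c(40, 150, 110)), "bg")
  rep_ <- compare_distributions(fg, bg)
  expect_s3_class(rep_, "comparison_report")
  expect_equal(sort(as.character(rep_$per_category$category)), sort(pc_categories()))
  expect_equal(nrow(rep_$per_category), 7L)
  expect_equal(rep_$per_category$p_adjusted,
               pmin(1, rep_$per_category$p_value * 7))
  out <- capture.output(print(rep_))
  expect_true(any(grepl("Brandt-Snedecor", out)))
})

test_that("a subset foreground makes the homogeneity test conservative, not anti-conservative", {
  # drawing the foreground as a random 25% subsample of the background's loci
  # violates the independence assumption; the statistic is then deflated by
  # roughly (1-f)/(1+f), so rejections should fall well below the nominal rate
  set.seed(55)
  probs <- c(0.1, 0.2, 0.15, 0.1, 0.1, 0.1, 0.25)
  n_bg <- 2000L; n_fg <- 500L
  rej <- 0L; reps <- 500L
  for (i in seq_len(reps)) {
    bg_cats <- sample.int(7L, n_bg, replace = TRUE, prob = probs)
    fg_cats <- bg_cats[sample.int(n_bg, n_fg)]
    r <- brandt_snedecor(category_distribution(tabulate(fg_cats, 7L)),
                         category_distribution(tabulate(bg_cats, 7L)))
    if (r$p_value < 0.05) rej <- rej + 1L
  }
  expect_lt(rej / reps, 0.05)
})
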