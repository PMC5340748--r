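test_that("median and IQR follow the interpolated-quartile convention", {
  s <- median_iqr(c(-140, -98, -574, -116))
  expect_equal(s$median, -128)
  expect_equal(s$iqr, 137)
  expect_equal(median_iqr(7)$median, 7)
  expect_equal(median_iqr(7)$iqr, 0)
  expect_error(median_iqr(numeric(0)), "empty")

  # brute-force sort-based oracle over random small samples
  set.seed(21)
  for (n in 1:8) {
    v <- sample(-50:50, n, replace = TRUE)
    s <- median_iqr(v)
    sv <- sort(v)
    med <- if (n %% 2) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
    expect_equal(s$median, med)
    qpos <- function(p) {
      h <- 1 + (n - 1) * p
      lo <- floor(h)
      sv[lo] + (h - lo) * (sv[min(n, lo + 1)] - sv[lo])
    }
    expect_equal(s$q1, qpos(0.25))
    expect_equal(s$q3, qpos(0.75))
  }
})

test_that("exact Mann-Whitney matches enumeration properties", {
  # disjoint groups n = m = 4: minimal two-sided p is 2/70
  mw <- mann_whitney_exact(1:4, 11:14)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 70, tolerance = 1e-12)
  mw2 <- mann_whitney_exact(11:14, 1:4)
  expect_equal(mw2$U, 16)
  expect_equal(mw2$p, mw$p)        # symmetric under group swap
  expect_equal(mw$U + mw2$U, 16)   # U_a + U_b = n m

  # identical samples: maximal overlap, p = 1
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # agrees with the exact Wilcoxon distribution when there are no ties
  set.seed(22)
  a <- rnorm(4)
  b <- rnorm(5)
  ours <- mann_whitney_exact(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  expect_error(mann_whitney_exact(1:11, 1:10), "n \\+ m")
  expect_error(mann_whitney_exact(numeric(0), 1), "non-empty")
})

test_that("bundled example coefficients reproduce the recomputable
           group statistics", {
  ed <- example_shape_vectors("ED")
  ctrl <- ed[ed$group == "control", ]
  asg <- ed[ed$group == "AS", ]
  expect_equal(median_iqr(ctrl$mode_1)$median, -128)
  expect_equal(median_iqr(ctrl$mode_1)$iqr, 137)
  expect_equal(median_iqr(ctrl$mode_4)$iqr, 156)
  expect_equal(median_iqr(asg$mode_1)$median, 385)
  es <- example_shape_vectors("ES")
  expect_equal(median_iqr(es$mode_3[es$group == "control"])$median, -159)
  expect_equal(median_iqr(es$mode_2[es$group == "AS"])$median, -349)
})

test_that("boxplot summaries respect whisker bounds against brute force", {
  set.seed(23)
  sv <- data.frame(subject_id = sprintf("s%d", 1:10),
                   mode_1 = c(rnorm(9), 25), mode_2 = rnorm(10))
  groups <- rep(c("g1", "g2"), each = 5)
  bd <- boxplot_data(sv, groups)
  expect_equal(nrow(bd), 4)
  for (r in seq_len(nrow(bd))) {
    v <- sv[[bd$mode[r]]][groups == bd$group[r]]
    s <- median_iqr(v)
    lo <- s$q1 - 1.5 * s$iqr
    hi <- s$q3 + 1.5 * s$iqr
    inside <- v[v >= lo & v <= hi]
    expect_equal(bd$whisker_low[r], min(inside))
    expect_equal(bd$whisker_high[r], max(inside))
    outl <- v[v < lo | v > hi]
    got <- if (bd$outliers[r] == "") numeric(0) else
      as.numeric(strsplit(bd$outliers[r], ",")[[1]])
    expect_equal(sort(got), sort(outl))
  }

  # single-subject group degenerates cleanly
  bd1 <- boxplot_data(data.frame(subject_id = "s", mode_1 = 3), "g")
  expect_equal(bd1$median, 3)
  expect_equal(bd1$iqr, 0)
  expect_equal(bd1$whisker_low, 3)
})
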