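# Group-level summaries of shape-vector coefficients: median / IQR per group
# and mode, boxplot data, and the exact (enumeration) Mann-Whitney U test,
# suited to the very small group sizes typical of pilot shape studies.

#' Median and interquartile range
#'
#' Median as the midpoint of the central order statistics; quartiles by
#' linear interpolation at position `1 + (n - 1) p` (the type-7 convention),
#' `IQR = Q3 - Q1`.
#'
#' @param values non-empty numeric vector.
#' @return list with `median`, `q1`, `q3`, `iqr`.
#' @export
median_iqr <- function(values) {
  if (!length(values)) stopf("empty input")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

mw_u_statistic <- function(a, b) {
  # U = #(a_i > b_j) + 1/2 per tie, via midranks
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Exact two-sided Mann-Whitney U test
#'
#' U counts pairs with `a_i > b_j` (ties count one half). The p-value is
#' computed by full enumeration of all `choose(n + m, n)` group assignments
#' of the pooled values (ties handled by the same midrank statistic);
#' two-sided as `min(1, 2 * min(P(U <= u), P(U >= u)))`. Enumeration is
#' limited to `n + m <= 20`.
#'
#' @param a,b non-empty numeric vectors.
#' @return list with `U` (for sample `a`) and `p` (two-sided exact).
#' @export
mann_whitney_exact <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  n <- length(a)
  m <- length(b)
  if (n + m > 20)
    stopf(paste0("exact enumeration limited to n + m <= 20 (got %d); ",
                 "use a normal approximation outside this package"), n + m)
  u_obs <- mw_u_statistic(a, b)
  r <- rank(c(a, b))
  combos <- combn(n + m, n)
  us <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

#' Boxplot summary per group and mode
#'
#' Median and quartiles via [median_iqr()]; whiskers extend to the most
#' extreme data points within `Q1 - 1.5 IQR` / `Q3 + 1.5 IQR`; points beyond
#' are listed as outliers.
#'
#' @param shape_vectors data frame with `subject_id` and `mode_*` columns.
#' @param groups group label per row of `shape_vectors` (or a data frame
#'   with `subject_id`, `group`).
#' @return data frame, one row per (mode, group), with median, quartiles,
#'   IQR, whiskers, n, and a comma-separated outlier list.
#' @export
boxplot_data <- function(shape_vectors, groups) {
  if (is.data.frame(groups))
    groups <- groups$group[match(shape_vectors$subject_id,
                                 groups$subject_id)]
  if (length(groups) != nrow(shape_vectors) || anyNA(groups))
    stopf("group labels must cover every subject")
  modes <- grep("^mode_", names(shape_vectors), value = TRUE)
  rows <- list()
  for (mode in modes)
    for (g in unique(groups)) {
      v <- shape_vectors[[mode]][groups == g]
      s <- median_iqr(v)
      lo <- s$q1 - 1.5 * s$iqr
      hi <- s$q3 + 1.5 * s$iqr
      inside <- v[v >= lo & v <= hi]
      rows[[length(rows) + 1]] <-
        data.frame(mode = mode, group = g, n = length(v),
                   median = s$median, q1 = s$q1, q3 = s$q3, iqr = s$iqr,
                   whisker_low = min(inside), whisker_high = max(inside),
                   outliers = paste(v[v < lo | v > hi], collapse = ","))
    }
  do.call(rbind, rows)
}

#' Group comparison table (exact Mann-Whitney per mode)
#'
#' @param shape_vectors,groups as in [boxplot_data()]; exactly two groups.
#' @return data frame with one row per mode: U and two-sided exact p.
#' @export
group_comparison <- function(shape_vectors, groups) {
  if (is.data.frame(groups))
    groups <- groups$group[match(shape_vectors$subject_id,
                                 groups$subject_id)]
  gl <- unique(groups)
  if (length(gl) != 2) stopf("exactly two groups required")
  modes <- grep("^mode_", names(shape_vectors), value = TRUE)
  do.call(rbind, lapply(modes, function(mode) {
    a <- shape_vectors[[mode]][groups == gl[1]]
    b <- shape_vectors[[mode]][groups == gl[2]]
    mw <- mann_whitney_exact(a, b)
    data.frame(mode = mode, group_a = gl[1], group_b = gl[2], U = mw$U,
               p = mw$p)
  }))
}

#' Bundled example shape-vector coefficients
#'
#' Per-subject shape-vector coefficients (first four modes, ED and ES) for an
#' example cohort of four repaired-aortic-stenosis patients and four healthy
#' controls, as rounded for reporting. Useful for exercising the statistics
#' module without running the full pipeline.
#'
#' @param phase `"ED"` or `"ES"`.
#' @return data frame with `subject_id`, `group`, `mode_1..mode_4`.
#' @export
example_shape_vectors <- function(phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  f <- system.file("extdata",
                   sprintf("example_shape_vectors_%s.csv", tolower(phase)),
                   package = "lvssa", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
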