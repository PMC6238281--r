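#' Summarize per-fiber metrics for one construct
#'
#' Mean, sample SD and SEM of each numeric metric across the included fibers
#' of a construct, plus the percentage of fibers showing spreading.
#' Percentages are computed per fiber first and then averaged across fibers
#' (never pooled over peaks), matching how fibers are treated as the unit of
#' replication.
#'
#' @param metrics Data frame of per-fiber metrics
#'   (rows from [compute_fiber_metrics()]).
#' @param construct Construct to summarize (default: all rows).
#' @param columns Metric columns to summarize.
#' @return Data frame with one row per metric: `metric`, `mean`, `sd`, `sem`,
#'   `n_fibers`. With a single fiber, SD and SEM are reported as 0 and
#'   flagged via the `single_fiber` column.
#' @export
summarize_construct <- function(metrics, construct = NULL,
                                columns = c("n_ref_peaks", "n_query_peaks",
                                            "peak_count_ratio",
                                            "ref_domain_size_um",
                                            "query_domain_size_um",
                                            "domain_size_ratio",
                                            "pct_query_coloc",
                                            "pct_ref_coloc",
                                            "pct_inside_noncoloc",
                                            "pct_outside",
                                            "ds_left_um", "ds_right_um")) {
  if (!is.null(construct)) {
    metrics <- metrics[metrics$construct == construct, , drop = FALSE]
  }
  n <- nrow(metrics)
  if (n == 0L) stop("no fibers to summarize")
  columns <- intersect(columns, names(metrics))
  rows <- lapply(columns, function(cl) {
    v <- metrics[[cl]]
    v <- v[!is.na(v)]
    m <- mean(v)
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(metric = cl, mean = m, sd = s, sem = s / sqrt(length(v)),
               n_fibers = length(v), single_fiber = length(v) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("spreads" %in% names(metrics)) {
    out <- rbind(out, data.frame(
      metric = "pct_fibers_spreading", mean = 100 * mean(metrics$spreads),
      sd = NA_real_, sem = NA_real_, n_fibers = n, single_fiber = n == 1L,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Normality-guided two-sample comparison
#'
#' Checks each group for normality with a Shapiro-Wilk test; when both groups
#' look normal (p >= `alpha_normality`) an unpaired two-sided Student's t test
#' is used, otherwise a two-sided two-sample Kolmogorov-Smirnov test.
#'
#' @param a,b Numeric vectors (each of length >= 3).
#' @param alpha_normality Normality alpha (default 0.05).
#' @param var_equal Use the equal-variance t statistic (default `TRUE`; set
#'   `FALSE` for the Welch variant).
#' @return One-row data frame: `test` (`"t_unpaired"` or `"ks_two_sample"`),
#'   `statistic`, `p`, plus the two Shapiro-Wilk p values.
#' @export
choose_and_run_test <- function(a, b, alpha_normality = 0.05,
                                var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L) stop("group a too small for normality check (n < 3)")
  if (length(b) < 3L) stop("group b too small for normality check (n < 3)")
  sw_a <- shapiro_p(a)
  sw_b <- shapiro_p(b)
  if (sw_a >= alpha_normality && sw_b >= alpha_normality) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(test = "t_unpaired", statistic = unname(tt$statistic),
               p = tt$p.value, shapiro_p_a = sw_a, shapiro_p_b = sw_b,
               stringsAsFactors = FALSE)
  } else {
    ks <- suppressWarnings(stats::ks.test(a, b))
    data.frame(test = "ks_two_sample", statistic = unname(ks$statistic),
               p = ks$p.value, shapiro_p_a = sw_a, shapiro_p_b = sw_b,
               stringsAsFactors = FALSE)
  }
}

# shapiro.test errors on constant input; a constant sample is treated as
# maximally non-normal (degenerate distribution) rather than failing the run.
shapiro_p <- function(x) {
  if (length(unique(x)) == 1L) return(0)
  stats::shapiro.test(x)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Adjusts p values with the Benjamini-Hochberg step-up procedure (R's
#' `p.adjust` method `"fdr"`), returning them in input order.
#'
#' @param pvalues Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order and length.
#' @export
fdr_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "fdr")
}

#' Significance stars
#'
#' `"ns"` for adjusted p > 0.05, `"*"` for p <= 0.05, `"**"` for p < 0.001.
#'
#' @param p_adj Adjusted p value(s) in \[0, 1\].
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p_adj) {
  p_adj <- as.numeric(p_adj)
  if (any(!is.finite(p_adj)) || any(p_adj < 0 | p_adj > 1)) {
    stop("p values must lie in [0, 1]")
  }
  ifelse(p_adj > 0.05, "ns", ifelse(p_adj < 0.001, "**", "*"))
}

#' Compare constructs against a reference construct
#'
#' For each metric, runs [choose_and_run_test()] between every non-reference
#' construct and the reference, then adjusts p values across constructs within
#' that metric (the FDR family is one metric's set of pairwise
#' construct-vs-reference comparisons).
#'
#' @param metrics Per-fiber metrics data frame (several constructs).
#' @param reference Reference construct label (default `"APEX-CENP-A"`).
#' @param columns Metric columns to compare.
#' @param min_n Minimum fibers per group to attempt a test.
#' @return Data frame of comparisons with `p_adj` and `stars` columns.
#' @export
compare_constructs <- function(metrics, reference = "APEX-CENP-A",
                               columns = c("peak_count_ratio",
                                           "domain_size_ratio",
                                           "pct_query_coloc",
                                           "pct_inside_noncoloc",
                                           "pct_outside",
                                           "ds_left_um", "ds_right_um"),
                               min_n = 3L) {
  if (!reference %in% metrics$construct) {
    stop("reference construct ", reference, " not present in metrics")
  }
  others <- setdiff(unique(metrics$construct), reference)
  columns <- intersect(columns, names(metrics))
  out <- list()
  for (cl in columns) {
    a_all <- metrics[metrics$construct == reference, cl]
    rows <- list()
    for (grp in others) {
      b <- metrics[metrics$construct == grp, cl]
      a <- a_all[!is.na(a_all)]
      b <- b[!is.na(b)]
      if (length(a) < min_n || length(b) < min_n) next
      res <- choose_and_run_test(a, b)
      rows[[grp]] <- cbind(
        data.frame(metric = cl, group_a = reference, group_b = grp,
                   n_a = length(a), n_b = length(b),
                   stringsAsFactors = FALSE),
        res)
    }
    if (length(rows)) {
      fam <- do.call(rbind, unname(rows))
      fam$p_adj <- fdr_adjust(fam$p)
      fam$stars <- significance_stars(fam$p_adj)
      out[[cl]] <- fam
    }
  }
  res <- do.call(rbind, unname(out))
  if (is.null(res)) {
    stop("no construct pair had >= ", min_n, " fibers per group")
  }
  rownames(res) <- NULL
  res
}
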