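#' Welch two-sample t-test
#'
#' Two-tailed t-test for independent samples without assuming equal
#' variances (Welch-Satterthwaite degrees of freedom). When both samples
#' are constant with equal means the test is degenerate and `t = 0,
#' p = 1` is returned.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return A `stat_result` tibble row: `statistic_name`, `statistic`,
#'   `df`, `p_value`, `n_a`, `n_b`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(stat_result("welch_t", 0, p = 1, a, b,
                         df = length(a) + length(b) - 2))
    }
    stop("both samples constant with different means: t undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  stat_result("welch_t", unname(ht$statistic), p = ht$p.value, a, b,
              df = unname(ht$parameter))
}

#' Mann-Whitney U test
#'
#' Rank-sum test for independent samples. The reported `statistic` is
#' `min(U_a, U_b)`; both one-sided U values are included. The two-tailed
#' p-value is exact (enumeration over rank assignments) when
#' `n_a + n_b <= 12` and there are no ties, otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param a,b numeric samples (each non-empty).
#' @return A `stat_result` tibble row with additional columns `U_a`,
#'   `U_b` and group medians/IQRs in place of means/sds.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (n_a + n_b <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  u_a <- unname(ht$statistic)          # W = U of the first sample
  u_b <- n_a * n_b - u_a
  out <- stat_result("mann_whitney_u", min(u_a, u_b), p = ht$p.value, a, b,
                     descriptive = "median")
  out$U_a <- u_a
  out$U_b <- u_b
  out$exact <- exact
  out
}

#' Pearson correlation
#'
#' Product-moment correlation with two-tailed p-value from the t-transform
#' with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return A `stat_result` tibble row with columns `statistic`
#'   (r), `df`, `p_value`, `n`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  tibble::tibble(
    statistic_name = "pearson_r",
    statistic = unname(ht$estimate),
    df = unname(ht$parameter),
    p_value = if (abs(unname(ht$estimate)) == 1) 0 else ht$p.value,
    n = length(x)
  )
}

stat_result <- function(name, statistic, p, a, b, df = NA_real_,
                        descriptive = c("mean", "median")) {
  descriptive <- match.arg(descriptive)
  if (descriptive == "mean") {
    tibble::tibble(
      statistic_name = name, statistic = statistic, df = df, p_value = p,
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), sd_a = stats::sd(a),
      mean_b = mean(b), sd_b = stats::sd(b)
    )
  } else {
    tibble::tibble(
      statistic_name = name, statistic = statistic, df = df, p_value = p,
      n_a = length(a), n_b = length(b),
      median_a = stats::median(a), iqr_a = stats::IQR(a),
      median_b = stats::median(b), iqr_b = stats::IQR(b)
    )
  }
}

#' Full group-comparison and correlation battery
#'
#' Reproduces the analysis families applied to a per-subject metrics
#' table: Welch t-tests between groups on the global mean PLI per band and
#' on each of the 24 region-grouped distance summaries per band;
#' Mann-Whitney U tests on the graph metrics C and L per band; and pooled
#' (both groups combined) Pearson correlations of C and L with the
#' cognitive score per band. Significance is flagged at `alpha`
#' uncorrected; an optional Benjamini-Hochberg adjusted column can be
#' added (off by default, matching the per-test procedure of the original
#' analysis design).
#'
#' @param metrics per-subject metrics table as produced by
#'   [subject_metrics()]: one row per subject x band with columns
#'   `subject_id`, `band`, `global_mean_pli`, `C`, `L` and optionally the
#'   distance-summary columns.
#' @param manifest cohort manifest tibble with columns `subject_id`,
#'   `group` (two levels), `score`.
#' @param alpha significance level (default 0.05).
#' @param fdr add a Benjamini-Hochberg adjusted p column per family?
#' @return Named list of tibbles: `global_pli_tests`, `distance_tests`,
#'   `graph_tests`, `correlations`.
#' @export
run_group_analysis <- function(metrics, manifest, alpha = 0.05,
                               fdr = FALSE) {
  stopifnot(all(c("subject_id", "group", "score") %in% names(manifest)))
  missing <- setdiff(manifest$subject_id, metrics$subject_id)
  if (length(missing)) {
    stop("subjects missing from metrics table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- sort(unique(manifest$group))
  if (length(groups) != 2) stop("manifest must contain exactly 2 groups",
                                call. = FALSE)
  metrics <- metrics[metrics$subject_id %in% manifest$subject_id, ]
  grp <- manifest$group[match(metrics$subject_id, manifest$subject_id)]
  score <- manifest$score[match(metrics$subject_id, manifest$subject_id)]
  bands <- unique(metrics$band)

  test_rows <- function(columns, test_fun) {
    out <- list()
    for (band in bands) {
      in_band <- metrics$band == band
      for (col in columns) {
        v <- metrics[[col]]
        va <- v[in_band & grp == groups[1]]
        vb <- v[in_band & grp == groups[2]]
        if (any(is.na(va)) || any(is.na(vb)) || !length(va) || !length(vb)) {
          next
        }
        row <- test_fun(va, vb)
        out[[length(out) + 1L]] <-
          cbind(tibble::tibble(band = band, measure = col), row)
      }
    }
    do.call(rbind, out)
  }

  finish <- function(tab) {
    if (is.null(tab)) return(tab)
    tab$significant <- tab$p_value < alpha
    if (fdr) tab$p_bh <- stats::p.adjust(tab$p_value, method = "BH")
    tibble::as_tibble(tab)
  }

  global_tab <- test_rows("global_mean_pli", welch_t)
  dist_cols <- setdiff(names(metrics),
                       c("subject_id", "band", "global_mean_pli", "C", "L"))
  dist_tab <- if (length(dist_cols)) test_rows(dist_cols, welch_t) else NULL
  graph_tab <- test_rows(c("C", "L"), mann_whitney_u)

  corr <- list()
  for (band in bands) {
    in_band <- metrics$band == band
    for (col in c("C", "L")) {
      v <- metrics[[col]][in_band]
      s <- score[in_band]
      ok <- is.finite(v) & is.finite(s)
      if (sum(ok) < 3) next
      row <- pearson_r(v[ok], s[ok])
      corr[[length(corr) + 1L]] <-
        cbind(tibble::tibble(band = band, measure = col), row)
    }
  }
  corr_tab <- if (length(corr)) do.call(rbind, corr) else NULL

  list(
    global_pli_tests = finish(global_tab),
    distance_tests = finish(dist_tab),
    graph_tests = finish(graph_tab),
    correlations = finish(corr_tab)
  )
}
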