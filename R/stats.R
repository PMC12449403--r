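# Descriptive and comparative statistics.  The nonparametric tests wrap
# the reference implementations in base R (wilcox.test, kruskal.test,
# chisq.test, fisher.test) behind a uniform comparison record.

#' Median and interquartile range
#'
#' Quantiles by the linear-interpolation convention (type 7, the common
#' statistical-package default).
#'
#' @param values Nonempty numeric vector.
#' @param label Group label carried in the result.
#' @return data.frame with `group`, `n`, `median`, `q25`, `q75`.
#' @export
median_iqr <- function(values, label = "all") {
  if (length(values) == 0L || all(is.na(values)))
    stop("median_iqr requires a nonempty sample", call. = FALSE)
  values <- values[!is.na(values)]
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(group = label, n = length(values),
             median = q[2L], q25 = q[1L], q75 = q[3L],
             stringsAsFactors = FALSE)
}

new_group_comparison <- function(test, statistic, p_value,
                                 adjusted_p = NA_real_, summaries = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), adjusted_p = adjusted_p,
                 summaries = summaries),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g%s\n",
              x$test, x$statistic, x$p_value,
              if (!is.na(x$adjusted_p))
                sprintf(" (Bonferroni-adjusted %.4g)", x$adjusted_p)
              else ""))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p by enumeration when both samples have at most eight
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction.  The reported U statistic is for
#' the first sample.
#'
#' @param x,y Nonempty numeric samples.
#' @param mode `"auto"` (the rule above), `"exact"`, or `"approx"`.
#' @return A `"group_comparison"` with per-sample median/IQR summaries.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop("mann_whitney_u requires two nonempty samples", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  auto = length(x) <= 8L && length(y) <= 8L && !ties,
                  exact = TRUE,
                  approx = FALSE)
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  new_group_comparison("mann_whitney_u", res$statistic, res$p.value,
                       summaries = rbind(median_iqr(x, "x"),
                                         median_iqr(y, "y")))
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction; p from the chi-square distribution on
#' k - 1 degrees of freedom.  If every value is identical across all
#' groups, H is 0 and p is 1.
#'
#' @param groups List of two or more nonempty numeric samples.
#' @return A `"group_comparison"` with per-group summaries.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("kruskal_wallis requires >= 2 nonempty groups", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    summ <- do.call(rbind, lapply(seq_along(groups), function(i)
      median_iqr(groups[[i]], paste0("group", i))))
    return(new_group_comparison("kruskal_wallis", 0, 1, summaries = summ))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::kruskal.test(vals, g)
  summ <- do.call(rbind, lapply(seq_along(groups), function(i)
    median_iqr(groups[[i]], paste0("group", i))))
  new_group_comparison("kruskal_wallis", res$statistic, res$p.value,
                       summaries = summ)
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)`, order preserved; `m` defaults to the
#' number of p-values and must be at least that.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of comparisons in the family.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values))
    stop("m must be at least the number of p-values", call. = FALSE)
  pmin(1, p_values * m)
}

#' Association test for a two-way count table
#'
#' Chi-square without continuity correction by default; for a 2x2 table
#' with any expected cell below 5, Fisher's exact test (two-sided) is
#' used instead.  A table with a zero margin has no defined test and is
#' an error.
#'
#' @param table Matrix of nonnegative integer counts.
#' @return A `"group_comparison"`.
#' @export
categorical_association <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero margin; association test undefined",
         call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(dim(table) == c(2L, 2L)) && any(expected < 5)) {
    res <- stats::fisher.test(table)
    new_group_comparison("fisher_exact", res$estimate %||% NA_real_,
                         res$p.value)
  } else {
    res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    new_group_comparison("chi_square", res$statistic, res$p.value)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
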