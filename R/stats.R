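#' Grouped measurements for nonparametric comparison
#'
#' @param value numeric measurements.
#' @param group group labels (coerced to factor).
#' @param name measurement name.
#' @param units measurement units.
#' @return Object of class `grouped_measurements`.
#' @export
grouped_measurements <- function(value, group, name = "measurement",
                                 units = "") {
  if (length(value) != length(group)) stop("value and group differ in length")
  g <- factor(group)
  if (nlevels(g) < 1) stop("at least one group is required")
  structure(list(value = as.numeric(value), group = g,
                 name = name, units = units),
            class = "grouped_measurements")
}

#' @export
print.grouped_measurements <- function(x, ...) {
  cat(sprintf("<grouped_measurements> %s%s: %d values in %d groups\n",
              x$name, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              length(x$value), nlevels(x$group)))
  invisible(x)
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value
#' (via [stats::kruskal.test()]), followed by Dunn z statistics on the
#' pooled ranks for every group pair, with multiplicity-adjusted p-values
#' (Bonferroni by default).
#'
#' @param data a [grouped_measurements()] with at least three groups, each
#'   of size >= 2.
#' @param p_adjust `"bonferroni"`, `"holm"`, or `"sidak"`.
#' @return Object of class `test_result`: `method`, `statistic` (H), `df`,
#'   `p_value`, and `comparisons` (group1, group2, z, p_raw, p_adj).
#' @export
kruskal_wallis_dunn <- function(data, p_adjust = c("bonferroni", "holm",
                                                   "sidak")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(data, "grouped_measurements"))
  k <- nlevels(data$group)
  if (k < 3)
    stop("Kruskal-Wallis post hoc needs >= 3 groups; use mann_whitney() for two")
  ns <- table(data$group)
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (length(unique(data$value)) == 1L) {
    # every observation tied: no evidence of any difference
    kw <- list(statistic = 0, parameter = k - 1, p.value = 1)
  } else {
    kw <- stats::kruskal.test(data$value, data$group)
  }
  rk <- rank(data$value)
  N <- length(rk)
  rbar <- tapply(rk, data$group, mean)
  ties <- table(data$value)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(data$group), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(max(N * (N + 1) / 12 - tie_corr, 0) *
               (1 / ns[[a]] + 1 / ns[[b]]))
    z[i] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p_raw[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  m <- length(p_raw)
  p_adj <- switch(p_adjust,
                  bonferroni = pmin(p_raw * m, 1),
                  holm = stats::p.adjust(p_raw, "holm"),
                  sidak = 1 - (1 - p_raw)^m)
  structure(list(method = paste0("Kruskal-Wallis + Dunn (", p_adjust, ")"),
                 statistic = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p_value = kw$p.value,
                 comparisons = data.frame(group1 = pairs[1, ],
                                          group2 = pairs[2, ],
                                          z = z, p_raw = p_raw,
                                          p_adj = pmax(p_adj, p_raw))),
            class = "test_result")
}

#' Mann-Whitney (Wilcoxon rank-sum) test for two groups
#'
#' Two-sided test of two independent samples. The exact null distribution
#' is used when the smaller sample has at most `exact_max` observations and
#' there are no ties; otherwise the tie-corrected normal approximation
#' (with continuity correction) applies.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param exact_max largest min(n1, n2) for which the exact p is computed.
#' @return Object of class `test_result`: `method`, `statistic` (U of the
#'   first sample), `p_value`, `exact`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stop("both groups need n >= 1")
  if (length(unique(c(x, y))) == 1L)
    return(structure(list(method = "Mann-Whitney (all values tied)",
                          statistic = length(x) * length(y) / 2,
                          p_value = 1, exact = FALSE, comparisons = NULL),
                     class = "test_result"))
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  structure(list(method = if (use_exact) "Mann-Whitney (exact)"
                          else "Mann-Whitney (normal approximation)",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 exact = use_exact,
                 comparisons = NULL),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$comparisons)) {
    cat("  post hoc comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Per-group summary: median, quartiles, 5th/95th percentiles, n
#'
#' Percentiles use linear interpolation (R type 7).
#'
#' @param data a [grouped_measurements()].
#' @return Data frame (group, n, p05, q25, median, q75, p95).
#' @export
summarize_groups <- function(data) {
  stopifnot(inherits(data, "grouped_measurements"))
  do.call(rbind, lapply(levels(data$group), function(g) {
    v <- data$value[data$group == g]
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                         names = FALSE)
    data.frame(group = g, n = length(v), p05 = q[1], q25 = q[2],
               median = q[3], q75 = q[4], p95 = q[5])
  }))
}

#' Box-whisker plot in the medians / 25-75 / 5-95 convention
#'
#' Boxes span the quartiles with the median line; whiskers reach the 5th
#' and 95th percentiles; individual values outside the box are drawn as
#' dots.
#'
#' @param data a [grouped_measurements()].
#' @return A ggplot object.
#' @export
plot_group_boxes <- function(data) {
  stopifnot(inherits(data, "grouped_measurements"))
  s <- summarize_groups(data)
  raw <- data.frame(group = data$group, value = data$value)
  lim <- merge(raw, s[, c("group", "q25", "q75")], by = "group")
  outl <- lim[lim$value < lim$q25 | lim$value > lim$q75, ]
  ylab <- if (nzchar(data$units)) paste0(data$name, " (", data$units, ")")
          else data$name
  ggplot2::ggplot(s, ggplot2::aes(x = group)) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = p05, lower = q25,
                                       middle = median,
                                       upper = q75, ymax = p95),
                          stat = "identity", width = 0.5) +
    ggplot2::geom_jitter(data = outl,
                         ggplot2::aes(x = group, y = value),
                         width = 0.08, size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}
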