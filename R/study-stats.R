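#' Summarize sensation ratings
#'
#' Median and standard deviation per group (the convention used for
#' naturalness ratings: median values +/- SD), robust to the row order of
#' the input table.
#'
#' @param table data.frame of ratings.
#' @param value name of the value column (default "naturalness").
#' @param groupBy character vector of grouping columns.
#' @return data.frame with one row per group: \code{n}, \code{median},
#'   \code{sd}.
#' @export
summarizeRatings <- function(table, value = "naturalness",
                             groupBy = "encoding") {
  stopifnot(is.data.frame(table), value %in% names(table),
            all(groupBy %in% names(table)))
  groups <- interaction(table[groupBy], drop = TRUE, sep = ":")
  if (any(tabulate(groups) == 0L)) stop("empty group")
  idx <- split(seq_len(nrow(table)), groups)
  out <- do.call(rbind, lapply(names(idx), function(g) {
    v <- table[[value]][idx[[g]]]
    if (!length(v)) stop("empty group: ", g)
    data.frame(group = g, n = length(v), median = median(v),
               sd = if (length(v) > 1) sd(v) else 0)
  }))
  key <- do.call(rbind, strsplit(out$group, ":", fixed = TRUE))
  colnames(key) <- groupBy
  cbind(as.data.frame(key), out[c("n", "median", "sd")])
}

# Tie-corrected Kruskal-Wallis H computed from ranks (used for the effect
# size; the omnibus p-value comes from stats::kruskal.test).
kwStatistic <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  sums <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(sums^2 / ns) - 3 * (N + 1)
  ties <- table(values)
  cf <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (cf > 0) H / cf else NaN
}

#' Nonparametric comparison of two or more groups
#'
#' Kruskal-Wallis omnibus test (tie-corrected) with Dunn-style pairwise
#' post-hoc z-tests and a multiplicity correction (Bonferroni family by
#' default).  The effect size is Cohen's f derived from the rank
#' epsilon-squared, \code{eps2 = (H - k + 1) / (N - k)} and
#' \code{f = sqrt(eps2 / (1 - eps2))}.
#'
#' @param valuesByGroup named list of numeric vectors (>= 2 groups, each
#'   with >= 2 observations).
#' @param alpha significance level recorded on the pairwise table.
#' @param pAdjust multiplicity correction method for \code{p.adjust}.
#' @return a \linkS4class{GroupComparison}.
#' @export
compareGroups <- function(valuesByGroup, alpha = 0.05,
                          pAdjust = "bonferroni") {
  stopifnot(is.list(valuesByGroup), length(valuesByGroup) >= 2)
  ns <- lengths(valuesByGroup)
  if (any(ns < 2)) stop("every group needs at least two observations")
  if (is.null(names(valuesByGroup)))
    names(valuesByGroup) <- paste0("g", seq_along(valuesByGroup))
  values <- unlist(valuesByGroup, use.names = FALSE)
  groups <- factor(rep(names(valuesByGroup), ns),
                   levels = names(valuesByGroup))
  if (var(values) == 0)
    stop("degenerate data: all observations identical (ranks undefined)")
  k <- length(valuesByGroup)
  N <- length(values)

  kw <- kruskal.test(values, groups)
  H <- unname(kw$statistic)
  eps2 <- max((H - k + 1) / (N - k), 0)
  f <- sqrt(eps2 / max(1 - eps2, 1e-12))

  # Dunn pairwise z-tests on mean ranks with tie correction
  r <- rank(values)
  meanRanks <- tapply(r, groups, mean)
  ties <- table(values)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(valuesByGroup), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    sePair <- sqrt((N * (N + 1) / 12 - tieTerm) *
                     (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (meanRanks[[g1]] - meanRanks[[g2]]) / sePair
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * pnorm(-abs(z)))
  }))
  pw$pAdjusted <- pmin(p.adjust(pw$p, method = pAdjust), 1)
  pw$significant <- pw$pAdjusted < alpha

  gs <- do.call(rbind, lapply(names(valuesByGroup), function(g) {
    v <- valuesByGroup[[g]]
    data.frame(group = g, n = length(v), median = median(v),
               mean = mean(v), sd = sd(v))
  }))
  new("GroupComparison", statistic = H, df = unname(kw$parameter),
      pValue = kw$p.value, pairwise = pw, effectSizeF = f, groupSummary = gs)
}

#' Normality screen
#'
#' One-sample Kolmogorov-Smirnov test against the standard normal (on
#' z-scored data by default, since raw-scale measurements cannot plausibly
#' match N(0,1) directly), plus QQ-plot points against normal quantiles and
#' a histogram summary for visual inspection.  \code{reject} is 1 if the
#' test rejects normality at the 5% level and 0 otherwise.
#'
#' @param x numeric sample (n >= 5).
#' @param standardize z-score the data before testing (default TRUE).
#' @param alpha significance level, default 0.05.
#' @return list with \code{reject} (0/1), \code{statistic}, \code{pValue},
#'   \code{qq} (data.frame of theoretical and sample quantiles) and
#'   \code{histogram} (counts and breaks).
#' @export
normalityScreen <- function(x, standardize = TRUE, alpha = 0.05) {
  if (length(x) < 5) stop("need at least 5 observations")
  z <- if (standardize) (x - mean(x)) / sd(x) else x
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  qq <- qqnorm(z, plot.it = FALSE)
  br <- pretty(range(z), n = max(10, ceiling(sqrt(length(z)))))
  counts <- binCount(z, br)
  list(reject = as.integer(ks$p.value < alpha),
       statistic = unname(ks$statistic), pValue = ks$p.value,
       qq = data.frame(theoretical = qq$x, sample = qq$y),
       histogram = list(breaks = br, counts = counts))
}

#' Learning effect across sessions
#'
#' Spearman rank correlation between a performance metric and the session
#' index; values near zero indicate no session-to-session learning trend.
#'
#' @param metric numeric metric per session (>= 3 sessions).
#' @param session session indices; defaults to \code{seq_along(metric)}.
#' @return Spearman's rho, or NA (with a warning) for a constant metric.
#' @export
learningEffect <- function(metric, session = seq_along(metric)) {
  if (length(metric) < 3) stop("need at least three sessions")
  if (var(metric) == 0) {
    warning("constant metric: rank correlation undefined")
    return(NA_real_)
  }
  cor(metric, session, method = "spearman")
}
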