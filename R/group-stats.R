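# Rank-based two-group comparisons (Mann-Whitney / Wilcoxon rank-sum) with
# exact small-sample p-values, and Benjamini-Hochberg step-up adjustment.
# Used for Jaccard-core-index contrasts between age groups and for
# attenuation/buffering comparisons.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' `U` is the Mann-Whitney statistic for `x`. The exact null distribution is
#' used when both samples have at most 12 observations and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is used. The two-sided exact p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param group_a,group_b labels carried into the output.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact method;
#'   `NULL` (default) auto-selects. Forcing exact with ties is an error.
#' @return one-row data.frame of class `group_comparison`: `group_a`,
#'   `group_b`, `n_a`, `n_b`, `U`, `p`, `method`
#'   (`"exact"`/`"normal-approx"`).
#' @export
wilcoxon_rank_sum <- function(x, y, group_a = "a", group_b = "b",
                              exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stopf("NA values not allowed")
  n_a <- length(x); n_b <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  use_exact <- exact %||% (n_a <= 12 && n_b <= 12 && !ties)
  if (use_exact && ties) stopf("exact method is unavailable with ties")
  if (use_exact) {
    p_lo <- stats::pwilcox(U, n_a, n_b)
    p_hi <- 1 - stats::pwilcox(U - 1, n_a, n_b)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    n <- n_a + n_b
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      dev <- U - mu
      z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
      if (abs(dev) < 0.5) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approx"
  }
  cs_log("debug", sprintf("wilcoxon %s vs %s: %s method", group_a, group_b,
                          method))
  out <- data.frame(group_a = group_a, group_b = group_b,
                    n_a = n_a, n_b = n_b, U = U, p = p, method = method,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are `min over j >= i of m * p_(j) / j`, capped at 1 and
#' returned in the original order; monotone over the sorted p-values and
#' idempotent (re-adjusting never decreases a value).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
}

#' Pairwise group comparisons of a metric
#'
#' Wilcoxon rank-sum tests between all pairs of groups, optionally BH
#' adjusted across the family (off by default for the Jaccard-core-index
#' contrasts). The significance threshold convention is p <= 0.05.
#'
#' @param values numeric metric values.
#' @param groups group label per value.
#' @param metric metric name carried into the output.
#' @param adjust `"none"` (default) or `"bh"`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per group pair: the
#'   [wilcoxon_rank_sum()] columns plus `metric`, `p_adjusted`,
#'   `significant`.
#' @export
compare_groups <- function(values, groups, metric = "metric",
                           adjust = c("none", "bh"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  lev <- intersect(age_group_levels, unique(groups))
  if (length(lev) < 2) lev <- sort(unique(groups))
  if (length(lev) < 2) stopf("need at least two groups")
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    wilcoxon_rank_sum(values[groups == ga], values[groups == gb],
                      group_a = ga, group_b = gb)
  })
  out <- do.call(rbind, rows)
  out$metric <- metric
  out$p_adjusted <- if (adjust == "bh") bh_adjust(out$p) else out$p
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}
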