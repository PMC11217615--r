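#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two independent samples with average ranks for
#' ties. The p-value is exact (enumeration) for small samples without ties
#' (combined n <= 12 by default) and otherwise uses the normal approximation
#' with tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_limit Combined sample size up to which the exact p is used
#'   when there are no ties.
#' @return List with `statistic` (Mann-Whitney U for `x`), `p_value` and
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    # every observation tied: the rank-sum variance is zero and there is no
    # evidence against the null
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= exact_limit
  ht <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis rank test across several groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups), or a numeric
#'   vector together with `labels`.
#' @param labels Optional group labels when `groups` is a single vector.
#' @return List with `statistic` (H), `df` and `p_value`.
#' @export
kruskal_wallis <- function(groups, labels = NULL) {
  if (!is.null(labels)) {
    groups <- split(groups, labels)
  }
  if (!is.list(groups) || length(groups) < 2) {
    stopf("kruskal_wallis needs at least two groups")
  }
  if (any(!lengths(groups))) stopf("empty group")
  if (length(unique(unlist(groups))) == 1) {
    # degenerate all-tied case: no rank variation, H is identically zero
    return(list(statistic = 0, df = length(groups) - 1, p_value = 1))
  }
  ht <- kruskal.test(groups)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at one, returned
#' in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs are passed through).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
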