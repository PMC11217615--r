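#' Hill-number diversity of order q
#'
#' Effective number of taxa of a relative-abundance profile: q = 0 is
#' richness, q = 1 the exponential of Shannon entropy (limit definition, with
#' 0 log 0 = 0), q = 2 the inverse Simpson concentration. General q >= 0 uses
#' \eqn{(\sum_i p_i^q)^{1/(1-q)}} on the normalised nonzero entries.
#'
#' @param x Numeric vector of non-negative abundances, or a matrix with
#'   samples as rows.
#' @param q Diversity order (scalar, >= 0).
#' @return A number (or, for a matrix, a named vector: one value per row).
#' @export
#' @examples
#' hill_diversity(c(0.5, 0.25, 0.25), q = 2)  # 2.6667
hill_diversity <- function(x, q) {
  if (length(q) != 1 || q < 0) stopf("q must be a single value >= 0")
  if (is.matrix(x)) {
    return(vapply(seq_len(nrow(x)), function(i) hill_diversity(x[i, ], q),
                  numeric(1)) |> setNames(rownames(x)))
  }
  if (any(x < 0)) stopf("abundances must be non-negative")
  p <- x[x > 0]
  if (!length(p)) stopf("all-zero abundance row has no defined diversity")
  p <- p / sum(p)
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-10) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Jaccard dissimilarity matrix from incidence data
#'
#' Qualitative pairwise dissimilarity \eqn{d = (b + c) / (a + b + c)} with
#' `a` shared presences and `b`, `c` the presences unique to each sample.
#'
#' @param incidence 0/1 matrix, samples as rows; every row needs at least one
#'   presence.
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
jaccard_matrix <- function(incidence) {
  incidence <- as.matrix(incidence)
  if (!all(incidence %in% c(0, 1))) stopf("incidence must be a 0/1 matrix")
  if (any(rowSums(incidence) == 0)) {
    stopf("row(s) with zero presences: %s",
          paste(head(rownames(incidence)[rowSums(incidence) == 0], 3),
                collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(incidence, method = "jaccard", binary = TRUE))
  diag(d) <- 0
  d
}

#' Bray-Curtis dissimilarity matrix from abundance data
#'
#' Quantitative pairwise dissimilarity
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}.
#'
#' @param rra Non-negative matrix (e.g. per-sample RRA), samples as rows; no
#'   row may be all zero.
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis_matrix <- function(rra) {
  rra <- as.matrix(rra)
  if (any(rra < 0)) stopf("abundances must be non-negative")
  if (any(rowSums(rra) == 0)) {
    stopf("all-zero row(s) make Bray-Curtis undefined: %s",
          paste(head(rownames(rra)[rowSums(rra) == 0], 3), collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(rra, method = "bray"))
  diag(d) <- 0
  d
}
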