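#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical metric scaling: eigendecomposition of the double-centred matrix
#' of squared dissimilarities. Axes are ordered by decreasing eigenvalue;
#' negative eigenvalues are dropped both from the coordinates and from the
#' denominator of the proportion of variation explained (no Cailliez/Lingoes
#' correction).
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param n_axes Number of axes requested (>= 1). If fewer positive
#'   eigenvalues exist, all available axes are returned with a warning.
#' @return List with `coordinates` (samples x axes), `eigenvalues`
#'   (descending, all of them) and `proportion_explained` (per returned axis,
#'   relative to the positive-eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as_distance_matrix(d)
  if (n_axes < 1) stopf("n_axes must be >= 1")
  n <- nrow(d)
  k_req <- min(n_axes, n - 1)
  res <- suppressWarnings(cmdscale(stats::as.dist(d), k = k_req, eig = TRUE))
  eig <- sort(res$eig, decreasing = TRUE)
  tol <- 1e-8 * max(1, abs(eig[1]))
  n_pos <- sum(eig > tol)
  if (n_pos == 0) {
    warnf("no positive eigenvalues; returning zero coordinates")
    coords <- matrix(0, n, n_axes,
                     dimnames = list(rownames(d), paste0("Axis", seq_len(n_axes))))
    return(list(coordinates = coords, eigenvalues = eig,
                proportion_explained = rep(0, n_axes)))
  }
  if (n_axes > n_pos) {
    warnf("only %d positive eigenvalue(s); returning %d axis/axes", n_pos, n_pos)
  }
  k <- min(n_axes, n_pos)
  coords <- res$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  rownames(coords) <- rownames(d)
  prop <- eig[seq_len(k)] / sum(eig[eig > tol])
  list(coordinates = coords, eigenvalues = eig, proportion_explained = prop)
}

# All distinct permutations of a label multiset, one column per permutation.
multiset_permutations <- function(counts) {
  if (sum(counts) == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
  cols <- list()
  for (k in seq_along(counts)) {
    if (counts[k] == 0) next
    c2 <- counts
    c2[k] <- c2[k] - 1L
    sub <- multiset_permutations(c2)
    cols[[length(cols) + 1L]] <- rbind(rep(k, ncol(sub)), sub)
  }
  do.call(cbind, cols)
}

# Pseudo-F for each column of a label-index matrix L (values 1..k).
permanova_f_stats <- function(D2, L, sizes) {
  n <- nrow(D2)
  k <- length(sizes)
  SSt <- sum(D2) / (2 * n)
  SSw <- numeric(ncol(L))
  for (g in seq_len(k)) {
    G <- (L == g) * 1
    SSw <- SSw + colSums(G * (D2 %*% G)) / (2 * sizes[g])
  }
  SSb <- SSt - SSw
  f <- ifelse(SSw <= .Machine$double.eps * SSt,
              ifelse(SSb > 0, Inf, 0),
              (SSb / (k - 1)) / (SSw / (n - k)))
  list(f = f, SSt = SSt, SSw = SSw, SSb = SSb)
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Distance-based pseudo-F with a permutation null obtained by freely
#' shuffling group labels. When the number of distinct label arrangements is
#' at most `exact_limit` the null is enumerated exhaustively and the p-value
#' is the exact proportion of arrangements with F at least as large as
#' observed; otherwise `n_permutations` random shuffles are drawn and
#' \eqn{p = (\#\{F_{perm} \ge F_{obs}\} + 1) / (n_{perm} + 1)}.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param groups Vector of group labels, one per sample (>= 2 groups, each
#'   non-empty, n >= 3).
#' @param n_permutations Random permutations when not enumerating
#'   (default 999).
#' @param seed Seed for the random-permutation path.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` enumerates automatically when feasible.
#' @param exact_limit Enumeration cutoff on the number of distinct label
#'   arrangements (default 10000).
#' @return List with `pseudo_F`, `R2`, `p_value`, `n_permutations` (random
#'   draws or arrangements enumerated) and `method` (`"exact"` or
#'   `"sampled"`).
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL,
                      exact = NULL, exact_limit = 10000) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (length(groups) != n) stopf("groups length must match the matrix")
  g <- as.integer(factor(groups))
  sizes <- tabulate(g)
  k <- length(sizes)
  if (k < 2) stopf("PERMANOVA needs at least two groups")
  if (any(sizes == 0)) stopf("empty group")
  if (n < 3) stopf("PERMANOVA needs n >= 3")
  D2 <- d^2
  obs <- permanova_f_stats(D2, matrix(g, ncol = 1), sizes)
  F_obs <- obs$f
  R2 <- if (obs$SSt > 0) obs$SSb / obs$SSt else 0
  tol <- 1e-12 * max(1, abs(F_obs[is.finite(F_obs)]), na.rm = TRUE)

  n_distinct <- round(exp(lfactorial(n) - sum(lfactorial(sizes))))
  use_exact <- exact %||% (n_distinct <= exact_limit)
  if (use_exact) {
    L <- multiset_permutations(tabulate(g))
    # columns are label sequences over sorted positions; relabel to match g's
    # multiset (values already 1..k with the right multiplicities)
    f_perm <- permanova_f_stats(D2, L, sizes)$f
    p <- mean(f_perm >= F_obs - tol)
    n_used <- ncol(L)
    method <- "exact"
  } else {
    f_perm <- with_seed(seed, function() {
      L <- vapply(seq_len(n_permutations), function(i) sample(g), integer(n))
      permanova_f_stats(D2, L, sizes)$f
    })
    p <- (sum(f_perm >= F_obs - tol) + 1) / (n_permutations + 1)
    n_used <- n_permutations
    method <- "sampled"
  }
  list(pseudo_F = unname(F_obs), R2 = unname(R2), p_value = p,
       n_permutations = n_used, method = method)
}
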