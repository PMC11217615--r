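#' SIMPER: per-OTU contributions to between-group Bray-Curtis dissimilarity
#'
#' For every pair of samples from different groups, OTU i contributes
#' \eqn{|x_i - y_i| / \sum_j (x_j + y_j)} to the pair's Bray-Curtis
#' dissimilarity; contributions are averaged over all between-group pairs.
#' The summed mean contributions reconstruct the mean between-group
#' dissimilarity exactly.
#'
#' @param rra Samples x OTUs abundance matrix.
#' @param groups Vector with exactly two distinct group labels, one per
#'   sample.
#' @return Data frame sorted by decreasing contribution with columns `otu_id`,
#'   `average` (mean contribution), `share` (fraction of the total) and
#'   `cumulative` (cumulative share); attribute `overall` holds the mean
#'   between-group dissimilarity.
#' @export
simper_contrast <- function(rra, groups) {
  rra <- as.matrix(rra)
  if (is.null(colnames(rra))) {
    colnames(rra) <- sprintf("otu%03d", seq_len(ncol(rra)))
  }
  g <- factor(groups)
  if (nlevels(g) != 2) stopf("SIMPER contrasts exactly two groups")
  ia <- which(g == levels(g)[1])
  ib <- which(g == levels(g)[2])
  if (!length(ia) || !length(ib)) stopf("a group has zero samples")
  contrib <- numeric(ncol(rra))
  n_pairs <- 0L
  for (i in ia) {
    for (j in ib) {
      tot <- sum(rra[i, ] + rra[j, ])
      if (tot == 0) stopf("sample pair with all-zero abundances")
      contrib <- contrib + abs(rra[i, ] - rra[j, ]) / tot
      n_pairs <- n_pairs + 1L
    }
  }
  contrib <- contrib / n_pairs
  overall <- sum(contrib)
  ord <- order(contrib, decreasing = TRUE)
  share <- if (overall > 0) contrib / overall else rep(0, length(contrib))
  out <- data.frame(otu_id = colnames(rra)[ord],
                    average = contrib[ord],
                    share = share[ord],
                    cumulative = cumsum(share[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "overall") <- overall
  rownames(out) <- NULL
  out
}

#' Habitat specificity of each OTU
#'
#' Specificity of OTU S in habitat H is the mean abundance of S over all
#' samples of H (zeros included) divided by the sum of its mean abundances
#' over all habitats. Rows sum to one for any OTU observed at least once;
#' OTUs absent everywhere get `NA` (undefined, never 0/0).
#'
#' @param rra Samples x OTUs abundance matrix.
#' @param habitats Habitat label per sample (>= 1 sample per habitat).
#' @return Matrix OTUs x habitats of specificities.
#' @export
specificity <- function(rra, habitats) {
  rra <- as.matrix(rra)
  h <- factor(habitats)
  if (length(h) != nrow(rra)) stopf("habitat labels must match samples")
  means <- vapply(levels(h), function(lv)
    colMeans(rra[h == lv, , drop = FALSE]), numeric(ncol(rra)))
  if (is.null(dim(means))) means <- matrix(means, ncol = nlevels(h))
  tot <- rowSums(means)
  spec <- means / tot
  spec[tot == 0, ] <- NA_real_
  dimnames(spec) <- list(colnames(rra), levels(h))
  spec
}

#' Habitat occupancy of each OTU
#'
#' Occupancy of OTU S in habitat H is the number of samples of H where S was
#' detected divided by the number of samples of H.
#'
#' @param incidence Samples x OTUs 0/1 matrix.
#' @param habitats Habitat label per sample.
#' @return Matrix OTUs x habitats of occupancies in `[0, 1]`.
#' @export
occupancy <- function(incidence, habitats) {
  incidence <- as.matrix(incidence)
  h <- factor(habitats)
  if (length(h) != nrow(incidence)) stopf("habitat labels must match samples")
  occ <- vapply(levels(h), function(lv)
    colMeans(incidence[h == lv, , drop = FALSE] > 0), numeric(ncol(incidence)))
  if (is.null(dim(occ))) occ <- matrix(occ, ncol = nlevels(h))
  dimnames(occ) <- list(colnames(incidence), levels(h))
  occ
}

#' Flag habitat specialists by the specificity-occupancy rule
#'
#' An OTU is a specialist of habitat H when both its specificity and its
#' occupancy in H reach the thresholds (inclusive; default 0.7 / 0.7).
#'
#' @param spec Specificity matrix from [specificity()].
#' @param occ Occupancy matrix from [occupancy()] on the same (OTU, habitat)
#'   grid.
#' @param theta_s,theta_o Thresholds in `[0, 1]`.
#' @return Tidy data frame with columns `otu_id`, `habitat`, `specificity`,
#'   `occupancy`, `is_specialist`.
#' @export
specialists <- function(spec, occ, theta_s = 0.7, theta_o = 0.7) {
  if (theta_s < 0 || theta_s > 1 || theta_o < 0 || theta_o > 1) {
    stopf("thresholds must lie in [0, 1]")
  }
  if (!identical(dim(spec), dim(occ))) {
    stopf("specificity and occupancy grids differ")
  }
  out <- data.frame(
    otu_id = rep(rownames(spec), times = ncol(spec)),
    habitat = rep(colnames(spec), each = nrow(spec)),
    specificity = as.vector(spec),
    occupancy = as.vector(occ),
    stringsAsFactors = FALSE)
  out$is_specialist <- !is.na(out$specificity) &
    out$specificity >= theta_s & out$occupancy >= theta_o
  out
}
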