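# Independent brute-force oracles, deliberately written with plain loops and
# no calls into the package's computational paths.

# Cohesion exactly as defined: per-OTU signed mean correlations times
# relative abundance, summed per sample.
brute_force_cohesion <- function(rra, r) {
  n_otu <- ncol(rra)
  conn_pos <- numeric(n_otu)
  conn_neg <- numeric(n_otu)
  for (i in seq_len(n_otu)) {
    pos <- c()
    neg <- c()
    for (j in seq_len(n_otu)) {
      if (i == j || is.na(r[i, j])) next
      if (r[i, j] > 0) pos <- c(pos, r[i, j])
      if (r[i, j] < 0) neg <- c(neg, r[i, j])
    }
    conn_pos[i] <- if (length(pos)) sum(pos) / length(pos) else 0
    conn_neg[i] <- if (length(neg)) sum(neg) / length(neg) else 0
  }
  coh_pos <- numeric(nrow(rra))
  coh_neg <- numeric(nrow(rra))
  for (s in seq_len(nrow(rra))) {
    for (i in seq_len(n_otu)) {
      coh_pos[s] <- coh_pos[s] + rra[s, i] * conn_pos[i]
      coh_neg[s] <- coh_neg[s] + rra[s, i] * conn_neg[i]
    }
  }
  list(pos = coh_pos, neg = coh_neg)
}

# Exhaustive two-group PERMANOVA by direct enumeration of all assignments of
# the smaller group's positions.
brute_force_permanova_2g <- function(d, groups) {
  g <- as.integer(factor(groups))
  n <- nrow(d)
  n1 <- sum(g == 1)
  f_for <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    sst <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) sst <- sst + d[i, j]^2
    }
    sst <- sst / n
    ssw <- 0
    for (set in list(idx1, idx2)) {
      if (length(set) > 1) {
        for (a in seq_len(length(set) - 1)) {
          for (b in (a + 1):length(set)) {
            ssw <- ssw + d[set[a], set[b]]^2 / length(set)
          }
        }
      }
    }
    ssb <- sst - ssw
    if (ssw == 0) return(if (ssb > 0) Inf else 0)
    (ssb / 1) / (ssw / (n - 2))
  }
  f_obs <- f_for(which(g == 1))
  splits <- utils::combn(n, n1)
  f_all <- apply(splits, 2, f_for)
  tol <- 1e-12 * max(1, abs(f_obs[is.finite(f_obs)]))
  list(f = f_obs, p = mean(f_all >= f_obs - tol))
}

random_rra <- function(n_samples, n_otus, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_samples * n_otus), n_samples, n_otus,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("otu%02d", seq_len(n_otus))))
  m / rowSums(m)
}

# Small pcr_counts fixture: one marker, explicit counts, optional NC rows.
toy_pcr_counts <- function(counts, n_nc = 0, nc_counts = NULL,
                           marker = "diatom", n_rep = 1) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  n_samples <- n / n_rep
  meta <- data.frame(
    sample_id = rep(sprintf("L1-C%02d-D1", seq_len(n_samples)), each = n_rep),
    lake = rep_len("L1", n), habitat = rep_len("water", n),
    replicate = rep(seq_len(n_rep), length.out = n),
    marker = rep_len(marker, n), is_negative_control = rep_len(FALSE, n),
    stringsAsFactors = FALSE)
  if (n_nc > 0) {
    if (is.null(nc_counts)) {
      nc_counts <- matrix(0, n_nc, ncol(counts))
    }
    counts <- rbind(counts, as.matrix(nc_counts))
    meta <- rbind(meta, data.frame(
      sample_id = sprintf("L1-NC%02d", seq_len(n_nc)),
      lake = "L1", habitat = NA, replicate = seq_len(n_nc),
      marker = marker, is_negative_control = TRUE,
      stringsAsFactors = FALSE))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("%s_%03d", marker, seq_len(ncol(counts)))
  }
  rownames(counts) <- paste(meta$sample_id, meta$marker, meta$replicate,
                            sep = ".")
  pcr_counts(counts, meta)
}

# Build a spearman_matrix-shaped correlation object by hand.
manual_corr <- function(r, p_adj) {
  ids <- colnames(r) %||% sprintf("otu%02d", seq_len(ncol(r)))
  dimnames(r) <- list(ids, ids)
  dimnames(p_adj) <- list(ids, ids)
  list(r = r, p = p_adj, p_adj = p_adj, otu_ids = ids, n_samples = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One shared default-pipeline run for the pipeline and smoke tests.
default_run_cache <- new.env(parent = emptyenv())
get_default_run <- function(seed = 42) {
  key <- paste0("run", seed)
  if (is.null(default_run_cache[[key]])) {
    default_run_cache[[key]] <- run_pipeline(default_run_config(seed = seed))
  }
  default_run_cache[[key]]
}
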