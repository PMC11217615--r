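#' Per-sample community cohesion
#'
#' Each OTU's positive (negative) connectedness is the mean of its positive
#' (negative) correlations with the other OTUs of the correlation matrix,
#' zero when it has none. A sample's positive (negative) cohesion is the sum
#' over OTUs of relative abundance times connectedness, and the
#' negative:positive cohesion ratio is `|cohesion-| / cohesion+` (undefined,
#' reported `NA`, when positive cohesion is zero).
#'
#' By default connectedness averages over the full prefiltered correlation
#' matrix, not only over correlations surviving the network edge filter; set
#' `edges_only` together with a [build_network()] result to restrict it.
#'
#' @param rra Samples x OTUs abundance matrix over the same OTU set (and, by
#'   convention, the same samples) used to fit `corr`.
#' @param corr Output of [spearman_matrix()] on those OTUs.
#' @param edges_only Optional `co_network`; when given, correlations of
#'   non-edges are ignored in the connectedness averages.
#' @return List with `connectedness` (data frame: `otu_id`, `positive`,
#'   `negative`) and `samples` (data frame: `sample_id`, `cohesion_pos`,
#'   `cohesion_neg`, `abs_cohesion_neg`, `neg_pos_ratio`).
#' @export
cohesion <- function(rra, corr, edges_only = NULL) {
  rra <- as.matrix(rra)
  r <- corr$r
  ids <- corr$otu_ids
  if (!all(ids %in% colnames(rra))) {
    stopf("rra lacks OTUs of the correlation matrix")
  }
  rra <- rra[, ids, drop = FALSE]
  diag(r) <- NA_real_
  if (!is.null(edges_only)) {
    stopifnot(inherits(edges_only, "co_network"))
    keep <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(edges_only$edges)) {
      e <- edges_only$edges
      keep[cbind(e$from, e$to)] <- TRUE
      keep[cbind(e$to, e$from)] <- TRUE
    }
    r[!keep] <- NA_real_
  }
  conn_pos <- apply(r, 1, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else 0
  })
  conn_neg <- apply(r, 1, function(v) {
    v <- v[!is.na(v) & v < 0]
    if (length(v)) mean(v) else 0
  })
  coh_pos <- as.vector(rra %*% conn_pos)
  coh_neg <- as.vector(rra %*% conn_neg)
  ratio <- ifelse(coh_pos > 0, abs(coh_neg) / coh_pos, NA_real_)
  list(
    connectedness = data.frame(otu_id = ids, positive = unname(conn_pos),
                               negative = unname(conn_neg),
                               stringsAsFactors = FALSE),
    samples = data.frame(sample_id = rownames(rra),
                         cohesion_pos = coh_pos, cohesion_neg = coh_neg,
                         abs_cohesion_neg = abs(coh_neg),
                         neg_pos_ratio = ratio, stringsAsFactors = FALSE))
}

#' Compare cohesion distributions across network contexts
#'
#' Kruskal-Wallis test across contexts followed by pairwise Wilcoxon rank-sum
#' tests with Benjamini-Hochberg correction, for positive cohesion, negative
#' cohesion and the negative:positive ratio. Contexts with fewer than two
#' samples are excluded with a warning.
#'
#' @param cohesion_by_context Named list of per-sample cohesion data frames
#'   (the `samples` element of [cohesion()]).
#' @return List with `kruskal` (one row per metric) and `pairwise` (one row
#'   per metric and context pair, BH-adjusted within metric).
#' @export
compare_networks <- function(cohesion_by_context) {
  if (length(cohesion_by_context) < 2) stopf("need >= 2 contexts")
  sizes <- vapply(cohesion_by_context, nrow, integer(1))
  if (any(sizes < 2)) {
    warnf("excluding context(s) with < 2 samples: %s",
          paste(names(cohesion_by_context)[sizes < 2], collapse = ", "))
    cohesion_by_context <- cohesion_by_context[sizes >= 2]
    if (length(cohesion_by_context) < 2) stopf("fewer than 2 usable contexts")
  }
  metrics <- c("cohesion_pos", "cohesion_neg", "neg_pos_ratio")
  ctx <- names(cohesion_by_context)
  kw <- list()
  pw <- list()
  for (met in metrics) {
    vals <- lapply(cohesion_by_context, function(df) {
      v <- df[[met]]
      v[!is.na(v)]
    })
    res <- kruskal_wallis(vals)
    kw[[length(kw) + 1L]] <- data.frame(metric = met, H = res$statistic,
                                        df = res$df, p_value = res$p_value,
                                        stringsAsFactors = FALSE)
    pairs <- combn(ctx, 2)
    praw <- apply(pairs, 2, function(pr)
      wilcoxon_rank_sum(vals[[pr[1]]], vals[[pr[2]]])$p_value)
    pw[[length(pw) + 1L]] <- data.frame(
      metric = met, context_a = pairs[1, ], context_b = pairs[2, ],
      p_value = praw, p_adj = bh_adjust(praw), stringsAsFactors = FALSE)
  }
  list(kruskal = do.call(rbind, kw), pairwise = do.call(rbind, pw))
}
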