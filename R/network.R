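#' Prefilter OTUs for network inference
#'
#' Keeps OTUs whose mean RRA over all input samples is at least
#' `min_mean_rra` (default 0.01%) and whose detection fraction is at least
#' `min_prevalence` (default 30%); both boundaries inclusive, both computed on
#' the full input sample set.
#'
#' @param rra Samples x OTUs abundance matrix for one network context.
#' @param min_mean_rra Minimum mean relative read abundance (default `1e-4`).
#' @param min_prevalence Minimum detection fraction (default `0.30`).
#' @return List with the reduced `rra` and the `kept` OTU ids.
#' @export
prefilter_otus <- function(rra, min_mean_rra = 1e-4, min_prevalence = 0.30) {
  rra <- as.matrix(rra)
  keep <- colMeans(rra) >= min_mean_rra &
    colMeans(rra > 0) >= min_prevalence
  list(rra = rra[, keep, drop = FALSE], kept = colnames(rra)[keep])
}

#' Pairwise Spearman correlations with BH-adjusted p-values
#'
#' Average-rank Spearman coefficient for every OTU pair, p-values from the
#' t-distribution approximation on n - 2 degrees of freedom, and
#' Benjamini-Hochberg adjustment over all unique off-diagonal pairs jointly.
#' Zero-variance OTUs yield `NA` correlations, which never pass the edge
#' filter.
#'
#' @param rra Samples x OTUs matrix (>= 4 samples, >= 2 OTUs).
#' @return List of symmetric matrices `r`, `p`, `p_adj` plus `otu_ids` and
#'   `n_samples`.
#' @export
spearman_matrix <- function(rra) {
  rra <- as.matrix(rra)
  n <- nrow(rra)
  if (n < 4) stopf("need at least 4 samples for correlation inference")
  if (ncol(rra) < 2) stopf("need at least 2 OTUs")
  constant <- apply(rra, 2, function(v) length(unique(v)) == 1)
  r <- suppressWarnings(cor(rra, method = "spearman"))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- NA_real_
  up <- upper.tri(p)
  p_adj <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  p_adj[up] <- bh_adjust(p[up])
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(r = r, p = p, p_adj = p_adj, otu_ids = colnames(rra), n_samples = n)
}

#' Threshold a correlation matrix into a signed co-occurrence network
#'
#' An edge joins OTUs i and j when `|r| >= r_threshold` (inclusive) and
#' `p_adj < alpha` (strict). OTUs left without any edge are dropped from the
#' node set.
#'
#' @param corr Output of [spearman_matrix()].
#' @param r_threshold Minimum absolute Spearman coefficient (default 0.75).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param node_data Optional data frame of node annotations (e.g. taxonomic
#'   group, mean RRA) with an `otu_id` column.
#' @return A `co_network`: list with the `igraph` `graph` (edge attributes
#'   `weight` = r, `sign`), `edges` data frame and `nodes`.
#' @export
build_network <- function(corr, r_threshold = 0.75, alpha = 0.05,
                          node_data = NULL) {
  r <- corr$r
  p_adj <- corr$p_adj
  sel <- which(upper.tri(r) & !is.na(r) & !is.na(p_adj) &
                 abs(r) >= r_threshold & p_adj < alpha, arr.ind = TRUE)
  edges <- data.frame(
    from = corr$otu_ids[sel[, 1]],
    to = corr$otu_ids[sel[, 2]],
    r = r[sel],
    p_adj = p_adj[sel],
    stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = if (length(nodes)) nodes else NULL)
  if (nrow(edges)) {
    igraph::E(g)$weight <- edges$r
    igraph::E(g)$sign <- edges$sign
  }
  if (!is.null(node_data) && length(nodes)) {
    idx <- match(nodes, node_data$otu_id)
    for (col in setdiff(names(node_data), "otu_id")) {
      g <- igraph::set_vertex_attr(g, col, value = node_data[[col]][idx])
    }
  }
  structure(list(graph = g, edges = edges, nodes = nodes), class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Louvain module detection on the unsigned network
#'
#' Greedy modularity maximisation on `|r|` edge weights; deterministic given
#' the seed. An edgeless network puts every node in its own module with
#' Q = 0.
#'
#' @param net A [build_network()] object.
#' @param seed Integer seed.
#' @param resolution Louvain resolution parameter (default 1).
#' @return List with `membership` (named integer vector) and `modularity`
#'   (Newman's Q of the returned partition at resolution 1, on `|r|` weights).
#' @export
detect_modules <- function(net, seed = 1, resolution = 1) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0) {
    memb <- seq_along(net$nodes)
    names(memb) <- net$nodes
    return(list(membership = memb, modularity = 0))
  }
  w <- abs(igraph::E(g)$weight)
  cl <- with_seed(seed, function()
    igraph::cluster_louvain(g, weights = w, resolution = resolution))
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb, weights = w)
  list(membership = setNames(as.integer(memb), names(memb)), modularity = q)
}

#' Topological metrics of a co-occurrence network
#'
#' Node counts, signed edge counts, mean (unweighted) degree, mean weighted
#' degree (sum of `|r|` per node), linkage density (edges per node), average
#' path length over connected pairs (with the number of disconnected pairs
#' reported), global clustering coefficient, and modularity of the supplied
#' partition.
#'
#' @param net A [build_network()] object.
#' @param partition Optional result of [detect_modules()].
#' @return List of metrics; all zero for an edgeless network.
#' @export
network_metrics <- function(net, partition = NULL) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  n <- length(net$nodes)
  m <- nrow(net$edges)
  if (n == 0 || m == 0) {
    return(list(n_nodes = n, n_edges = 0, n_positive = 0, n_negative = 0,
                mean_degree = 0, mean_weighted_degree = 0, linkage_density = 0,
                average_path_length = 0, n_disconnected_pairs = 0,
                clustering_coefficient = 0, modularity = 0))
  }
  w <- abs(igraph::E(g)$weight)
  deg <- igraph::degree(g)
  sp <- igraph::distances(g, weights = NA)
  off <- sp[upper.tri(sp)]
  reachable <- is.finite(off)
  apl <- if (any(reachable)) mean(off[reachable]) else 0
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc)) cc <- 0
  q <- if (!is.null(partition)) {
    igraph::modularity(g, partition$membership[names(igraph::V(g))], weights = w)
  } else NA_real_
  list(n_nodes = n, n_edges = m,
       n_positive = sum(net$edges$sign == "positive"),
       n_negative = sum(net$edges$sign == "negative"),
       mean_degree = mean(deg),
       mean_weighted_degree = mean(igraph::strength(g, weights = w)),
       linkage_density = m / n,
       average_path_length = apl,
       n_disconnected_pairs = sum(!reachable),
       clustering_coefficient = cc,
       modularity = q)
}

#' Zi-Pi keystone roles of network nodes
#'
#' Within-module degree z-score
#' \eqn{Z_i = (k_{i,within} - \bar{k}_{module}) / sd_{module}} (unweighted
#' degree; Z = 0 when the module sd is zero or the module is a singleton) and
#' among-module participation \eqn{P_i = 1 - \sum_m (k_{i,m} / k_i)^2}. Roles
#' follow the four-quadrant thresholds: network hubs (Z > 2.5, P > 0.62),
#' module hubs (Z > 2.5, P <= 0.62), connectors (Z <= 2.5, P > 0.62),
#' peripherals (Z <= 2.5, P <= 0.62).
#'
#' @param net A [build_network()] object.
#' @param partition Result of [detect_modules()] covering the node set.
#' @return Data frame with `otu_id`, `module`, `degree`, `Zi`, `Pi`, `role`.
#' @export
zi_pi <- function(net, partition) {
  stopifnot(inherits(net, "co_network"))
  memb <- partition$membership
  if (!all(net$nodes %in% names(memb))) {
    stopf("partition does not cover the node set")
  }
  memb <- memb[net$nodes]
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  adj <- adj[net$nodes, net$nodes, drop = FALSE]
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  k_by_mod <- vapply(mods, function(mm)
    rowSums(adj[, memb == mm, drop = FALSE]), numeric(length(k)))
  if (is.null(dim(k_by_mod))) k_by_mod <- matrix(k_by_mod, nrow = length(k))
  k_within <- k_by_mod[cbind(seq_along(k), match(memb, mods))]
  zi <- numeric(length(k))
  for (mm in mods) {
    idx <- which(memb == mm)
    mu <- mean(k_within[idx])
    s <- if (length(idx) > 1) sd(k_within[idx]) else 0
    zi[idx] <- if (is.na(s) || s == 0) 0 else (k_within[idx] - mu) / s
  }
  pi <- 1 - rowSums((k_by_mod / k)^2)
  role <- ifelse(zi > 2.5,
                 ifelse(pi > 0.62, "network hub", "module hub"),
                 ifelse(pi > 0.62, "connector", "peripheral"))
  data.frame(otu_id = net$nodes, module = unname(memb), degree = unname(k),
             Zi = zi, Pi = pi, role = role, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Export a network as GraphML and an edge-list TSV
#'
#' @param net A [build_network()] object.
#' @param path_graphml,path_edges Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, path_graphml = NULL, path_edges = NULL) {
  stopifnot(inherits(net, "co_network"))
  if (!is.null(path_graphml)) {
    igraph::write_graph(net$graph, path_graphml, format = "graphml")
  }
  if (!is.null(path_edges)) {
    utils::write.table(net$edges, path_edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(path_graphml, path_edges))
}
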