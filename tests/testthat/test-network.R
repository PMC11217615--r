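test_that("the network prefilter applies both inclusive thresholds", {
  rra <- matrix(0, 10, 3, dimnames = list(NULL, c("rare", "patchy", "good")))
  rra[, "rare"] <- 5e-5                 # mean below 0.01%
  rra[1:3, "patchy"] <- c(0.5, 0.5, 0.5)  # prevalence exactly 0.30
  rra[, "good"] <- 0.01
  out <- prefilter_otus(rra)
  expect_false("rare" %in% out$kept)
  expect_true("patchy" %in% out$kept)
  expect_true("good" %in% out$kept)

  boundary <- matrix(1e-4, 5, 1, dimnames = list(NULL, "edge"))
  expect_equal(prefilter_otus(boundary)$kept, "edge")
})

test_that("Spearman matrix matches the rank-difference formula", {
  x <- 1:5
  y <- c(1, 3, 2, 5, 4)
  m <- cbind(a = x, b = y, c = 6 - x)
  corr <- spearman_matrix(m)
  expect_equal(corr$r["a", "b"], 0.8, tolerance = 1e-12)  # 1 - 6*4/120
  expect_equal(corr$r["a", "a"], 1)
  expect_equal(corr$r["a", "c"], -1)
  expect_equal(corr$p["a", "c"], 0)
  expect_equal(corr$r, t(corr$r))
})

test_that("zero-variance OTUs give missing correlations that never form edges", {
  m <- cbind(a = c(1, 2, 3, 4, 5), flat = rep(2, 5), b = c(2, 1, 4, 3, 5))
  corr <- spearman_matrix(m)
  expect_true(is.na(corr$r["flat", "a"]))
  net <- build_network(corr, r_threshold = 0, alpha = 1)
  expect_false("flat" %in% net$nodes)
  expect_error(spearman_matrix(m[1:3, ]), "4 samples")
})

test_that("p adjustment is joint over all unique pairs", {
  m <- random_rra(10, 5, seed = 4)
  corr <- spearman_matrix(m)
  up <- upper.tri(corr$p)
  expect_equal(corr$p_adj[up], p.adjust(corr$p[up], "BH"))
  expect_equal(corr$p_adj, t(corr$p_adj))
})

test_that("edge thresholds are inclusive on |r| and strict on adjusted p", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.75
  r[1, 3] <- r[3, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- -0.8
  p <- matrix(0.01, 3, 3)
  p[1, 3] <- p[3, 1] <- 0.05   # not < 0.05 -> no edge
  p[2, 3] <- p[3, 2] <- 0.049
  corr <- manual_corr(r, p)
  net <- build_network(corr)
  key <- paste(net$edges$from, net$edges$to)
  expect_true(paste("otu01", "otu02") %in% key)   # r = 0.75 boundary kept
  expect_false(paste("otu01", "otu03") %in% key)  # p_adj = alpha excluded
  expect_true(paste("otu02", "otu03") %in% key)
  expect_equal(sort(unique(net$edges$sign)), c("negative", "positive"))

  none <- build_network(manual_corr(diag(2), matrix(1, 2, 2)))
  expect_equal(length(none$nodes), 0)
  expect_equal(nrow(none$edges), 0)
})

triangle_corr <- function() {
  # two disconnected triangles, all |r| = 0.8, all significant
  r <- diag(6)
  for (tri in list(1:3, 4:6)) {
    for (i in tri) for (j in tri) if (i != j) r[i, j] <- 0.8
  }
  p <- matrix(ifelse(r != 0 & r != 1, 1e-4, 1), 6, 6)
  p[r == 0] <- 0.9
  colnames(r) <- rownames(r) <- paste0("n", 1:6)
  manual_corr(r, p)
}

test_that("Louvain recovers two disconnected triangles with Q = 0.5", {
  net <- build_network(triangle_corr())
  expect_equal(nrow(net$edges), 6)
  part <- detect_modules(net, seed = 3)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  expect_equal(unname(part$membership["n1"]), unname(part$membership["n2"]))
  expect_false(part$membership["n1"] == part$membership["n4"])
  # determinism under a fixed seed
  expect_identical(part$membership, detect_modules(net, seed = 3)$membership)
  # the trivial one-module partition scores Q = 0 by Newman's formula
  g <- net$graph
  expect_equal(igraph::modularity(g, rep(1, 6),
                                  weights = abs(igraph::E(g)$weight)), 0)
  expect_gte(part$modularity, 0)
})

test_that("module detection handles edgeless networks", {
  net <- build_network(manual_corr(diag(2), matrix(1, 2, 2)))
  part <- detect_modules(net, seed = 1)
  expect_equal(part$modularity, 0)
  expect_length(part$membership, 0)
})

test_that("topology metrics are exact on canonical graphs", {
  # triangle
  r <- matrix(0.9, 3, 3); diag(r) <- 1
  p <- matrix(1e-5, 3, 3)
  net <- build_network(manual_corr(r, p))
  met <- network_metrics(net)
  expect_equal(met$n_nodes, 3)
  expect_equal(met$n_edges, 3)
  expect_equal(met$clustering_coefficient, 1)
  expect_equal(met$linkage_density, 1)
  expect_equal(met$mean_degree, 2)
  expect_equal(met$mean_weighted_degree, 1.8, tolerance = 1e-12)
  expect_equal(met$average_path_length, 1)

  # 3-node path: 1-2, 2-3
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.8
  r2[2, 3] <- r2[3, 2] <- 0.8
  p2 <- matrix(1e-5, 3, 3)
  path_net <- build_network(manual_corr(r2, p2))
  met2 <- network_metrics(path_net)
  expect_equal(met2$average_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(met2$n_disconnected_pairs, 0)

  # two triangles: 9 unreachable pairs across components
  two_tri <- network_metrics(build_network(triangle_corr()))
  expect_equal(two_tri$n_disconnected_pairs, 9)
  expect_equal(two_tri$average_path_length, 1)

  empty <- network_metrics(build_network(manual_corr(diag(2), matrix(1, 2, 2))))
  expect_true(all(unlist(empty) == 0))
})

test_that("networks have symmetric edges and no self-loops", {
  set.seed(60)
  for (rep in 1:5) {
    m <- random_rra(12, 8, seed = 60 + rep)
    corr <- spearman_matrix(m)
    net <- build_network(corr, r_threshold = 0.3, alpha = 1)
    expect_false(any(net$edges$from == net$edges$to))
    expect_false(igraph::any_multiple(net$graph))
    adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
    expect_equal(adj, t(adj))
    part <- detect_modules(net, seed = rep)
    expect_gte(part$modularity, -0.5)
    expect_lte(part$modularity, 1)
  }
})

test_that("Zi-Pi follows the four-quadrant definition", {
  # two triangles bridged by a connector node c linked to both
  edges <- rbind(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                 c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
                 c("c", "a1"), c("c", "b1"))
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3", "c")
  r <- diag(length(ids)); dimnames(r) <- list(ids, ids)
  p <- matrix(1, length(ids), length(ids), dimnames = dimnames(r))
  for (k in seq_len(nrow(edges))) {
    r[edges[k, 1], edges[k, 2]] <- r[edges[k, 2], edges[k, 1]] <- 0.8
    p[edges[k, 1], edges[k, 2]] <- p[edges[k, 2], edges[k, 1]] <- 1e-5
  }
  net <- build_network(manual_corr(r, p))
  memb <- c(a1 = 1, a2 = 1, a3 = 1, b1 = 2, b2 = 2, b3 = 2, c = 3)
  roles <- zi_pi(net, list(membership = memb))
  rl <- setNames(roles$role, roles$otu_id)
  pi <- setNames(roles$Pi, roles$otu_id)
  zi <- setNames(roles$Zi, roles$otu_id)

  # c has no within-module links (singleton module): Zi = 0; Pi = 1 - 2*(1/2)^2
  expect_equal(unname(pi["c"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(zi["c"]), 0)
  expect_equal(unname(rl["c"]), "peripheral")
  # a2 keeps all links inside its module: Pi = 0
  expect_equal(unname(pi["a2"]), 0)
  expect_equal(unname(rl["a2"]), "peripheral")
  # a1: 3 links, 2 within + 1 to c's module: Pi = 1 - (4/9 + 1/9)
  expect_equal(unname(pi["a1"]), 1 - 5 / 9, tolerance = 1e-12)
})

test_that("a node bridging three modules is a connector", {
  # three triangles, plus c linked to one node of each
  tri <- function(p) paste0(p, 1:3)
  edges <- do.call(rbind, lapply(c("a", "b", "d"), function(p)
    rbind(c(tri(p)[1], tri(p)[2]), c(tri(p)[1], tri(p)[3]),
          c(tri(p)[2], tri(p)[3]))))
  edges <- rbind(edges, c("c", "a1"), c("c", "b1"), c("c", "d1"))
  ids <- c(tri("a"), tri("b"), tri("d"), "c")
  r <- diag(length(ids)); dimnames(r) <- list(ids, ids)
  p <- matrix(1, length(ids), length(ids), dimnames = dimnames(r))
  for (k in seq_len(nrow(edges))) {
    r[edges[k, 1], edges[k, 2]] <- r[edges[k, 2], edges[k, 1]] <- 0.9
    p[edges[k, 1], edges[k, 2]] <- p[edges[k, 2], edges[k, 1]] <- 1e-5
  }
  net <- build_network(manual_corr(r, p))
  memb <- setNames(c(rep(1, 3), rep(2, 3), rep(3, 3), 4), ids)
  roles <- zi_pi(net, list(membership = memb))
  crow <- roles[roles$otu_id == "c", ]
  expect_equal(crow$Pi, 2 / 3, tolerance = 1e-12)  # 1 - 3*(1/3)^2 > 0.62
  expect_equal(crow$Zi, 0)                          # singleton module
  expect_equal(crow$role, "connector")
  expect_true(all(roles$Pi >= 0 & roles$Pi < 1))
  expect_error(zi_pi(net, list(membership = memb[-1])), "cover")
})
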