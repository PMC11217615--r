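# Recovery experiments that exercise the whole chain against the generator's
# planted ground truth. Used by the test suite and the acceptance script.

#' Study design and model for the specialist-recovery experiment
#'
#' One lake sampled at 20 columns with one water stratum and one sediment
#' sample each (balanced 20 + 20 samples, so both habitat means are equally
#' precise), a single 60-OTU marker with three sediment and three water
#' specialists planted at the stated fold enrichment. Specialist baselines
#' sit at `log(0.02)` so that an enriched specialist reaches parity with a
#' typical OTU inside its habitat instead of dominating the closed
#' composition (which would drag every other OTU's specificity toward the
#' opposite habitat).
#'
#' @param fold_enrichment Planted enrichment (1 disables planting).
#' @return List with `design` and `model`.
#' @export
specialist_experiment_setup <- function(fold_enrichment = 50) {
  design <- build_design(
    lakes = list(L1 = lake_spec(n_columns = 20, water_depth_strata = 1,
                                sediment_per_column = TRUE)),
    markers = c(diatom = 100))
  spec <- data.frame(marker = "diatom", otu = 1:6,
                     habitat = rep(c("sediment", "water"), each = 3),
                     fold_enrichment = fold_enrichment,
                     baseline_offset = log(0.02), stringsAsFactors = FALSE)
  # occupancy-saturating depth: detection, not sequencing effort, must be the
  # binding constraint when scoring the 0.7/0.7 rule, so even a specialist
  # whose baseline draw sits 2-3 sd low still clears the 5-read cell filter
  model <- community_model(n_otus = c(diatom = 60), specialists = spec,
                           depth_mean = 1e5)
  list(design = design, model = model)
}

#' Planted-specialist recovery across seeds
#'
#' Simulates the [specialist_experiment_setup()] study repeatedly, runs the
#' preprocessing chain and the specificity-occupancy rule on the habitat
#' grid, and scores recovery of the planted specialists.
#'
#' @param n_seeds Number of replicate simulations.
#' @param fold_enrichment Planted enrichment.
#' @param theta_s,theta_o Specialist thresholds (default 0.7 / 0.7).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List with `recovery_rate` (flagged planted specialists, planted
#'   habitat, over planted; `NA` when nothing is planted),
#'   `false_positive_rate` (non-planted OTUs flagged anywhere over non-planted
#'   OTUs scored) and the per-seed counts.
#' @export
specialist_recovery_experiment <- function(n_seeds = 20, fold_enrichment = 50,
                                           theta_s = 0.7, theta_o = 0.7,
                                           seed = 100) {
  setup <- specialist_experiment_setup(fold_enrichment)
  n_planted <- 0L
  n_recovered <- 0L
  n_nonplanted <- 0L
  n_fp <- 0L
  for (r in seq_len(n_seeds)) {
    sim <- simulate_dataset(setup$design, setup$model, seed = seed + r)
    st <- suppressWarnings(preprocess(sim$table,
                                      min_depth_by_marker = c(diatom = 100)))
    tab <- marker_table(st, "diatom", drop_empty_otus = FALSE)
    spec <- specificity(tab$rra, tab$meta$habitat)
    occ <- occupancy(tab$incidence, tab$meta$habitat)
    flags <- specialists(spec, occ, theta_s = theta_s, theta_o = theta_o)
    planted <- sim$truth$specialists
    hit <- merge(flags[flags$is_specialist, c("otu_id", "habitat")],
                 planted[, c("otu_id", "habitat")],
                 by = c("otu_id", "habitat"))
    n_planted <- n_planted + nrow(planted)
    n_recovered <- n_recovered + nrow(hit)
    flagged_otus <- unique(flags$otu_id[flags$is_specialist])
    non_planted <- setdiff(unique(flags$otu_id), planted$otu_id)
    n_nonplanted <- n_nonplanted + length(non_planted)
    n_fp <- n_fp + length(intersect(flagged_otus, non_planted))
  }
  list(recovery_rate = if (n_planted) n_recovered / n_planted else NA_real_,
       false_positive_rate = n_fp / n_nonplanted,
       n_planted = n_planted, n_recovered = n_recovered,
       n_nonplanted = n_nonplanted, n_false_positives = n_fp)
}

#' Study design and model for the module-recovery experiment
#'
#' One lake with 50 water samples and a single 30-OTU marker carrying three
#' planted correlation blocks of six OTUs (`rho_within` as given,
#' uncorrelated otherwise).
#'
#' @param rho_within Within-block latent correlation (0 disables planting).
#' @return List with `design` and `model`.
#' @export
module_experiment_setup <- function(rho_within = 0.95) {
  design <- build_design(
    lakes = list(L1 = lake_spec(n_columns = 13, water_depth_strata = 4,
                                n_water_samples = 50,
                                sediment_per_column = FALSE)),
    markers = c(diatom = 100))
  mods <- if (rho_within > 0) {
    list(list(marker = "diatom", otus = 1:6, rho_within = rho_within),
         list(marker = "diatom", otus = 7:12, rho_within = rho_within),
         list(marker = "diatom", otus = 13:18, rho_within = rho_within))
  } else list()
  model <- community_model(n_otus = c(diatom = 30), modules = mods)
  list(design = design, model = model)
}

#' Planted-module recovery across seeds
#'
#' Simulates the [module_experiment_setup()] study repeatedly and runs the
#' full network chain (prefilter, Spearman with BH adjustment, `|r| >= 0.75`
#' edge filter, Louvain), scoring the adjusted Rand index of the detected
#' partition against the planted blocks over the network's nodes (non-planted
#' nodes count as singleton truth modules).
#'
#' @param n_seeds Number of replicate simulations.
#' @param rho_within Planted within-block correlation.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List with per-seed `ari` and `n_edges`, plus `median_ari` and
#'   `median_edges`.
#' @export
module_recovery_experiment <- function(n_seeds = 20, rho_within = 0.95,
                                       seed = 200) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    stopf("the module-recovery experiment needs the 'mclust' package")
  }
  setup <- module_experiment_setup(rho_within)
  ari <- rep(NA_real_, n_seeds)
  n_edges <- integer(n_seeds)
  for (r in seq_len(n_seeds)) {
    sim <- simulate_dataset(setup$design, setup$model, seed = seed + r)
    st <- suppressWarnings(preprocess(sim$table,
                                      min_depth_by_marker = c(diatom = 100)))
    tab <- marker_table(st, "diatom")
    pf <- prefilter_otus(tab$rra)
    corr <- spearman_matrix(pf$rra)
    net <- build_network(corr)
    part <- detect_modules(net, seed = seed + r)
    n_edges[r] <- nrow(net$edges)
    if (length(net$nodes) >= 2) {
      planted <- sim$truth$modules
      truth_lab <- planted$module[match(net$nodes, planted$otu_id)]
      truth_lab[is.na(truth_lab)] <- paste0("single_", which(is.na(truth_lab)))
      ari[r] <- mclust::adjustedRandIndex(part$membership[net$nodes], truth_lab)
    }
  }
  list(ari = ari, n_edges = n_edges,
       median_ari = median(ari, na.rm = TRUE),
       median_edges = median(n_edges))
}
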