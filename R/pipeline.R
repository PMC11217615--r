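#' Default pipeline configuration
#'
#' All thresholds default to the survey's printed values: per-PCR OTU minimum
#' 5 reads; PCR depth minimum 100 reads (500 for invertebrates); network
#' prefilter mean RRA >= 0.01% and prevalence >= 30%; edges at Spearman
#' `|r| >= 0.75` with BH-adjusted `p < 0.05`; specialist rule 0.7/0.7;
#' PERMANOVA on 999 permutations.
#'
#' @param seed Master seed for the run.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    thresholds = list(
      min_otu_reads = 5,
      min_depth = c(cyanobacteria = 100, diatom = 100, invertebrate = 500,
                    vertebrate = 100),
      r_threshold = 0.75, alpha = 0.05,
      theta_s = 0.7, theta_o = 0.7,
      min_mean_rra = 1e-4, min_prevalence = 0.30),
    n_permutations = 999,
    permanova_factors = c("lake", "habitat"),
    network_markers = c("cyanobacteria", "diatom", "invertebrate"),
    exclude_otus = NULL,
    out_dir = NULL)
}

#' Read a pipeline configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; `thresholds$min_depth` entries are merged by
#' marker.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1)
  if (!is.null(user$thresholds)) {
    md <- user$thresholds$min_depth
    if (!is.null(md)) {
      cfg$thresholds$min_depth[names(md)] <- unlist(md)
      user$thresholds$min_depth <- NULL
    }
    cfg$thresholds <- modifyList(cfg$thresholds, user$thresholds)
  }
  for (key in c("n_permutations", "permanova_factors", "network_markers",
                "exclude_otus", "out_dir")) {
    if (!is.null(user[[key]])) cfg[[key]] <- user[[key]]
  }
  cfg
}

validate_config <- function(config, design) {
  th <- config$thresholds
  miss <- setdiff(names(design$markers), names(th$min_depth))
  if (length(miss)) {
    stopf("config lacks a min_depth threshold for marker(s): %s",
          paste(miss, collapse = ", "))
  }
  checks <- c(th$r_threshold >= 0 && th$r_threshold <= 1,
              th$alpha > 0 && th$alpha <= 1,
              th$theta_s >= 0 && th$theta_s <= 1,
              th$theta_o >= 0 && th$theta_o <= 1,
              th$min_mean_rra >= 0, th$min_prevalence >= 0,
              th$min_otu_reads >= 1, config$n_permutations >= 1)
  if (!all(checks)) stopf("configuration threshold out of range")
  invisible(TRUE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full simulate-to-networks pipeline
#'
#' Orchestrates synthetic-data generation (or a supplied count table),
#' preprocessing, alpha/beta diversity with PCoA and PERMANOVA, indicator
#' taxa, and one co-occurrence network per (lake, habitat) context, with
#' cohesion comparisons across contexts. Identical (config, design, model,
#' seed) give identical results.
#'
#' @param config Configuration from [default_run_config()] or
#'   [read_run_config()].
#' @param design Study design (default [two_lake_design()] with the config's
#'   depth thresholds).
#' @param model Community model for simulation (default
#'   [default_community_model()]); ignored when `table` is supplied.
#' @param table Optional existing [pcr_counts()] table; when `NULL` one is
#'   simulated from `design` and `model`.
#' @return List with `table`, `truth`, `samples` (the preprocessed
#'   `sample_table`), `diversity`, `indicators`, `networks` (one entry per
#'   context), `cohesion_tests` and `report`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         design = NULL, model = NULL, table = NULL) {
  th <- config$thresholds
  design <- design %||% two_lake_design(markers = th$min_depth)
  model <- model %||% default_community_model()
  validate_config(config, design)
  seed <- config$seed

  truth <- NULL
  if (is.null(table)) {
    sim <- run_stage("simulate", simulate_dataset(design, model, seed = seed))
    table <- sim$table
    truth <- sim$truth
  }

  st <- run_stage("preprocess", suppressWarnings(
    preprocess(table, min_otu_reads = th$min_otu_reads,
               min_depth_by_marker = th$min_depth,
               exclude_otus = config$exclude_otus)))

  markers <- names(design$markers)
  diversity <- list()
  for (m in markers) {
    tab <- marker_table(st, m)
    quantitative <- m != "vertebrate"
    alpha <- data.frame(
      sample_id = rownames(tab$rra),
      richness = hill_diversity(tab$rra, 0),
      shannon = hill_diversity(tab$rra, 1),
      simpson = hill_diversity(tab$rra, 2),
      stringsAsFactors = FALSE, row.names = NULL)
    dmat <- run_stage("diversity", if (quantitative) {
      bray_curtis_matrix(tab$rra)
    } else {
      jaccard_matrix(tab$incidence[rowSums(tab$incidence) > 0, , drop = FALSE])
    })
    ord <- suppressWarnings(pcoa(dmat, n_axes = 2))
    keep <- rownames(dmat)
    perm <- list()
    for (f in config$permanova_factors) {
      labels <- tab$meta[match(keep, tab$meta$sample_id), f]
      ok <- !is.na(labels)
      if (length(unique(labels[ok])) < 2) next
      perm[[f]] <- permanova(dmat[ok, ok], labels[ok],
                             n_permutations = config$n_permutations,
                             seed = seed)
    }
    diversity[[m]] <- list(alpha = alpha, distance = dmat, pcoa = ord,
                           permanova = perm,
                           index = if (quantitative) "bray-curtis" else "jaccard")
  }

  indicators <- list()
  for (m in markers) {
    tab <- marker_table(st, m)
    grid <- interaction(tab$meta$lake, tab$meta$habitat, drop = TRUE)
    spec <- specificity(tab$rra, grid)
    occ <- occupancy(tab$incidence, grid)
    flags <- specialists(spec, occ, theta_s = th$theta_s, theta_o = th$theta_o)
    simpers <- list()
    for (lk in unique(tab$meta$lake)) {
      rows <- tab$meta$lake == lk
      if (length(unique(tab$meta$habitat[rows])) == 2) {
        simpers[[lk]] <- simper_contrast(tab$rra[rows, , drop = FALSE],
                                         tab$meta$habitat[rows])
      }
    }
    indicators[[m]] <- list(specialists = flags, simper = simpers)
  }

  net_markers <- intersect(config$network_markers, markers)
  combined <- run_stage("network", combine_markers(st, net_markers))
  contexts <- unique(combined$meta[, c("lake", "habitat")])
  networks <- list()
  cohesion_by_context <- list()
  for (i in seq_len(nrow(contexts))) {
    lk <- contexts$lake[i]
    hb <- contexts$habitat[i]
    ctx <- paste(lk, hb, sep = ".")
    rows <- combined$meta$lake == lk & combined$meta$habitat == hb
    rra <- combined$rra[rows, , drop = FALSE]
    pf <- prefilter_otus(rra, min_mean_rra = th$min_mean_rra,
                         min_prevalence = th$min_prevalence)
    if (ncol(pf$rra) < 2 || nrow(pf$rra) < 4) {
      networks[[ctx]] <- list(empty = TRUE, n_otus_prefiltered = ncol(pf$rra))
      next
    }
    corr <- spearman_matrix(pf$rra)
    net <- build_network(corr, r_threshold = th$r_threshold, alpha = th$alpha)
    part <- detect_modules(net, seed = seed)
    coh <- cohesion(pf$rra, corr)
    networks[[ctx]] <- list(
      context = c(lake = lk, habitat = hb),
      n_otus_prefiltered = ncol(pf$rra),
      network = net,
      partition = part,
      metrics = network_metrics(net, part),
      roles = if (length(net$nodes)) zi_pi(net, part) else NULL,
      cohesion = coh)
    cohesion_by_context[[ctx]] <- coh$samples
  }
  cohesion_tests <- if (length(cohesion_by_context) >= 2) {
    suppressWarnings(compare_networks(cohesion_by_context))
  } else NULL

  report <- list(
    package_version = as.character(utils::packageVersion("ednanet")),
    seed = seed,
    thresholds = th,
    n_permutations = config$n_permutations,
    counts = list(
      pcrs_input = nrow(table$counts),
      otus_input = ncol(table$counts),
      sample_units_retained = nrow(st$rra),
      dropped_pcrs = length(attr(st, "report")$dropped_pcrs),
      dropped_samples = length(st$dropped_samples),
      networks = lapply(networks, function(nw) {
        if (isTRUE(nw$empty)) list(nodes = 0, edges = 0) else
          list(nodes = nw$metrics$n_nodes, edges = nw$metrics$n_edges)
      })))

  result <- list(table = table, truth = truth, samples = st,
                 diversity = diversity, indicators = indicators,
                 networks = networks, cohesion_tests = cohesion_tests,
                 report = report)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' Write all pipeline artifacts to a directory
#'
#' Counts and truth (TSV/JSON), the sample table, per-marker distance
#' matrices, per-context networks (GraphML + edge lists), cohesion tables and
#' the machine-readable run report.
#'
#' @param result Output of [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pcr_counts(result$table, file.path(dir, "pcr_counts.tsv"))
  if (!is.null(result$truth)) {
    write_truth_record(result$truth, file.path(dir, "truth.json"))
  }
  write_sample_table(result$samples, dir)
  for (m in names(result$diversity)) {
    d <- result$diversity[[m]]$distance
    utils::write.table(
      cbind(sample_id = rownames(d), as.data.frame(d)),
      file.path(dir, sprintf("distance_%s.tsv", m)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (ctx in names(result$networks)) {
    nw <- result$networks[[ctx]]
    if (isTRUE(nw$empty)) next
    write_network(nw$network,
                  path_graphml = file.path(dir, sprintf("network_%s.graphml", ctx)),
                  path_edges = file.path(dir, sprintf("edges_%s.tsv", ctx)))
    utils::write.table(nw$cohesion$samples,
                       file.path(dir, sprintf("cohesion_%s.tsv", ctx)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
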