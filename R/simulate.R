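#' Define the generative model of a synthetic multi-marker community
#'
#' Latent per-sample OTU abundances follow a log-normal model: each OTU draws
#' a baseline log-abundance, and per-sample deviations are multivariate normal
#' with a block correlation structure that plants co-occurrence modules.
#' Habitat specialists are planted by multiplying the latent abundance by
#' `fold_enrichment` in their preferred habitat (and optionally shifting their
#' baseline so that strong enrichment does not dominate the closed
#' composition). Read counts are then drawn multinomially per PCR with a
#' negative-binomial total depth; negative controls receive sparse Poisson
#' contamination.
#'
#' @param n_otus Named integer vector: OTUs per marker group.
#' @param log_mean,log_sd Mean and sd of the OTU baseline log-abundance draws.
#' @param sample_log_sd Sd of per-sample log-abundance deviations (the scale
#'   on which planted modules correlate).
#' @param habitat_offset,lake_offset Optional named log-abundance offsets
#'   applied to all OTUs by habitat / lake.
#' @param specialists Data frame with columns `marker`, `otu` (index within
#'   marker), `habitat`, `fold_enrichment` (>= 1; 1 means no planted effect),
#'   and optionally `baseline_offset` (log scale, default 0).
#' @param modules List of planted correlation blocks, each a list with
#'   `marker`, `otus` (index vector) and `rho_within`.
#' @param rho_between Latent correlation between OTUs not in the same block
#'   (0 <= rho_between <= rho_within).
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of the
#'   total reads per PCR.
#' @param contamination_rate Poisson mean of contaminant reads per OTU in each
#'   negative-control PCR.
#' @param dropout_prob Probability that an OTU drops out of one PCR replicate.
#' @return A `community_model` list.
#' @export
community_model <- function(n_otus = c(cyanobacteria = 40, diatom = 60,
                                       invertebrate = 80, vertebrate = 15),
                            log_mean = 0, log_sd = 1.5, sample_log_sd = 1,
                            habitat_offset = NULL, lake_offset = NULL,
                            specialists = NULL, modules = list(),
                            rho_between = 0,
                            depth_mean = 2e4, depth_dispersion = 5,
                            contamination_rate = 0.5, dropout_prob = 0.02) {
  if (is.null(names(n_otus)) || any(n_otus < 1)) {
    stopf("n_otus must be a named vector of positive counts")
  }
  if (depth_mean <= 0 || depth_dispersion <= 0) stopf("depths must be > 0")
  if (contamination_rate < 0) stopf("contamination_rate must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1) stopf("dropout_prob must be in [0, 1)")
  if (log_sd < 0 || sample_log_sd < 0) stopf("log sds must be >= 0")
  if (!is.null(specialists)) {
    need <- c("marker", "otu", "habitat", "fold_enrichment")
    if (!all(need %in% names(specialists))) {
      stopf("specialists needs columns %s", paste(need, collapse = ", "))
    }
    if (any(specialists$fold_enrichment < 1)) {
      stopf("fold_enrichment must be >= 1")
    }
    if (is.null(specialists$baseline_offset)) specialists$baseline_offset <- 0
  }
  for (b in modules) {
    if (!all(c("marker", "otus", "rho_within") %in% names(b))) {
      stopf("each module block needs marker, otus, rho_within")
    }
    if (b$rho_within < 0 || b$rho_within > 1) stopf("rho_within must be in [0, 1]")
    if (rho_between > b$rho_within) {
      stopf("rho_between must not exceed rho_within")
    }
  }
  if (rho_between < 0 || rho_between > 1) stopf("rho_between must be in [0, 1]")
  structure(
    list(n_otus = n_otus, log_mean = log_mean, log_sd = log_sd,
         sample_log_sd = sample_log_sd,
         habitat_offset = habitat_offset, lake_offset = lake_offset,
         specialists = specialists, modules = modules,
         rho_between = rho_between,
         depth_mean = depth_mean, depth_dispersion = depth_dispersion,
         contamination_rate = contamination_rate,
         dropout_prob = dropout_prob),
    class = "community_model")
}

#' The default synthetic community for the two-lake survey
#'
#' Desk-scale marker richness (40 cyanobacteria, 60 diatom, 80 invertebrate,
#' 15 vertebrate OTUs) with, per non-vertebrate marker, two sediment and two
#' water specialists (50-fold enrichment, baseline an order of magnitude below
#' the community average) and planted co-occurrence blocks in the diatom and
#' invertebrate markers.
#'
#' @param ... Overrides passed on to [community_model()].
#' @return A `community_model`.
#' @export
default_community_model <- function(...) {
  spec <- do.call(rbind, lapply(c("cyanobacteria", "diatom", "invertebrate"),
    function(m) data.frame(marker = m, otu = 1:4,
                           habitat = c("sediment", "sediment", "water", "water"),
                           fold_enrichment = 50,
                           baseline_offset = log(0.1),
                           stringsAsFactors = FALSE)))
  mods <- list(
    list(marker = "diatom", otus = 11:15, rho_within = 0.9),
    list(marker = "diatom", otus = 16:20, rho_within = 0.9),
    list(marker = "invertebrate", otus = 11:15, rho_within = 0.9),
    list(marker = "invertebrate", otus = 16:20, rho_within = 0.9),
    list(marker = "invertebrate", otus = 21:25, rho_within = 0.9))
  args <- modifyList(list(specialists = spec, modules = mods), list(...))
  do.call(community_model, args)
}

otu_ids_for <- function(marker, n) sprintf("%s_%03d", marker, seq_len(n))

# Block correlation matrix for one marker; errors name the offending block.
marker_correlation <- function(model, marker) {
  n <- model$n_otus[[marker]]
  R <- matrix(model$rho_between, n, n)
  diag(R) <- 1
  blocks <- Filter(function(b) b$marker == marker, model$modules)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (any(b$otus < 1 | b$otus > n)) {
      stopf("module block %d of marker '%s' references OTUs outside 1..%d",
            i, marker, n)
    }
    R[b$otus, b$otus] <- b$rho_within
    diag(R) <- 1
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    stopf("latent correlation for marker '%s' is not positive definite (blocks: %s)",
          marker, paste(vapply(blocks, function(b)
            paste(range(b$otus), collapse = "-"), ""), collapse = ", "))
  }
  ch
}

#' Simulate latent per-sample abundances with planted ground truth
#'
#' Draws log-normal latent abundances for every (sample, OTU) of the design:
#' OTU baselines plus correlated per-sample deviations (planting modules) plus
#' specialist enrichment in the preferred habitat. Identical
#' (design, model, seed) give identical output.
#'
#' @param design A [build_design()] object.
#' @param model A [community_model()].
#' @param seed Integer seed.
#' @return List with `latents` (named list per marker of samples x OTUs
#'   abundance matrices) and `truth` (a `truth_record`: planted specialists,
#'   planted modules, latents).
#' @export
simulate_latents <- function(design, model, seed) {
  stopifnot(inherits(design, "study_design"), inherits(model, "community_model"))
  miss <- setdiff(names(design$markers), names(model$n_otus))
  if (length(miss)) stopf("model lacks n_otus for marker(s): %s",
                          paste(miss, collapse = ", "))
  s <- design$samples
  with_seed(seed, function() {
    latents <- list()
    spec_rows <- list()
    mod_rows <- list()
    for (m in names(design$markers)) {
      n <- model$n_otus[[m]]
      ids <- otu_ids_for(m, n)
      baseline <- rnorm(n, model$log_mean, model$log_sd)
      ch <- marker_correlation(model, m)
      z <- matrix(rnorm(nrow(s) * n), nrow(s), n) %*% ch
      loglat <- sweep(model$sample_log_sd * z, 2, baseline, `+`)
      if (!is.null(model$habitat_offset)) {
        off <- model$habitat_offset[s$habitat]
        off[is.na(off)] <- 0
        loglat <- loglat + off
      }
      if (!is.null(model$lake_offset)) {
        off <- model$lake_offset[s$lake]
        off[is.na(off)] <- 0
        loglat <- loglat + off
      }
      sp <- model$specialists
      if (!is.null(sp)) {
        sp <- sp[sp$marker == m, , drop = FALSE]
        for (k in seq_len(nrow(sp))) {
          o <- sp$otu[k]
          loglat[, o] <- loglat[, o] + sp$baseline_offset[k] +
            log(sp$fold_enrichment[k]) * (s$habitat == sp$habitat[k] &
                                          !is.na(s$habitat))
          if (sp$fold_enrichment[k] > 1) {
            spec_rows[[length(spec_rows) + 1L]] <- data.frame(
              otu_id = ids[o], marker = m, habitat = sp$habitat[k],
              fold_enrichment = sp$fold_enrichment[k],
              stringsAsFactors = FALSE)
          }
        }
      }
      blocks <- Filter(function(b) b$marker == m && b$rho_within > model$rho_between,
                       model$modules)
      for (bi in seq_along(blocks)) {
        mod_rows[[length(mod_rows) + 1L]] <- data.frame(
          otu_id = ids[blocks[[bi]]$otus], marker = m,
          module = sprintf("%s_block%d", m, bi), stringsAsFactors = FALSE)
      }
      lat <- exp(loglat)
      dimnames(lat) <- list(s$sample_id, ids)
      latents[[m]] <- lat
    }
    truth <- structure(
      list(specialists = if (length(spec_rows)) do.call(rbind, spec_rows) else
             data.frame(otu_id = character(), marker = character(),
                        habitat = character(), fold_enrichment = numeric()),
           modules = if (length(mod_rows)) do.call(rbind, mod_rows) else
             data.frame(otu_id = character(), marker = character(),
                        module = character()),
           contamination = NULL,
           latents = latents),
      class = "truth_record")
    list(latents = latents, truth = truth)
  })
}

#' Draw PCR read counts from latent abundances
#'
#' For every sample PCR of the design, a total depth is drawn from a negative
#' binomial and reads are allocated multinomially according to the sample's
#' latent composition (after Bernoulli dropout of individual OTUs). Negative
#' controls receive independent Poisson contamination per OTU.
#'
#' @param latents Output of [simulate_latents()] (the full list or its
#'   `latents` element).
#' @param design,model As in [simulate_latents()].
#' @param seed Integer seed.
#' @return A [pcr_counts()] table covering all markers.
#' @export
simulate_counts <- function(latents, design, model, seed) {
  if (!is.null(latents$latents)) latents <- latents$latents
  pcrs <- design_pcrs(design)
  all_ids <- unlist(lapply(names(design$markers), function(m)
    otu_ids_for(m, model$n_otus[[m]])), use.names = FALSE)
  counts <- matrix(0L, nrow(pcrs), length(all_ids),
                   dimnames = list(pcrs$pcr_id, all_ids))
  with_seed(seed, function() {
    for (m in names(design$markers)) {
      lat <- latents[[m]]
      ids <- colnames(lat)
      n <- length(ids)
      rows <- which(pcrs$marker == m & !pcrs$is_negative_control)
      depths <- rnbinom(length(rows), mu = model$depth_mean,
                        size = model$depth_dispersion)
      for (j in seq_along(rows)) {
        i <- rows[j]
        p <- lat[pcrs$sample_id[i], ]
        if (model$dropout_prob > 0) {
          p <- p * (runif(n) >= model$dropout_prob)
        }
        if (depths[j] > 0 && sum(p) > 0) {
          counts[i, ids] <<- as.integer(rmultinom(1, depths[j], p))
        }
      }
      nc_rows <- which(pcrs$marker == m & pcrs$is_negative_control)
      for (i in nc_rows) {
        counts[i, ids] <<- rpois(n, model$contamination_rate)
      }
    }
    NULL
  })
  pcr_counts(counts, pcrs[, setdiff(names(pcrs), "pcr_id")])
}

#' Simulate a full study: latent abundances, ground truth and PCR counts
#'
#' @param design A [build_design()] object (default [two_lake_design()]).
#' @param model A [community_model()] (default [default_community_model()]).
#' @param seed Integer seed; latent draws use `seed`, count draws a fixed
#'   offset of it, so one seed pins the whole dataset.
#' @return List with `table` (a [pcr_counts()]) and `truth` (a
#'   `truth_record` including the contamination counts injected into the
#'   negative controls).
#' @export
simulate_dataset <- function(design = two_lake_design(),
                             model = default_community_model(),
                             seed = 1) {
  lat <- simulate_latents(design, model, seed)
  tab <- simulate_counts(lat$latents, design, model, seed + 1L)
  truth <- lat$truth
  nc <- tab$meta$is_negative_control
  truth$contamination <- tab$counts[nc, , drop = FALSE]
  list(table = tab, truth = truth)
}

#' Write a truth record as JSON
#'
#' @param truth A `truth_record` from [simulate_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  out <- list(
    specialists = truth$specialists,
    modules = truth$modules,
    contamination_total = if (!is.null(truth$contamination))
      sum(truth$contamination) else 0)
  jsonlite::write_json(out, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
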