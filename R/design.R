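#' Specify the sampling layout of one lake
#'
#' A lake contributes water samples collected at fixed depth strata along
#' vertical sampling columns, plus one surface-sediment sample per column and
#' optionally extra sediment samples. Real bathymetry rarely allows every
#' stratum in every column, so `n_water_samples` can be set below
#' `n_columns * water_depth_strata`; the deepest strata of the last columns
#' are then omitted deterministically.
#'
#' @param n_columns Number of vertical sampling columns (>= 1).
#' @param water_depth_strata Number of depth strata sampled per column.
#' @param n_water_samples Total water samples for the lake; defaults to the
#'   full `n_columns * water_depth_strata` grid.
#' @param sediment_per_column Collect one surface-sediment sample per column?
#' @param extra_sediment_samples Additional sediment samples beyond the
#'   per-column ones.
#' @return A `lake_spec` list.
#' @export
#' @examples
#' lake_spec(n_columns = 12, water_depth_strata = 4, n_water_samples = 40,
#'           extra_sediment_samples = 2)
lake_spec <- function(n_columns,
                      water_depth_strata = 4,
                      n_water_samples = NULL,
                      sediment_per_column = TRUE,
                      extra_sediment_samples = 0) {
  if (n_columns < 1) stopf("a lake needs at least one sampling column")
  if (water_depth_strata < 0 || extra_sediment_samples < 0) {
    stopf("counts must be non-negative")
  }
  n_water_samples <- n_water_samples %||% (n_columns * water_depth_strata)
  if (n_water_samples > n_columns * water_depth_strata) {
    stopf("n_water_samples exceeds the column x stratum grid")
  }
  structure(
    list(n_columns = n_columns,
         water_depth_strata = water_depth_strata,
         n_water_samples = n_water_samples,
         sediment_per_column = isTRUE(sediment_per_column),
         extra_sediment_samples = extra_sediment_samples),
    class = "lake_spec"
  )
}

#' Build a study design from lake specifications
#'
#' Enumerates every sample (lake, habitat, column, depth stratum) of a
#' multi-lake survey in a deterministic order, together with the PCR
#' replication scheme and the per-marker minimum read depth used later by
#' [filter_shallow_pcrs()].
#'
#' @param lakes Named list of [lake_spec()] objects; names are lake ids.
#' @param n_pcr_replicates PCR replicates per DNA extract (>= 1).
#' @param n_negative_controls Negative-control PCRs per (lake, marker) run.
#' @param markers Named numeric vector: minimum post-filter reads per PCR for
#'   each marker group (the survey default discards PCRs with < 100 reads for
#'   cyanobacteria, diatoms and vertebrates and < 500 for invertebrates).
#' @return A `study_design` with a `samples` data frame (`sample_id`, `lake`,
#'   `habitat`, `column_id`, `depth_stratum`) and the replication fields.
#' @export
#' @examples
#' d <- build_design(list(CRL = lake_spec(12, 4, 40, TRUE, 2)))
#' nrow(d$samples)  # 54 = 40 water + 14 sediment
build_design <- function(lakes,
                         n_pcr_replicates = 3,
                         n_negative_controls = 3,
                         markers = c(cyanobacteria = 100, diatom = 100,
                                     invertebrate = 500, vertebrate = 100)) {
  if (length(lakes) < 1) stopf("at least one lake is required")
  if (is.null(names(lakes)) || any(!nzchar(names(lakes)))) {
    stopf("lakes must be a named list")
  }
  if (n_pcr_replicates < 1) stopf("n_pcr_replicates must be >= 1")
  if (n_negative_controls < 0) stopf("n_negative_controls must be >= 0")
  if (length(markers) < 1 || is.null(names(markers))) {
    stopf("markers must be a named vector of minimum PCR read depths")
  }

  rows <- lapply(names(lakes), function(lk) {
    spec <- lakes[[lk]]
    if (!inherits(spec, "lake_spec")) stopf("lake '%s' is not a lake_spec", lk)
    water <- if (spec$n_water_samples > 0) {
      grid <- expand.grid(depth_stratum = seq_len(spec$water_depth_strata),
                          column_id = seq_len(spec$n_columns))
      grid <- grid[order(grid$column_id, grid$depth_stratum), ]
      grid <- grid[seq_len(spec$n_water_samples), ]
      data.frame(
        sample_id = sprintf("%s-C%02d-D%d", lk, grid$column_id,
                            grid$depth_stratum),
        lake = lk, habitat = "water",
        column_id = sprintf("C%02d", grid$column_id),
        depth_stratum = grid$depth_stratum,
        stringsAsFactors = FALSE)
    } else NULL
    sed_cols <- if (spec$sediment_per_column) seq_len(spec$n_columns) else integer()
    sed <- if (length(sed_cols)) {
      data.frame(
        sample_id = sprintf("%s-C%02d-S", lk, sed_cols),
        lake = lk, habitat = "sediment",
        column_id = sprintf("C%02d", sed_cols),
        depth_stratum = NA_integer_, stringsAsFactors = FALSE)
    } else NULL
    extra <- if (spec$extra_sediment_samples > 0) {
      data.frame(
        sample_id = sprintf("%s-X%02d-S", lk,
                            seq_len(spec$extra_sediment_samples)),
        lake = lk, habitat = "sediment",
        column_id = sprintf("X%02d", seq_len(spec$extra_sediment_samples)),
        depth_stratum = NA_integer_, stringsAsFactors = FALSE)
    } else NULL
    out <- rbind(water, sed, extra)
    out[order(out$sample_id), , drop = FALSE]
  })
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  if (anyDuplicated(samples$sample_id)) stopf("duplicate sample ids generated")

  structure(
    list(samples = samples,
         n_pcr_replicates = as.integer(n_pcr_replicates),
         n_negative_controls = as.integer(n_negative_controls),
         markers = markers),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  tab <- table(x$samples$lake, x$samples$habitat)
  cat(sprintf("Study design: %d samples, %d lakes, %d PCR replicates, %d NCs/run\n",
              nrow(x$samples), length(unique(x$samples$lake)),
              x$n_pcr_replicates, x$n_negative_controls))
  print(tab)
  cat("Markers (min reads/PCR):",
      paste(sprintf("%s=%g", names(x$markers), x$markers), collapse = ", "),
      "\n")
  invisible(x)
}

#' Enumerate every PCR of a design
#'
#' Expands a study design into one row per PCR: sample PCRs for every
#' (sample, marker, replicate) plus negative-control PCRs for each
#' (lake, marker) run.
#'
#' @param design A [build_design()] object.
#' @return Data frame with columns `pcr_id`, `sample_id`, `lake`, `habitat`,
#'   `column_id`, `depth_stratum`, `replicate`, `marker`,
#'   `is_negative_control`.
#' @export
design_pcrs <- function(design) {
  stopifnot(inherits(design, "study_design"))
  s <- design$samples
  out <- list()
  for (m in names(design$markers)) {
    for (r in seq_len(design$n_pcr_replicates)) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s$sample_id, lake = s$lake, habitat = s$habitat,
        column_id = s$column_id, depth_stratum = s$depth_stratum,
        replicate = r, marker = m, is_negative_control = FALSE,
        stringsAsFactors = FALSE)
    }
    for (lk in unique(s$lake)) {
      if (design$n_negative_controls > 0) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sprintf("%s-NC%02d", lk,
                              seq_len(design$n_negative_controls)),
          lake = lk, habitat = NA_character_, column_id = NA_character_,
          depth_stratum = NA_integer_,
          replicate = seq_len(design$n_negative_controls), marker = m,
          is_negative_control = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  pcrs <- do.call(rbind, out)
  ord <- order(pcrs$marker, pcrs$lake, pcrs$is_negative_control,
               pcrs$sample_id, pcrs$replicate)
  pcrs <- pcrs[ord, , drop = FALSE]
  pcrs$pcr_id <- sprintf("%s.%s.R%d", pcrs$sample_id, pcrs$marker,
                         pcrs$replicate)
  rownames(pcrs) <- NULL
  pcrs[, c("pcr_id", "sample_id", "lake", "habitat", "column_id",
           "depth_stratum", "replicate", "marker", "is_negative_control")]
}

#' The default two-lake survey design
#'
#' A freshwater lake (CRL: 40 water samples over 12 columns x 4 depth strata,
#' 14 sediment samples) and a hypersaline lake (MCL: 36 water samples over 11
#' columns x 4 strata, 11 sediment samples), triplicate PCRs per extract and
#' 3 negative controls per (lake, marker) run.
#'
#' @param markers Named vector of per-marker minimum PCR read depths.
#' @return A `study_design`.
#' @export
two_lake_design <- function(markers = c(cyanobacteria = 100, diatom = 100,
                                        invertebrate = 500, vertebrate = 100)) {
  build_design(
    lakes = list(
      CRL = lake_spec(n_columns = 12, water_depth_strata = 4,
                      n_water_samples = 40, sediment_per_column = TRUE,
                      extra_sediment_samples = 2),
      MCL = lake_spec(n_columns = 11, water_depth_strata = 4,
                      n_water_samples = 36, sediment_per_column = TRUE,
                      extra_sediment_samples = 0)),
    n_pcr_replicates = 3, n_negative_controls = 3, markers = markers)
}
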