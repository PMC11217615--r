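#' Subtract negative-control reads from sample PCRs
#'
#' Within each PCR run (grouped by marker and, when present, lake), the
#' maximum count of each OTU across the run's negative-control PCRs is
#' subtracted from every sample PCR of that run, clamping at zero. Negative
#' controls are removed from the output.
#'
#' @param x A [pcr_counts()] table.
#' @param run_key Metadata columns defining a PCR run; defaults to `marker`
#'   plus `lake` when available.
#' @return A `pcr_counts` table without negative-control rows.
#' @export
subtract_negative_controls <- function(x, run_key = NULL) {
  stopifnot(inherits(x, "pcr_counts"))
  run_key <- run_key %||% intersect(c("marker", "lake"), names(x$meta))
  if (!length(run_key) || !all(run_key %in% names(x$meta))) {
    stopf("run grouping key not found in PCR metadata")
  }
  grp <- interaction(x$meta[run_key], drop = TRUE)
  counts <- x$counts
  for (g in levels(grp)) {
    idx <- which(grp == g)
    nc <- idx[x$meta$is_negative_control[idx]]
    smp <- idx[!x$meta$is_negative_control[idx]]
    if (!length(nc) || !length(smp)) next
    m <- apply(x$counts[nc, , drop = FALSE], 2, max)
    if (any(m > 0)) {
      counts[smp, ] <- pmax(sweep(counts[smp, , drop = FALSE], 2, m, `-`), 0)
    }
  }
  keep <- !x$meta$is_negative_control
  pcr_counts(counts[keep, , drop = FALSE], x$meta[keep, , drop = FALSE])
}

#' Zero low-count OTU detections within each PCR
#'
#' Counts below `min_reads` in a PCR are set to zero (a per-cell rule guarding
#' against cross-contamination and tag jumps), leaving higher counts
#' untouched. The boundary is inclusive: a count equal to `min_reads` is kept.
#'
#' @param x A [pcr_counts()] table.
#' @param min_reads Minimum reads per OTU per PCR (default 5).
#' @return A `pcr_counts` table.
#' @export
filter_low_count_otus <- function(x, min_reads = 5) {
  stopifnot(inherits(x, "pcr_counts"))
  if (min_reads < 1) stopf("min_reads must be >= 1")
  counts <- x$counts
  counts[counts < min_reads] <- 0L
  pcr_counts(counts, x$meta)
}

#' Drop PCRs with insufficient total reads
#'
#' Removes PCR rows whose post-filter total reads fall below the per-marker
#' threshold (e.g. < 100 for cyanobacteria, diatoms and vertebrates, < 500 for
#' invertebrates). The boundary is inclusive: a PCR with exactly the threshold
#' is retained.
#'
#' @param x A [pcr_counts()] table.
#' @param min_depth_by_marker Named numeric vector of thresholds per marker.
#' @return A `pcr_counts` table with attribute `dropped_pcrs` listing removed
#'   PCR ids.
#' @export
filter_shallow_pcrs <- function(x, min_depth_by_marker) {
  stopifnot(inherits(x, "pcr_counts"))
  miss <- setdiff(unique(x$meta$marker), names(min_depth_by_marker))
  if (length(miss)) stopf("no depth threshold for marker(s): %s",
                          paste(miss, collapse = ", "))
  tot <- rowSums(x$counts)
  thr <- min_depth_by_marker[x$meta$marker]
  keep <- tot >= thr
  out <- pcr_counts(x$counts[keep, , drop = FALSE],
                    x$meta[keep, , drop = FALSE])
  attr(out, "dropped_pcrs") <- rownames(x$counts)[!keep]
  out
}

#' Per-PCR relative read abundance
#'
#' Divides each PCR row by its total reads, so every row sums to one over its
#' marker's OTUs. Zero-total rows are an error: they indicate that
#' [filter_shallow_pcrs()] was not applied first.
#'
#' @param x A [pcr_counts()] table with no negative controls and no zero-total
#'   rows.
#' @return Numeric matrix of per-PCR RRA values with the dimnames of
#'   `x$counts`.
#' @export
compute_rra <- function(x) {
  stopifnot(inherits(x, "pcr_counts"))
  tot <- rowSums(x$counts)
  if (any(tot == 0)) {
    stopf("zero-total PCR row(s) %s: run filter_shallow_pcrs() before compute_rra()",
          paste(head(rownames(x$counts)[tot == 0], 3), collapse = ", "))
  }
  x$counts / tot
}

#' Collapse replicate PCRs into per-sample RRA and incidence
#'
#' A sample's quantitative profile is the arithmetic mean RRA over its
#' retained replicate PCRs (per marker); its qualitative profile marks an OTU
#' present when it has a nonzero post-filter count in at least one retained
#' replicate. Samples that lost all replicates to the depth filter are dropped
#' and reported.
#'
#' @param per_pcr_rra RRA matrix from [compute_rra()].
#' @param x The [pcr_counts()] table the RRA was computed from.
#' @return A `sample_table`: list with `rra` and `incidence` matrices (rows =
#'   sample-marker units named `<sample_id>.<marker>`), `meta` (sample_id,
#'   lake, habitat, column_id, depth_stratum, marker, n_replicates) and
#'   `dropped_samples`.
#' @export
collapse_replicates <- function(per_pcr_rra, x) {
  stopifnot(inherits(x, "pcr_counts"))
  key <- paste(x$meta$sample_id, x$meta$marker, sep = ".")
  ukey <- unique(key)
  rra <- matrix(0, length(ukey), ncol(per_pcr_rra),
                dimnames = list(ukey, colnames(per_pcr_rra)))
  inc <- rra
  nrep <- integer(length(ukey))
  for (i in seq_along(ukey)) {
    rows <- which(key == ukey[i])
    rra[i, ] <- colMeans(per_pcr_rra[rows, , drop = FALSE])
    inc[i, ] <- as.numeric(colSums(x$counts[rows, , drop = FALSE] > 0) > 0)
    nrep[i] <- length(rows)
  }
  first <- match(ukey, key)
  meta_cols <- intersect(c("sample_id", "lake", "habitat", "column_id",
                           "depth_stratum", "marker"), names(x$meta))
  meta <- x$meta[first, meta_cols, drop = FALSE]
  meta$n_replicates <- nrep
  rownames(meta) <- ukey
  structure(list(rra = rra, incidence = inc, meta = meta,
                 dropped_samples = character()),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("Sample table: %d sample-marker units x %d OTUs (%d marker(s), %d dropped sample(s))\n",
              nrow(x$rra), ncol(x$rra), length(unique(x$meta$marker)),
              length(x$dropped_samples)))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Fixed order: negative-control subtraction, per-PCR low-count zeroing,
#' shallow-PCR removal, optional OTU exclusion (e.g. livestock sequences),
#' per-PCR RRA, replicate collapsing. Samples whose replicates are all removed
#' are dropped with a warning, mirroring the exclusion of low-yield field
#' samples.
#'
#' @param x A [pcr_counts()] table including negative controls.
#' @param min_otu_reads Per-PCR minimum reads per OTU (default 5).
#' @param min_depth_by_marker Named per-marker minimum PCR depth; defaults to
#'   the thresholds stored in a design (`100` / `500` style).
#' @param exclude_otus Character vector of OTU ids removed after the depth
#'   filter, before RRA.
#' @param run_key Passed to [subtract_negative_controls()].
#' @return A `sample_table` with a `report` attribute: reads removed per
#'   stage, dropped PCRs, dropped samples, excluded OTUs.
#' @export
preprocess <- function(x,
                       min_otu_reads = 5,
                       min_depth_by_marker = c(cyanobacteria = 100,
                                               diatom = 100,
                                               invertebrate = 500,
                                               vertebrate = 100),
                       exclude_otus = NULL,
                       run_key = NULL) {
  stopifnot(inherits(x, "pcr_counts"))
  reads0 <- sum(x$counts[!x$meta$is_negative_control, ])
  st1 <- subtract_negative_controls(x, run_key = run_key)
  reads1 <- sum(st1$counts)
  st2 <- filter_low_count_otus(st1, min_reads = min_otu_reads)
  reads2 <- sum(st2$counts)
  st3 <- filter_shallow_pcrs(st2, min_depth_by_marker)
  dropped_pcrs <- attr(st3, "dropped_pcrs")
  reads3 <- sum(st3$counts)
  excluded <- intersect(exclude_otus %||% character(), colnames(st3$counts))
  if (length(excluded)) {
    keep_cols <- setdiff(colnames(st3$counts), excluded)
    st3 <- pcr_counts(st3$counts[, keep_cols, drop = FALSE], st3$meta)
  }
  # exclusion can empty a PCR; such rows cannot enter RRA
  tot <- rowSums(st3$counts)
  emptied <- rownames(st3$counts)[tot == 0]
  if (length(emptied)) {
    st3 <- pcr_counts(st3$counts[tot > 0, , drop = FALSE],
                      st3$meta[tot > 0, , drop = FALSE])
    dropped_pcrs <- c(dropped_pcrs, emptied)
  }
  rra <- compute_rra(st3)
  st <- collapse_replicates(rra, st3)

  # report samples that lost every replicate
  all_keys <- unique(paste(x$meta$sample_id[!x$meta$is_negative_control],
                           x$meta$marker[!x$meta$is_negative_control],
                           sep = "."))
  lost <- setdiff(all_keys, rownames(st$rra))
  st$dropped_samples <- lost
  if (length(lost)) {
    warnf("%d sample-marker unit(s) lost all PCR replicates and were dropped",
          length(lost))
  }
  attr(st, "report") <- list(
    reads_input = reads0,
    reads_after_nc_subtraction = reads1,
    reads_after_low_count_filter = reads2,
    reads_after_depth_filter = reads3,
    dropped_pcrs = dropped_pcrs,
    dropped_samples = lost,
    excluded_otus = excluded)
  st
}

#' Extract one marker's sample x OTU matrices
#'
#' @param st A `sample_table` from [preprocess()].
#' @param marker Marker id.
#' @param drop_empty_otus Drop OTU columns that are zero everywhere in this
#'   marker (default TRUE).
#' @return List with `rra`, `incidence` (rows named by `sample_id`) and
#'   `meta`.
#' @export
marker_table <- function(st, marker, drop_empty_otus = TRUE) {
  stopifnot(inherits(st, "sample_table"))
  rows <- which(st$meta$marker == marker)
  if (!length(rows)) stopf("no samples for marker '%s'", marker)
  rra <- st$rra[rows, , drop = FALSE]
  inc <- st$incidence[rows, , drop = FALSE]
  cols <- startsWith(colnames(rra), paste0(marker, "_"))
  rra <- rra[, cols, drop = FALSE]
  inc <- inc[, cols, drop = FALSE]
  if (drop_empty_otus) {
    keep <- colSums(rra) > 0 | colSums(inc) > 0
    rra <- rra[, keep, drop = FALSE]
    inc <- inc[, keep, drop = FALSE]
  }
  meta <- st$meta[rows, , drop = FALSE]
  rownames(rra) <- rownames(inc) <- rownames(meta) <- meta$sample_id
  list(rra = rra, incidence = inc, meta = meta)
}

#' Combine several markers into one sample x OTU RRA matrix
#'
#' Restricts to the samples retained by every requested marker and binds the
#' marker matrices column-wise. Each OTU keeps its within-marker RRA scale;
#' rank-based downstream statistics (Spearman networks) are unaffected by the
#' per-marker closure.
#'
#' @param st A `sample_table`.
#' @param markers Character vector of marker ids.
#' @return List with `rra`, `incidence`, `meta` for the common samples.
#' @export
combine_markers <- function(st, markers) {
  tabs <- lapply(markers, function(m) marker_table(st, m))
  common <- Reduce(intersect, lapply(tabs, function(t) rownames(t$rra)))
  if (!length(common)) stopf("no samples shared by markers %s",
                             paste(markers, collapse = ", "))
  rra <- do.call(cbind, lapply(tabs, function(t) t$rra[common, , drop = FALSE]))
  inc <- do.call(cbind, lapply(tabs, function(t)
    t$incidence[common, , drop = FALSE]))
  meta <- tabs[[1]]$meta[match(common, tabs[[1]]$meta$sample_id), , drop = FALSE]
  list(rra = rra, incidence = inc, meta = meta)
}

#' Write a sample table to disk
#'
#' Writes `rra.tsv` and `incidence.tsv` (rows = sample-marker units, columns =
#' OTUs, preceded by the metadata columns) and `filter_report.json` into
#' `dir`.
#'
#' @param st A `sample_table`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample_table <- function(st, dir) {
  stopifnot(inherits(st, "sample_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (what in c("rra", "incidence")) {
    df <- cbind(st$meta, as.data.frame(st[[what]]))
    utils::write.table(df, file.path(dir, paste0(what, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  rep <- attr(st, "report") %||% list()
  rep$dropped_samples <- st$dropped_samples
  jsonlite::write_json(rep, file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
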