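#' Construct a PCR-level OTU count table
#'
#' The raw input of the pipeline: one row per PCR (sample replicates and
#' negative controls), one column per OTU, non-negative integer read counts.
#' Rows belonging to a marker group carry counts only in that marker's OTU
#' columns.
#'
#' @param counts Integer matrix, PCRs x OTUs, with `pcr_id` rownames and OTU
#'   id colnames.
#' @param meta Data frame aligned with `counts` rows; must contain
#'   `sample_id`, `marker`, `replicate`, `is_negative_control` (additional
#'   columns such as `lake`, `habitat`, `column_id`, `depth_stratum` are kept).
#' @return A `pcr_counts` object.
#' @export
pcr_counts <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("read counts must be non-negative")
  if (nrow(counts) != nrow(meta)) stopf("counts and meta row mismatch")
  need <- c("sample_id", "marker", "replicate", "is_negative_control")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("meta lacks column(s): %s", paste(miss, collapse = ", "))
  key <- with(meta[!meta$is_negative_control, ],
              paste(sample_id, marker, replicate))
  if (anyDuplicated(key)) stopf("duplicate (sample_id, marker, replicate) keys")
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste(meta$sample_id, meta$marker, meta$replicate,
                              sep = ".")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("OTU%04d", seq_len(ncol(counts)))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  rownames(meta) <- rownames(counts)
  structure(list(counts = counts, meta = meta), class = "pcr_counts")
}

#' @export
print.pcr_counts <- function(x, ...) {
  cat(sprintf("PCR count table: %d PCRs (%d negative controls) x %d OTUs, %d marker(s)\n",
              nrow(x$counts), sum(x$meta$is_negative_control), ncol(x$counts),
              length(unique(x$meta$marker))))
  invisible(x)
}

#' Write / read a PCR count table as tab-separated text
#'
#' The TSV carries the metadata columns first (`pcr_id`, `sample_id`, `lake`,
#' `habitat`, `column_id`, `depth_stratum`, `replicate`, `marker`,
#' `is_negative_control`) followed by one integer column per OTU.
#'
#' @param x A [pcr_counts()] object.
#' @param path File path.
#' @return `write_pcr_counts` returns `path` invisibly; `read_pcr_counts`
#'   returns a `pcr_counts` object.
#' @export
write_pcr_counts <- function(x, path) {
  stopifnot(inherits(x, "pcr_counts"))
  df <- cbind(data.frame(pcr_id = rownames(x$counts),
                         stringsAsFactors = FALSE),
              x$meta, as.data.frame(x$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pcr_counts
#' @export
read_pcr_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(
    c("pcr_id", "sample_id", "lake", "habitat", "column_id", "depth_stratum",
      "replicate", "marker", "is_negative_control"), names(df))
  otu_cols <- setdiff(names(df), meta_cols)
  counts <- as.matrix(df[, otu_cols, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$pcr_id
  meta <- df[, setdiff(meta_cols, "pcr_id"), drop = FALSE]
  meta$is_negative_control <- as.logical(meta$is_negative_control)
  pcr_counts(counts, meta)
}
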