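`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, fun) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  fun()
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Coerce a dist or square matrix to a validated symmetric matrix with ids.
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stopf("distance input must be a 'dist' or a square matrix")
  }
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("distance matrix diagonal is not zero")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  d
}
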