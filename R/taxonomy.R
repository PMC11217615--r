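#' Refine a vertebrate OTU's species assignment against local records
#'
#' Database hits (pre-filtered to 100% query coverage and > 95% identity) are
#' reconciled with a local species list: a single local species matched at
#' >= 98% identity yields a species-level assignment; several local species at
#' >= 98% yield the lowest taxonomic level containing all of them; otherwise
#' the best hit in the 95-98% similarity band is assigned at genus level. Ties
#' are broken by max score, then lexicographic species name.
#'
#' @param hits Data frame of candidate hits with columns `species`,
#'   `identity` (percent), `coverage` (percent) and `max_score`.
#' @param local_species Data frame of local records with column `species` and
#'   lineage columns among `genus`, `family`, `order`, `class`.
#' @return List with `name` and `rank` (`"species"`, `"genus"`, `"family"`,
#'   `"order"`, `"class"` or `"unassigned"`).
#' @export
refine_species_assignment <- function(hits, local_species) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(name = "unassigned", rank = "unassigned"))
  }
  need <- c("species", "identity", "coverage", "max_score")
  if (!all(need %in% names(hits))) {
    stopf("hits needs columns %s", paste(need, collapse = ", "))
  }
  if (any(hits$identity < 0 | hits$identity > 100 |
          hits$coverage < 0 | hits$coverage > 100)) {
    stopf("identity and coverage must lie in [0, 100]")
  }
  hits <- hits[hits$coverage == 100 & hits$identity > 95, , drop = FALSE]
  if (nrow(hits) == 0) return(list(name = "unassigned", rank = "unassigned"))

  local_hits <- merge(hits, local_species, by = "species")
  strong <- local_hits[local_hits$identity >= 98, , drop = FALSE]
  if (nrow(strong) > 0) {
    sp <- unique(strong$species)
    if (length(sp) == 1) return(list(name = sp, rank = "species"))
    for (rank in intersect(c("genus", "family", "order", "class"),
                           names(local_species))) {
      vals <- unique(strong[[rank]])
      if (length(vals) == 1 && !is.na(vals)) {
        return(list(name = vals, rank = rank))
      }
    }
    return(list(name = "unassigned", rank = "unassigned"))
  }

  # best hit in the 95-98 band -> genus of that hit
  band <- hits[hits$identity < 98, , drop = FALSE]
  if (nrow(band) == 0) return(list(name = "unassigned", rank = "unassigned"))
  ord <- order(-band$identity, -band$max_score, band$species)
  best <- band[ord[1], , drop = FALSE]
  idx <- match(best$species, local_species$species)
  genus <- if (!is.na(idx) && "genus" %in% names(local_species)) {
    local_species$genus[idx]
  } else {
    strsplit(best$species, "[ _]")[[1]][1]
  }
  list(name = genus, rank = "genus")
}
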