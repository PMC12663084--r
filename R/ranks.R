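#' Taxonomic rank order
#'
#' The fixed rank ladder used throughout the package, coarse to fine. The
#' name of the coarsest rank ("Kingdom" vs "Domain") is cosmetic; all
#' algorithms work on rank indices.
#'
#' @param domain_name Label for the coarsest rank.
#' @return Character vector of the seven rank names, coarse to fine.
#' @export
#' @examples
#' rank_levels()
rank_levels <- function(domain_name = "Kingdom") {
  c(domain_name, "Phylum", "Class", "Order", "Family", "Genus", "Species")
}

# ranks for which distance thresholds are learned (Kingdom is gated by the
# Phylum threshold during propagation)
threshold_ranks <- function() {
  rank_levels()[-1]
}

rank_index <- function(rank, ranks = rank_levels()) {
  idx <- match(rank, ranks)
  if (anyNA(idx)) {
    abort(paste0("unknown rank(s): ", paste(rank[is.na(idx)], collapse = ", ")))
  }
  idx
}
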