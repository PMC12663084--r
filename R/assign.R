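#' Taxonomic assignment from a single placement
#'
#' The index node is the child node of the placement edge. The query's
#' distance to a reference tip is `pendant_length + ` the path length
#' from the attachment point to the tip, where the attachment point sits
#' on the placement edge at `distal_length` above the index node. The
#' proposed level is the finest rank at which this distance is below the
#' rank's effective threshold for every tip under the index node. If no
#' rank qualifies at the index node, assignment walks toward the root,
#' re-testing against each ancestor's tip set, and returns unassigned if
#' even the root fails. Labels are the evaluated node's labels from the
#' Phylum ladder down to the proposed level.
#'
#' @param placement One row from [place_query()].
#' @param labeling A `node_labeling` from [propagate()].
#' @param thresholds A `threshold_set`.
#' @param index Optional precomputed [tree_index()] of the labeled tree.
#' @param use_distal Include `distal_length` in query-tip distances
#'   (default); `FALSE` ignores the position along the edge.
#' @return List: `sets` (named list rank -> label set), `level`
#'   (proposed rank index, `NA` if unassigned), `node` (node whose
#'   labels were used).
#' @export
assign_from_placement <- function(placement, labeling, thresholds,
                                  index = NULL, use_distal = TRUE) {
  ix <- index %||% tree_index(labeling$tree)
  eff <- effective_thresholds(thresholds)
  pendant <- placement$pendant_length
  distal <- if (use_distal) placement$distal_length else 0

  v <- placement$node
  # distances from the attachment point to every tip under v
  dvec <- distal + ix$tipdist[[v]]
  tipset <- ix$tips[[v]]
  att_to_v <- distal
  repeat {
    dq <- pendant + dvec
    ok <- max(dq) < eff
    if (any(ok)) {
      level <- max(which(ok))
      sets <- labeling$sets[[v]]
      out <- setNames(vector("list", 7L), rank_levels())
      for (i in seq_len(7L)) {
        out[[i]] <- if (i <= level) sets[[i]] else character(0)
      }
      return(list(sets = out, level = level, node = v))
    }
    if (v == ix$root) break
    parent <- ix$parent[v]
    att_to_parent <- if (v == placement$node) {
      ix$edge_len_to_parent[v] - distal
    } else {
      att_to_v + ix$edge_len_to_parent[v]
    }
    new_d <- att_to_parent + ix$tipdist[[parent]]
    # tips already under v keep their exact (shorter) attachment distance
    keep <- match(tipset, ix$tips[[parent]])
    new_d[keep] <- dvec
    dvec <- new_d
    tipset <- ix$tips[[parent]]
    att_to_v <- att_to_parent
    v <- parent
  }
  list(sets = setNames(rep(list(character(0)), 7L), rank_levels()),
       level = NA_integer_, node = NA_integer_)
}

#' Combine per-placement assignments into one record
#'
#' The appropriate level is the mode of the proposed levels across
#' surviving placements (ties broken toward the coarser level); the
#' final label set at each rank down to that level is the union of the
#' per-placement label sets, and finer ranks are emptied.
#'
#' @param results List of results from [assign_from_placement()].
#' @return List with `sets` (named list rank -> label set) and `level`.
#' @export
combine_placements <- function(results) {
  if (length(results) == 0L) abort("no placement results to combine")
  levels <- vapply(results, function(r) r$level, integer(1))
  if (all(is.na(levels))) {
    return(list(sets = setNames(rep(list(character(0)), 7L), rank_levels()),
                level = NA_integer_))
  }
  lv <- levels[!is.na(levels)]
  tab <- table(lv)
  modal <- as.integer(names(tab)[tab == max(tab)])
  level <- min(modal)                       # tie -> coarser
  sets <- setNames(vector("list", 7L), rank_levels())
  for (i in seq_len(7L)) {
    sets[[i]] <- if (i <= level) {
      sort(unique(unlist(lapply(results, function(r) r$sets[[i]]))))
    } else {
      character(0)
    }
  }
  list(sets = sets, level = level)
}

#' Classify query amplicons against a labeled reference tree
#'
#' Full query path: NAST-style alignment to the trimmed reference,
#' coverage QC (default 80%, inclusive), placement (from a jplace file
#' if given, otherwise the internal distance-based placer), LWR
#' filtering (within 50% of the maximum), per-placement assignment and
#' combination.
#'
#' @param queries Tibble with columns `id`, `seq` (unaligned).
#' @param reference Region slice tibble the tree was built from.
#' @param tree Rooted `ape::phylo`.
#' @param labeling A `node_labeling` from [propagate()].
#' @param thresholds A `threshold_set`.
#' @param jplace Optional `jplace` object; when supplied the internal
#'   placer is skipped.
#' @param min_cov Minimum template coverage.
#' @param lwr_frac LWR filter fraction.
#' @param top_k,k Internal placer parameters.
#' @param use_distal See [assign_from_placement()].
#' @return Assignment tibble: `id`, one column per rank (canonical
#'   `";"`-joined label sets, `NA` where unassigned), `resolved_rank`,
#'   `n_placements`, `max_lwr`, `coverage`, `status` (one of
#'   `assigned`, `unassigned`, `low_coverage`, `unplaced`).
#' @export
classify_queries <- function(queries, reference, tree, labeling, thresholds,
                             jplace = NULL, min_cov = 0.80, lwr_frac = 0.5,
                             top_k = 5L, k = 8L, use_distal = TRUE) {
  ix <- tree_index(tree)
  ref_kmers <- lapply(reference$seq, kmer_set, k = k)
  alns <- purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    align_query(queries$seq[i], reference, query_id = queries$id[i], k = k,
                ref_kmers = ref_kmers)
  }) |>
    qc_coverage(min_cov = min_cov)
  ranks <- rank_levels()

  purrr::map_dfr(seq_len(nrow(alns)), function(i) {
    aln <- alns[i, ]
    base <- tibble(id = aln$id)
    empty <- as_tibble(setNames(as.list(rep(NA_character_, 7L)), ranks))
    if (!aln$keep) {
      return(dplyr::bind_cols(base, empty,
                              tibble(resolved_rank = NA_character_,
                                     n_placements = 0L, max_lwr = NA_real_,
                                     coverage = aln$coverage,
                                     status = "low_coverage")))
    }
    pl <- if (!is.null(jplace)) {
      place_query(aln, tree, reference, source = "jplace", jplace = jplace)
    } else {
      place_query(aln, tree, reference, source = "internal",
                  top_k = top_k, k = k, ref_kmers = ref_kmers)
    }
    if (nrow(pl) == 0L) {
      return(dplyr::bind_cols(base, empty,
                              tibble(resolved_rank = NA_character_,
                                     n_placements = 0L, max_lwr = NA_real_,
                                     coverage = aln$coverage,
                                     status = "unplaced")))
    }
    pl <- filter_placements(pl, frac = lwr_frac)
    results <- lapply(seq_len(nrow(pl)), function(j) {
      assign_from_placement(pl[j, ], labeling, thresholds, index = ix,
                            use_distal = use_distal)
    })
    comb <- combine_placements(results)
    labels <- vapply(comb$sets, function(s) {
      if (length(s) == 0L) NA_character_ else render_labels(s)
    }, character(1))
    dplyr::bind_cols(
      base, as_tibble(as.list(labels)),
      tibble(resolved_rank = if (is.na(comb$level)) NA_character_
             else ranks[comb$level],
             n_placements = nrow(pl),
             max_lwr = max(pl$like_weight_ratio),
             coverage = aln$coverage,
             status = if (is.na(comb$level)) "unassigned" else "assigned"))
  })
}

#' Write an assignment table
#'
#' @param assignments Tibble from [classify_queries()].
#' @param path Output TSV path.
#' @param sentinel Text written for unassigned ranks.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path, sentinel = "unassigned") {
  out <- assignments
  for (r in rank_levels()) {
    out[[r]] <- ifelse(is.na(out[[r]]), sentinel, out[[r]])
  }
  readr::write_tsv(out, path)
  invisible(path)
}
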