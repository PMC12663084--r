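#' Cut a tree into groups at a distance threshold
#'
#' Groups are the maximal clades whose tip diameter (largest cophenetic
#' distance among member tips) is strictly less than `t`: a single
#' preorder traversal stops descending at the first qualifying node. Tips
#' reached without any qualifying ancestor become singleton groups, so
#' `t = 0` yields one group per tip.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param t Threshold (>= 0).
#' @param index Optional precomputed [tree_index()] (internal reuse).
#' @return Tibble with columns `group` (ape node id of the group's root)
#'   and `id` (tip label); groups partition the tips.
#' @export
cut_tree <- function(tree, t, index = NULL) {
  if (t < 0) abort("threshold must be >= 0")
  ix <- index %||% tree_index(tree)
  groups <- integer(0)
  stack <- ix$root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (ix$diam[v] < t || v <= ix$n_tip) {
      groups <- c(groups, v)
    } else {
      stack <- c(stack, ix$children[[v]])
    }
  }
  tibble(
    group = rep(groups, times = lengths(ix$tips[groups])),
    id = ix$tree$tip.label[unlist(ix$tips[groups])]
  )
}

#' Score a tree partition against known taxonomy at one rank
#'
#' Each group is named for its majority (plurality) taxon at the rank,
#' ties broken lexicographically. Every additional distinct ground-truth
#' taxon present in a group adds one to the over-merging error; every
#' additional group carrying an already-used majority name adds one to
#' the over-splitting error. The total is normalized by the number of
#' tips labeled at the rank, giving a tree-wise error in `[0, 1]`. Tips
#' with a missing designation at the rank are excluded from both terms.
#'
#' @param partition Tibble from [cut_tree()].
#' @param taxonomy Taxonomy tibble from [parse_taxonomy()].
#' @param rank Rank name (see [rank_levels()]).
#' @return One-row tibble: `over_merge`, `over_split`, `error`,
#'   `n_groups`, `n_labeled`.
#' @export
score_threshold <- function(partition, taxonomy, rank) {
  rank_index(rank)   # validates
  lab <- taxonomy[[rank]][match(partition$id, taxonomy$id)]
  keep <- !is.na(lab)
  part <- tibble(group = partition$group[keep], label = lab[keep])
  n_labeled <- nrow(part)
  if (n_labeled == 0L) {
    return(tibble(over_merge = 0L, over_split = 0L, error = 0,
                  n_groups = 0L, n_labeled = 0L))
  }
  # contingency of groups x labels; columns are sorted by label name, so
  # ties.method = "first" breaks majority ties lexicographically
  tab <- table(part$group, part$label)
  n_taxa <- rowSums(tab > 0L)
  majority <- colnames(tab)[max.col(tab, ties.method = "first")]
  over_merge <- sum(n_taxa - 1L)
  over_split <- nrow(tab) - length(unique(majority))
  tibble(over_merge = as.integer(over_merge),
         over_split = as.integer(over_split),
         error = (over_merge + over_split) / n_labeled,
         n_groups = nrow(tab), n_labeled = n_labeled)
}

#' Optimize per-rank cophenetic distance thresholds
#'
#' For each rank independently, evaluates a grid of candidate thresholds:
#' the tree is cut with [cut_tree()], the partition scored with
#' [score_threshold()], and the threshold minimizing the normalized
#' total (over-merging + over-splitting) error is kept; ties go to the
#' smallest threshold (most conservative grouping). The full error curve
#' per rank is retained for diagnostics.
#'
#' @param tree Rooted `ape::phylo`.
#' @param taxonomy Taxonomy tibble ([parse_taxonomy()]); every tree tip
#'   must appear in it.
#' @param ranks Ranks to optimize (default Phylum..Species).
#' @param grid Optional numeric vector of candidate thresholds; by
#'   default a hybrid linear + geometric grid of `n_grid` points spanning
#'   0 to the tree diameter (geometric points resolve the small-distance
#'   regime where species/genus optima live).
#' @param n_grid Number of grid points for the default grid.
#' @param mode Species-specificity preset, see [specificity_mode()].
#' @return A `threshold_set`: chosen thresholds, species multiplier, and
#'   per-rank error curves. Use [tidy()] / [autoplot()] to inspect.
#' @export
find_thresholds <- function(tree, taxonomy, ranks = threshold_ranks(),
                            grid = NULL, n_grid = 200,
                            mode = c("specific", "sensitive")) {
  mode <- match.arg(mode)
  missing_tips <- setdiff(tree$tip.label, taxonomy$id)
  if (length(missing_tips) > 0L) {
    abort(paste0("tree tips absent from taxonomy: ",
                 paste(head(missing_tips, 5), collapse = ", ")))
  }
  ix <- tree_index(tree)
  if (is.null(grid)) grid <- threshold_grid(ix$diam[ix$root], n_grid)
  grid <- sort(unique(grid))
  if (length(grid) == 0L) abort("empty threshold grid")

  partitions <- lapply(grid, function(t) cut_tree(tree, t, index = ix))
  curves <- purrr::map_dfr(ranks, function(r) {
    rows <- purrr::map_dfr(seq_along(grid), function(i) {
      score_threshold(partitions[[i]], taxonomy, r)
    })
    dplyr::bind_cols(tibble(rank = r, threshold = grid), rows)
  })
  chosen <- curves |>
    group_by(.data$rank) |>
    slice_min(.data$error, n = 1, with_ties = TRUE) |>
    slice_min(.data$threshold, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(match(.data$rank, rank_levels()))

  ts <- structure(
    list(thresholds = setNames(chosen$threshold, chosen$rank),
         multiplier = 1,
         mode = "sensitive",
         chosen = chosen,
         curves = curves),
    class = "threshold_set"
  )
  specificity_mode(ts, mode)
}

# hybrid grid: half linear, half geometric (resolves the small-distance
# regime); the top point sits just above the tree diameter so the
# strict "diameter < t" rule can still form a single all-tips group
threshold_grid <- function(diameter, n_grid = 200) {
  if (diameter <= 0) return(c(0, 1e-8))
  top <- diameter * (1 + 1e-6)
  n_half <- max(2L, ceiling(n_grid / 2))
  lin <- seq(0, top, length.out = n_half)
  geo <- exp(seq(log(top * 1e-4), log(top), length.out = n_half))
  sort(unique(c(0, lin, geo)))
}

#' Set the species-specificity mode of a threshold set
#'
#' The optimizer's species threshold tends to over-call novel sequences;
#' a species-level multiplier trades recall for precision. `"specific"`
#' (the default mode) multiplies the species threshold by 0.1;
#' `"sensitive"` uses the learned threshold unchanged (multiplier 1).
#' A custom multiplier can be supplied instead of a named mode.
#'
#' @param ts A `threshold_set`.
#' @param mode `"specific"` or `"sensitive"`.
#' @param multiplier Optional numeric override (> 0).
#' @return Updated `threshold_set`.
#' @export
specificity_mode <- function(ts, mode = c("specific", "sensitive"),
                             multiplier = NULL) {
  stopifnot(inherits(ts, "threshold_set"))
  if (!is.null(multiplier)) {
    if (multiplier <= 0) abort("multiplier must be > 0")
    ts$multiplier <- multiplier
    ts$mode <- "custom"
    return(ts)
  }
  mode <- match.arg(mode)
  ts$multiplier <- if (mode == "specific") 0.1 else 1
  ts$mode <- mode
  ts
}

# effective thresholds across all 7 ranks: Kingdom is gated by the Phylum
# threshold; Species uses the multiplier-adjusted value
effective_thresholds <- function(ts) {
  th <- ts$thresholds
  out <- setNames(rep(-Inf, 7L), rank_levels())   # absent rank: never gates
  present <- intersect(names(th), names(out))
  out[present] <- th[present]
  if ("Phylum" %in% present) out["Kingdom"] <- th[["Phylum"]]
  if ("Species" %in% present) out["Species"] <- th[["Species"]] * ts$multiplier
  out
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> mode:", x$mode,
      sprintf("(species multiplier %g)\n", x$multiplier))
  print(tidy(x))
  invisible(x)
}

#' Tidy a threshold set
#'
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @return Tibble: rank, chosen threshold, effective threshold (after the
#'   species multiplier), over-merge / over-split counts and normalized
#'   error at the chosen threshold.
#' @method tidy threshold_set
#' @export
tidy.threshold_set <- function(x, ...) {
  eff <- effective_thresholds(x)
  x$chosen |>
    mutate(effective = unname(eff[.data$rank])) |>
    select("rank", "threshold", "effective", "over_merge", "over_split",
           "error")
}

#' @method glance threshold_set
#' @export
glance.threshold_set <- function(x, ...) {
  tibble(mode = x$mode, multiplier = x$multiplier,
         n_ranks = length(x$thresholds),
         mean_error = mean(x$chosen$error),
         grid_size = length(unique(x$curves$threshold)))
}

#' Plot threshold error curves
#'
#' One panel per rank: normalized total error against candidate
#' threshold (log x-axis), with the chosen threshold marked.
#'
#' @param object A `threshold_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_set
#' @export
autoplot.threshold_set <- function(object, ...) {
  curves <- dplyr::filter(object$curves, .data$threshold > 0)
  chosen <- object$chosen
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$threshold, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = chosen,
                        ggplot2::aes(xintercept = .data$threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~factor(rank, levels = rank_levels())) +
    ggplot2::labs(x = "cophenetic distance threshold",
                  y = "normalized over-merge + over-split error")
}

#' Serialize / read a threshold set
#'
#' JSON with the chosen thresholds, multiplier, mode and error table;
#' curves are included so diagnostics survive a round trip.
#'
#' @param ts A `threshold_set`.
#' @param path JSON path.
#' @return `path` (write) or a `threshold_set` (read).
#' @export
write_threshold_set <- function(ts, path) {
  jsonlite::write_json(
    list(thresholds = as.list(ts$thresholds), multiplier = ts$multiplier,
         mode = ts$mode, chosen = ts$chosen, curves = ts$curves),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_set
#' @export
read_threshold_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(thresholds = unlist(x$thresholds), multiplier = x$multiplier,
         mode = x$mode, chosen = as_tibble(x$chosen),
         curves = as_tibble(x$curves)),
    class = "threshold_set")
}
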