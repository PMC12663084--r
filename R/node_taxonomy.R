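#' Dominant labels under a binomial misclassification model
#'
#' Decides which taxon labels among a node's descendant tips are "real"
#' rather than plausible annotation error. Assuming each tip label is an
#' error independently with probability `error_rate`, a label observed
#' `k` times among `n` tips is retained iff the upper-tail probability
#' `P(X >= k)` under `Binomial(n, error_rate)` is at most `error_prob` -
#' i.e. the label is too frequent to be explained as error. If several
#' labels pass, all are retained (a one-to-many assignment); if none
#' passes, all observed labels are returned.
#'
#' `tail_rule = "ge"` switches to the alternative reading of the rule
#' (retain when the tail probability is at least `error_prob`); the
#' default `"le"` is the interpretation under which abundant labels
#' survive and rare ones are absorbed.
#'
#' @param counts Named integer vector: label -> tip count (all > 0).
#' @param error_rate Assumed per-tip misclassification rate.
#' @param error_prob Maximum probability that a non-dominant label was
#'   assigned in error.
#' @param tail_rule `"le"` (default) or `"ge"`, see above.
#' @return Character vector of retained labels (sorted).
#' @export
#' @examples
#' dominant_labels(c(X = 19, Y = 1))   # Y absorbed as plausible error
#' dominant_labels(c(X = 10, Y = 10))  # genuine ambiguity: both retained
dominant_labels <- function(counts, error_rate = 0.05, error_prob = 0.20,
                            tail_rule = c("le", "ge")) {
  tail_rule <- match.arg(tail_rule)
  if (length(counts) == 0L) abort("empty count vector")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n <= 0) abort("total count must be > 0")
  tail <- pbinom(counts - 1, size = n, prob = error_rate,
                 lower.tail = FALSE)   # P(X >= k)
  pass <- if (tail_rule == "le") tail <= error_prob else tail >= error_prob
  out <- if (any(pass)) names(counts)[pass] else names(counts)
  sort(out)
}

#' Propagate tip taxonomy to interior nodes
#'
#' Labels every node of the reference tree at every rank for which the
#' node's tip diameter is within that rank's effective threshold
#' (species uses the multiplier-adjusted threshold; the coarsest rank is
#' gated by the Phylum threshold). At a qualifying rank the descendant
#' tips' labels are passed through [dominant_labels()]. Once a rank
#' resolves ambiguously (more than one retained label), finer ranks are
#' computed hierarchically: the tip set is partitioned by each retained
#' label and the dominance model runs separately within each partition,
#' the results being unioned (`hierarchical = FALSE` pools instead).
#' Tips with a missing designation at a rank are excluded from that
#' rank's counts.
#'
#' @param tree Rooted `ape::phylo`.
#' @param taxonomy Taxonomy tibble ([parse_taxonomy()]) covering all tips.
#' @param thresholds A `threshold_set` from [find_thresholds()].
#' @param hierarchical Partition by retained parent labels after an
#'   ambiguous rank (default) or keep pooling all tips?
#' @inheritParams dominant_labels
#' @return A `node_labeling`: per-node per-rank label sets plus node
#'   diameters; see [tidy.node_labeling()].
#' @export
propagate <- function(tree, taxonomy, thresholds, hierarchical = TRUE,
                      error_rate = 0.05, error_prob = 0.20) {
  stopifnot(inherits(thresholds, "threshold_set"))
  missing_tips <- setdiff(tree$tip.label, taxonomy$id)
  if (length(missing_tips) > 0L) {
    abort(paste0("tree tips absent from taxonomy: ",
                 paste(head(missing_tips, 5), collapse = ", ")))
  }
  ix <- tree_index(tree)
  eff <- effective_thresholds(thresholds)
  ranks <- rank_levels()
  # tip labels as a matrix aligned with ape tip numbering
  lab_mat <- as.matrix(taxonomy[match(tree$tip.label, taxonomy$id), ranks])

  sets <- vector("list", ix$n_node)
  for (v in seq_len(ix$n_node)) {
    tip_idx <- ix$tips[[v]]
    result <- setNames(vector("list", 7L), ranks)
    for (i in seq_len(7L)) result[[i]] <- character(0)
    qualifies <- ix$diam[v] < eff

    descend <- function(idx, ri) {
      if (ri > 7L || length(idx) == 0L) return(invisible(NULL))
      labs <- character(0)
      here <- lab_mat[idx, ri]
      if (qualifies[ri]) {
        here_ok <- here[!is.na(here)]
        if (length(here_ok) > 0L) {
          labs <- dominant_labels(table(here_ok),
                                  error_rate = error_rate,
                                  error_prob = error_prob)
          result[[ri]] <<- sort(union(result[[ri]], labs))
        }
      }
      if (hierarchical && length(labs) > 1L) {
        for (L in labs) descend(idx[!is.na(here) & here == L], ri + 1L)
      } else {
        descend(idx, ri + 1L)
      }
    }
    descend(tip_idx, 1L)
    sets[[v]] <- result
  }
  structure(
    list(sets = sets, diameter = ix$diam, n_tips = lengths(ix$tips),
         tree = tree, thresholds = thresholds,
         hierarchical = hierarchical),
    class = "node_labeling")
}

#' @export
print.node_labeling <- function(x, ...) {
  cat("<node_labeling>", length(x$sets), "nodes,",
      sum(vapply(x$sets, function(s) any(lengths(s) > 1), logical(1))),
      "with one-to-many labels\n")
  invisible(x)
}

#' Tidy a node labeling
#'
#' @param x A `node_labeling`.
#' @param ... Unused.
#' @return Long tibble: `node` (ape id), `rank`, `labels` (canonical
#'   `";"`-joined set, `NA` if none), `n_labels`, `diameter`, `n_tips`.
#' @method tidy node_labeling
#' @export
tidy.node_labeling <- function(x, ...) {
  ranks <- rank_levels()
  purrr::map_dfr(seq_along(x$sets), function(v) {
    s <- x$sets[[v]]
    tibble(node = v, rank = ranks,
           labels = vapply(s, function(l) {
             if (length(l) == 0L) NA_character_ else render_labels(l)
           }, character(1)),
           n_labels = lengths(s),
           diameter = x$diameter[v], n_tips = x$n_tips[v])
  })
}

#' Write the node annotation table
#'
#' TSV companion to the annotated tree: one row per node and rank that
#' carries at least one label.
#'
#' @param labeling A `node_labeling`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(labeling, path) {
  tab <- tidy(labeling) |> dplyr::filter(.data$n_labels > 0)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Annotated Newick export
#'
#' Writes the reference tree with internal-node labels encoding the
#' finest resolved rank and its label set (`rank:labelset`), enabling
#' inspection of the regional tree in standard viewers.
#'
#' @param labeling A `node_labeling`.
#' @param path Output Newick path.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(labeling, path) {
  tree <- labeling$tree
  n_tip <- length(tree$tip.label)
  ranks <- rank_levels()
  node_lab <- vapply(seq_len(tree$Nnode) + n_tip, function(v) {
    s <- labeling$sets[[v]]
    fin <- which(lengths(s) > 0)
    if (length(fin) == 0L) return("")
    ri <- max(fin)
    paste0(ranks[ri], ":", render_labels(s[[ri]]))
  }, character(1))
  tree$node.label <- gsub("[ ;,():]", "_", node_lab)
  ape::write.tree(tree, file = path)
  invisible(path)
}
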