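#' Judge a single prediction against truth
#'
#' Ambiguity-aware outcome classes: a non-empty prediction is correct if
#' it contains the truth label (one-to-many assignments count as correct
#' when at least one member matches); an empty prediction is correct
#' exactly when the truth is absent from the classification database
#' (a sequence the classifier *should* leave unassigned).
#'
#' @param truth Truth label at the rank (`NA` treated as not-in-db).
#' @param predicted Character vector of predicted labels (possibly
#'   empty), or a `";"`-joined string.
#' @param truth_in_db Is the truth label present in the reference
#'   database at this rank?
#' @return One of `"correct_assigned"`, `"incorrect_assigned"`,
#'   `"correct_unassigned"`, `"incorrect_unassigned"`.
#' @export
judge <- function(truth, predicted, truth_in_db) {
  if (length(predicted) == 1L && (is.na(predicted) || grepl(";", predicted))) {
    predicted <- if (is.na(predicted)) character(0) else split_labels(predicted)
  }
  predicted <- predicted[!is.na(predicted)]
  if (length(predicted) > 0L) {
    if (!is.na(truth) && truth %in% predicted) "correct_assigned"
    else "incorrect_assigned"
  } else {
    if (isTRUE(truth_in_db)) "incorrect_unassigned" else "correct_unassigned"
  }
}

#' Judge a full assignment table
#'
#' @param assignments Tibble from [classify_queries()].
#' @param truth Tibble: `id` plus one truth column per rank.
#' @param db_taxonomy Taxonomy tibble of the sequences actually in the
#'   classification database, used to decide `truth_in_db` per rank.
#' @param ranks Ranks to evaluate.
#' @return Outcomes tibble: `id`, `rank`, `outcome`, `n_labels`,
#'   `truth_in_db`.
#' @export
evaluate_assignments <- function(assignments, truth, db_taxonomy,
                                 ranks = rank_levels()) {
  db_labels <- lapply(setNames(ranks, ranks), function(r) {
    unique(stats::na.omit(db_taxonomy[[r]]))
  })
  purrr::map_dfr(ranks, function(r) {
    tr <- truth[[r]][match(assignments$id, truth$id)]
    in_db <- !is.na(tr) & tr %in% db_labels[[r]]
    purrr::map_dfr(seq_len(nrow(assignments)), function(i) {
      pred <- split_labels(assignments[[r]][i] %||% NA_character_)
      if (length(assignments[[r]][i]) == 1L && is.na(assignments[[r]][i])) {
        pred <- character(0)
      }
      tibble(id = assignments$id[i], rank = r,
             outcome = judge(tr[i], pred, in_db[i]),
             n_labels = length(pred), truth_in_db = in_db[i])
    })
  })
}

#' Ambiguity-aware classification metrics
#'
#' With the paper-style convention (`convention = "unassigned_tp"`,
#' the default) correct non-assignments count as true positives:
#' `TP = correct_assigned + correct_unassigned`,
#' `FP = incorrect_assigned`, `FN = incorrect_unassigned`;
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `accuracy =
#' TP/total`, `F1` the harmonic mean. The `"standard"` convention
#' treats correct non-assignments as true negatives instead.
#' Zero denominators yield `NA` ("undefined, reported as such").
#'
#' @param outcomes Tibble from [evaluate_assignments()].
#' @param convention `"unassigned_tp"` or `"standard"`.
#' @return One row per rank: counts, `accuracy`, `precision`, `recall`,
#'   `f1`, `n_ambiguous` (multi-label assignments) and
#'   `mean_labels_ambiguous`.
#' @export
compute_metrics <- function(outcomes, convention = c("unassigned_tp",
                                                     "standard")) {
  convention <- match.arg(convention)
  outcomes |>
    group_by(.data$rank) |>
    summarise(
      n = dplyr::n(),
      ca = sum(.data$outcome == "correct_assigned"),
      ia = sum(.data$outcome == "incorrect_assigned"),
      cu = sum(.data$outcome == "correct_unassigned"),
      iu = sum(.data$outcome == "incorrect_unassigned"),
      n_ambiguous = sum(.data$n_labels > 1),
      mean_labels_ambiguous = ifelse(.data$n_ambiguous > 0,
                                     mean(.data$n_labels[.data$n_labels > 1]),
                                     NA_real_),
      .groups = "drop"
    ) |>
    mutate(
      tp = if (convention == "unassigned_tp") .data$ca + .data$cu else .data$ca,
      tn = if (convention == "unassigned_tp") 0L else .data$cu,
      precision = safe_div(.data$tp, .data$tp + .data$ia),
      recall = safe_div(.data$tp, .data$tp + .data$iu),
      f1 = ifelse(is.na(.data$precision) | is.na(.data$recall) |
                    (.data$precision + .data$recall) == 0, NA_real_,
                  2 * .data$precision * .data$recall /
                    (.data$precision + .data$recall)),
      accuracy = (.data$tp + .data$tn) / .data$n
    ) |>
    arrange(match(.data$rank, rank_levels())) |>
    select("rank", "n", "ca", "ia", "cu", "iu", "accuracy", "precision",
           "recall", "f1", "n_ambiguous", "mean_labels_ambiguous")
}

safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Precision-recall sweep over the species threshold multiplier
#'
#' Re-runs species-level assignment over a grid of species threshold
#' multipliers (default 0 to 1.95), reusing cached alignments and
#' placements: only node labeling and assignment are recomputed per
#' multiplier. Precision/recall are at the Species rank under the
#' paper-style accounting of [compute_metrics()].
#'
#' @param queries Query tibble (`id`, `seq`).
#' @param reference Region slice.
#' @param tree Reference tree.
#' @param taxonomy Taxonomy tibble for the reference.
#' @param thresholds A `threshold_set` (multiplier ignored; swept).
#' @param truth Truth tibble (`id` + rank columns).
#' @param multipliers Multiplier grid; endpoints 0 and 1.95 by default.
#' @param ... Passed to [classify_queries()] (e.g. `min_cov`, `top_k`).
#' @return Tibble: `multiplier`, `precision`, `recall`, `f1`,
#'   `n_assigned`.
#' @export
pr_sweep <- function(queries, reference, tree, taxonomy, thresholds, truth,
                     multipliers = seq(0, 1.95, by = 0.15), ...) {
  ix <- tree_index(tree)
  alns <- align_queries(queries, reference) |> qc_coverage()
  placements <- lapply(seq_len(nrow(alns)), function(i) {
    if (!alns$keep[i]) return(NULL)
    pl <- place_query(alns[i, ], tree, reference, source = "internal")
    if (nrow(pl) == 0L) NULL else filter_placements(pl)
  })
  purrr::map_dfr(multipliers, function(m) {
    ts <- thresholds
    ts$multiplier <- m
    ts$mode <- "custom"
    labeling <- propagate(tree, taxonomy, ts)
    assignments <- purrr::map_dfr(seq_len(nrow(alns)), function(i) {
      pl <- placements[[i]]
      sp <- if (is.null(pl)) NA_character_ else {
        res <- lapply(seq_len(nrow(pl)), function(j) {
          assign_from_placement(pl[j, ], labeling, ts, index = ix)
        })
        comb <- combine_placements(res)
        if (length(comb$sets$Species) == 0L) NA_character_
        else render_labels(comb$sets$Species)
      }
      tibble(id = alns$id[i], Species = sp)
    })
    out <- evaluate_assignments(assignments, truth, taxonomy,
                                ranks = "Species")
    met <- compute_metrics(out)
    tibble(multiplier = m, precision = met$precision, recall = met$recall,
           f1 = met$f1, n_assigned = sum(!is.na(assignments$Species)))
  })
}

#' Plot a precision-recall sweep
#'
#' @param sweep Tibble from [pr_sweep()].
#' @return A ggplot of the precision-recall curve, points labeled by
#'   multiplier.
#' @export
plot_pr_curve <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$multiplier)) +
    ggplot2::labs(x = "recall", y = "precision",
                  colour = "species threshold\nmultiplier")
}

#' Construct a holdout query set from a reference database
#'
#' Sampled sequences are removed from the classification database and
#' returned (degapped, `N`-free) as queries with a truth table.
#' Schemes:
#'
#' * `per-genus-rate`: per genus, `max(ceiling(rate * n), min_n)`
#'   sequences (all available if fewer) - the "1% or at least five"
#'   rule,
#' * `random-n`: `n` sequences uniformly at random,
#' * `single-rep-genus`: one random sequence per genus,
#' * `genus-outside-db`: all sequences of `n_genera` random genera, so
#'   every truth genus is absent from the remaining database and
#'   correct behavior is non-assignment at genus/species.
#'
#' @param reference Region slice tibble.
#' @param taxonomy Taxonomy tibble covering the reference.
#' @param scheme Holdout scheme (above).
#' @param rate,min_n,n,n_genera Scheme parameters.
#' @param seed Optional RNG seed for reproducible sampling.
#' @return List: `db` (remaining slice), `db_taxonomy`, `queries`
#'   (tibble `id`, `seq`, degapped), `truth` (tibble `id` + rank
#'   columns).
#' @export
build_holdout <- function(reference, taxonomy,
                          scheme = c("per-genus-rate", "random-n",
                                     "single-rep-genus", "genus-outside-db"),
                          rate = 0.01, min_n = 5L, n = 10L, n_genera = 1L,
                          seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  tax <- taxonomy[match(reference$id, taxonomy$id), ]
  genus <- tax$Genus
  ids <- reference$id

  pick <- switch(scheme,
    "per-genus-rate" = {
      unlist(lapply(split(ids, genus), function(g) {
        take <- min(length(g), max(ceiling(rate * length(g)), min_n))
        sample(g, take)
      }), use.names = FALSE)
    },
    "random-n" = {
      if (n > length(ids)) abort("n exceeds database size")
      sample(ids, n)
    },
    "single-rep-genus" = {
      vapply(split(ids, genus), function(g) sample(g, 1L), character(1))
    },
    "genus-outside-db" = {
      gen <- unique(stats::na.omit(genus))
      if (n_genera > length(gen) - 1L) {
        abort("n_genera would empty the database of genera")
      }
      out_gen <- sample(gen, n_genera)
      ids[!is.na(genus) & genus %in% out_gen]
    })
  if (length(pick) == 0L) abort("holdout scheme selected no sequences")
  held <- reference$id %in% pick
  queries <- tibble(id = reference$id[held],
                    seq = degap(reference$seq[held])) |>
    dplyr::filter(!grepl("N", .data$seq, fixed = TRUE))
  db <- reference[!held, , drop = FALSE]
  for (a in c("start", "end")) attr(db, a) <- attr(reference, a)
  if (nrow(db) < 3L) abort("holdout would leave fewer than 3 database sequences")
  list(db = db,
       db_taxonomy = taxonomy[taxonomy$id %in% db$id, ],
       queries = queries,
       truth = taxonomy[match(queries$id, taxonomy$id), ])
}
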