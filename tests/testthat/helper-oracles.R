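# Independent brute-force oracles used across tests. These deliberately
# avoid the package's traversal code paths: everything is computed from
# the full cophenetic matrix or by exhaustive enumeration.

# all-pairs path-sum distances via ape (matrix form)
oracle_cophenetic <- function(tree) ape::cophenetic.phylo(tree)

# descendant tip labels of every node, from the edge table only
oracle_tipsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- lapply(seq_len(n_node), function(v) {
    if (v <= n_tip) return(tree$tip.label[v])
    tree$tip.label[unlist(phangorn::Descendants(tree, v, "tips"))]
  })
  sets
}

# maximal nodes with tip diameter < t, by checking every node against the
# cophenetic matrix and discarding nodes with a qualifying proper ancestor
oracle_cut <- function(tree, t) {
  dm <- oracle_cophenetic(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- oracle_tipsets(tree)
  diam <- vapply(sets, function(s) {
    if (length(s) == 1L) 0 else max(dm[s, s])
  }, numeric(1))
  qualifies <- diam < t
  parent <- integer(n_node)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  has_qual_ancestor <- vapply(seq_len(n_node), function(v) {
    p <- parent[v]
    while (p != 0L) {
      if (qualifies[p]) return(TRUE)
      p <- parent[p]
    }
    FALSE
  }, logical(1))
  # maximal qualifying nodes, plus tips with no qualifying ancestor
  maximal <- which(qualifies & !has_qual_ancestor)
  orphan_tips <- which(seq_len(n_node) <= n_tip & !qualifies & !has_qual_ancestor)
  nodes <- sort(unique(c(maximal, orphan_tips)))
  lapply(nodes, function(v) sort(sets[[v]]))
}

# over-merge / over-split errors from first principles on a list of
# tip-label groups
oracle_score <- function(groups, labels) {
  per_group <- lapply(groups, function(ids) {
    l <- labels[ids]
    l[!is.na(l)]
  })
  per_group <- per_group[lengths(per_group) > 0]
  over_merge <- sum(vapply(per_group, function(l) length(unique(l)) - 1L,
                           integer(1)))
  majors <- vapply(per_group, function(l) {
    tab <- sort(table(l), decreasing = TRUE)
    best <- names(tab)[tab == max(tab)]
    sort(best)[1]
  }, character(1))
  over_split <- length(majors) - length(unique(majors))
  list(over_merge = over_merge, over_split = over_split,
       n_labeled = sum(lengths(per_group)))
}

# exact binomial upper tail by explicit summation (no pbinom)
oracle_binom_tail <- function(k, n, p) {
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

oracle_dominant <- function(counts, error_rate = 0.05, error_prob = 0.20) {
  n <- sum(counts)
  pass <- vapply(counts, function(k) {
    oracle_binom_tail(k, n, error_rate) <= error_prob
  }, logical(1))
  out <- if (any(pass)) names(counts)[pass] else names(counts)
  sort(out)
}

# random labeled tree for property tests
random_labeled_tree <- function(n_tips, n_taxa = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n_tips)
  tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
  labels <- setNames(sample(paste0("tax", seq_len(n_taxa)), n_tips,
                            replace = TRUE), tree$tip.label)
  list(tree = tree, labels = labels)
}

# taxonomy tibble with a single rank of interest filled in
labels_as_taxonomy <- function(labels, rank = "Genus") {
  tax <- tibble::tibble(id = names(labels))
  for (r in rank_levels()) tax[[r]] <- NA_character_
  tax[[rank]] <- unname(labels)
  tax
}
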