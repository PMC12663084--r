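#' Specify a synthetic reference fixture
#'
#' Describes a rank-nested random phylogeny whose clades *are* taxa by
#' construction, with sequences evolved along it. Defaults give a small
#' but fully structured database: 2 phyla x 2 classes x 1 order x 2
#' families x 2 genera x 2 species x 3 sequences = 96 tips of 1500 bp
#' (full-length marker-gene scale). The per-rank branch-length scales
#' mirror typical 16S rRNA divergence ladders - within-species tip
#' diameters under 1%, between-species distances ~3%, between-genus
#' ~9%, and so on - so within-taxon diameters and between-taxon
#' distances are separated at every rank and threshold recovery is
#' well-posed.
#'
#' @param counts Named integer vector: number of child taxa per parent
#'   at each rank Phylum..Species.
#' @param seqs_per_species Tip sequences per species.
#' @param branch_lengths Per-rank branch length (expected substitutions
#'   per site) of the edge leading into each taxon at that rank.
#' @param tip_length Branch length of each tip (sequence) edge.
#' @param seq_length Alignment length in columns.
#' @param region Optional `c(start, end)` 0-based half-open column
#'   window emulating a primer-trimmed region (default: full length).
#' @param gap_rate Per-site probability of decorating a database
#'   sequence position with a gap.
#' @param label_swap_rate Fraction of tips whose *database* lineage is
#'   replaced by another random tip's lineage (annotation error); truth
#'   is recorded before swapping.
#' @param seed RNG seed; fixtures are byte-identical given a seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(counts = c(Phylum = 2, Class = 2, Order = 1,
                                    Family = 2, Genus = 2, Species = 2),
                         seqs_per_species = 3,
                         branch_lengths = c(Phylum = 0.30, Class = 0.15,
                                            Order = 0.08, Family = 0.05,
                                            Genus = 0.03, Species = 0.012),
                         tip_length = 0.003,
                         seq_length = 1500,
                         region = NULL,
                         gap_rate = 0,
                         label_swap_rate = 0,
                         seed = 1L) {
  stopifnot(all(counts >= 1), seqs_per_species >= 1,
            all(branch_lengths > 0), tip_length > 0,
            gap_rate >= 0, gap_rate <= 1,
            label_swap_rate >= 0, label_swap_rate <= 1)
  structure(list(counts = counts, seqs_per_species = seqs_per_species,
                 branch_lengths = branch_lengths, tip_length = tip_length,
                 seq_length = seq_length,
                 region = region %||% c(0L, seq_length),
                 gap_rate = gap_rate, label_swap_rate = label_swap_rate,
                 seed = seed),
            class = "fixture_spec")
}

#' Simulate a reference fixture
#'
#' Builds the rank-nested tree described by a [fixture_spec()], evolves
#' sequences along it under a Jukes-Cantor-style substitution process
#' (per-site substitution probability `3/4 (1 - exp(-4d/3))` for branch
#' length `d`), and emits an aligned (gapless unless decorated)
#' database, its taxonomy, the true tree, and a clean truth table.
#' Label swaps, if any, are applied to the returned `taxonomy` after
#' `truth` is recorded.
#'
#' @param spec A `fixture_spec`.
#' @return List: `db` (tibble `id`, `seq`), `taxonomy` (tibble,
#'   possibly with swapped labels), `truth` (clean taxonomy), `tree`
#'   (`ape::phylo`, tips = sequence ids), `spec`.
#' @export
simulate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  ranks6 <- threshold_ranks()
  counts <- spec$counts[ranks6]
  blen <- spec$branch_lengths[ranks6]

  env <- new.env()
  env$tip_i <- 0L
  env$rows <- list()
  prefixes <- c(Phylum = "P", Class = "C", Order = "O", Family = "F",
                Genus = "G", Species = "S")

  rec <- function(level, path, lineage) {
    if (level > 6L) {
      # species node: spawn tip sequences
      subs <- vapply(seq_len(spec$seqs_per_species), function(i) {
        env$tip_i <- env$tip_i + 1L
        id <- sprintf("seq%04d", env$tip_i)
        env$rows[[env$tip_i]] <- c(id = id, lineage)
        paste0(id, ":", format(spec$tip_length, scientific = FALSE))
      }, character(1))
      return(paste0("(", paste(subs, collapse = ","), "):0"))
    }
    rank <- ranks6[level]
    subs <- vapply(seq_len(counts[[rank]]), function(j) {
      p <- c(path, j)
      name <- paste0(prefixes[[rank]], paste(p, collapse = "."))
      lin <- lineage
      lin[[rank]] <- if (rank == "Species") {
        paste(lineage[["Genus"]], paste0("sp", j))
      } else {
        name
      }
      sub <- rec(level + 1L, p, lin)
      # wrap child under the taxon-defining edge
      inner <- sub
      paste0(sub_root(inner),
             ":", format(blen[[rank]], scientific = FALSE))
    }, character(1))
    paste0("(", paste(subs, collapse = ","), "):0")
  }
  sub_root <- function(s) sub(":0$", "", s)

  lineage0 <- setNames(as.list(rep(NA_character_, 7L)), rank_levels())
  lineage0[["Kingdom"]] <- "Bacteria"
  newick <- paste0(sub_root(rec(1L, integer(0), lineage0)), ";")
  tree <- ape::read.tree(text = newick)
  tree <- ape::collapse.singles(tree)

  truth <- dplyr::bind_rows(lapply(env$rows, function(r) {
    as_tibble(as.list(r))
  }))

  # evolve sequences preorder from a random root sequence
  ix <- tree_index(tree)
  bases <- c("A", "C", "G", "T")
  seqs <- vector("list", ix$n_node)
  seqs[[ix$root]] <- sample(bases, spec$seq_length, replace = TRUE)
  for (v in preorder_nodes(ix$children, ix$root)) {
    if (v == ix$root) next
    parent_seq <- seqs[[ix$parent[v]]]
    d <- ix$edge_len_to_parent[v]
    p_sub <- 0.75 * (1 - exp(-4 * d / 3))
    hit <- runif(spec$seq_length) < p_sub
    child <- parent_seq
    if (any(hit)) {
      child[hit] <- vapply(parent_seq[hit], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1))
    }
    seqs[[v]] <- child
  }
  db <- tibble(
    id = tree$tip.label,
    seq = vapply(seq_len(ix$n_tip), function(i) {
      s <- seqs[[i]]
      if (spec$gap_rate > 0) {
        g <- runif(length(s)) < spec$gap_rate
        s[g] <- "-"
      }
      paste(s, collapse = "")
    }, character(1))
  )
  truth <- truth[match(db$id, truth$id), ]

  taxonomy <- truth
  if (spec$label_swap_rate > 0) {
    n <- nrow(taxonomy)
    swap <- which(runif(n) < spec$label_swap_rate)
    for (i in swap) {
      donor <- sample(setdiff(seq_len(n), i), 1L)
      taxonomy[i, rank_levels()] <- truth[donor, rank_levels()]
    }
    attr(taxonomy, "n_swapped") <- length(swap)
  }
  list(db = db, taxonomy = taxonomy, truth = truth, tree = tree, spec = spec)
}

#' Derive holdout queries from a fixture
#'
#' Region-trims the fixture database to the spec's window, applies a
#' holdout scheme (see [build_holdout()]), and optionally mutates the
#' query sequences (per-site substitution rate `mutation_rate`,
#' emulating sequencing divergence).
#'
#' @param fixture Result of [simulate_fixture()].
#' @param scheme,... Passed to [build_holdout()].
#' @param mutation_rate Per-site substitution probability applied to
#'   queries after holdout.
#' @param seed RNG seed for sampling and mutation.
#' @return As [build_holdout()], with the regional slice as `db`.
#' @export
make_queries <- function(fixture, scheme = "per-genus-rate",
                         mutation_rate = 0, seed = NULL, ...) {
  slice <- region_slice(fixture$db, fixture$spec$region[1],
                        fixture$spec$region[2])
  hold <- build_holdout(slice, fixture$truth, scheme = scheme,
                        seed = seed, ...)
  if (mutation_rate > 0) {
    bases <- c("A", "C", "G", "T")
    hold$queries$seq <- vapply(hold$queries$seq, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- runif(length(ch)) < mutation_rate & ch %in% bases
      if (any(hit)) {
        ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L),
                          character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  hold
}
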