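#' Read a jplace placement file
#'
#' Parses the standard jplace JSON (version 3 dialect): the reference
#' tree with `{edge_num}` annotations, the `fields` vector, and the
#' per-query placements. Edge numbers are mapped to the child node of
#' each edge in ape numbering, which is how placements are consumed
#' downstream (the child node is the "index node" of an assignment).
#'
#' @param path jplace JSON path.
#' @return A `jplace` object: `tree` (`ape::phylo`), `edge_map` (named
#'   integer: edge number -> child node id), `placements` tibble
#'   (`name`, `edge_num`, `like_weight_ratio`, `pendant_length`,
#'   `distal_length`, `node`), `version`, `fields`.
#' @export
read_jplace <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$tree)) abort("jplace file has no tree")
  parsed <- parse_jplace_tree(x$tree)
  fields <- unlist(x$fields)
  need <- c("edge_num", "like_weight_ratio", "pendant_length")
  if (!all(need %in% fields)) {
    abort(paste0("jplace fields missing: ",
                 paste(setdiff(need, fields), collapse = ", ")))
  }
  rows <- purrr::map_dfr(x$placements, function(pl) {
    names_of <- if (!is.null(pl$n)) {
      unlist(pl$n)
    } else if (!is.null(pl$nm)) {
      vapply(pl$nm, function(e) as.character(e[[1]]), character(1))
    } else {
      abort("jplace placement without 'n' or 'nm'")
    }
    per <- purrr::map_dfr(pl$p, function(p) {
      vals <- setNames(as.numeric(unlist(p)), fields)
      tibble(edge_num = as.integer(vals[["edge_num"]]),
             like_weight_ratio = vals[["like_weight_ratio"]],
             pendant_length = vals[["pendant_length"]],
             distal_length = if ("distal_length" %in% fields)
               vals[["distal_length"]] else 0)
    })
    tidyr::crossing(tibble(name = names_of), per)
  })
  bad <- setdiff(unique(rows$edge_num), as.integer(names(parsed$edge_map)))
  if (length(bad) > 0L) {
    abort(paste0("jplace placements reference unknown edges: ",
                 paste(bad, collapse = ", ")))
  }
  rows$node <- unname(parsed$edge_map[as.character(rows$edge_num)])
  rows <- arrange(rows, .data$name, dplyr::desc(.data$like_weight_ratio))
  structure(list(tree = parsed$tree, edge_map = parsed$edge_map,
                 placements = rows,
                 version = x$version %||% 3, fields = fields),
            class = "jplace")
}

# jplace trees attach "{k}" to the edge above each node; encode the edge
# number into the node label, read with ape, then recover the mapping
parse_jplace_tree <- function(tree_string) {
  s <- tree_string
  s <- gsub("\\):([0-9.eE+-]+)\\{(\\d+)\\}", ")##\\2:\\1", s)          # internal
  s <- gsub("([^(),:]+):([0-9.eE+-]+)\\{(\\d+)\\}", "\\1##\\3:\\2", s) # tips
  s <- gsub("\\{\\d+\\}", "", s)                                       # e.g. root
  tree <- ape::read.tree(text = s)
  if (is.null(tree)) abort("could not parse jplace tree string")
  n_tip <- length(tree$tip.label)
  edge_map <- integer(0)
  grab <- function(labels, offset) {
    hit <- grepl("##\\d+$", labels)
    num <- as.integer(sub("^.*##", "", labels[hit]))
    setNames(which(hit) + offset, num)
  }
  edge_map <- c(grab(tree$tip.label, 0L),
                if (!is.null(tree$node.label)) grab(tree$node.label, n_tip))
  tree$tip.label <- sub("##\\d+$", "", tree$tip.label)
  if (!is.null(tree$node.label)) {
    tree$node.label <- sub("##\\d+$", "", tree$node.label)
  }
  storage.mode(edge_map) <- "integer"
  list(tree = tree, edge_map = edge_map[order(as.integer(names(edge_map)))])
}

#' Write a jplace placement file
#'
#' Serializes a `jplace` object (or an internally-placed result) back to
#' version-3 jplace JSON. Round-trips the fields used by the classifier.
#'
#' @param jp A `jplace` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(jp, path) {
  tree_str <- jplace_tree_string(jp$tree, jp$edge_map)
  fields <- c("edge_num", "like_weight_ratio", "pendant_length",
              "distal_length")
  placements <- jp$placements |>
    group_by(.data$name) |>
    dplyr::group_map(function(rows, key) {
      list(p = lapply(seq_len(nrow(rows)), function(i) {
        list(rows$edge_num[i], rows$like_weight_ratio[i],
             rows$pendant_length[i], rows$distal_length[i])
      }),
      n = list(key$name))
    })
  jsonlite::write_json(
    list(version = 3, tree = tree_str, fields = fields,
         placements = placements, metadata = list(invocation = "phylotaxa")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# newick with {edge_num} after each branch length
jplace_tree_string <- function(tree, edge_map) {
  ix <- tree_index(tree)
  node_edge <- setNames(as.integer(names(edge_map)), edge_map)
  rec <- function(v) {
    len <- ix$edge_len_to_parent[v]
    en <- node_edge[as.character(v)]
    suffix <- if (v == ix$root) "" else {
      paste0(":", format(len, scientific = FALSE),
             if (!is.na(en)) paste0("{", en, "}") else "")
    }
    if (v <= ix$n_tip) {
      paste0(tree$tip.label[v], suffix)
    } else {
      paste0("(", paste(vapply(ix$children[[v]], rec, character(1)),
                        collapse = ","), ")", suffix)
    }
  }
  paste0(rec(ix$root), ";")
}

# default numbering (child node -> its own id) used when we synthesize
# jplace output from internal placements
default_edge_map <- function(tree) {
  ix <- tree_index(tree)
  nodes <- setdiff(seq_len(ix$n_node), ix$root)
  setNames(as.integer(nodes), seq_along(nodes) - 1L)
}

#' Place a query into the reference tree
#'
#' `source = "jplace"` looks the query up in placements parsed with
#' [read_jplace()]. `source = "internal"` is the built-in distance-based
#' placer: the `top_k` reference tips sharing the most k-mers with the
#' query are taken as candidate attachment edges, each scored by the
#' Jukes-Cantor distance between the projected query row and that tip's
#' row (pairwise deletion); scores are converted to normalized weights
#' `w_i ~ exp(-L * (d_i - min d))` (`L` = compared sites), an analog of
#' the likelihood weight ratio; an exact sequence match (distance 0)
#' pins the placement to the matching tip(s). The placement attaches at
#' the tip node:
#' `distal_length = 0` (distance from the attachment point to the child
#' node of the edge) and `pendant_length = d_i`.
#'
#' @param alignment One-row tibble from [align_query()].
#' @param tree Reference `ape::phylo`.
#' @param reference Region slice the tree was built from.
#' @param source `"internal"` or `"jplace"`.
#' @param jplace A `jplace` object (required for `source = "jplace"`).
#' @param top_k Candidate count for the internal placer.
#' @param k k-mer size for candidate search.
#' @param ref_kmers Optional precomputed reference k-mer sets.
#' @return Tibble of placements: `name`, `node` (child node id),
#'   `like_weight_ratio`, `pendant_length`, `distal_length`, ordered by
#'   decreasing weight. Zero rows if the query cannot be placed.
#' @export
place_query <- function(alignment, tree, reference,
                        source = c("internal", "jplace"), jplace = NULL,
                        top_k = 5L, k = 8L, ref_kmers = NULL) {
  source <- match.arg(source)
  if (source == "jplace") {
    if (is.null(jplace)) abort("source='jplace' needs a jplace object")
    rows <- dplyr::filter(jplace$placements, .data$name == alignment$id)
    return(select(rows, "name", "node", "like_weight_ratio",
                  "pendant_length", "distal_length"))
  }
  stopifnot(nrow(alignment) == 1L)
  qk <- kmer_set(alignment$seq, k)
  ref_kmers <- ref_kmers %||% lapply(reference$seq, kmer_set, k = k)
  shared <- vapply(ref_kmers, function(rk) sum(qk %in% rk), integer(1))
  ord <- order(-shared, reference$id)
  cand <- head(ord, top_k)
  qchars <- strsplit(alignment$seq, "")[[1]]
  scored <- purrr::map_dfr(cand, function(i) {
    rchars <- strsplit(reference$seq[i], "")[[1]]
    both <- qchars != "-" & rchars != "-"
    n_sites <- sum(both)
    if (n_sites == 0L) return(tibble())
    p_mm <- sum(qchars[both] != rchars[both]) / n_sites
    d <- jc_correct(p_mm)
    tibble(tip = reference$id[i], d = d, n_sites = n_sites)
  })
  if (nrow(scored) == 0L) return(tibble(
    name = character(0), node = integer(0), like_weight_ratio = numeric(0),
    pendant_length = numeric(0), distal_length = numeric(0)))
  if (min(scored$d) == 0) {
    # exact matches pin the placement
    scored <- scored[scored$d == 0, , drop = FALSE]
  }
  w <- exp(-(scored$d - min(scored$d)) * scored$n_sites)
  scored$lwr <- w / sum(w)
  node <- match(scored$tip, tree$tip.label)
  out <- tibble(name = alignment$id, node = node,
                like_weight_ratio = scored$lwr,
                pendant_length = scored$d, distal_length = 0) |>
    dplyr::filter(!is.na(.data$node)) |>
    arrange(dplyr::desc(.data$like_weight_ratio))
  out
}

jc_correct <- function(p) {
  if (p >= 0.749) return(5)          # saturated; effectively unplaceable
  -0.75 * log(1 - 4 * p / 3)
}

#' Filter placements by likelihood weight ratio
#'
#' Keeps placements whose LWR is within 50% of the best one (boundary
#' inclusive): `lwr >= frac * max(lwr)`.
#'
#' @param placements Tibble from [place_query()].
#' @param frac Fraction of the maximum LWR to keep (default 0.5).
#' @return Filtered tibble.
#' @export
filter_placements <- function(placements, frac = 0.5) {
  if (nrow(placements) == 0L) return(placements)
  dplyr::filter(placements,
                .data$like_weight_ratio >=
                  frac * max(.data$like_weight_ratio))
}
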