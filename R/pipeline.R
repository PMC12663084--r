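#' Build a primer-specific labeled reference set
#'
#' End-to-end reference preparation: optional in-silico PCR trimming of
#' the aligned database to the primer region (or an explicit column
#' window), sequence quality filtering, tree construction (internal
#' neighbor joining or an externally supplied Newick), per-rank
#' threshold optimization, and propagation of tip taxonomy to interior
#' nodes. The result bundles everything [classify_queries()] needs.
#'
#' @param db Aligned database tibble ([read_alignment()]).
#' @param taxonomy Taxonomy tibble ([parse_taxonomy()]).
#' @param primers Optional one-row tibble (`name`, `forward`,
#'   `reverse`), see [read_primer_file()].
#' @param region Optional `c(start, end)` 0-based half-open column
#'   window (used when `primers` is `NULL`).
#' @param tree Optional external tree (path, Newick string or `phylo`);
#'   otherwise an internal NJ tree is built.
#' @param mode Species-specificity mode, see [specificity_mode()].
#' @param min_ungapped_len,drop_N Passed to [filter_sequences()].
#' @param keep_primers Passed to [trim_to_region()].
#' @param n_grid Threshold grid size ([find_thresholds()]).
#' @param hierarchical Passed to [propagate()].
#' @return A `reference_set`: list with `reference` (region slice),
#'   `taxonomy`, `tree`, `thresholds`, `labeling`.
#' @export
build_reference_set <- function(db, taxonomy, primers = NULL, region = NULL,
                                tree = NULL,
                                mode = c("specific", "sensitive"),
                                min_ungapped_len = 0, drop_N = TRUE,
                                keep_primers = FALSE, n_grid = 200,
                                hierarchical = TRUE) {
  mode <- match.arg(mode)
  validate_alignment(db)
  missing_tax <- setdiff(db$id, taxonomy$id)
  if (length(missing_tax) > 0L) {
    abort(paste0("database sequences absent from taxonomy: ",
                 paste(head(missing_tax, 5), collapse = ", ")))
  }
  slice <- if (!is.null(primers)) {
    fwd <- find_primer_site(db, primers$forward[1], "forward")
    rev <- find_primer_site(db, primers$reverse[1], "reverse")
    trim_to_region(db, fwd, rev, keep_primers = keep_primers)
  } else if (!is.null(region)) {
    region_slice(db, region[1], region[2])
  } else {
    region_slice(db, 0L, nchar(db$seq[1]))
  }
  slice <- filter_sequences(slice, min_ungapped_len = min_ungapped_len,
                            drop_N = drop_N)
  tr <- if (is.null(tree)) {
    build_region_tree(slice, "internal-nj")
  } else {
    build_region_tree(slice, "external-newick", newick = tree)
  }
  ts <- find_thresholds(tr, taxonomy, n_grid = n_grid, mode = mode)
  labeling <- propagate(tr, taxonomy, ts, hierarchical = hierarchical)
  structure(list(reference = slice,
                 taxonomy = taxonomy[taxonomy$id %in% slice$id, ],
                 tree = tr, thresholds = ts, labeling = labeling),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>", nrow(x$reference), "sequences,",
      length(x$tree$tip.label), "tree tips, mode:", x$thresholds$mode, "\n")
  invisible(x)
}

#' Classify queries against a reference set
#'
#' Convenience wrapper of [classify_queries()] for a bundled
#' `reference_set`.
#'
#' @param queries Query tibble (`id`, `seq`).
#' @param rs A `reference_set`.
#' @param ... Passed to [classify_queries()].
#' @return Assignment tibble.
#' @export
classify_with <- function(queries, rs, ...) {
  classify_queries(queries, rs$reference, rs$tree, rs$labeling,
                   rs$thresholds, ...)
}

#' Write / read a reference-set bundle
#'
#' A directory containing the trimmed alignment (`reference.fasta`),
#' taxonomy (`taxonomy.tsv`), tree (`tree.nwk`), thresholds
#' (`thresholds.json`), the node annotation table (`nodes.tsv`), and a
#' `manifest.json` with provenance (package version, mode, region
#' coordinates). Node labels are regenerated deterministically on read
#' by re-running [propagate()].
#'
#' @param rs A `reference_set`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (write) or a `reference_set` (read).
#' @export
write_reference_set <- function(rs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(rs$reference, file.path(dir, "reference.fasta"))
  write_taxonomy(rs$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(rs$tree, file.path(dir, "tree.nwk"))
  write_threshold_set(rs$thresholds, file.path(dir, "thresholds.json"))
  write_node_table(rs$labeling, file.path(dir, "nodes.tsv"))
  jsonlite::write_json(
    list(package = "phylotaxa",
         version = as.character(utils::packageVersion("phylotaxa")),
         mode = rs$thresholds$mode,
         multiplier = rs$thresholds$multiplier,
         hierarchical = rs$labeling$hierarchical,
         region = list(start = attr(rs$reference, "start"),
                       end = attr(rs$reference, "end")),
         n_sequences = nrow(rs$reference)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  reference <- read_alignment(file.path(dir, "reference.fasta"))
  attr(reference, "start") <- manifest$region$start
  attr(reference, "end") <- manifest$region$end
  taxonomy <- parse_taxonomy(file.path(dir, "taxonomy.tsv"))
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  thresholds <- read_threshold_set(file.path(dir, "thresholds.json"))
  labeling <- propagate(tree, taxonomy, thresholds,
                        hierarchical = manifest$hierarchical %||% TRUE)
  structure(list(reference = reference, taxonomy = taxonomy, tree = tree,
                 thresholds = thresholds, labeling = labeling),
            class = "reference_set")
}
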