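#' Locate a primer binding site in an aligned database
#'
#' In-silico PCR against an aligned reference: each sequence's ungapped
#' text is scanned for an IUPAC-compatible primer match (at most
#' `max_mismatch` mismatching positions; a template `N` matches anything),
#' the best (fewest-mismatch, leftmost) hit is mapped back to alignment
#' columns, and the modal column interval across sequences is returned.
#' Reverse primers are reverse-complemented before scanning, so both
#' primers can be given 5'->3' on their own strand.
#'
#' @param db Aligned database tibble (`id`, `seq`), see [read_alignment()].
#' @param primer IUPAC primer sequence.
#' @param orientation `"forward"` or `"reverse"`.
#' @param max_mismatch Allowed mismatches per hit (default 0, strict).
#' @param min_frac Minimum fraction of sequences that must contain a hit.
#' @return Integer vector `c(start, end)`: 0-based half-open alignment
#'   column interval of the binding site.
#' @export
find_primer_site <- function(db, primer, orientation = c("forward", "reverse"),
                             max_mismatch = 0, min_frac = 0.5) {
  orientation <- match.arg(orientation)
  validate_alignment(db)
  primer <- gsub("U", "T", toupper(primer), fixed = TRUE)
  if (!nzchar(primer)) abort("empty primer")
  if (orientation == "reverse") primer <- iupac_revcomp(primer)
  allowed <- lapply(strsplit(primer, "")[[1]], iupac_expand)
  p_len <- length(allowed)

  intervals <- vapply(db$seq, function(gapped) {
    chars <- strsplit(gapped, "")[[1]]
    keep <- chars != "-"
    ungapped <- chars[keep]
    m <- length(ungapped)
    if (m < p_len) return(c(NA_integer_, NA_integer_))
    npos <- m - p_len + 1L
    mism <- integer(npos)
    for (j in seq_len(p_len)) {
      tmpl <- ungapped[seq_len(npos) + j - 1L]
      ok <- tmpl %in% allowed[[j]] | tmpl == "N"
      mism <- mism + !ok
    }
    best <- min(mism)
    if (best > max_mismatch) return(c(NA_integer_, NA_integer_))
    hit <- which(mism == best)[1]          # leftmost best hit (ungapped, 1-based)
    cols <- which(keep)                    # ungapped index -> alignment column
    c(cols[hit] - 1L, cols[hit + p_len - 1L])  # 0-based half-open
  }, integer(2))

  found <- !is.na(intervals[1, ])
  if (mean(found) < min_frac) {
    abort(paste0("primer not located: matched ",
                 round(100 * mean(found), 1), "% of sequences (need >= ",
                 round(100 * min_frac, 1), "%)"))
  }
  key <- paste(intervals[1, found], intervals[2, found])
  modal <- names(sort(table(key), decreasing = TRUE))[1]
  as.integer(strsplit(modal, " ")[[1]])
}

#' Trim an aligned database to a primer-delimited region
#'
#' A pure column slice in alignment coordinates, so trimmed sequences stay
#' aligned. With `keep_primers = FALSE` (default) the slice spans the
#' columns strictly between the forward and reverse binding sites.
#' Sequences whose region is entirely gaps are dropped (count recorded in
#' the `n_dropped` attribute).
#'
#' @param db Aligned database tibble.
#' @param fwd_site,rev_site 0-based half-open column intervals from
#'   [find_primer_site()].
#' @param keep_primers Keep the primer-binding columns in the slice?
#' @return Region slice: tibble (`id`, `seq`) with attributes `start`,
#'   `end` (0-based half-open columns) and `n_dropped`.
#' @export
trim_to_region <- function(db, fwd_site, rev_site, keep_primers = FALSE) {
  validate_alignment(db)
  if (fwd_site[2] > rev_site[1]) abort("forward site must precede reverse site")
  if (keep_primers) {
    start <- fwd_site[1]; end <- rev_site[2]
  } else {
    start <- fwd_site[2]; end <- rev_site[1]
  }
  region_slice(db, start, end)
}

# cut columns [start, end) (0-based) and drop all-gap rows
region_slice <- function(db, start, end) {
  width <- nchar(db$seq[1])
  if (start < 0 || end > width || start >= end) {
    abort("invalid region interval")
  }
  out <- tibble(id = db$id,
                seq = substr(db$seq, start + 1L, end))
  allgap <- !grepl("[^-]", out$seq)
  out <- out[!allgap, , drop = FALSE]
  if (nrow(out) == 0L) abort("no sequences left after region trimming")
  attr(out, "start") <- as.integer(start)
  attr(out, "end") <- as.integer(end)
  attr(out, "n_dropped") <- sum(allgap)
  out
}

#' Filter trimmed sequences on quality
#'
#' Removes sequences containing ambiguous `N` bases (when `drop_N`) and
#' sequences whose ungapped length is below `min_ungapped_len`.
#'
#' @param slice Region slice tibble.
#' @param min_ungapped_len Minimum ungapped length to keep.
#' @param drop_N Drop sequences containing `N`?
#' @return Filtered slice; attributes `n_dropped_N` and `n_dropped_short`
#'   record removal counts.
#' @export
filter_sequences <- function(slice, min_ungapped_len = 0, drop_N = TRUE) {
  has_n <- drop_N & grepl("N", slice$seq, fixed = TRUE)
  short <- nchar(degap(slice$seq)) < min_ungapped_len
  out <- slice[!(has_n | short), , drop = FALSE]
  if (nrow(out) == 0L) abort("no sequences left after filtering")
  for (a in c("start", "end")) attr(out, a) <- attr(slice, a)
  attr(out, "n_dropped_N") <- sum(has_n)
  attr(out, "n_dropped_short") <- sum(short & !has_n)
  out
}

#' Build or ingest the region-specific reference tree
#'
#' `"internal-nj"` computes Jukes-Cantor distances on the trimmed
#' alignment (pairwise deletion of gap positions), runs neighbor joining,
#' clamps negative branch lengths to zero and midpoint-roots the result.
#' This is a documented lightweight stand-in for a maximum-likelihood
#' GTR tree; `"external-newick"` ingests such a tree (e.g. from FastTree)
#' verbatim after validating that its tips are present in the slice, and
#' midpoint-roots it if unrooted.
#'
#' @param slice Region slice tibble.
#' @param method `"internal-nj"` or `"external-newick"`.
#' @param newick For `"external-newick"`: path to a Newick file, or a
#'   Newick string, or an `ape::phylo` object.
#' @return Rooted `ape::phylo` with branch lengths.
#' @export
build_region_tree <- function(slice, method = c("internal-nj", "external-newick"),
                              newick = NULL) {
  method <- match.arg(method)
  if (method == "external-newick") {
    tree <- if (inherits(newick, "phylo")) {
      newick
    } else if (is.character(newick) && grepl("\\(", newick)) {
      ape::read.tree(text = newick)
    } else {
      ape::read.tree(newick)
    }
    unknown <- setdiff(tree$tip.label, slice$id)
    if (length(unknown) > 0L) {
      abort(paste0("external tree has tips absent from the reference: ",
                   paste(unknown, collapse = ", ")))
    }
    if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
    return(tree)
  }
  if (nrow(slice) < 3L) abort("internal-nj needs at least 3 sequences")
  dm <- jc_distance_matrix(slice)
  tree <- ape::nj(dm)
  tree$edge.length[tree$edge.length < 0] <- 0
  phangorn::midpoint(tree)
}

# JC69 distances with pairwise deletion of gap/N positions
jc_distance_matrix <- function(slice) {
  mat <- do.call(rbind, strsplit(tolower(slice$seq), ""))
  rownames(mat) <- slice$id
  bin <- ape::as.DNAbin(mat)
  d <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
  d[is.na(d) | is.infinite(d)] <- max(d[is.finite(d)], 0) + 1
  d
}
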