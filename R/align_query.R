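# k-mer utilities for template search (shared-kmer counts, set semantics)
kmer_set <- function(seq, k = 8L) {
  s <- degap(toupper(seq))
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Align a query against a trimmed reference alignment (NAST-style)
#'
#' Template-based alignment that preserves the reference coordinate
#' frame: the reference sequence sharing the most k-mers with the query
#' is chosen as template, query and degapped template are aligned
#' globally (Needleman-Wunsch), and the query is projected into
#' alignment columns following the template's gap pattern. Query
#' insertions relative to the template are shifted into adjacent
#' template gap columns where available, otherwise trimmed (count
#' recorded). If the reverse complement of the query shares more k-mers
#' with the reference than the forward orientation, it is flipped
#' before alignment (`auto_flip`).
#'
#' Coverage is the fraction of template (ungapped) positions aligned to
#' a query base; a query missing 10 of 100 template bases has coverage
#' 0.90.
#'
#' @param query Unaligned query sequence (A/C/G/T/U/N).
#' @param reference Region slice tibble (`id`, `seq`), all rows equal
#'   aligned width.
#' @param query_id Identifier carried into the output.
#' @param k k-mer size for the template search.
#' @param match,mismatch,gap_opening,gap_extension Alignment scores.
#' @param auto_flip Consider the reverse complement?
#' @param ref_kmers Optional precomputed list of reference k-mer sets
#'   (one per reference row), reused across queries by [align_queries()].
#' @return One-row tibble: `id`, `template`, `seq` (gapped, reference
#'   width), `coverage`, `n_trimmed`, `flipped`.
#' @export
align_query <- function(query, reference, query_id = "query", k = 8L,
                        match = 1, mismatch = -1,
                        gap_opening = 4, gap_extension = 1,
                        auto_flip = TRUE, ref_kmers = NULL) {
  query <- normalize_seq(degap(query))
  if (!nzchar(query)) abort("empty query sequence")
  ref_kmers <- ref_kmers %||% lapply(reference$seq, kmer_set, k = k)

  qk <- kmer_set(query, k)
  shared_fwd <- vapply(ref_kmers, function(rk) sum(qk %in% rk), integer(1))
  best_fwd <- max(shared_fwd)
  flipped <- FALSE
  shared <- shared_fwd
  if (auto_flip) {
    qk_rc <- kmer_set(revcomp(query), k)
    shared_rc <- vapply(ref_kmers, function(rk) sum(qk_rc %in% rk), integer(1))
    if (max(shared_rc) > best_fwd) {
      query <- revcomp(query)
      shared <- shared_rc
      flipped <- TRUE
    }
  }
  cand <- which(shared == max(shared))
  template_i <- cand[order(reference$id[cand])][1]
  template <- reference$seq[template_i]

  proj <- nast_project(query, template,
                       match = match, mismatch = mismatch,
                       gap_opening = gap_opening,
                       gap_extension = gap_extension)
  tibble(id = query_id, template = reference$id[template_i],
         seq = proj$seq, coverage = proj$coverage,
         n_trimmed = proj$n_trimmed, flipped = flipped)
}

#' @rdname align_query
#' @param queries Tibble with columns `id`, `seq`.
#' @param ... Passed to [align_query()].
#' @export
align_queries <- function(queries, reference, k = 8L, ...) {
  ref_kmers <- lapply(reference$seq, kmer_set, k = k)
  purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    align_query(queries$seq[i], reference, query_id = queries$id[i], k = k,
                ref_kmers = ref_kmers, ...)
  })
}

# global NW of query vs degapped template, then projection of the query
# into the template's alignment columns; insertions go into adjacent
# template gap columns, overflow is trimmed
nast_project <- function(query, template_gapped, match = 1, mismatch = -1,
                         gap_opening = 4, gap_extension = 1) {
  tchars <- strsplit(template_gapped, "")[[1]]
  tcols <- which(tchars != "-")
  width <- length(tchars)
  t_ungapped <- paste(tchars[tcols], collapse = "")

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(t_ungapped),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]

  out <- rep("-", width)
  n_trimmed <- 0L
  buffer <- character(0)
  prev_col <- 0L
  tpos <- 0L
  n_covered <- 0L
  flush <- function(gap_cols, chars, justify) {
    # place chars into available gap columns; overflow trimmed
    n_avail <- length(gap_cols)
    n_put <- min(n_avail, length(chars))
    if (n_put > 0L) {
      use <- if (justify == "right") tail(gap_cols, n_put) else head(gap_cols, n_put)
      put <- if (justify == "right") tail(chars, n_put) else head(chars, n_put)
      out[use] <<- put
    }
    n_trimmed <<- n_trimmed + (length(chars) - n_put)
  }
  for (i in seq_along(s)) {
    if (s[i] != "-") {
      tpos <- tpos + 1L
      col <- tcols[tpos]
      if (length(buffer) > 0L) {
        gap_cols <- if (col - prev_col > 1L) {
          setdiff(seq(prev_col + 1L, col - 1L), tcols)
        } else {
          integer(0)
        }
        flush(gap_cols, buffer, "right")
        buffer <- character(0)
      }
      if (p[i] != "-") {
        out[col] <- p[i]
        n_covered <- n_covered + 1L
      }
      prev_col <- col
    } else if (p[i] != "-") {
      buffer <- c(buffer, p[i])
    }
  }
  if (length(buffer) > 0L) {
    gap_cols <- if (prev_col < width) setdiff(seq(prev_col + 1L, width), tcols) else integer(0)
    flush(gap_cols, buffer, "left")
  }
  list(seq = paste(out, collapse = ""),
       coverage = n_covered / length(tcols),
       n_trimmed = n_trimmed)
}

#' Coverage quality control
#'
#' Drops query alignments covering less than `min_cov` of their template
#' (boundary inclusive: exactly `min_cov` is kept).
#'
#' @param alignments Tibble from [align_queries()].
#' @param min_cov Minimum template coverage (default 0.80).
#' @return Input tibble with a logical `keep` column and a `reason`
#'   column (`NA` for kept rows).
#' @export
qc_coverage <- function(alignments, min_cov = 0.80) {
  alignments |>
    mutate(keep = .data$coverage >= min_cov,
           reason = ifelse(.data$coverage >= min_cov, NA_character_,
                           sprintf("coverage %.3f < %.2f", .data$coverage,
                                   min_cov)))
}
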