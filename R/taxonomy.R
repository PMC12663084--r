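#' Parse a semicolon-delimited lineage string
#'
#' Splits a lineage such as
#' `"Bacteria;Firmicutes;Bacilli;Lactobacillales;Enterococcaceae;Enterococcus;Enterococcus faecalis"`
#' into one label per rank. Curation applied on ingest:
#'
#' * subspecies / strain information is grouped to the species level: the
#'   species token is truncated to its first two whitespace-separated words
#'   (a binomial); single-word tokens are kept verbatim,
#' * tokens matching the missing-label vocabulary (case-insensitive, also
#'   matched as a leading word so `"uncultured bacterium"` counts) become
#'   `NA` ("missing designation"),
#' * tokens beyond the seventh are treated as sub-ranks and dropped.
#'
#' @param raw Non-empty lineage string, ranks separated by `";"`.
#' @param dialect `"silva"` (bare names) or `"gtdb"` (`d__`, `p__`, ...
#'   prefixes, which are validated and stripped).
#' @param missing_vocab Tokens mapped to a missing designation.
#' @return Named character vector over [rank_levels()]; `NA` = unclassified
#'   at that rank.
#' @export
#' @examples
#' parse_taxonomy_string(
#'   "Bacteria;Firmicutes;Bacilli;Lactobacillales;Enterococcaceae;Enterococcus;Enterococcus faecalis"
#' )
parse_taxonomy_string <- function(raw,
                                  dialect = c("silva", "gtdb"),
                                  missing_vocab = missing_label_vocabulary()) {
  dialect <- match.arg(dialect)
  if (length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw))) {
    abort("`raw` must be a single non-empty lineage string")
  }
  tokens <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])

  if (dialect == "gtdb") {
    prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
    for (i in seq_along(tokens)) {
      pfx <- substr(tokens[i], 1L, 3L)
      want <- prefixes[min(i, 7L)]
      if (!grepl("^[a-z]__", tokens[i])) {
        abort(paste0("gtdb lineage token has no rank prefix: '", tokens[i], "'"))
      }
      if (i <= 7L && pfx != want) {
        abort(paste0("gtdb rank prefix out of order: '", tokens[i],
                     "' (expected '", want, "')"))
      }
      tokens[i] <- sub("^[a-z]__", "", tokens[i])
    }
  }

  tokens <- tokens[seq_len(min(length(tokens), 7L))]
  lin <- rep(NA_character_, 7L)
  lin[seq_along(tokens)] <- tokens

  # missing designations
  is_missing <- vapply(lin, function(tok) {
    if (is.na(tok) || !nzchar(tok)) return(TRUE)
    low <- tolower(tok)
    first <- strsplit(low, "\\s+")[[1]][1]
    any(low == missing_vocab | first == missing_vocab)
  }, logical(1))
  lin[is_missing] <- NA_character_

  # collapse subspecies/strain suffixes in the species token to a binomial
  if (!is.na(lin[7L])) {
    lin[7L] <- collapse_species_token(lin[7L])
  }
  setNames(lin, rank_levels())
}

#' Missing-label vocabulary
#'
#' Tokens that denote "no classification" in common 16S databases; matched
#' case-insensitively against whole tokens and their first word.
#' @return Character vector.
#' @export
missing_label_vocabulary <- function() {
  c("unclassified", "uncultured", "metagenome", "unidentified", "")
}

# first two whitespace-separated words; fewer than two words kept verbatim
collapse_species_token <- function(tok) {
  words <- strsplit(trimws(tok), "\\s+")[[1]]
  if (length(words) < 2L) return(tok)
  paste(words[1:2], collapse = " ")
}

#' Parse a taxonomy table
#'
#' Vectorized lineage parsing: one row per sequence, one column per rank.
#'
#' @param x Data frame with columns `id` and `lineage`, or a path to a
#'   two-column headerless TSV (mothur-style `ID<TAB>lineage`).
#' @inheritParams parse_taxonomy_string
#' @return Tibble with columns `id`, then one column per rank
#'   ([rank_levels()]); `NA` marks a missing designation.
#' @export
parse_taxonomy <- function(x, dialect = c("silva", "gtdb"),
                           missing_vocab = missing_label_vocabulary()) {
  dialect <- match.arg(dialect)
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_tsv(x, col_names = c("id", "lineage"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  }
  x <- as_tibble(x)
  if (!all(c("id", "lineage") %in% names(x))) {
    abort("taxonomy input needs columns `id` and `lineage`")
  }
  if (anyDuplicated(x$id)) abort("duplicate sequence IDs in taxonomy table")
  mat <- t(vapply(x$lineage, parse_taxonomy_string, character(7L),
                  dialect = dialect, missing_vocab = missing_vocab))
  rownames(mat) <- NULL
  dplyr::bind_cols(tibble(id = x$id), as_tibble(mat))
}

#' Write a taxonomy table as mothur-style TSV
#'
#' @param taxonomy Tibble from [parse_taxonomy()].
#' @param path Output path.
#' @param sentinel Placeholder written for missing designations.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path, sentinel = "unclassified") {
  ranks <- rank_levels()
  lin <- apply(as.matrix(taxonomy[ranks]), 1L, function(row) {
    row[is.na(row)] <- sentinel
    paste(row, collapse = ";")
  })
  readr::write_tsv(tibble(id = taxonomy$id, lineage = lin), path,
                   col_names = FALSE)
  invisible(path)
}

#' Render a label set as canonical text
#'
#' Multi-label (ambiguous) assignments are rendered as the sorted unique
#' labels joined by `";"`, e.g. `"Denitratisoma;Sulfuritalea"`.
#'
#' @param labels Character vector of labels (may be empty or `NA`).
#' @param sentinel Rendering for an empty set.
#' @return Single string.
#' @export
#' @examples
#' render_labels(c("Sulfuritalea", "Denitratisoma"))
#' render_labels(character(0))
render_labels <- function(labels, sentinel = "unassigned") {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) return(sentinel)
  paste(sort(unique(labels)), collapse = ";")
}

# inverse of render_labels for internal plumbing; sentinel -> character(0)
split_labels <- function(text, sentinel = "unassigned") {
  if (is.na(text) || !nzchar(text) || identical(text, sentinel)) {
    return(character(0))
  }
  strsplit(text, ";", fixed = TRUE)[[1]]
}
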