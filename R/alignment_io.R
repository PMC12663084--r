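#' Read an aligned FASTA database
#'
#' Accepts mothur/SILVA-style alignments where both `"-"` and `"."` denote
#' gaps. Sequences are uppercased, `U` is normalized to `T`, and `.` to
#' `-`. All sequences must have equal (aligned) length.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  tib <- tibble(id = ids, seq = normalize_seq(as.character(ss)))
  validate_alignment(tib)
  tib
}

#' Write an alignment (or unaligned sequences) as FASTA
#'
#' @param seqs Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(seqs, path) {
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

normalize_seq <- function(x) {
  x <- toupper(x)
  x <- gsub(".", "-", x, fixed = TRUE)
  gsub("U", "T", x, fixed = TRUE)
}

validate_alignment <- function(tib) {
  if (nrow(tib) == 0L) abort("empty alignment")
  if (anyDuplicated(tib$id)) abort("duplicate sequence IDs in alignment")
  lens <- nchar(tib$seq)
  if (length(unique(lens)) != 1L) {
    abort("alignment is ragged: sequences have unequal lengths")
  }
  invisible(tib)
}

degap <- function(seq) gsub("-", "", seq, fixed = TRUE)

#' Read a primer pair file
#'
#' Three-column TSV: name, forward primer, reverse primer (both written
#' 5'->3' on their own strands; IUPAC degeneracies allowed).
#'
#' @param path TSV path.
#' @return Tibble with columns `name`, `forward`, `reverse`.
#' @export
read_primer_file <- function(path) {
  tib <- readr::read_tsv(path, col_names = c("name", "forward", "reverse"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  ok <- grepl("^[ACGTUMRWSYKVHDBN]+$", toupper(tib$forward)) &
    grepl("^[ACGTUMRWSYKVHDBN]+$", toupper(tib$reverse))
  if (!all(ok)) abort("primer file contains non-IUPAC characters")
  tib$forward <- gsub("U", "T", toupper(tib$forward), fixed = TRUE)
  tib$reverse <- gsub("U", "T", toupper(tib$reverse), fixed = TRUE)
  tib
}

# IUPAC code -> base set
iupac_expand <- function(code) {
  map <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
              S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
              V = c("A", "C", "G"), H = c("A", "C", "T"),
              D = c("A", "G", "T"), B = c("C", "G", "T"),
              N = c("A", "C", "G", "T"))
  out <- map[[code]]
  if (is.null(out)) abort(paste0("invalid IUPAC code: '", code, "'"))
  out
}

iupac_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  out <- comp[chars]
  if (anyNA(out)) abort("invalid IUPAC code in primer")
  paste(out, collapse = "")
}
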