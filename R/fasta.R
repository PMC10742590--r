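#' Read a FASTA file into a tibble of sequence records
#'
#' Thin tidy wrapper over [Biostrings::readBStringSet()]. Record ids are the
#' first whitespace-delimited token of each header; order is preserved and
#' sequence line breaks are stripped.
#'
#' @param path Path to a FASTA file.
#' @param moltype Either `"dna"` or `"protein"`; stored on every record.
#' @return A tibble with columns `id`, `seq`, `moltype`. An empty file gives
#'   a zero-row tibble.
#' @details Duplicate ids and empty sequences are hard errors, since both
#'   break the downstream assumption that a collection is keyed by id.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("read_fasta(): duplicate record id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("read_fasta(): empty sequence under header(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  tibble::tibble(id = ids, seq = unname(seqs), moltype = moltype)
}

#' Write sequence records to a FASTA file
#'
#' @param records A data frame with columns `id` and `seq` (as returned by
#'   [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- tibble::tibble(id = names(records), seq = unname(records))
  }
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' IUPAC ambiguity codes are complemented correctly.
#'
#' @param x A single nucleotide string.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
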