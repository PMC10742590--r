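#' Extract the spliced CDS of each gene model
#'
#' Concatenates the CDS segments of the representative transcript in
#' transcription order: ascending genomic order on the plus strand, and the
#' reverse complement of the ascending concatenation on the minus strand.
#' A spliced CDS whose length is not divisible by 3 is flagged `pseudo_cds`
#' and must be excluded from translation-dependent stages.
#'
#' @param genome Genome tibble from [read_fasta()].
#' @param genes Gene-model tibble from [read_gff3()].
#' @return `genes` with added columns `cds_seq` and `pseudo_cds`.
#' @export
spliced_cds <- function(genome, genes) {
  chrom_seq <- stats::setNames(genome$seq, genome$id)
  out <- genes
  out$cds_seq <- purrr::pmap_chr(
    list(genes$chrom, genes$strand, genes$cds, genes$gene_id),
    function(chrom, strand, segs, id) {
      chr <- chrom_seq[[chrom]]
      if (is.null(chr)) stop("spliced_cds(): unknown chromosome ", chrom)
      if (any(segs$start < 1) || any(segs$end > nchar(chr))) {
        stop("spliced_cds(): CDS segment out of chromosome bounds for ", id)
      }
      s <- paste(substring(chr, segs$start, segs$end), collapse = "")
      if (strand == "-") revcomp(s) else s
    }
  )
  out$pseudo_cds <- nchar(out$cds_seq) %% 3 != 0
  if (any(out$pseudo_cds)) {
    message("spliced_cds(): ", sum(out$pseudo_cds),
            " pseudo-CDS gene(s) flagged (length not divisible by 3): ",
            paste(out$gene_id[out$pseudo_cds], collapse = ", "))
  }
  out
}

#' Translate a coding sequence
#'
#' Standard genetic code via [Biostrings::translate()]; codons containing
#' IUPAC ambiguity bases translate to `X`. A single trailing stop codon is
#' removed; internal stops are kept as `*` so callers can flag the record.
#'
#' @param cds A single in-frame nucleotide string (length divisible by 3).
#' @return The amino-acid string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) {
    stop("translate_cds(): CDS length not divisible by 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Translate gene models, flagging untranslatable records
#'
#' Adds `protein` and `internal_stop` columns to the output of
#' [spliced_cds()]. Pseudo-CDS genes get `NA` proteins; genes with internal
#' stop codons are flagged for exclusion from the family set.
#'
#' @param genes_cds Tibble from [spliced_cds()].
#' @return The tibble with `protein` and `internal_stop` columns added.
#' @export
add_proteins <- function(genes_cds) {
  out <- genes_cds
  out$protein <- ifelse(
    out$pseudo_cds, NA_character_,
    vapply(out$cds_seq, function(s) if (nchar(s) %% 3 == 0) translate_cds(s)
           else NA_character_, character(1), USE.NAMES = FALSE)
  )
  out$internal_stop <- !is.na(out$protein) & grepl("*", out$protein, fixed = TRUE)
  if (any(out$internal_stop)) {
    message("add_proteins(): internal stop codon in: ",
            paste(out$gene_id[out$internal_stop], collapse = ", "))
  }
  out
}

#' Extract promoter sequences upstream of the translation start
#'
#' The promoter is measured from the first CDS base (the translation start):
#' on the plus strand the genomic window `[start - length, start - 1]`, on
#' the minus strand the reverse complement of `[end + 1, end + length]`.
#' Windows are clipped at chromosome edges and the obtained length reported.
#'
#' @param genome Genome tibble from [read_fasta()].
#' @param genes Gene-model tibble from [read_gff3()].
#' @param length Promoter length in bp (default 1500).
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `promoter`, `obtained_length`, `truncated`.
#' @export
extract_upstream <- function(genome, genes, length = 1500L) {
  chrom_seq <- stats::setNames(genome$seq, genome$id)
  rows <- purrr::pmap_dfr(
    list(genes$gene_id, genes$chrom, genes$strand, genes$cds),
    function(id, chrom, strand, segs) {
      chr <- chrom_seq[[chrom]]
      clen <- nchar(chr)
      if (strand == "+") {
        cds_start <- min(segs$start)
        s <- max(1L, cds_start - length)
        e <- cds_start - 1L
        seq <- if (e >= s) substring(chr, s, e) else ""
      } else {
        cds_end <- max(segs$end)
        s <- cds_end + 1L
        e <- min(clen, cds_end + length)
        seq <- if (e >= s) revcomp(substring(chr, s, e)) else ""
      }
      tibble::tibble(gene_id = id, chrom = chrom,
                     start = if (nzchar(seq)) s else NA_integer_,
                     end = if (nzchar(seq)) e else NA_integer_,
                     strand = strand, promoter = seq,
                     obtained_length = nchar(seq),
                     truncated = nchar(seq) < length)
    }
  )
  if (any(rows$obtained_length == 0)) {
    warning("extract_upstream(): empty promoter for gene(s) at contig edge: ",
            paste(rows$gene_id[rows$obtained_length == 0], collapse = ", "))
  } else if (any(rows$truncated)) {
    warning("extract_upstream(): promoter truncated at chromosome edge for: ",
            paste(rows$gene_id[rows$truncated], collapse = ", "))
  }
  rows
}
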