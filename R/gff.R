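#' Read gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/CDS features (via [rtracklayer::readGFF()]) into one row
#' per gene, keeping the representative transcript: the one with the longest
#' total CDS, ties broken by the lexicographically smallest transcript id.
#' GFF3 coordinates are 1-based inclusive and are kept that way in R.
#'
#' @param path Path to a GFF3 file with gene, mRNA (or transcript) and CDS
#'   features linked by `ID`/`Parent` attributes.
#' @param genome Optional genome tibble from [read_fasta()]; when supplied,
#'   a CDS on a seqid absent from the genome is an error.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `transcript_id` (representative), `n_transcripts`, `exon_count`,
#'   `cds_len`, and a `cds` list-column of tibbles with ascending
#'   non-overlapping `start`/`end` segments.
#' @export
read_gff3 <- function(path, genome = NULL) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff$seqid <- as.character(gff$seqid)
  gff$strand <- as.character(gff$strand)
  first_parent <- function(p) vapply(p, function(x) {
    if (length(x) == 0) NA_character_ else as.character(x[[1]])
  }, character(1))

  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop("read_gff3(): no CDS features in ", path)

  mrna_gene <- stats::setNames(first_parent(mrna$Parent), mrna$ID)
  cds_parent <- first_parent(cds$Parent)
  undeclared <- setdiff(unique(cds_parent), names(mrna_gene))
  if (length(undeclared) > 0) {
    stop("read_gff3(): CDS with undeclared Parent transcript(s): ",
         paste(undeclared, collapse = ", "))
  }
  if (!is.null(genome)) {
    missing_chr <- setdiff(unique(cds$seqid), genome$id)
    if (length(missing_chr) > 0) {
      stop("read_gff3(): CDS on seqid(s) absent from the genome: ",
           paste(missing_chr, collapse = ", "))
    }
  }
  if (!all(cds$strand %in% c("+", "-"))) {
    stop("read_gff3(): CDS strand must be '+' or '-'")
  }

  tx <- tibble::tibble(
    transcript_id = cds_parent,
    chrom = cds$seqid, strand = cds$strand,
    start = as.integer(cds$start), end = as.integer(cds$end)
  ) %>%
    dplyr::group_by(.data$transcript_id, .data$chrom, .data$strand) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    tidyr::nest(cds = c("start", "end")) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      gene_id = unname(mrna_gene[.data$transcript_id]),
      cds_len = purrr::map_dbl(.data$cds, ~ sum(.x$end - .x$start + 1)),
      exon_count = purrr::map_int(.data$cds, nrow)
    )

  bad_overlap <- purrr::map_lgl(tx$cds, function(s) {
    nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])
  })
  if (any(bad_overlap)) {
    stop("read_gff3(): overlapping CDS segments in transcript(s): ",
         paste(tx$transcript_id[bad_overlap], collapse = ", "))
  }

  tx %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::arrange(dplyr::desc(.data$cds_len), .data$transcript_id,
                   .by_group = TRUE) %>%
    dplyr::mutate(n_transcripts = dplyr::n()) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("gene_id", "transcript_id", "chrom", "strand",
                  "n_transcripts", "exon_count", "cds_len", "cds") %>%
    dplyr::arrange(.data$gene_id)
}
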