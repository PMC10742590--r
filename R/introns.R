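#' Intron records of gene models
#'
#' One record per junction between consecutive CDS segments in transcription
#' order. `cum_cds` is the number of coding nucleotides upstream of the
#' intron, `phase = cum_cds %% 3` (0: between codons; 1: after the first
#' codon base; 2: after the second), and `residue` is the 1-based index of
#' the protein residue containing the intron (phase 1/2) or immediately
#' following it (phase 0). Single-exon genes contribute no records;
#' pseudo-CDS genes are excluded with a message since phases are undefined.
#'
#' @param genes Gene-model tibble from [read_gff3()] (optionally already
#'   carrying a `pseudo_cds` column from [spliced_cds()]).
#' @return A tibble with `gene_id`, `intron_index`, `cum_cds`, `phase`,
#'   `residue`.
#' @export
gene_introns <- function(genes) {
  if ("pseudo_cds" %in% names(genes) && any(genes$pseudo_cds)) {
    message("gene_introns(): excluding ", sum(genes$pseudo_cds),
            " pseudo-CDS gene(s): ",
            paste(genes$gene_id[genes$pseudo_cds], collapse = ", "))
    genes <- genes[!genes$pseudo_cds, ]
  }
  purrr::pmap_dfr(
    list(genes$gene_id, genes$strand, genes$cds),
    function(id, strand, segs) {
      k <- nrow(segs)
      if (k < 2) return(NULL)
      lens <- segs$end - segs$start + 1
      if (strand == "-") lens <- rev(lens)
      cum <- cumsum(lens)[-k]
      tibble::tibble(
        gene_id = id,
        intron_index = seq_len(k - 1),
        cum_cds = cum,
        phase = cum %% 3,
        residue = cum %/% 3 + 1L
      )
    }
  )
}

#' Project intron records onto alignment columns
#'
#' The alignment column of a record is the position of the `residue`-th
#' non-gap character of that gene's alignment row.
#'
#' @param records Tibble from [gene_introns()].
#' @param alignment Alignment tibble (`gene_id`, `aligned`).
#' @return `records` with an added `column` (1-based alignment column).
#' @export
project_introns <- function(records, alignment) {
  rows <- stats::setNames(alignment$aligned, alignment$gene_id)
  missing <- setdiff(unique(records$gene_id), names(rows))
  if (length(missing) > 0) {
    stop("project_introns(): gene(s) missing from alignment: ",
         paste(missing, collapse = ", "))
  }
  records$column <- purrr::map2_int(
    records$gene_id, records$residue,
    function(id, res) {
      chars <- strsplit(rows[[id]], "", fixed = TRUE)[[1]]
      nongap <- which(chars != "-")
      if (res > length(nongap)) {
        stop("project_introns(): residue ", res, " beyond the degapped row ",
             "of ", id, " (CDS/alignment mismatch)")
      }
      nongap[res]
    }
  )
  records
}

#' Cluster projected introns into positional classes I-1, I-2, ...
#'
#' Single-linkage clustering of alignment columns: introns whose columns
#' chain within `tolerance` of each other form one class. Classes are
#' ordered by their leftmost column and labelled `I-1` upward; clustering is
#' by position only, so a class may mix phases (which is reported, not
#' split). Tolerance 0 gives exact-column classes.
#'
#' @param records Projected records from [project_introns()].
#' @param tolerance Column linkage threshold (default 3).
#' @return `records` with an added `class_label`.
#' @export
cluster_intron_classes <- function(records, tolerance = 3) {
  if (nrow(records) == 0) {
    records$class_label <- character(0)
    return(records)
  }
  if (nrow(records) == 1) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(records$column), method = "single")
    cl <- stats::cutree(hc, h = tolerance)
  }
  mins <- tapply(records$column, cl, min)
  rank <- rank(mins, ties.method = "first")
  records$class_label <- paste0("I-", rank[as.character(cl)])
  records
}

#' Per-class summary of intron classes
#'
#' @param classified Records with `class_label` from
#'   [cluster_intron_classes()].
#' @return A tibble with one row per class: member counts, column range, and
#'   phase composition.
#' @export
intron_class_summary <- function(classified) {
  classified %>%
    dplyr::group_by(.data$class_label) %>%
    dplyr::summarise(
      n_introns = dplyr::n(),
      n_genes = dplyr::n_distinct(.data$gene_id),
      col_min = min(.data$column),
      col_max = max(.data$column),
      phase0 = sum(.data$phase == 0),
      phase1 = sum(.data$phase == 1),
      phase2 = sum(.data$phase == 2),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$col_min)
}

#' Conservation of intron classes across intron-bearing genes
#'
#' Reports, per class, the number and percentage of intron-bearing genes
#' carrying it, plus the phase breakdown. The percentage denominator is the
#' number of genes with at least one intron (not the whole family), the
#' convention under which a class carried by 39 of 67 intron-bearing genes
#' reads as 58%.
#'
#' @param classified Records with `class_label`.
#' @param n_intron_bearing Denominator; defaults to the number of distinct
#'   genes in `classified`.
#' @return [intron_class_summary()] columns plus `pct_genes`.
#' @export
conservation_table <- function(classified, n_intron_bearing = NULL) {
  denom <- n_intron_bearing %||% dplyr::n_distinct(classified$gene_id)
  intron_class_summary(classified) %>%
    dplyr::mutate(pct_genes = 100 * .data$n_genes / denom,
                  denominator = denom)
}

#' Intron gain/loss table by phylogenetic group
#'
#' Each cell is the fraction of the group's genes (including intron-less
#' ones) that carry the intron class: 0 means absent, 1 fixed, anything
#' between a partial gain/loss.
#'
#' @param classified Records with `class_label`.
#' @param groups Tibble with `gene_id`, `group` covering the whole family.
#' @return A wide tibble, one row per group, one column per class, plus
#'   `n_genes`.
#' @export
gain_loss_matrix <- function(classified, groups) {
  sizes <- dplyr::count(groups, .data$group, name = "n_genes")
  cells <- classified %>%
    dplyr::inner_join(groups, by = "gene_id") %>%
    dplyr::distinct(.data$group, .data$class_label, .data$gene_id) %>%
    dplyr::count(.data$group, .data$class_label) %>%
    dplyr::left_join(sizes, by = "group") %>%
    dplyr::mutate(fraction = .data$n / .data$n_genes)
  labels <- unique(classified$class_label)
  labels <- labels[order(as.integer(sub("^I-", "", labels)))]
  wide <- cells %>%
    dplyr::select("group", "class_label", "fraction") %>%
    tidyr::pivot_wider(names_from = "class_label", values_from = "fraction",
                       values_fill = 0)
  out <- sizes %>% dplyr::left_join(wide, by = "group")
  for (lab in labels) if (!lab %in% names(out)) out[[lab]] <- 0
  out[is.na(out)] <- 0
  dplyr::select(out, "group", "n_genes", dplyr::all_of(labels))
}
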