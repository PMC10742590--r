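#' Classify genes as expressed per tissue
#'
#' A gene is expressed in a tissue iff its value exceeds `tau` (default 0,
#' i.e. strictly positive). Genes expressed nowhere are flagged `dropped`
#' and counted, matching the convention of removing all-zero rows from
#' tissue heatmaps.
#'
#' @param mat Wide expression tibble: `gene_id` plus one non-negative numeric
#'   column per tissue/condition.
#' @param tau Expression threshold (default 0).
#' @return A tibble with `gene_id`, `n_expressed`, `expressed_in`
#'   (list-column of tissue labels), `specific_to` (the single tissue for
#'   genes expressed in exactly one, else `NA`), `dropped`. The number of
#'   dropped genes is attached as attribute `n_dropped`.
#' @export
call_expressed <- function(mat, tau = 0) {
  tissues <- setdiff(names(mat), "gene_id")
  vals <- as.matrix(mat[tissues])
  if (any(vals < 0)) stop("call_expressed(): negative expression value")
  if (anyDuplicated(tissues)) stop("call_expressed(): duplicate tissue labels")
  expressed <- vals > tau
  out <- tibble::tibble(
    gene_id = mat$gene_id,
    n_expressed = rowSums(expressed),
    expressed_in = purrr::map(seq_len(nrow(mat)),
                              ~ tissues[expressed[.x, ]]),
    specific_to = ifelse(rowSums(expressed) == 1,
                         tissues[apply(expressed, 1, which.max)],
                         NA_character_),
    dropped = rowSums(expressed) == 0
  )
  attr(out, "n_dropped") <- sum(out$dropped)
  out
}

#' Tally tissue-specific genes per tissue
#'
#' @param calls Output of [call_expressed()].
#' @param tissues Optional tissue order for zero-filled tallies.
#' @return A tibble with `tissue`, `n_specific`.
#' @export
tissue_specific_tally <- function(calls, tissues = NULL) {
  tal <- calls %>%
    dplyr::filter(!is.na(.data$specific_to)) %>%
    dplyr::count(tissue = .data$specific_to, name = "n_specific")
  if (!is.null(tissues)) {
    tal <- tibble::tibble(tissue = tissues) %>%
      dplyr::left_join(tal, by = "tissue") %>%
      tidyr::replace_na(list(n_specific = 0L))
  }
  tal
}

#' Fold-change flags between control and treated expression
#'
#' `log2fc = log2((treated + pseudocount) / (control + pseudocount))`; a gene
#' is upregulated iff `log2fc > threshold` and downregulated symmetrically
#' (`log2fc < -threshold`).
#'
#' @param expr Tibble with columns `gene_id`, `control`, `treated`.
#' @param pseudocount Added to both values before the ratio (default 1).
#' @param threshold Absolute log2 fold-change cutoff (default 1).
#' @return `expr` with `log2fc`, `upregulated`, `downregulated` columns.
#' @export
fold_changes <- function(expr, pseudocount = 1, threshold = 1) {
  expr %>%
    dplyr::mutate(
      log2fc = log2((.data$treated + pseudocount) /
                      (.data$control + pseudocount)),
      upregulated = .data$log2fc > threshold,
      downregulated = .data$log2fc < -threshold
    )
}

#' Relative expression by the 2^-ddCt method
#'
#' Per (target gene, condition): `dCt` is the mean target Ct minus the mean
#' reference-gene Ct of the same condition; `ddCt` subtracts the gene's
#' `dCt` in the calibrator condition; relative expression is `2^-ddCt`, so
#' the calibrator is exactly 1. Replicate scatter is propagated as
#' `sd_delta_ct = sqrt(sd_target^2 + sd_reference^2)` and reported as an
#' asymmetric error bar `2^-(ddCt +/- sd)`.
#'
#' @param ct Long Ct tibble with columns `gene`, `condition`, `replicate`,
#'   `ct` (all Ct values positive). Reference-gene rows use
#'   `gene == reference_gene`.
#' @param reference_gene Housekeeping gene id (e.g. `"EF1a"`).
#' @param calibrator Calibrator condition label (e.g. the untreated
#'   timepoint).
#' @return A tibble of class `ugt_ddct`: `gene`, `condition`, `n_reps`,
#'   `delta_ct`, `sd_delta_ct`, `ddct`, `rel_expr`, `rel_lo`, `rel_hi`.
#' @export
ddct <- function(ct, reference_gene, calibrator) {
  stopifnot(all(c("gene", "condition", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("ddct(): Ct values must be positive")
  if (!calibrator %in% ct$condition) {
    stop("ddct(): calibrator condition '", calibrator, "' absent from table")
  }
  means <- ct %>%
    dplyr::group_by(.data$gene, .data$condition) %>%
    dplyr::summarise(mean_ct = mean(.data$ct),
                     sd_ct = stats::sd(.data$ct),
                     n_reps = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(sd_ct = tidyr::replace_na(.data$sd_ct, 0))
  ref <- means %>%
    dplyr::filter(.data$gene == reference_gene) %>%
    dplyr::select("condition", ref_ct = "mean_ct", ref_sd = "sd_ct")
  targets <- means %>% dplyr::filter(.data$gene != reference_gene)
  missing_ref <- setdiff(unique(targets$condition), ref$condition)
  if (length(missing_ref) > 0) {
    stop("ddct(): reference gene Ct missing for condition(s): ",
         paste(missing_ref, collapse = ", "))
  }
  out <- targets %>%
    dplyr::inner_join(ref, by = "condition") %>%
    dplyr::mutate(delta_ct = .data$mean_ct - .data$ref_ct,
                  sd_delta_ct = sqrt(.data$sd_ct^2 + .data$ref_sd^2))
  cal <- out %>%
    dplyr::filter(.data$condition == calibrator) %>%
    dplyr::select("gene", cal_dct = "delta_ct")
  missing_cal <- setdiff(unique(out$gene), cal$gene)
  if (length(missing_cal) > 0) {
    stop("ddct(): calibrator measurement missing for gene(s): ",
         paste(missing_cal, collapse = ", "))
  }
  out <- out %>%
    dplyr::inner_join(cal, by = "gene") %>%
    dplyr::mutate(ddct = .data$delta_ct - .data$cal_dct,
                  rel_expr = 2^(-.data$ddct),
                  rel_lo = 2^(-(.data$ddct + .data$sd_delta_ct)),
                  rel_hi = 2^(-(.data$ddct - .data$sd_delta_ct))) %>%
    dplyr::select("gene", "condition", "n_reps", "delta_ct", "sd_delta_ct",
                  "ddct", "rel_expr", "rel_lo", "rel_hi") %>%
    dplyr::arrange(.data$gene, .data$condition)
  class(out) <- c("ugt_ddct", class(out))
  out
}
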