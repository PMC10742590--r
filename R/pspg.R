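#' Build a PSPG-box position-specific scoring model
#'
#' The PSPG box is the conserved 44-residue C-terminal block that diagnoses
#' family-1 UDP-glycosyltransferases. From a gapless block of aligned
#' reference motifs this builds per-column log-odds weights
#' `log2((count(a) + pc * bg(a)) / (n + pc) / bg(a))`.
#'
#' @param block Character vector of aligned motif rows (all of width
#'   `width`), or a tibble with a `seq` column.
#' @param pseudocount Positive pseudocount mass (default 1).
#' @param background Named length-20 frequency vector summing to 1; default
#'   uniform.
#' @param width Motif width; 44 for the PSPG box.
#' @return An object of class `pspg_model`.
#' @export
build_pspg_model <- function(block, pseudocount = 1, background = NULL,
                             width = 44L) {
  if (is.data.frame(block)) block <- block$seq
  if (length(block) < 1) stop("build_pspg_model(): need at least one row")
  if (any(nchar(block) != width)) {
    stop("build_pspg_model(): all rows must have the required width ", width,
         " (got ", paste(unique(nchar(block)), collapse = ", "), ")")
  }
  rows <- do.call(rbind, strsplit(toupper(block), "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(rows)), AA_ORDER)
  if (length(bad) > 0) {
    stop("build_pspg_model(): non-amino-acid character(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ORDER)
  }
  background <- background[AA_ORDER]
  if (abs(sum(background) - 1) > 1e-6) {
    stop("build_pspg_model(): background frequencies must sum to 1")
  }
  if (pseudocount <= 0) stop("build_pspg_model(): pseudocount must be > 0")
  n <- length(block)
  counts <- t(apply(rows, 2, function(col) {
    tabulate(match(col, AA_ORDER), nbins = 20)
  }))
  dimnames(counts) <- list(NULL, AA_ORDER)
  weights <- log2(sweep(counts, 2, pseudocount * background, "+") /
                    (n + pseudocount))
  weights <- sweep(weights, 2, log2(background), "-")
  structure(
    list(width = as.integer(width), weights = weights,
         background = background, pseudocount = pseudocount,
         n_sequences = n,
         consensus = paste(AA_ORDER[apply(weights, 1, which.max)],
                           collapse = "")),
    class = "pspg_model"
  )
}

#' @export
print.pspg_model <- function(x, ...) {
  cat("PSPG position-specific scoring model\n")
  cat("  width:", x$width, "columns;", x$n_sequences, "reference row(s)\n")
  cat("  consensus:", x$consensus, "\n")
  cat("  max achievable score:", round(sum(apply(x$weights, 1, max)), 2),
      "bits\n")
  invisible(x)
}

#' @rdname tidy_ugtfam
#' @export
tidy.pspg_model <- function(x, ...) {
  tibble::as_tibble(x$weights) %>%
    dplyr::mutate(position = dplyr::row_number()) %>%
    tidyr::pivot_longer(-"position", names_to = "aa", values_to = "weight")
}

#' Write / read a PSPG model as a TSV of column weights
#'
#' @param model A `pspg_model`.
#' @param path File path.
#' @return `path` (write) or a `pspg_model` (read).
#' @export
write_pspg_model <- function(model, path) {
  df <- tibble::as_tibble(model$weights) %>%
    dplyr::mutate(position = dplyr::row_number(), .before = 1)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_pspg_model
#' @export
read_pspg_model <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  w <- as.matrix(df[AA_ORDER])
  structure(
    list(width = nrow(w), weights = w,
         background = stats::setNames(rep(1 / 20, 20), AA_ORDER),
         pseudocount = NA_real_, n_sequences = NA_integer_,
         consensus = paste(AA_ORDER[apply(w, 1, which.max)], collapse = "")),
    class = "pspg_model"
  )
}

#' Scan proteins for the best-scoring PSPG window
#'
#' Slides the model across each protein, keeps the best window (ties go to
#' the leftmost), and estimates an empirical p value as the fraction of
#' `n_shuffles` residue-shuffled copies of the protein whose best window
#' scores at least as high. The Monte-Carlo resolution is therefore
#' `1 / n_shuffles` and is recorded on every hit.
#'
#' @param proteins Tibble with columns `gene_id` and `protein` (or a named
#'   character vector).
#' @param model A `pspg_model`.
#' @param n_shuffles Shuffle-null size (default 1000; use more for
#'   calibration runs).
#' @param seed Optional integer seed for the shuffle null (restores the RNG
#'   state afterwards).
#' @return A tibble with one row per scannable protein: `gene_id`, `start`
#'   (1-based offset of the window), `score` (bits), `empirical_p`,
#'   `n_shuffles`. Proteins shorter than the motif are omitted with a
#'   message.
#' @export
scan_proteins <- function(proteins, model, n_shuffles = 1000L, seed = NULL) {
  stopifnot(inherits(model, "pspg_model"))
  if (is.character(proteins)) {
    proteins <- tibble::tibble(
      gene_id = names(proteins) %||% paste0("seq", seq_along(proteins)),
      protein = unname(proteins)
    )
  }
  run <- function() {
    purrr::map2_dfr(proteins$gene_id, proteins$protein, function(id, p) {
      L <- nchar(p)
      if (L < model$width) return(NULL)
      enc <- aa_encode(p)
      scores <- pssm_window_scores_cpp(enc, model$weights)
      best <- max(scores)
      start <- which(scores == best)[1]
      perms <- matrix(0L, nrow = n_shuffles, ncol = L)
      for (r in seq_len(n_shuffles)) perms[r, ] <- sample.int(L)
      null_best <- pssm_null_best_cpp(enc, model$weights, perms)
      # a shuffled best window is often a permutation of the observed one;
      # a small slack keeps such exact ties from flipping on float order
      tibble::tibble(gene_id = id, start = start, score = best,
                     empirical_p = mean(null_best >= best - 1e-9),
                     n_shuffles = n_shuffles)
    })
  }
  short <- nchar(proteins$protein) < model$width
  if (any(short)) {
    message("scan_proteins(): ", sum(short),
            " protein(s) shorter than the motif skipped: ",
            paste(proteins$gene_id[short], collapse = ", "))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Filter motif hits into a gene-family candidate set
#'
#' Retains proteins with a significant PSPG hit (`empirical_p <= p_threshold`)
#' and a length inside `length_window`, then collapses exact duplicate
#' protein sequences to the representative with the smallest gene id. Every
#' removal carries a machine-readable reason.
#'
#' @param proteins Tibble with columns `gene_id` and `protein`.
#' @param hits Tibble from [scan_proteins()].
#' @param p_threshold Significance threshold on the empirical p (default
#'   1e-5).
#' @param length_window Two-element numeric `c(min, max)` residue window
#'   (default `c(300, 600)`).
#' @param dedupe Collapse identical protein sequences (default TRUE).
#' @return A tibble with one row per input protein: scan columns plus
#'   `length`, `retained` and `reason` (`NA` when retained; otherwise one of
#'   `"no_significant_pspg_hit"`, `"too_short"`, `"too_long"`,
#'   `"duplicate_of_<id>"`).
#' @export
classify_candidates <- function(proteins, hits, p_threshold = 1e-5,
                                length_window = c(300, 600), dedupe = TRUE) {
  out <- proteins %>%
    dplyr::left_join(hits, by = "gene_id") %>%
    dplyr::mutate(length = nchar(.data$protein), reason = NA_character_)
  no_hit <- is.na(out$empirical_p) | out$empirical_p > p_threshold
  out$reason[no_hit] <- "no_significant_pspg_hit"
  sel <- is.na(out$reason) & out$length < length_window[1]
  out$reason[sel] <- "too_short"
  sel <- is.na(out$reason) & out$length > length_window[2]
  out$reason[sel] <- "too_long"
  if (dedupe) {
    kept <- out[is.na(out$reason), ]
    kept <- kept[order(kept$gene_id), ]
    rep_of <- tapply(kept$gene_id, kept$protein, function(ids) ids[1])
    dup <- kept$gene_id[kept$gene_id != rep_of[kept$protein]]
    sel <- out$gene_id %in% dup
    out$reason[sel] <- paste0("duplicate_of_",
                              rep_of[out$protein[sel]])
  }
  out$retained <- is.na(out$reason)
  dropped <- sum(!out$retained)
  if (dropped > 0) {
    message("classify_candidates(): dropped ", dropped, " of ", nrow(out),
            " protein(s)")
  }
  out %>% dplyr::arrange(.data$gene_id)
}

#' Retained family members of a classification
#'
#' @param classified Output of [classify_candidates()].
#' @return The retained rows.
#' @export
family_members <- function(classified) {
  dplyr::filter(classified, .data$retained)
}
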