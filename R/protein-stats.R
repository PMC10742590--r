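# Average (not monoisotopic) residue masses in Da, Expasy values, and the
# EMBOSS pKa set used for the charge model. Both tables are package data so
# the provenance of every number in protein_stats() is inspectable.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)
WATER_MASS <- 18.01524

AA_PKA <- list(
  nterm = 8.6, cterm = 3.6,
  basic  = c(H = 6.5, K = 10.8, R = 12.5),
  acidic = c(C = 8.5, D = 3.9, E = 4.1, Y = 10.1)
)

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch net charge using the packaged EMBOSS pKa set:
#' termini plus H/K/R (basic) and C/D/E/Y (acidic) side chains.
#'
#' @param protein Amino-acid string (standard residues; X is ignored).
#' @param ph pH value.
#' @return Net charge (numeric scalar).
#' @export
protein_charge <- function(protein, ph) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  pos <- 1 / (1 + 10^(ph - AA_PKA$nterm))
  neg <- -1 / (1 + 10^(AA_PKA$cterm - ph))
  for (aa in names(AA_PKA$basic)) {
    n <- sum(chars == aa)
    if (n > 0) pos <- pos + n / (1 + 10^(ph - AA_PKA$basic[[aa]]))
  }
  for (aa in names(AA_PKA$acidic)) {
    n <- sum(chars == aa)
    if (n > 0) neg <- neg - n / (1 + 10^(AA_PKA$acidic[[aa]] - ph))
  }
  pos + neg
}

isoelectric_point <- function(protein, tol = 1e-4) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    ch <- protein_charge(protein, mid)
    if (abs(ch) < tol || (hi - lo) < 1e-10) return(mid)
    if (ch > 0) lo <- mid else hi <- mid
  }
}

#' Protein length, molecular weight and isoelectric point
#'
#' Computes per-protein summary statistics: residue count, molecular weight in
#' kDa (sum of average residue masses plus one water), and the isoelectric
#' point found by bisecting the net-charge curve to |charge| < 1e-4.
#' X residues are excluded from the mass and charge sums with a warning.
#'
#' @param proteins A data frame with columns `gene_id` and `protein`, or a
#'   (optionally named) character vector of protein sequences.
#' @return A tibble with columns `gene_id`, `length`, `mw_kda`, `pi`.
#' @examples
#' protein_stats(c(g1 = "MKWVTFISLLFLFSSAYS"))
#' @export
protein_stats <- function(proteins) {
  if (is.character(proteins)) {
    proteins <- tibble::tibble(
      gene_id = names(proteins) %||% paste0("seq", seq_along(proteins)),
      protein = unname(proteins)
    )
  }
  stopifnot(all(c("gene_id", "protein") %in% names(proteins)))
  if (any(!nzchar(proteins$protein))) {
    stop("protein_stats(): empty protein sequence for ",
         paste(proteins$gene_id[!nzchar(proteins$protein)], collapse = ", "))
  }
  n_x <- sum(stringr::str_count(proteins$protein, "X"))
  if (n_x > 0) {
    warning(sprintf("%d X residue(s) excluded from MW/pI computation", n_x))
  }
  purrr::map2_dfr(proteins$gene_id, proteins$protein, function(id, p) {
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), c(AA_ORDER, "X"))
    if (length(bad) > 0) {
      stop("protein_stats(): invalid residue(s) ", paste(bad, collapse = ", "),
           " in ", id)
    }
    known <- chars[chars != "X"]
    tibble::tibble(
      gene_id = id,
      length = length(chars),
      mw_kda = (sum(AA_RESIDUE_MASS[known]) + WATER_MASS) / 1000,
      pi = isoelectric_point(paste(known, collapse = ""))
    )
  })
}
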