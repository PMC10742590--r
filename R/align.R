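# One-hot / count encoding of profile columns for the C++ aligner.
profile_counts <- function(char_mat) {
  L <- ncol(char_mat)
  counts <- matrix(0, nrow = 20, ncol = max(L, 0))
  if (L > 0) {
    for (j in seq_len(L)) {
      m <- match(char_mat[, j], AA_ORDER)
      m <- m[!is.na(m)]
      if (length(m) > 0) counts[, j] <- tabulate(m, nbins = 20)
    }
  }
  counts
}

seq_to_mat <- function(x) {
  matrix(strsplit(x, "", fixed = TRUE)[[1]], nrow = 1)
}

#' Optimal affine-gap global alignment of two protein sequences
#'
#' Gotoh dynamic programming with gap cost `gap_open + (g - 1) * gap_extend`
#' for a gap of length g. Traceback ties are broken deterministically:
#' match/mismatch over a gap in `a` over a gap in `b`.
#'
#' @param a,b Protein sequences (character scalars).
#' @param submat 20 x 20 substitution matrix (default [blosum62_matrix()]).
#' @param gap_open,gap_extend Gap penalties (positive numbers; defaults 10
#'   and 0.5).
#' @return A list with `a_aligned`, `b_aligned` (gapped strings) and `score`.
#' @examples
#' pairwise_global("HEAGAWGHEE", "PAWHEAE")
#' @export
pairwise_global <- function(a, b, submat = blosum62_matrix(),
                            gap_open = 10, gap_extend = 0.5) {
  ma <- if (nzchar(a)) seq_to_mat(a) else matrix(character(0), nrow = 1, ncol = 0)
  mb <- if (nzchar(b)) seq_to_mat(b) else matrix(character(0), nrow = 1, ncol = 0)
  res <- profile_align_cpp(profile_counts(ma), profile_counts(mb),
                           submat, gap_open, gap_extend, 1, 1)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  list(
    a_aligned = paste(ifelse(res$a_cols == 0, "-", ca[pmax(res$a_cols, 1)]),
                      collapse = ""),
    b_aligned = paste(ifelse(res$b_cols == 0, "-", cb[pmax(res$b_cols, 1)]),
                      collapse = ""),
    score = res$score
  )
}

kmer_distance_matrix <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character(0)))
    table(substring(s, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- intersect(names(ci), names(cj))
      common <- sum(pmin(ci[shared], cj[shared]))
      denom <- max(1, min(nchar(seqs[i]), nchar(seqs[j])) - k + 1)
      D[i, j] <- D[j, i] <- 1 - common / denom
    }
  }
  D
}

#' Progressive multiple alignment of a protein family
#'
#' Builds a guide tree by UPGMA (average-linkage [stats::hclust()]) on a
#' shared k-mer distance, then merges sequences and profiles with the same
#' affine-gap dynamic program as [pairwise_global()], scoring profile
#' columns by their mean substitution score. Degapping any output row
#' reproduces the input sequence exactly.
#'
#' @param proteins Tibble with columns `gene_id` and `protein`, or a named
#'   character vector.
#' @param submat,gap_open,gap_extend As in [pairwise_global()].
#' @param k k-mer size for the guide-tree distance (default 3).
#' @return A tibble of class `ugt_alignment` with columns `gene_id` and
#'   `aligned` (rows in input order), and attribute `n_columns`.
#' @export
progressive_align <- function(proteins, submat = blosum62_matrix(),
                              gap_open = 10, gap_extend = 0.5, k = 3L) {
  if (is.character(proteins)) {
    proteins <- tibble::tibble(
      gene_id = names(proteins) %||% paste0("seq", seq_along(proteins)),
      protein = unname(proteins)
    )
  }
  n <- nrow(proteins)
  if (n == 0) stop("progressive_align(): no sequences")
  if (n == 1) {
    out <- tibble::tibble(gene_id = proteins$gene_id,
                          aligned = proteins$protein)
    attr(out, "n_columns") <- nchar(proteins$protein)
    class(out) <- c("ugt_alignment", class(out))
    return(out)
  }
  D <- kmer_distance_matrix(proteins$protein, k = k)
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  profiles <- vector("list", n - 1)   # profiles produced by each merge
  members <- vector("list", n - 1)    # row ids (input indices) of each profile
  get_node <- function(id) {
    if (id < 0) {
      list(mat = seq_to_mat(proteins$protein[-id]), rows = -id)
    } else {
      list(mat = profiles[[id]], rows = members[[id]])
    }
  }
  for (m in seq_len(n - 1)) {
    a <- get_node(hc$merge[m, 1])
    b <- get_node(hc$merge[m, 2])
    res <- profile_align_cpp(profile_counts(a$mat), profile_counts(b$mat),
                             submat, gap_open, gap_extend,
                             nrow(a$mat), nrow(b$mat))
    La <- length(res$a_cols)
    merged <- matrix("-", nrow = nrow(a$mat) + nrow(b$mat), ncol = La)
    sel <- res$a_cols > 0
    merged[seq_len(nrow(a$mat)), sel] <- a$mat[, res$a_cols[sel], drop = FALSE]
    sel <- res$b_cols > 0
    merged[nrow(a$mat) + seq_len(nrow(b$mat)), sel] <-
      b$mat[, res$b_cols[sel], drop = FALSE]
    profiles[[m]] <- merged
    members[[m]] <- c(a$rows, b$rows)
  }
  final <- profiles[[n - 1]]
  ord <- order(members[[n - 1]])
  out <- tibble::tibble(
    gene_id = proteins$gene_id,
    aligned = apply(final[ord, , drop = FALSE], 1, paste, collapse = "")
  )
  attr(out, "n_columns") <- ncol(final)
  class(out) <- c("ugt_alignment", class(out))
  out
}

alignment_codes <- function(alignment) {
  rows <- strsplit(alignment$aligned, "", fixed = TRUE)
  L <- unique(lengths(rows))
  if (length(L) != 1) stop("alignment rows have unequal lengths")
  m <- do.call(rbind, lapply(rows, function(r) {
    idx <- match(r, AA_ORDER)
    idx[is.na(idx)] <- 0L
    idx - 1L
  }))
  rownames(m) <- alignment$gene_id
  m
}

#' Pairwise-deletion p-distance matrix of an alignment
#'
#' `d(i, j)` is the fraction of mismatching residues over columns where
#' neither row has a gap. A pair with zero comparable columns is an error.
#'
#' @param alignment An alignment tibble (columns `gene_id`, `aligned`), e.g.
#'   from [progressive_align()].
#' @param cols Optional 1-based column subset (with repeats allowed), as used
#'   by bootstrap resampling.
#' @return A symmetric numeric matrix with zero diagonal and gene-id
#'   dimnames.
#' @export
p_distance <- function(alignment, cols = NULL) {
  codes <- alignment_codes(alignment)
  if (nrow(codes) < 2) stop("p_distance(): need at least 2 rows")
  if (is.null(cols)) cols <- seq_len(ncol(codes))
  D <- pdist_cpp(codes, as.integer(cols))
  if (anyNA(D)) {
    bad <- sort(which(is.na(D), arr.ind = TRUE)[1, ])
    stop("p_distance(): no comparable columns for pair ",
         alignment$gene_id[bad[1]], " / ", alignment$gene_id[bad[2]])
  }
  dimnames(D) <- list(alignment$gene_id, alignment$gene_id)
  D
}
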