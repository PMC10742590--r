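# Independent top-down memoized affine-gap aligner used as the DP oracle.
# States encode the last move: 1 = diagonal, 2 = gap in a (consume b),
# 3 = gap in b (consume a). Opening a gap from a different state costs
# gap_open; extending the same gap costs gap_extend.
oracle_affine_score <- function(a, b, submat = ugtfam::blosum62_matrix(),
                                gap_open = 10, gap_extend = 0.5) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))
  rec <- function(i, j, last) {
    if (i == 0 && j == 0) return(if (last == 1) 0 else -Inf)
    v <- memo[i + 1, j + 1, last]
    if (!is.na(v)) return(v)
    v <- -Inf
    if (last == 1) {
      if (i > 0 && j > 0) {
        v <- max(rec(i - 1, j - 1, 1), rec(i - 1, j - 1, 2),
                 rec(i - 1, j - 1, 3)) + submat[A[i], B[j]]
      }
    } else if (last == 2) {
      if (j > 0) {
        v <- max(rec(i, j - 1, 1) - gap_open,
                 rec(i, j - 1, 2) - gap_extend,
                 rec(i, j - 1, 3) - gap_open)
      }
    } else {
      if (i > 0) {
        v <- max(rec(i - 1, j, 1) - gap_open,
                 rec(i - 1, j, 2) - gap_open,
                 rec(i - 1, j, 3) - gap_extend)
      }
    }
    memo[i + 1, j + 1, last] <<- v
    v
  }
  max(rec(n, m, 1), rec(n, m, 2), rec(n, m, 3))
}

# Plain-R brute-force shuffle null for the PSPG scan, consuming the RNG the
# same way as the scanner (one sample.int(L) per shuffle).
oracle_empirical_p <- function(protein, model, n_shuffles, seed) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  w <- model$width
  L <- length(chars)
  score_windows <- function(ch) {
    vapply(seq_len(L - w + 1), function(s) {
      sum(vapply(seq_len(w), function(j) {
        a <- ch[s + j - 1]
        if (a %in% colnames(model$weights)) model$weights[j, a] else 0
      }, numeric(1)))
    }, numeric(1))
  }
  obs <- max(score_windows(chars))
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(r) {
      max(score_windows(chars[sample.int(L)]))
    }, numeric(1))
  })
  mean(nulls >= obs - 1e-9)  # same tie slack as the scanner
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
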