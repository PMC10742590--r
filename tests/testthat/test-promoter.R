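tmp_dict <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path)
  path
}

test_that("dictionary loading validates entries", {
  good <- tmp_dict(tibble::tibble(
    name = c("E1", "E2", "E3"),
    pattern = c("ACGTG", "CANNTG", "GGTTAA"),
    category = c("hormone", "light", "light")))
  d <- load_element_dictionary(good)
  expect_equal(nrow(d), 3L)
  bad_code <- tmp_dict(tibble::tibble(name = "E1", pattern = "ACGTZ",
                                      category = "light"))
  expect_error(load_element_dictionary(bad_code), "invalid IUPAC.*E1")
  dup <- tmp_dict(tibble::tibble(name = c("E1", "E1"),
                                 pattern = c("ACGT", "GGCC"),
                                 category = c("light", "stress")))
  expect_error(load_element_dictionary(dup), "duplicate.*E1")
  expect_equal(nrow(plantcare_dictionary()), 16L)
})

abre <- tibble::tibble(name = "ABRE", pattern = "ACGTG", category = "hormone")

test_that("scanning finds planted occurrences on both strands", {
  set.seed(801)
  bg <- gsub("ACGTG|CACGT", "TTTTT", random_dna(300))
  prom <- paste0(substr(bg, 1, 99), "ACGTG", substr(bg, 105, 300))
  hits <- scan_promoters(c(g1 = prom), abre)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, 100L)
  expect_equal(plus$match, "ACGTG")

  prom2 <- paste0(substr(bg, 1, 99), "CACGT", substr(bg, 105, 300))
  hits2 <- scan_promoters(c(g1 = prom2), abre)
  minus <- hits2[hits2$strand == "-", ]
  expect_equal(minus$start, 100L)

  # overlapping occurrences all count
  hits3 <- scan_promoters(c(g = "ACGTGACGTGACGTG"), abre)
  expect_equal(hits3$start[hits3$strand == "+"], c(1L, 6L, 11L))
  expect_equal(nrow(scan_promoters(c(g = ""), abre)), 0L)

  # non-overlapping mode keeps a greedy left-to-right subset
  aca <- tibble::tibble(name = "E", pattern = "ACA", category = "other")
  expect_equal(scan_promoters(c(g = "ACACACA"), aca)$start, c(1L, 3L, 5L))
  expect_equal(scan_promoters(c(g = "ACACACA"), aca,
                              overlapping = FALSE)$start, c(1L, 5L))
})

test_that("IUPAC codes in patterns match their base sets", {
  dict <- tibble::tibble(name = "DEG", pattern = "CRT", category = "other")
  hits <- scan_promoters(c(g = "CATCCTCGT"), dict)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, c(1L, 7L))   # CAT and CGT, not CCT
})

test_that("scanning respects the strand-symmetry invariant", {
  set.seed(802)
  dict <- synthetic_dictionary()
  for (i in 1:20) {
    prom <- random_dna(250)
    fwd <- scan_promoters(c(g = prom), dict)
    rev <- scan_promoters(c(g = ugtfam::revcomp(prom)), dict)
    # mirror reverse hits back into forward coordinates
    w <- stats::setNames(nchar(dict$pattern), dict$name)
    mirrored <- tibble::tibble(
      element = rev$element,
      start = 250L - (rev$start + w[rev$element] - 1L) + 1L,
      strand = c("-", "+")[match(rev$strand, c("+", "-"))])
    a <- dplyr::arrange(fwd[c("element", "start", "strand")],
                        element, start, strand)
    b <- dplyr::arrange(mirrored, element, start, strand)
    expect_equal(as.data.frame(a), as.data.frame(b, row.names = NULL),
                 ignore_attr = TRUE)
  }
})

test_that("hits re-validate against their patterns and ignore dictionary order", {
  set.seed(803)
  dict <- synthetic_dictionary()
  prom <- random_dna(400)
  h1 <- scan_promoters(c(g = prom), dict)
  h2 <- scan_promoters(c(g = prom), dict[rev(seq_len(nrow(dict))), ])
  expect_equal(dplyr::arrange(h1, element, start, strand),
               dplyr::arrange(h2, element, start, strand))
  if (nrow(h1) > 0) {
    for (i in seq_len(nrow(h1))) {
      pat <- dict$pattern[dict$name == h1$element[i]]
      seqs <- if (h1$strand[i] == "+") h1$match[i] else revcomp(h1$match[i])
      expect_equal(
        length(Biostrings::matchPattern(pat, Biostrings::DNAString(seqs),
                                        fixed = "subject")), 1L)
    }
  }
})

test_that("category counts bin correctly and conserve gene totals", {
  dict <- synthetic_dictionary()
  hits <- tibble::tibble(
    gene_id = c(rep("g1", 3), "g2"),
    element = c("LRE-A", "LRE-A", "LRE-B", "SRE-A"),
    category = c("light", "light", "light", "stress"),
    start = 1L, strand = "+", match = "NNN")
  cc <- categorize_counts(hits, gene_ids = c("g1", "g2", "g3"))
  counts <- cc$counts
  expect_equal(counts$light[counts$gene_id == "g1"], 3L)
  expect_equal(counts$stress[counts$gene_id == "g1"], 0L)
  expect_equal(counts$light[counts$gene_id == "g3"], 0L)
  # every gene lands in exactly one bin per category
  for (cat in unique(cc$bins$category)) {
    expect_equal(sum(cc$bins$n_genes[cc$bins$category == cat]), 3)
  }
})
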