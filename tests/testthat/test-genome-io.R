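test_that("read_fasta round-trips records and enforces id uniqueness", {
  path <- tmp_fasta(list(s1 = "ACGTACGT", s2 = c("ACGT", "TTTT")))
  recs <- read_fasta(path)
  expect_equal(recs$id, c("s1", "s2"))
  expect_equal(nchar(recs$seq), c(8L, 8L))       # wrapping stripped
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, out)
  expect_equal(read_fasta(out)$seq, recs$seq)

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  dup <- tmp_fasta(list(a = "ACGT"))
  cat(">a\nTTTT\n", file = dup, append = TRUE)
  expect_error(read_fasta(dup), "duplicate.*a")
  emptyseq <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "", ">b", "ACGT"), emptyseq)
  expect_error(read_fasta(emptyseq), "empty sequence.*a")
})

test_that("read_gff3 builds gene models and picks the longest-CDS transcript", {
  fx <- toy_genome_annotation()
  genome <- read_fasta(fx$genome)
  genes <- read_gff3(fx$gff, genome = genome)
  expect_equal(nrow(genes), 2L)
  gA <- genes[genes$gene_id == "gA", ]
  expect_equal(gA$exon_count, 2L)
  expect_equal(gA$cds[[1]]$start, c(101L, 201L))  # ascending storage
  gB <- genes[genes$gene_id == "gB", ]
  expect_equal(gB$strand, "-")
  expect_equal(gB$cds[[1]]$start, c(301L, 391L))  # still ascending

  # representative = longest total CDS; tie broken by smallest transcript id
  gff2 <- tmp_gff3(c(
    gff_line("chr1", "gene", 1, 500, "+", "ID=g1"),
    gff_line("chr1", "mRNA", 1, 300, "+", "ID=g1.b;Parent=g1"),
    gff_line("chr1", "CDS", 1, 300, "+", "ID=c1;Parent=g1.b"),
    gff_line("chr1", "mRNA", 1, 360, "+", "ID=g1.a;Parent=g1"),
    gff_line("chr1", "CDS", 1, 360, "+", "ID=c2;Parent=g1.a")
  ))
  g <- read_gff3(gff2)
  expect_equal(g$transcript_id, "g1.a")
  expect_equal(g$cds_len, 360)
  expect_equal(g$n_transcripts, 2L)

  bad <- tmp_gff3(c(
    gff_line("chr1", "gene", 1, 90, "+", "ID=g1"),
    gff_line("chr1", "CDS", 1, 90, "+", "ID=c1;Parent=g1.missing")
  ))
  expect_error(read_gff3(bad), "undeclared Parent.*g1.missing")
  other_chr <- tmp_gff3(c(
    gff_line("chrZ", "gene", 1, 90, "+", "ID=g1"),
    gff_line("chrZ", "mRNA", 1, 90, "+", "ID=g1.1;Parent=g1"),
    gff_line("chrZ", "CDS", 1, 90, "+", "ID=c1;Parent=g1.1")
  ))
  expect_error(read_gff3(other_chr, genome = genome), "absent.*chrZ")
})

test_that("spliced_cds concatenates in transcription order on both strands", {
  fx <- toy_genome_annotation()
  genome <- read_fasta(fx$genome)
  genes <- spliced_cds(genome, read_gff3(fx$gff))
  gA <- genes[genes$gene_id == "gA", ]
  expect_equal(gA$cds_seq,
               paste0(substring(fx$chr, 101, 160), substring(fx$chr, 201, 260)))
  gB <- genes[genes$gene_id == "gB", ]
  expect_equal(gB$cds_seq,
               revcomp(paste0(substring(fx$chr, 301, 360),
                              substring(fx$chr, 391, 420))))
  expect_false(any(genes$pseudo_cds))
  expect_equal(revcomp("ATGC"), "GCAT")
})

test_that("spliced CDS obeys strand symmetry under chromosome reversal", {
  set.seed(77)
  chr <- random_dna(400)
  genome_fwd <- tibble::tibble(id = "c", seq = chr, moltype = "dna")
  genome_rev <- tibble::tibble(id = "c", seq = revcomp(chr), moltype = "dna")
  segs <- tibble::tibble(start = c(51L, 121L), end = c(80L, 180L))
  gene_fwd <- tibble::tibble(gene_id = "g", transcript_id = "g.1",
                             chrom = "c", strand = "+", n_transcripts = 1L,
                             exon_count = 2L, cds_len = 90,
                             cds = list(segs))
  L <- nchar(chr)
  segs_rev <- tibble::tibble(start = L - segs$end + 1L, end = L - segs$start + 1L)
  segs_rev <- segs_rev[order(segs_rev$start), ]
  gene_rev <- gene_fwd
  gene_rev$strand <- "-"
  gene_rev$cds <- list(segs_rev)
  expect_equal(spliced_cds(genome_fwd, gene_fwd)$cds_seq,
               spliced_cds(genome_rev, gene_rev)$cds_seq)
})

test_that("pseudo-CDS lengths are flagged", {
  genome <- tibble::tibble(id = "c", seq = random_dna(200), moltype = "dna")
  gene <- tibble::tibble(gene_id = "g", transcript_id = "g.1", chrom = "c",
                         strand = "+", n_transcripts = 1L, exon_count = 1L,
                         cds_len = 121, cds = list(tibble::tibble(start = 10L,
                                                                  end = 130L)))
  expect_message(out <- spliced_cds(genome, gene), "pseudo-CDS")
  expect_true(out$pseudo_cds)
})

test_that("translation follows the standard code with stop handling", {
  expect_equal(translate_cds("ATGAAATAG"), "MK")
  expect_equal(translate_cds("ATG"), "M")
  expect_error(translate_cds("ATGA"), "divisible")
  expect_equal(translate_cds("ATGNNNAAA"), "MXK")  # ambiguity -> X
  flagged <- add_proteins(tibble::tibble(
    gene_id = "g", cds_seq = "ATGTAGAAA", pseudo_cds = FALSE))
  expect_true(flagged$internal_stop)
})

test_that("extract_upstream measures 1500 bp before the CDS, clipped at edges", {
  set.seed(5)
  chr <- random_dna(8000)
  genome <- tibble::tibble(id = "c", seq = chr, moltype = "dna")
  mk <- function(strand, s, e) {
    tibble::tibble(gene_id = "g", transcript_id = "g.1", chrom = "c",
                   strand = strand, n_transcripts = 1L, exon_count = 1L,
                   cds_len = e - s + 1,
                   cds = list(tibble::tibble(start = as.integer(s),
                                             end = as.integer(e))))
  }
  up <- extract_upstream(genome, mk("+", 2000, 2300))
  expect_equal(c(up$start, up$end, up$obtained_length), c(500, 1999, 1500))
  expect_equal(up$promoter, substring(chr, 500, 1999))

  expect_warning(trunc <- extract_upstream(genome, mk("+", 800, 1000)),
                 "truncated")
  expect_equal(c(trunc$start, trunc$end, trunc$obtained_length), c(1, 799, 799))

  minus <- extract_upstream(genome, mk("-", 4000, 5000))
  expect_equal(c(minus$start, minus$end), c(5001, 6500))
  expect_equal(minus$promoter, revcomp(substring(chr, 5001, 6500)))

  expect_warning(none <- extract_upstream(genome, mk("-", 7000, 8000)),
                 "empty promoter")
  expect_equal(none$obtained_length, 0L)
})
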