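mk_gene <- function(id, strand, segs) {
  tibble::tibble(gene_id = id, transcript_id = paste0(id, ".1"), chrom = "c",
                 strand = strand, n_transcripts = 1L,
                 exon_count = nrow(segs),
                 cds_len = sum(segs$end - segs$start + 1), cds = list(segs))
}

test_that("intron phase arithmetic follows cum_cds mod 3", {
  # exon lengths 300/301/302 ahead of the junction give phases 0/1/2
  for (cum in c(300L, 301L, 302L)) {
    g <- mk_gene("g", "+", tibble::tibble(start = c(1L, cum + 101L),
                                          end = c(cum, cum + 400L)))
    rec <- gene_introns(g)
    expect_equal(rec$cum_cds, cum)
    expect_equal(rec$phase, cum %% 3)
    expect_equal(rec$residue, cum %/% 3 + 1L)
  }
  # single-exon gene: no records
  expect_equal(nrow(gene_introns(mk_gene("s", "+",
                                         tibble::tibble(start = 1L, end = 300L)))),
               0L)
})

test_that("minus-strand genes count coding nucleotides in transcription order", {
  # transcription order on '-' is descending genomic coordinate
  g <- mk_gene("g", "-", tibble::tibble(start = c(101L, 1001L),
                                        end = c(400L, 1100L)))
  rec <- gene_introns(g)
  expect_equal(rec$cum_cds, 100L)  # the genomically-last segment comes first
  expect_equal(rec$phase, 1)
})

test_that("projection maps residues to alignment columns", {
  rec <- tibble::tibble(gene_id = "g", intron_index = 1L, cum_cds = 6L,
                        phase = 0L, residue = 3L)
  aln <- tibble::tibble(gene_id = "g", aligned = "MK-LV")
  expect_equal(project_introns(rec, aln)$column, 4L)  # third non-gap char
  gapless <- tibble::tibble(gene_id = "g", aligned = "MKLV")
  expect_equal(project_introns(rec, gapless)$column, 3L)
  rec_bad <- dplyr::mutate(rec, residue = 9L)
  expect_error(project_introns(rec_bad, aln), "beyond the degapped row")
})

test_that("projection is order preserving within a gene", {
  sim <- small_sim()
  genome <- read_fasta(sim$paths$genome)
  genes <- add_proteins(spliced_cds(genome, read_gff3(sim$paths$gff3)))
  fam <- genes[genes$gene_id %in% sim$truth$family, ]
  aln <- progressive_align(tibble::tibble(gene_id = fam$gene_id,
                                          protein = fam$protein))
  rec <- project_introns(gene_introns(fam), aln)
  by_gene <- split(rec, rec$gene_id)
  for (g in by_gene) {
    expect_true(all(diff(g$column[order(g$intron_index)]) > 0))
  }
})

test_that("single-linkage clustering labels classes left to right", {
  rec <- tibble::tibble(gene_id = c("a", "b", "c"),
                        intron_index = 1L, cum_cds = 3L, phase = 0L,
                        residue = 2L, column = c(10L, 11L, 50L))
  cl <- cluster_intron_classes(rec, tolerance = 3)
  expect_equal(cl$class_label, c("I-1", "I-1", "I-2"))
  # one gene, two introns: two singleton classes in positional order
  rec2 <- tibble::tibble(gene_id = "a", intron_index = 1:2,
                         cum_cds = c(3L, 9L), phase = 0L, residue = c(2L, 4L),
                         column = c(40L, 12L))
  cl2 <- cluster_intron_classes(rec2, tolerance = 3)
  expect_equal(cl2$class_label, c("I-2", "I-1"))
  # tolerance 0 keeps exact columns apart
  cl0 <- cluster_intron_classes(rec, tolerance = 0)
  expect_equal(length(unique(cl0$class_label)), 3L)
})

test_that("class labels are stable under alignment row permutation", {
  set.seed(701)
  rec <- tibble::tibble(gene_id = sample(letters[1:8]), intron_index = 1L,
                        cum_cds = 3L, phase = sample(0:2, 8, TRUE),
                        residue = 2L,
                        column = c(5L, 6L, 5L, 30L, 31L, 30L, 60L, 61L))
  a <- cluster_intron_classes(rec, tolerance = 3)
  b <- cluster_intron_classes(rec[sample(1:8), ], tolerance = 3)
  key_a <- stats::setNames(a$class_label, paste(a$gene_id, a$column))
  key_b <- stats::setNames(b$class_label, paste(b$gene_id, b$column))
  expect_equal(key_a[sort(names(key_a))], key_b[sort(names(key_b))])
})

test_that("conservation percentages use intron-bearing genes as denominator", {
  rec <- tibble::tibble(
    gene_id = c(paste0("g", 1:9), "g10"),
    intron_index = 1L, cum_cds = 3L,
    phase = c(rep(1L, 9), 0L), residue = 2L,
    column = c(rep(20L, 9), 80L))
  cl <- cluster_intron_classes(rec, tolerance = 3)
  tab <- conservation_table(cl)
  expect_equal(tab$pct_genes[tab$class_label == "I-1"], 90)
  expect_equal(sum(tab$n_introns), nrow(rec))
  expect_equal(sum(tab$phase0 + tab$phase1 + tab$phase2), nrow(rec))
})

test_that("gain/loss matrix reports per-group class fractions", {
  cl <- tibble::tibble(gene_id = c("a1", "a2", "b1"),
                       intron_index = 1L, cum_cds = 3L, phase = 1L,
                       residue = 2L, column = 10L, class_label = "I-1")
  groups <- tibble::tibble(gene_id = c("a1", "a2", "b1", "b2", "c1"),
                           group = c("A", "A", "B", "B", "C"))
  gl <- gain_loss_matrix(cl, groups)
  expect_equal(gl$`I-1`[gl$group == "A"], 1)
  expect_equal(gl$`I-1`[gl$group == "B"], 0.5)
  expect_equal(gl$`I-1`[gl$group == "C"], 0)
  # column sums consistent with conservation counts
  expect_equal(sum(gl$`I-1` * gl$n_genes), 3)
})
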