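# Tiny on-disk fixtures built in code.

tmp_fasta <- function(records, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = env)
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

tmp_gff3 <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".gff3", .local_envir = env)
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_line <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "test", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# A two-exon plus-strand gene and a minus-strand gene on a toy chromosome.
toy_genome_annotation <- function(env = parent.frame()) {
  set.seed(404)
  chr <- random_dna(600)
  # plant a known CDS: exon1 101-160, exon2 201-260 (plus strand)
  genome_path <- tmp_fasta(list(chr1 = chr), env = env)
  gff_path <- tmp_gff3(c(
    gff_line("chr1", "gene", 101, 260, "+", "ID=gA"),
    gff_line("chr1", "mRNA", 101, 260, "+", "ID=gA.1;Parent=gA"),
    gff_line("chr1", "CDS", 101, 160, "+", "ID=cA1;Parent=gA.1"),
    gff_line("chr1", "CDS", 201, 260, "+", "ID=cA2;Parent=gA.1"),
    gff_line("chr1", "gene", 301, 420, "-", "ID=gB"),
    gff_line("chr1", "mRNA", 301, 420, "-", "ID=gB.1;Parent=gB"),
    gff_line("chr1", "CDS", 301, 360, "-", "ID=cB1;Parent=gB.1"),
    gff_line("chr1", "CDS", 391, 420, "-", "ID=cB2;Parent=gB.1")
  ), env = env)
  list(genome = genome_path, gff = gff_path, chr = chr)
}

# A small simulated study shared by generator/pipeline tests; built once.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "ugtfam-small-sim")
      cache <<- ugtfam::simulate_ugt_study(
        ugtfam::sim_config(seed = 11, n_family = 12, n_decoys = 6),
        dir = dir)
    }
    cache
  }
})
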