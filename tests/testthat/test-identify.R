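consensus44 <- "WAPQVEVLAHPAVGCFVTHCGWNSTLESLSCGVPMVAWPLYAEQ"

test_that("build_pspg_model validates input and scores sensibly", {
  m <- build_pspg_model(consensus44)
  expect_s3_class(m, "pspg_model")
  expect_equal(m$width, 44L)
  # single all-W column: W uniquely maximal there
  expect_equal(names(which.max(m$weights[1, ])), "W")
  expect_error(build_pspg_model(substr(consensus44, 1, 40)), "44")
  expect_error(build_pspg_model(gsub("A", "1", consensus44)),
               "non-amino-acid")
  # symmetric counts give symmetric weights under uniform background
  rows <- c(paste(rep("A", 44), collapse = ""),
            paste(rep("C", 44), collapse = ""))
  m2 <- build_pspg_model(rows)
  expect_equal(unname(m2$weights[1, "A"]), unname(m2$weights[1, "C"]))
  expect_gt(m2$weights[1, "A"], m2$weights[1, "D"])
})

test_that("scan finds a planted consensus and is shift invariant", {
  m <- build_pspg_model(consensus44)
  set.seed(301)
  prot <- paste0(random_protein(17), consensus44, random_protein(60))
  hit <- scan_proteins(c(p1 = prot), m, n_shuffles = 50, seed = 1)
  expect_equal(hit$start, 18L)                      # 1-based offset
  expect_equal(hit$score, sum(apply(m$weights, 1, max)), tolerance = 1e-12)

  shifted <- paste0(random_protein(7), prot)
  hit2 <- scan_proteins(c(p1 = shifted), m, n_shuffles = 50, seed = 1)
  expect_equal(hit2$start, hit$start + 7L)
  expect_equal(hit2$score, hit$score)

  expect_message(none <- scan_proteins(c(tiny = random_protein(30)), m,
                                       n_shuffles = 10, seed = 1),
                 "shorter")
  expect_equal(nrow(none), 0L)
})

test_that("window scores are additive per-column lookups", {
  m <- build_pspg_model(consensus44)
  set.seed(302)
  prot <- random_protein(60)
  chars <- strsplit(prot, "")[[1]]
  hit <- scan_proteins(c(p = prot), m, n_shuffles = 10, seed = 1)
  # brute-force re-scan
  manual <- vapply(seq_len(60 - 44 + 1), function(s) {
    sum(vapply(1:44, function(j) m$weights[j, chars[s + j - 1]], numeric(1)))
  }, numeric(1))
  expect_equal(hit$score, max(manual), tolerance = 1e-12)
  expect_equal(hit$start, which.max(manual))
})

test_that("empirical p agrees with the brute-force shuffle null", {
  m <- build_pspg_model(consensus44)
  set.seed(303)
  prot <- random_protein(80)
  got <- scan_proteins(c(p = prot), m, n_shuffles = 200, seed = 99)
  want <- oracle_empirical_p(prot, m, n_shuffles = 200, seed = 99)
  expect_equal(got$empirical_p, want, tolerance = 1e-12)
})

test_that("classify_candidates applies p, length and duplicate filters", {
  m <- build_pspg_model(consensus44)
  set.seed(304)
  core <- paste0(random_protein(150), consensus44, random_protein(150))
  proteins <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    protein = c(core,
                core,                                   # exact duplicate
                paste0(random_protein(100), consensus44,
                       random_protein(500)),            # too long
                random_protein(400),                    # decoy, no motif
                paste0(random_protein(50), consensus44,
                       random_protein(100)))            # too short
  )
  hits <- scan_proteins(proteins, m, n_shuffles = 400, seed = 5)
  cls <- suppressMessages(classify_candidates(proteins, hits))
  expect_equal(cls$reason[cls$gene_id == "g2"], "duplicate_of_g1")
  expect_equal(cls$reason[cls$gene_id == "g3"], "too_long")
  expect_equal(cls$reason[cls$gene_id == "g4"], "no_significant_pspg_hit")
  expect_equal(cls$reason[cls$gene_id == "g5"], "too_short")
  expect_equal(family_members(cls)$gene_id, "g1")
})

test_that("a PSPG model round-trips through its TSV representation", {
  m <- build_pspg_model(consensus44)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pspg_model(m, path)
  m2 <- read_pspg_model(path)
  expect_equal(unname(m2$weights), unname(m$weights), tolerance = 1e-9)
  expect_equal(m2$consensus, m$consensus)
})

test_that("protein stats match hand-computed masses and charge behavior", {
  g <- protein_stats(c(gly = "G"))
  expect_equal(g$mw_kda, (57.0519 + 18.01524) / 1000, tolerance = 1e-9)
  set.seed(305)
  p <- random_protein(120)
  st <- protein_stats(c(x = p))
  expect_lt(abs(protein_charge(p, st$pi)), 1e-3)
  expect_lt(protein_stats(c(a = "DDDD"))$pi, protein_stats(c(b = "KKKK"))$pi)
  expect_error(protein_stats(c(bad = "")), "empty")
  expect_warning(protein_stats(c(x = "AXA")), "X residue")
})

test_that("pI is in the ballpark of an independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(306)
  for (p in replicate(5, random_protein(200))) {
    ours <- protein_stats(c(x = p))$pi
    theirs <- seqinr::computePI(strsplit(p, "")[[1]])
    expect_lt(abs(ours - theirs), 1.5)  # different pKa tables
  }
})
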