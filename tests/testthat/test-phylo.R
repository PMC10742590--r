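test_that("NJ recovers the stated 4-taxon tree exactly", {
  # distances by path summation on ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(D)
  expect_equal(unname(stats::cophenetic(tree)[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-12)
  # AB|CD is the single split
  split_tips <- phangorn::Descendants(
    tree, setdiff(unique(tree$edge[, 2]), 1:4), "tips")
  keys <- lapply(split_tips, function(i) sort(tree$tip.label[i]))
  expect_true(list(c("A", "B")) %in% keys || list(c("C", "D")) %in% keys)
})

test_that("3-taxon and 2-taxon cases use the closed forms", {
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- neighbor_joining(D3)
  # v_a = (3 + 4 - 5)/2 = 1, v_b = 2, v_c = 3
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  t2 <- neighbor_joining(matrix(c(0, 4, 4, 0), 2, 2,
                                dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(sum(t2$edge.length), 4)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ is exact on random additive matrices", {
  set.seed(601)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = stats::runif, min = 0.1, max = 2)
    D <- make_additive_matrix(tr)
    nj <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), nj), 0)
    expect_lt(max(abs(stats::cophenetic(nj)[rownames(D), colnames(D)] - D)),
              1e-9)
  }
})

test_that("NJ tie-breaking is deterministic", {
  D <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap gives 100% support to a clean two-clade signal", {
  aln <- tibble::tibble(
    gene_id = c("a1", "a2", "b1", "b2"),
    aligned = c(strrep("A", 30), strrep("A", 30),
                strrep("T", 30), strrep("T", 30)))
  phy <- bootstrap_support(aln, replicates = 50, seed = 3)
  expect_equal(nrow(phy$supports), 1L)
  expect_equal(phy$supports$support, 100)
})

test_that("bootstrap is seed-deterministic and row-order invariant", {
  set.seed(602)
  base <- random_protein(60)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(seq_along(ch), k)
    ch[i] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], k, replace = TRUE)
    paste(ch, collapse = "")
  }
  aln <- progressive_align(c(a = mut(base, 2), b = mut(base, 3),
                             c = mut(base, 8), d = mut(base, 9),
                             e = mut(base, 15)))
  p1 <- bootstrap_support(aln, replicates = 100, seed = 42)
  p2 <- bootstrap_support(aln, replicates = 100, seed = 42)
  expect_equal(p1$supports, p2$supports)
  perm <- aln[c(3, 1, 5, 2, 4), ]
  p3 <- bootstrap_support(perm, replicates = 100, seed = 42)
  s1 <- p1$supports[order(p1$supports$key), c("key", "support")]
  s3 <- p3$supports[order(p3$supports$key), c("key", "support")]
  expect_equal(s1, s3)
})

test_that("tidy and glance summarize a phylogeny", {
  aln <- tibble::tibble(
    gene_id = c("a1", "a2", "b1", "b2"),
    aligned = c(strrep("A", 30), strrep("C", 30),
                strrep("T", 30), strrep("G", 30)))
  phy <- bootstrap_support(aln, replicates = 20, seed = 1)
  td <- tidy(phy)
  expect_true(all(c("parent", "child", "length", "support") %in% names(td)))
  expect_equal(nrow(td), nrow(phy$tree$edge))
  gl <- glance(phy)
  expect_equal(gl$n_tips, 4L)
  expect_equal(gl$replicates, 20L)
})

test_that("group assignment follows anchors, ties and fresh clades", {
  # leaf sister to a lone group-D anchor inherits D
  tr <- ape::read.tree(text = "((aD:1,x:1):1,(aA:1,y:1):1);")
  g <- assign_groups(tr, c(aD = "D", aA = "A"))
  expect_equal(g$group[g$gene_id == "x"], "D")
  expect_equal(g$group[g$gene_id == "y"], "A")
  expect_true(all(g$is_anchor[g$gene_id %in% c("aD", "aA")]))

  # exact tie between groups C and D: warning, alphabetically earlier wins
  tie <- ape::read.tree(text = "((x:1,aC:3):1,(aD:1,z:4):1);")
  expect_warning(gt <- assign_groups(tie, c(aC = "C", aD = "D")),
                 "equidistant")
  expect_equal(gt$group[gt$gene_id == "x"], "C")

  # an anchor-free clade between two multi-group flanks gets a fresh letter
  tr2 <- ape::read.tree(text = paste0(
    "(((aA:1,a2:1):2,(aB:1,b2:1):2):1,",
    "((f1:1,f2:1):2,((aC:1,c2:1):2,(aD:1,d2:1):2):1):1);"))
  anchors <- c(aA = "A", aB = "B", aC = "C", aD = "D")
  g2 <- suppressWarnings(assign_groups(tr2, anchors))  # f-leaves tie C/D
  expect_equal(unique(g2$group[g2$gene_id %in% c("f1", "f2")]), "E")
  expect_equal(g2$group[g2$gene_id == "c2"], "C")
  # labels partition all leaves
  expect_false(any(is.na(g2$group)))

  expect_error(assign_groups(tr, c(missing_anchor = "A")),
               "missing from tree.*missing_anchor")
})
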