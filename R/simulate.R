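# 44-residue PSPG-box consensus used as the generator's ancestral motif.
PSPG_CONSENSUS <- "WAPQVEVLAHPAVGCFVTHCGWNSTLESLSCGVPMVAWPLYAEQ"

random_aa <- function(n) sample(AA_ORDER, n, replace = TRUE)
random_nt <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

mutate_residue <- function(aa) {
  vapply(aa, function(a) sample(setdiff(AA_ORDER, a), 1), character(1),
         USE.NAMES = FALSE)
}

#' Default synthetic cis-element dictionary
#'
#' Six invented elements (two per category) with non-palindromic,
#' mutually non-complementary patterns, so a planted occurrence yields
#' exactly one hit. One pattern carries an IUPAC degeneracy to exercise
#' ambiguity matching. Used by the simulator and its recovery tests; real
#' analyses use [plantcare_dictionary()] or a user dictionary.
#'
#' @return A dictionary tibble.
#' @export
synthetic_dictionary <- function() {
  tibble::tibble(
    name = c("LRE-A", "LRE-B", "HRE-A", "HRE-B", "SRE-A", "SRE-B"),
    pattern = c("GGTTAA", "CTCCRC", "ACGTGG", "TGACGT", "CAACTG", "CCGAAA"),
    category = c("light", "light", "hormone", "hormone", "stress", "stress")
  )
}

#' Simulation configuration for the synthetic study
#'
#' Bundles every knob of the generator; the defaults define the study
#' conditions under which the pipeline's recovery properties are asserted.
#' The seed fully determines all output bytes.
#'
#' @param seed Integer seed.
#' @param n_chromosomes Number of chromosomes genes are spread over.
#' @param n_family Number of planted family genes (>= n_anchor_groups + 4).
#' @param n_decoys Number of motif-free decoy genes.
#' @param motif_identity Fraction of motif columns left at consensus per
#'   family gene, in (0, 1].
#' @param n_anchor_groups Number of anchored phylogenetic groups (>= 4); one
#'   additional anchor-free clade is always planted in the middle of the
#'   backbone so group discovery is exercised.
#' @param ancestor_length Ancestral protein length (residues).
#' @param motif_start 1-based residue where the 44-aa motif begins.
#' @param substitution_rate Per-site substitution probability per unit
#'   branch length.
#' @param indel_rate Per-branch probability of one 1-3 residue indel
#'   (kept out of the motif and a +/-2 residue guard band around intron
#'   sites so planted truth stays unambiguous).
#' @param clade_branch_range,backbone_branch_range Branch-length ranges for
#'   within-group subtrees and the backbone joining groups.
#' @param intron_sites Tibble of planted homologous intron sites:
#'   `residue` (strictly increasing 1-based ancestor positions) and `phase`
#'   (0/1/2).
#' @param intron_loss_rate Per-gene probability of losing a site present in
#'   its clade.
#' @param intron_length_range Intron lengths in nt (canonical GT...AG).
#' @param promoter_length Promoter length in bp.
#' @param dictionary Cis-element dictionary used for planting; default
#'   [synthetic_dictionary()].
#' @param tissues Tissue labels of the expression matrix.
#' @param tissue_specific_plan Named integer vector: how many genes are
#'   specific to each tissue.
#' @param n_zero_genes Genes with zero expression everywhere (dropped by
#'   expression calls).
#' @param up_folds,down_folds Planted fold changes for the treatment
#'   contrast (others get fold 1).
#' @param ct_targets Number of qPCR target genes.
#' @param ct_conditions Condition labels; the first is the calibrator.
#' @param ct_replicates Replicates per (gene, condition).
#' @param ddct_plan Matrix (targets x conditions) of planted ddCt values;
#'   a default ladder is used when NULL.
#' @param expression_noise_cv,ct_noise_sd Noise knobs, 0 by default so
#'   recovery is exact.
#' @param decoy_length_range Decoy protein lengths.
#' @param decoy_margin Required score gap (bits) between the weakest family
#'   motif and the strongest decoy window.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       n_family = 20L,
                       n_decoys = 30L,
                       motif_identity = 0.8,
                       n_anchor_groups = 4L,
                       ancestor_length = 460L,
                       motif_start = 380L,
                       substitution_rate = 1,
                       indel_rate = 0.3,
                       clade_branch_range = c(0.02, 0.08),
                       backbone_branch_range = c(0.10, 0.20),
                       intron_sites = tibble::tibble(
                         residue = c(60L, 150L, 240L, 330L),
                         phase = c(0L, 1L, 1L, 2L)),
                       intron_loss_rate = 0.1,
                       intron_length_range = c(80L, 200L),
                       promoter_length = 1500L,
                       dictionary = NULL,
                       tissues = c("flower", "leaf", "stem", "stolon",
                                   "young_tuber", "mature_tuber", "root"),
                       tissue_specific_plan = c(leaf = 3L, root = 2L,
                                                stolon = 2L, young_tuber = 1L),
                       n_zero_genes = 2L,
                       up_folds = c(3, 4, 6, 8, 10),
                       down_folds = c(0.2, 0.25, 0.3),
                       ct_targets = 4L,
                       ct_conditions = c("0h", "6h", "12h", "24h"),
                       ct_replicates = 3L,
                       ddct_plan = NULL,
                       expression_noise_cv = 0,
                       ct_noise_sd = 0,
                       decoy_length_range = c(360L, 520L),
                       decoy_margin = 10) {
  cfg <- as.list(environment())
  cfg$dictionary <- dictionary %||% synthetic_dictionary()
  if (n_anchor_groups < 4) {
    stop("sim_config(): need at least 4 anchored groups so the planted ",
         "anchor-free clade is separable from any single group")
  }
  if (n_family < n_anchor_groups + 4) {
    stop("sim_config(): n_family too small for the group layout")
  }
  stopifnot(motif_identity > 0, motif_identity <= 1,
            indel_rate >= 0, indel_rate <= 1,
            intron_loss_rate >= 0, intron_loss_rate <= 1,
            all(diff(cfg$intron_sites$residue) > 0),
            all(cfg$intron_sites$phase %in% 0:2),
            motif_start + 43 <= ancestor_length)
  if (any(cfg$intron_sites$residue + 2 >= motif_start &
            cfg$intron_sites$residue - 2 <= motif_start + 43)) {
    stop("sim_config(): intron site guard band overlaps the motif")
  }
  if (max(cfg$intron_sites$residue) + 2 > ancestor_length ||
      min(cfg$intron_sites$residue) < 3) {
    stop("sim_config(): intron site beyond the ancestor protein")
  }
  if (is.null(cfg$ddct_plan)) {
    ladder <- rbind(c(0, -1, -2, -3), c(0, -2, -1, -0.5),
                    c(0, 1, 0.5, -1), c(0, 2, 1, 0.5))
    cfg$ddct_plan <- ladder[rep_len(seq_len(nrow(ladder)), ct_targets),
                            rep_len(seq_len(4), length(ct_conditions)),
                            drop = FALSE]
    cfg$ddct_plan[, 1] <- 0
  }
  structure(cfg, class = "sim_config")
}

# ---- internal generator pieces ------------------------------------------

subtree_fragment <- function(tips, range) {
  if (length(tips) == 1) return(tips)
  t <- ape::rtree(length(tips), tip.label = tips, br = stats::runif,
                  min = range[1], max = range[2])
  sub(";$", "", ape::write.tree(t))
}

make_family_tree <- function(cfg) {
  k <- cfg$n_anchor_groups
  free_size <- max(2L, round(0.2 * cfg$n_family))
  rest <- cfg$n_family - free_size
  sizes <- rep(rest %/% k, k)
  if (rest %% k > 0) sizes[seq_len(rest %% k)] <- sizes[seq_len(rest %% k)] + 1
  ids <- sprintf("g%03d", seq_len(cfg$n_family))
  clade_of <- character(0)
  frags <- character(k)
  used <- 0
  for (i in seq_len(k)) {
    tips <- ids[used + seq_len(sizes[i])]
    used <- used + sizes[i]
    frags[i] <- subtree_fragment(tips, cfg$clade_branch_range)
    clade_of[tips] <- LETTERS[i]
  }
  free_tips <- ids[used + seq_len(free_size)]
  clade_of[free_tips] <- "free"
  free_frag <- subtree_fragment(free_tips, cfg$clade_branch_range)
  bb <- function() sprintf("%.6f", stats::runif(1, cfg$backbone_branch_range[1],
                                                cfg$backbone_branch_range[2]))
  join <- function(fr) {
    out <- fr[1]
    for (f in fr[-1]) out <- paste0("(", out, ":", bb(), ",", f, ":", bb(), ")")
    out
  }
  left <- join(frags[seq_len(ceiling(k / 2))])
  right <- join(frags[(ceiling(k / 2) + 1):k])
  newick <- paste0("((", left, ":", bb(), ",(", free_frag, ":", bb(), ",",
                   right, ":", bb(), "):", bb(), "):", bb(), ");")
  tree <- ape::read.tree(text = newick)
  anchors <- tibble::tibble(
    id = vapply(LETTERS[seq_len(k)],
                function(g) min(names(clade_of)[clade_of == g]), character(1)),
    group = LETTERS[seq_len(k)]
  )
  expected <- ifelse(clade_of == "free", LETTERS[k + 1], clade_of)
  list(tree = tree, clade_of = clade_of,
       expected_groups = stats::setNames(expected, names(clade_of)),
       anchors = anchors, fresh_letter = LETTERS[k + 1])
}

evolve_family <- function(cfg, tree) {
  L <- cfg$ancestor_length
  motif_idx <- cfg$motif_start:(cfg$motif_start + 43)
  guard_idx <- unique(unlist(lapply(cfg$intron_sites$residue,
                                    function(r) (r - 2):(r + 2))))
  protect_indel <- union(motif_idx, guard_idx)
  ancestor <- random_aa(L)
  ancestor[motif_idx] <- strsplit(PSPG_CONSENSUS, "")[[1]]

  n <- length(tree$tip.label)
  states <- vector("list", n + tree$Nnode)
  root <- n + 1L
  states[[root]] <- list(anc = seq_len(L), aa = ancestor)
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    par <- edges$edge[e, 1]; chd <- edges$edge[e, 2]
    bl <- edges$edge.length[e]
    st <- states[[par]]
    p <- min(0.5, cfg$substitution_rate * bl)
    mutable <- which(!(st$anc %in% motif_idx))
    hit <- mutable[stats::runif(length(mutable)) < p]
    if (length(hit) > 0) st$aa[hit] <- mutate_residue(st$aa[hit])
    if (stats::runif(1) < cfg$indel_rate) {
      len <- sample(1:3, 1)
      cur <- length(st$aa)
      free_slot <- !(st$anc %in% protect_indel) | is.na(st$anc)
      if (stats::runif(1) < 0.5) {        # deletion
        ok <- which(vapply(seq_len(cur - len + 1),
                           function(s) all(free_slot[s:(s + len - 1)]),
                           logical(1)))
        if (length(ok) > 0) {
          s <- ok[sample.int(length(ok), 1)]
          keep <- setdiff(seq_len(cur), s:(s + len - 1))
          st$aa <- st$aa[keep]; st$anc <- st$anc[keep]
        }
      } else {                            # insertion
        ok <- which(vapply(0:cur, function(pos) {
          left_ok <- pos == 0 || free_slot[pos]
          right_ok <- pos == cur || free_slot[pos + 1]
          left_ok && right_ok
        }, logical(1))) - 1L
        if (length(ok) > 0) {
          pos <- ok[sample.int(length(ok), 1)]
          st$aa <- append(st$aa, random_aa(len), after = pos)
          st$anc <- append(st$anc, rep(NA_integer_, len), after = pos)
        }
      }
    }
    states[[chd]] <- st
  }

  n_mut <- round((1 - cfg$motif_identity) * 44)
  tips <- stats::setNames(vector("list", n), tree$tip.label)
  for (i in seq_len(n)) {
    st <- states[[i]]
    if (n_mut > 0) {
      pos <- match(sample(motif_idx, n_mut), st$anc)
      st$aa[pos] <- mutate_residue(st$aa[pos])
    }
    tips[[tree$tip.label[i]]] <- list(
      protein = paste(st$aa, collapse = ""),
      anc_map = match(seq_len(L), st$anc)  # ancestor residue -> tip residue
    )
  }
  list(tips = tips, ancestor = paste(ancestor, collapse = ""),
       motif_idx = motif_idx)
}

reverse_translate <- function(protein) {
  if (is.null(the$codons)) {
    gc <- Biostrings::GENETIC_CODE
    the$codons <- split(names(gc), unname(gc))
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(chars, function(a) {
    opts <- the$codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1), USE.NAMES = FALSE)
  stop_codon <- sample(c("TAA", "TGA", "TAG"), 1)
  paste(c(codons, stop_codon), collapse = "")
}

scan_hits_any <- function(seq, dictionary) {
  subj <- Biostrings::DNAString(seq)
  purrr::pmap_dfr(dictionary, function(name, pattern, category) {
    p <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
    m <- Biostrings::matchPattern(revcomp(pattern), subj, fixed = "subject")
    tibble::tibble(
      element = name,
      start = c(BiocGenerics::start(p), BiocGenerics::start(m)),
      width = nchar(pattern)
    )
  })
}

clean_background <- function(len, dictionary) {
  x <- random_nt(len)
  for (iter in 1:100) {
    hits <- scan_hits_any(paste(x, collapse = ""), dictionary)
    if (nrow(hits) == 0) return(x)
    for (h in seq_len(nrow(hits))) {
      span <- hits$start[h]:(hits$start[h] + hits$width[h] - 1)
      x[span] <- random_nt(length(span))
    }
  }
  stop("clean_background(): could not clear dictionary matches")
}

realize_iupac <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) {
    s <- sets[[c]]
    s[sample.int(length(s), 1)]
  }, character(1)), collapse = "")
}

# Build a promoter carrying exactly `plan` occurrences of each element
# (counts over both strands) and nothing else.
build_promoter <- function(len, plan, dictionary) {
  occ <- plan[plan$count > 0, , drop = FALSE]
  for (try in 1:30) {
    x <- clean_background(len, dictionary)
    placed <- list()
    intervals <- matrix(numeric(0), ncol = 2)
    ok <- TRUE
    for (r in seq_len(nrow(occ))) {
      pat <- dictionary$pattern[dictionary$name == occ$element[r]]
      w <- nchar(pat)
      for (k in seq_len(occ$count[r])) {
        pos <- NA
        for (att in 1:200) {
          cand <- sample.int(len - w + 1, 1)
          if (nrow(intervals) == 0 ||
              all(cand + w <= intervals[, 1] | cand > intervals[, 2] + 1)) {
            pos <- cand
            break
          }
        }
        if (is.na(pos)) { ok <- FALSE; break }
        intervals <- rbind(intervals, c(pos, pos + w - 1))
        strand <- sample(c("+", "-"), 1)
        real <- realize_iupac(pat)
        if (strand == "-") real <- revcomp(real)
        x[pos:(pos + w - 1)] <- strsplit(real, "", fixed = TRUE)[[1]]
      }
      if (!ok) break
    }
    if (!ok) next
    seq <- paste(x, collapse = "")
    got <- scan_hits_any(seq, dictionary) %>% dplyr::count(.data$element)
    want <- occ %>% dplyr::select("element", n = "count")
    merged <- dplyr::full_join(got, want, by = "element",
                               suffix = c("_got", "_want")) %>%
      tidyr::replace_na(list(n_got = 0L, n_want = 0L))
    if (all(merged$n_got == merged$n_want)) return(seq)
  }
  stop("build_promoter(): could not realize the planted element plan")
}

# Split a CDS (with stop codon) at the given cumulative-coding-nt cut points
# and interleave canonical GT...AG introns. Returns the gene body in sense
# orientation plus CDS segment coordinates within the body (1-based).
assemble_gene_body <- function(cds_nt, cums, intron_length_range) {
  len <- nchar(cds_nt)
  stopifnot(all(cums > 0), all(cums < len), !is.unsorted(cums, strictly = TRUE))
  starts <- c(1, cums + 1)
  ends <- c(cums, len)
  exons <- substring(cds_nt, starts, ends)
  body <- ""
  segs <- tibble::tibble(start = integer(0), end = integer(0))
  for (k in seq_along(exons)) {
    s <- nchar(body) + 1L
    body <- paste0(body, exons[k])
    segs <- dplyr::bind_rows(segs, tibble::tibble(start = s, end = nchar(body)))
    if (k < length(exons)) {
      ilen <- sample(intron_length_range[1]:intron_length_range[2], 1)
      intron <- paste0("GT", paste(random_nt(ilen - 4), collapse = ""), "AG")
      body <- paste0(body, intron)
    }
  }
  list(body = body, segs = segs)
}

gff_escape <- function(x) x  # synthetic ids are plain

# CDS phase column values in transcription order.
cds_phases <- function(lens) {
  cum <- c(0, cumsum(lens)[-length(lens)])
  (3 - cum %% 3) %% 3
}

#' Simulate a synthetic UGT-family study with planted ground truth
#'
#' Emits a toy genome (FASTA), annotation (GFF3), PSPG reference block,
#' anchor table, cis-element dictionary, expression/treatment/Ct tables, the
#' generating tree (Newick) and a `truth.json` recording every planted fact,
#' so each pipeline stage has an exact recovery target. Deterministic: the
#' same config (including its seed) reproduces identical bytes.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `paths` (named file paths), `truth`
#'   (the planted truth, as written to truth.json) and `config`.
#' @export
simulate_ugt_study <- function(config = sim_config(), dir = tempfile("ugtsim")) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::local_seed(cfg$seed)
  dict <- cfg$dictionary

  fam <- make_family_tree(cfg)
  evo <- evolve_family(cfg, fam$tree)
  family_ids <- sort(names(evo$tips))
  decoy_ids <- sprintf("d%03d", seq_len(cfg$n_decoys))

  # reference motif block and scoring model (used to reject decoys)
  ref_block <- c(PSPG_CONSENSUS, vapply(1:7, function(i) {
    ch <- strsplit(PSPG_CONSENSUS, "")[[1]]
    pos <- sample.int(44, 2)
    ch[pos] <- mutate_residue(ch[pos])
    paste(ch, collapse = "")
  }, character(1)))
  model <- build_pspg_model(ref_block)
  fam_scores <- vapply(family_ids, function(id) {
    max(pssm_window_scores_cpp(aa_encode(evo$tips[[id]]$protein),
                               model$weights))
  }, numeric(1))
  score_cap <- min(fam_scores) - cfg$decoy_margin

  draw_decoy <- function() {
    for (try in 1:500) {
      L <- sample(cfg$decoy_length_range[1]:cfg$decoy_length_range[2], 1)
      p <- paste(random_aa(L), collapse = "")
      enc <- aa_encode(p)
      best <- max(pssm_window_scores_cpp(enc, model$weights))
      if (best >= score_cap) next
      perms <- matrix(0L, 200, L)
      for (r in 1:200) perms[r, ] <- sample.int(L)
      if (mean(pssm_null_best_cpp(enc, model$weights, perms) >= best) >= 0.05) {
        return(list(protein = p, best = best))
      }
    }
    stop("simulate_ugt_study(): decoy rejection sampling failed")
  }
  decoys <- stats::setNames(lapply(decoy_ids, function(i) draw_decoy()),
                            decoy_ids)
  stopifnot(max(vapply(decoys, `[[`, numeric(1), "best")) <
              min(fam_scores) - cfg$decoy_margin + 1e-9)

  # planted intron sites: each gained on a random internal clade, with
  # per-gene losses
  sets <- node_tip_sets(fam$tree)
  n_t <- length(fam$tree$tip.label)
  cand_nodes <- setdiff(which(lengths(sets) >= 2 & lengths(sets) <= n_t - 2),
                        seq_len(n_t))
  site_presence <- lapply(seq_len(nrow(cfg$intron_sites)), function(s) {
    node <- cand_nodes[sample.int(length(cand_nodes), 1)]
    present <- sets[[node]]
    keep <- present[stats::runif(length(present)) >= cfg$intron_loss_rate]
    if (length(keep) == 0) keep <- present[1]
    sort(keep)
  })

  empty_introns <- tibble::tibble(site = integer(0), residue = integer(0),
                                  cum_cds = integer(0), phase = integer(0))
  introns_truth <- stats::setNames(lapply(family_ids, function(id) {
    tip <- evo$tips[[id]]
    rows <- purrr::map_dfr(seq_len(nrow(cfg$intron_sites)), function(s) {
      if (!id %in% site_presence[[s]]) return(NULL)
      r_gene <- tip$anc_map[cfg$intron_sites$residue[s]]
      ph <- cfg$intron_sites$phase[s]
      tibble::tibble(site = s, residue = as.integer(r_gene),
                     cum_cds = as.integer(3 * (r_gene - 1) + ph),
                     phase = as.integer(ph))
    })
    if (nrow(rows) == 0) return(empty_introns)
    rows <- rows[order(rows$cum_cds), ]
    stopifnot(all(rows$cum_cds %% 3 == rows$phase))  # generator self-check
    rows
  }), family_ids)

  # promoter element plans (family genes only; decoys get clean background)
  plans <- stats::setNames(lapply(family_ids, function(id) {
    tibble::tibble(
      element = dict$name,
      count = sample(0:3, nrow(dict), replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1))
    )
  }), family_ids)

  # build gene blocks (promoter + body, sense orientation)
  blocks <- list()
  for (id in family_ids) {
    promoter <- build_promoter(cfg$promoter_length, plans[[id]], dict)
    cds_nt <- reverse_translate(evo$tips[[id]]$protein)
    asm <- assemble_gene_body(cds_nt, introns_truth[[id]]$cum_cds,
                              cfg$intron_length_range)
    blocks[[id]] <- list(promoter = promoter, body = asm$body,
                         segs = asm$segs, cds_nt = cds_nt)
  }
  for (id in decoy_ids) {
    promoter <- paste(clean_background(cfg$promoter_length, dict),
                      collapse = "")
    cds_nt <- reverse_translate(decoys[[id]]$protein)
    blocks[[id]] <- list(promoter = promoter, body = cds_nt,
                         segs = tibble::tibble(start = 1L,
                                               end = nchar(cds_nt)),
                         cds_nt = cds_nt)
  }

  # place genes on chromosomes
  all_ids <- sample(c(family_ids, decoy_ids))
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  chrom_of <- stats::setNames(
    chrom_names[(seq_along(all_ids) - 1) %% cfg$n_chromosomes + 1], all_ids)
  strand_of <- stats::setNames(sample(c("+", "-"), length(all_ids),
                                      replace = TRUE), all_ids)
  chrom_seq <- stats::setNames(rep("", cfg$n_chromosomes), chrom_names)
  gene_segments <- list()   # genomic CDS segments (ascending) per gene
  spacer <- function() paste(random_nt(400), collapse = "")
  for (chr in chrom_names) chrom_seq[[chr]] <- spacer()
  for (id in all_ids) {
    chr <- chrom_of[[id]]
    b <- blocks[[id]]
    sense <- paste0(b$promoter, b$body)
    off <- nchar(chrom_seq[[chr]])
    plen <- nchar(b$promoter)
    lb <- nchar(sense)
    if (strand_of[[id]] == "+") {
      placed <- sense
      segs <- tibble::tibble(start = off + plen + b$segs$start,
                             end = off + plen + b$segs$end)
    } else {
      placed <- revcomp(sense)
      s_sense <- plen + b$segs$start
      e_sense <- plen + b$segs$end
      segs <- tibble::tibble(start = off + lb - e_sense + 1,
                             end = off + lb - s_sense + 1)
      segs <- segs[order(segs$start), ]
    }
    gene_segments[[id]] <- segs
    chrom_seq[[chr]] <- paste0(chrom_seq[[chr]], placed, spacer())
  }

  # GFF3 with 1-3 splice variants per gene; variant 1 is the full (longest)
  # CDS and therefore the representative
  gff_lines <- c("##gff-version 3")
  n_variants <- stats::setNames(
    sample(1:3, length(all_ids), replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    all_ids)
  variant_segs <- function(segs, strand, v) {
    if (v == 1) return(segs)
    if (nrow(segs) >= 2) {
      drop_idx <- if (strand == "+") nrow(segs) else 1L
      segs[-drop_idx, , drop = FALSE]
    } else {
      shrink <- 30L * (v - 1L)
      if (strand == "+") segs$end <- segs$end - shrink
      else segs$start <- segs$start + shrink
      segs
    }
  }
  for (id in all_ids) {
    chr <- chrom_of[[id]]; strand <- strand_of[[id]]
    segs <- gene_segments[[id]]
    gff_lines <- c(gff_lines, paste(
      chr, "ugtsim", "gene", min(segs$start), max(segs$end), ".", strand, ".",
      paste0("ID=", id), sep = "\t"))
    for (v in seq_len(n_variants[[id]])) {
      vs <- variant_segs(segs, strand, v)
      tid <- paste0(id, ".", v)
      gff_lines <- c(gff_lines, paste(
        chr, "ugtsim", "mRNA", min(vs$start), max(vs$end), ".", strand, ".",
        paste0("ID=", tid, ";Parent=", id), sep = "\t"))
      lens <- vs$end - vs$start + 1
      tr_order <- if (strand == "+") seq_len(nrow(vs)) else rev(seq_len(nrow(vs)))
      phases <- integer(nrow(vs))
      phases[tr_order] <- cds_phases(lens[tr_order])
      for (k in seq_len(nrow(vs))) {
        gff_lines <- c(gff_lines, paste(
          chr, "ugtsim", "CDS", vs$start[k], vs$end[k], ".", strand,
          phases[k], paste0("ID=cds-", tid, "-", k, ";Parent=", tid),
          sep = "\t"))
      }
    }
  }

  # expression matrix with planted tissue-specific and all-zero genes
  roles <- sample(family_ids)
  spec_plan <- cfg$tissue_specific_plan
  spec_genes <- list(); used <- 0
  for (tis in names(spec_plan)) {
    take <- roles[used + seq_len(spec_plan[[tis]])]
    used <- used + spec_plan[[tis]]
    for (g in take) spec_genes[[g]] <- tis
  }
  zero_genes <- roles[used + seq_len(cfg$n_zero_genes)]
  general_genes <- setdiff(family_ids, c(names(spec_genes), zero_genes))
  expr <- matrix(0, nrow = length(family_ids), ncol = length(cfg$tissues),
                 dimnames = list(family_ids, cfg$tissues))
  for (g in names(spec_genes)) {
    expr[g, spec_genes[[g]]] <- stats::runif(1, 50, 500)
  }
  for (g in general_genes) {
    k <- sample(2:length(cfg$tissues), 1)
    tis <- sample(cfg$tissues, k)
    expr[g, tis] <- stats::runif(k, 1, 300)
  }
  if (cfg$expression_noise_cv > 0) {
    pos <- expr > 0
    expr[pos] <- expr[pos] *
      exp(stats::rnorm(sum(pos), 0, cfg$expression_noise_cv))
  }

  # treatment contrast with planted fold changes
  fold_roles <- sample(family_ids)
  folds <- stats::setNames(rep(1, length(family_ids)), family_ids)
  nf <- length(cfg$up_folds)
  folds[fold_roles[seq_len(nf)]] <- cfg$up_folds
  folds[fold_roles[nf + seq_along(cfg$down_folds)]] <- cfg$down_folds
  control <- stats::setNames(stats::runif(length(family_ids), 100, 400),
                             family_ids)
  treated <- control * folds
  planted_log2fc <- log2((treated + 1) / (control + 1))
  expected_up <- sort(family_ids[planted_log2fc > 1])
  expected_down <- sort(family_ids[planted_log2fc < -1])

  # qPCR Ct table realizing the planted ddCt ladder
  ct_genes <- family_ids[seq_len(cfg$ct_targets)]
  ref_ct <- 20
  base_dct <- 5
  ct_rows <- list()
  for (cond_i in seq_along(cfg$ct_conditions)) {
    cond <- cfg$ct_conditions[cond_i]
    for (rep_i in seq_len(cfg$ct_replicates)) {
      ct_rows[[length(ct_rows) + 1]] <- tibble::tibble(
        gene = "EF1a", condition = cond, replicate = rep_i,
        ct = ref_ct + stats::rnorm(1, 0, cfg$ct_noise_sd))
    }
    for (gi in seq_along(ct_genes)) {
      for (rep_i in seq_len(cfg$ct_replicates)) {
        ct_rows[[length(ct_rows) + 1]] <- tibble::tibble(
          gene = ct_genes[gi], condition = cond, replicate = rep_i,
          ct = ref_ct + base_dct + cfg$ddct_plan[gi, cond_i] +
            stats::rnorm(1, 0, cfg$ct_noise_sd))
      }
    }
  }
  ct_tbl <- dplyr::bind_rows(ct_rows)

  # realized intron classes, ordered left to right along the protein
  nonempty <- which(vapply(seq_len(nrow(cfg$intron_sites)), function(s)
    length(site_presence[[s]]) > 0, logical(1)))
  class_members <- stats::setNames(
    lapply(seq_along(nonempty), function(k) site_presence[[nonempty[k]]]),
    paste0("I-", seq_along(nonempty)))

  promoter_truth <- lapply(plans, function(pl) {
    counts <- merge(pl, dict, by.x = "element", by.y = "name")
    by_cat <- tapply(counts$count, counts$category, sum)
    list(
      elements = stats::setNames(as.list(as.integer(pl$count)), pl$element),
      categories = list(
        light = as.integer(sum(counts$count[counts$category == "light"])),
        hormone = as.integer(sum(counts$count[counts$category == "hormone"])),
        stress = as.integer(sum(counts$count[counts$category == "stress"]))
      )
    )
  })

  truth <- list(
    family = family_ids,
    decoys = decoy_ids,
    tree = ape::write.tree(fam$tree),
    clades = as.list(fam$clade_of[family_ids]),
    anchors = stats::setNames(as.list(fam$anchors$group), fam$anchors$id),
    expected_groups = as.list(fam$expected_groups[family_ids]),
    fresh_group_letter = fam$fresh_letter,
    proteins = stats::setNames(
      lapply(family_ids, function(id) evo$tips[[id]]$protein), family_ids),
    chrom = as.list(chrom_of[c(family_ids, decoy_ids)]),
    strand = as.list(strand_of[c(family_ids, decoy_ids)]),
    n_variants = as.list(n_variants[c(family_ids, decoy_ids)]),
    intron_sites = purrr::transpose(as.list(cfg$intron_sites)),
    introns = lapply(introns_truth, function(x) purrr::transpose(as.list(x))),
    intron_classes = class_members,
    n_intron_bearing = sum(vapply(introns_truth, nrow, integer(1)) > 0),
    promoters = promoter_truth,
    tissues = cfg$tissues,
    tissue_specific = spec_genes,
    zero_expression = zero_genes,
    fold_plan = as.list(folds),
    expected_upregulated = expected_up,
    expected_downregulated = expected_down,
    ct_targets = ct_genes,
    ct_reference = "EF1a",
    ct_calibrator = cfg$ct_conditions[1],
    ddct_plan = stats::setNames(
      lapply(seq_along(ct_genes), function(gi)
        stats::setNames(as.list(cfg$ddct_plan[gi, ]), cfg$ct_conditions)),
      ct_genes),
    family_min_motif_score = unname(min(fam_scores)),
    decoy_max_motif_score = unname(max(vapply(decoys, `[[`, numeric(1),
                                              "best")))
  )

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "annot.gff3"),
    pspg_block = file.path(dir, "pspg_ref.fa"),
    anchors = file.path(dir, "anchors.tsv"),
    dictionary = file.path(dir, "elements.tsv"),
    expression = file.path(dir, "expression.tsv"),
    treatment = file.path(dir, "treatment.tsv"),
    ct = file.path(dir, "ct.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(tibble::tibble(id = chrom_names,
                             seq = unname(unlist(chrom_seq))), paths$genome)
  writeLines(gff_lines, paths$gff3)
  write_fasta(tibble::tibble(id = paste0("ref", seq_along(ref_block)),
                             seq = ref_block), paths$pspg_block)
  readr::write_tsv(fam$anchors, paths$anchors)
  readr::write_tsv(dict, paths$dictionary)
  readr::write_tsv(tibble::as_tibble(expr, rownames = "gene_id"),
                   paths$expression)
  readr::write_tsv(tibble::tibble(gene_id = family_ids,
                                  control = unname(control[family_ids]),
                                  treated = unname(treated[family_ids])),
                   paths$treatment)
  readr::write_tsv(ct_tbl, paths$ct)
  ape::write.tree(fam$tree, file = paths$tree)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(dir = dir, paths = paths, truth = truth, config = cfg))
}

#' Additive distance matrix of a tree by path-length summation
#'
#' `d(i, j)` is the sum of branch lengths on the path between tips i and j;
#' such matrices are exactly recoverable by neighbor joining.
#'
#' @param tree A `phylo` with branch lengths.
#' @return A symmetric matrix in tip-label order.
#' @export
make_additive_matrix <- function(tree) {
  D <- stats::cophenetic(tree)
  D[tree$tip.label, tree$tip.label]
}
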