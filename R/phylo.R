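fmt_bl <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration. Deterministic: a tie in the Q matrix joins the
#' pair whose cluster keys (the smallest leaf label in each cluster) are
#' lexicographically smallest. Negative estimated branch lengths are clamped
#' to zero and the total deficit recorded as attribute
#' `negative_branch_deficit`. NJ is exact on additive matrices.
#'
#' @param D Square symmetric distance matrix with zero diagonal and row
#'   names. With 2 taxa the full distance is split evenly across the single
#'   edge's two halves.
#' @return An unrooted [ape] `phylo` object.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("neighbor_joining(): need at least 2 taxa")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  }
  if (max(abs(D - t(D))) > 1e-8) {
    stop("neighbor_joining(): distance matrix must be symmetric")
  }
  if (any(abs(diag(D)) > 1e-12)) {
    stop("neighbor_joining(): diagonal must be zero")
  }
  labels <- rownames(D)
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  frag <- labels
  key <- labels
  d <- D
  if (n == 2) {
    half <- d[1, 2] / 2
    txt <- paste0("(", frag[1], ":", fmt_bl(half), ",",
                  frag[2], ":", fmt_bl(half), ");")
    tree <- ape::read.tree(text = txt)
    attr(tree, "negative_branch_deficit") <- deficit
    return(tree)
  }
  while (nrow(d) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    k1 <- pmin(key[cand[, 1]], key[cand[, 2]])
    k2 <- pmax(key[cand[, 1]], key[cand[, 2]])
    pick <- order(k1, k2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    vi <- clamp(0.5 * d[i, j] + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(0.5 * d[i, j] + (R[j] - R[i]) / (2 * (r - 2)))
    newfrag <- paste0("(", frag[i], ":", fmt_bl(vi), ",",
                      frag[j], ":", fmt_bl(vj), ")")
    newkey <- min(key[i], key[j])
    others <- setdiff(seq_len(r), c(i, j))
    newd <- 0.5 * (d[i, others] + d[j, others] - d[i, j])
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, newd), c(newd, 0))
    frag <- c(frag[others], newfrag)
    key <- c(key[others], newkey)
  }
  v1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- paste0("(", frag[1], ":", fmt_bl(v1), ",", frag[2], ":", fmt_bl(v2),
                ",", frag[3], ":", fmt_bl(v3), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_branch_deficit") <- deficit
  tree
}

# Descendant tip label sets for every node of a phylo object.
node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    sets[[po[k, 1]]] <- c(sets[[po[k, 1]]], sets[[po[k, 2]]])
  }
  sets
}

# Canonical keys of the non-trivial bipartitions of an unrooted tree,
# one per internal edge. The side not containing the alphabetically first
# tip label is sorted and pasted, so keys are comparable across trees on
# the same leaf set regardless of tip order.
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  ref <- all_tips[1]
  sets <- node_tip_sets(tree)
  nodes <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  keys <- character(0); ids <- integer(0)
  for (v in nodes) {
    s <- sets[[v]]
    if (length(s) < 2 || length(s) > n - 2) next
    if (ref %in% s) s <- setdiff(all_tips, s)
    keys <- c(keys, paste(sort(s), collapse = "|"))
    ids <- c(ids, v)
  }
  tibble::tibble(node = ids, key = keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree of the full alignment's p-distance matrix, then
#' resamples alignment columns with replacement `replicates` times, rebuilds
#' the tree each time, and reports for each internal edge the percentage of
#' replicate trees containing the same bipartition. Deterministic for a
#' fixed seed, and invariant to the row order of the alignment.
#'
#' @param alignment An `ugt_alignment` (or any tibble with `gene_id`,
#'   `aligned`) with at least 4 rows.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed for resampling.
#' @return An object of class `ugt_phylogeny`: list with `tree` (a `phylo`
#'   whose `node.label` carries integer supports), `supports` (tibble of
#'   `node`, `key`, `support`), `replicates`, `skipped`.
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = NULL) {
  codes <- alignment_codes(alignment)
  if (nrow(codes) < 4) stop("bootstrap_support(): need at least 4 rows")
  L <- ncol(codes)
  D <- p_distance(alignment)
  tree <- neighbor_joining(D)
  splits <- tree_splits(tree)
  run <- function() {
    counts <- stats::setNames(numeric(nrow(splits)), splits$key)
    skipped <- 0L
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      Db <- pdist_cpp(codes, cols)
      if (anyNA(Db)) { skipped <- skipped + 1L; next }
      dimnames(Db) <- dimnames(D)
      kb <- tree_splits(neighbor_joining(Db))$key
      hit <- splits$key %in% kb
      counts[hit] <- counts[hit] + 1
    }
    list(counts = counts, skipped = skipped)
  }
  res <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  support <- 100 * unname(res$counts) / replicates
  n <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  labs[splits$node - n] <- as.character(round(support))
  tree$node.label <- labs
  structure(
    list(tree = tree,
         supports = dplyr::mutate(splits, support = support),
         replicates = replicates, skipped = res$skipped,
         alignment_columns = L),
    class = "ugt_phylogeny"
  )
}

#' @export
print.ugt_phylogeny <- function(x, ...) {
  cat("Neighbor-joining phylogeny with bootstrap supports\n")
  cat("  tips:", length(x$tree$tip.label),
      " internal splits:", nrow(x$supports), "\n")
  cat("  replicates:", x$replicates,
      " mean support:", round(mean(x$supports$support), 1), "%\n")
  invisible(x)
}

#' Tidiers for ugtfam result objects
#'
#' Broom-style [generics::tidy()] and [generics::glance()] methods.
#' `tidy()` on a `pspg_model` returns the long table of column weights; on a
#' `ugt_phylogeny` it returns one row per edge with branch length and
#' bootstrap support.
#'
#' @param x A `pspg_model` or `ugt_phylogeny`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_ugtfam
NULL

#' @rdname tidy_ugtfam
#' @export
tidy.ugt_phylogeny <- function(x, ...) {
  tree <- x$tree
  n <- length(tree$tip.label)
  sup <- stats::setNames(x$supports$support, x$supports$node)
  tibble::tibble(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    length = tree$edge.length,
    is_tip = tree$edge[, 2] <= n,
    label = ifelse(tree$edge[, 2] <= n, tree$tip.label[tree$edge[, 2]],
                   NA_character_),
    support = unname(sup[as.character(tree$edge[, 2])])
  )
}

#' @rdname tidy_ugtfam
#' @export
glance.ugt_phylogeny <- function(x, ...) {
  tibble::tibble(
    n_tips = length(x$tree$tip.label),
    n_splits = nrow(x$supports),
    replicates = x$replicates,
    skipped_replicates = x$skipped,
    mean_support = mean(x$supports$support),
    min_support = min(x$supports$support),
    negative_branch_deficit =
      attr(x$tree, "negative_branch_deficit") %||% 0
  )
}

#' Assign phylogenetic group letters from reference anchors
#'
#' Each non-anchor leaf takes the group of its nearest anchor by patristic
#' distance, provided the smallest clade (on the midpoint-rooted tree)
#' containing both is anchor-consistent (all anchors inside share that
#' group). Leaves failing the proviso form maximal unassigned clades, each
#' of which receives a fresh letter continuing alphabetically after the
#' highest anchor letter (mirroring how novel groups are named in plant UGT
#' surveys). An exact distance tie between anchors of different groups is
#' broken toward the alphabetically earlier group with a warning.
#'
#' @param phylogeny A `phylo` or `ugt_phylogeny`.
#' @param anchors Tibble with columns `id` and `group`, or a named character
#'   vector `group` names by id. Every anchor must be a leaf of the tree.
#' @return A tibble with `gene_id`, `group`, `is_anchor`.
#' @export
assign_groups <- function(phylogeny, anchors) {
  tree <- if (inherits(phylogeny, "ugt_phylogeny")) phylogeny$tree else phylogeny
  if (is.character(anchors)) {
    anchors <- tibble::tibble(id = names(anchors), group = unname(anchors))
  }
  names(anchors)[names(anchors) == "gene_id"] <- "id"
  missing <- setdiff(anchors$id, tree$tip.label)
  if (length(missing) > 0) {
    stop("assign_groups(): anchor(s) missing from tree: ",
         paste(missing, collapse = ", "))
  }
  rooted <- phangorn::midpoint(tree)
  rooted$node.label <- NULL
  pat <- stats::cophenetic(tree)
  n <- length(rooted$tip.label)
  sets <- node_tip_sets(rooted)
  anchor_group <- stats::setNames(anchors$group, anchors$id)

  group <- stats::setNames(rep(NA_character_, n), rooted$tip.label)
  group[anchors$id] <- anchors$group

  for (x in setdiff(rooted$tip.label, anchors$id)) {
    dx <- pat[x, anchors$id]
    best <- min(dx)
    cand <- anchors[dx <= best + 1e-12, ]
    if (length(unique(cand$group)) > 1) {
      warning("assign_groups(): ", x, " equidistant from groups ",
              paste(sort(unique(cand$group)), collapse = ", "),
              "; using the alphabetically earlier group")
    }
    cand <- cand[order(cand$group, cand$id), ]
    a <- cand$id[1]; grp <- cand$group[1]
    mrca <- ape::getMRCA(rooted, c(x, a))
    inside <- intersect(sets[[mrca]], anchors$id)
    if (all(anchor_group[inside] == grp)) group[x] <- grp
  }

  unassigned <- names(group)[is.na(group)]
  if (length(unassigned) > 0) {
    pure <- logical(n + rooted$Nnode)
    for (v in seq_along(pure)) pure[v] <- all(sets[[v]] %in% unassigned)
    parent <- integer(n + rooted$Nnode)
    parent[rooted$edge[, 2]] <- rooted$edge[, 1]
    root <- setdiff(rooted$edge[, 1], rooted$edge[, 2])[1]
    maximal <- which(pure & (!pure[pmax(parent, 1)] | seq_along(pure) == root))
    # deterministic left-to-right order from the cladewise edge list
    cl <- ape::reorder.phylo(rooted, "cladewise")$edge[, 2]
    maximal <- maximal[order(match(maximal, cl))]
    used <- sort(unique(anchors$group))
    pool <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))
    start <- max(match(used, pool))
    fresh <- setdiff(pool[(start + 1):length(pool)], used)
    for (k in seq_along(maximal)) {
      group[sets[[maximal[k]]]] <- fresh[k]
    }
  }

  tibble::tibble(gene_id = names(group),
                 is_anchor = names(group) %in% anchors$id,
                 group = unname(group)) %>%
    dplyr::select("gene_id", "group", "is_anchor") %>%
    dplyr::arrange(.data$gene_id)
}

#' Write a phylogeny to a Newick file
#'
#' Branch lengths are kept; bootstrap supports (if present) are written as
#' internal node labels.
#'
#' @param phylogeny A `phylo` or `ugt_phylogeny`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(phylogeny, path) {
  tree <- if (inherits(phylogeny, "ugt_phylogeny")) phylogeny$tree else phylogeny
  ape::write.tree(tree, file = path)
  invisible(path)
}
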