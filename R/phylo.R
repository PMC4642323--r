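# Distance-based phylogenetics: pairwise-deletion protein distances,
# neighbor joining (Saitou-Nei) with deterministic tie-breaking, bootstrap
# supports by column resampling, and clade reports (species-specific
# duplication clades on the midpoint-rooted tree; monophyly checks).

#' Protein distance matrix
#'
#' Pairwise-deletion proportion of differing residues, optionally Poisson
#' corrected (`d = -ln(1 - p)`).
#'
#' @param msa Character matrix of aligned residues (rows = sequences).
#' @param model `"poisson"` (default) or `"p"` for the raw proportion.
#' @return Symmetric distance matrix with the alignment's row names.
#' @export
protein_distance <- function(msa, model = c("poisson", "p")) {
  model <- match.arg(model)
  stopifnot(is.matrix(msa), nrow(msa) >= 2L)
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- msa[i, ] != "-" & msa[j, ] != "-"
      m <- sum(both)
      if (m == 0L) stop("no comparable sites between ", rownames(msa)[i],
                        " and ", rownames(msa)[j])
      p <- sum(msa[i, both] != msa[j, both]) / m
      d <- if (model == "p") p else {
        if (p >= 1) {
          stop(errorCondition(
            "saturated distance (p = 1) under the Poisson model",
            class = c("nbsevol_saturated", "error", "condition")))
        }
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the Q-criterion. Ties in Q are broken
#' deterministically by the lexicographically smallest pair of subtree
#' representative labels. Negative branch lengths are clamped to zero with
#' the deficit transferred to the sibling branch; the raw values are kept in
#' the `"raw_lengths"` attribute.
#'
#' @param dm Symmetric distance matrix with row/column names (>= 3 labels).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L, !is.null(rownames(dm)))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distance matrix must be non-negative")
  D <- dm
  labels <- rownames(dm)
  nwk <- labels            # newick substring per active node
  repr <- labels           # representative (smallest) leaf label per node
  raw <- numeric(0)
  clamp <- function(bi, bj) {
    r <- c(bi, bj)
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    list(bi = bi, bj = bj, raw = r)
  }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(repr[cand[k, 1]], repr[cand[k, 2]]))
      paste(pr, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    cl <- clamp(bi, bj)
    raw <- c(raw, cl$raw)
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], cl$bi, nwk[j], cl$bj)
    new_repr <- min(repr[i], repr[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    du <- du[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, du), c(du, 0))
    nwk <- c(nwk[-c(i, j)], new_nwk)
    repr <- c(repr[-c(i, j)], new_repr)
    rownames(D) <- colnames(D) <- repr
  }
  # final three-way join (unrooted trifurcation)
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  raw <- c(raw, b1, b2, b3)
  b <- pmax(c(b1, b2, b3), 0)
  tree_str <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                      nwk[1], b[1], nwk[2], b[2], nwk[3], b[3])
  tree <- ape::read.tree(text = tree_str)
  attr(tree, "raw_lengths") <- raw
  tree
}

# Canonical bipartition keys of a tree: one key per internal edge, each key
# the sorted leaf set on the side NOT containing the alphabetically first
# leaf, pasted with a separator.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  n_tip <- length(tips)
  internal <- setdiff(unique(tree$edge[, 1]), 0)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  nodes <- setdiff((n_tip + 1):(n_tip + tree$Nnode), root)
  keys <- character(0)
  key_nodes <- integer(0)
  for (nd in nodes) {
    clade_tips <- tips[unlist(phangorn::Descendants(tree, nd, "tips"))]
    side <- if (ref %in% clade_tips) setdiff(tips, clade_tips) else clade_tips
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    key_nodes <- c(key_nodes, nd)
  }
  stats::setNames(keys, key_nodes)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and annotates each internal edge of the full-data tree
#' with the percentage of replicate trees containing the same leaf
#' bipartition. Supports are stored as internal node labels.
#'
#' @param msa Character matrix of aligned residues.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the column resampling.
#' @param model Distance model passed to [protein_distance()].
#' @return An `ape::phylo` tree with `node.label` support percentages.
#' @export
bootstrap_nj <- function(msa, replicates = 1000, seed = 1,
                         model = c("poisson", "p")) {
  model <- match.arg(model)
  stopifnot(replicates >= 1)
  tree <- neighbor_joining(protein_distance(msa, model))
  bip <- tree_bipartitions(tree)
  hits <- stats::setNames(numeric(length(bip)), bip)
  set.seed(seed)
  for (rep in seq_len(replicates)) {
    cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
    rep_tree <- neighbor_joining(protein_distance(msa[, cols, drop = FALSE],
                                                  model))
    rep_bip <- tree_bipartitions(rep_tree)
    found <- intersect(bip, rep_bip)
    hits[found] <- hits[found] + 1
  }
  support <- round(100 * hits / replicates, 1)
  n_tip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  node_ids <- as.integer(names(bip))
  labels[node_ids - n_tip] <- as.character(support[bip])
  tree$node.label <- labels
  tree
}

#' Species-specific duplication clades
#'
#' Roots the tree at the midpoint and reports the MAXIMAL clades (no
#' counted clade nested inside another) whose leaves all belong to one
#' species, have >= 2 members, and whose support strictly exceeds the
#' threshold.
#'
#' @param tree A supported tree from [bootstrap_nj()] (node labels =
#'   support percentages).
#' @param species_map Named character vector: leaf label -> species.
#' @param support_threshold Clades require support strictly greater than
#'   this (default 50).
#' @param focal Optional species name: restrict the report to clades of this
#'   species, with the proportion computed against that species' leaf
#'   count. Default `NULL` reports clades of every species against all
#'   leaves.
#' @return List of class `species_clade_report`: `clades` (list of leaf
#'   vectors), `supports`, `species`, `n_clades`, `n_genes`,
#'   `mean_paralogs`, `proportion` (%).
#' @export
species_specific_clades <- function(tree, species_map,
                                    support_threshold = 50, focal = NULL) {
  missing <- setdiff(tree$tip.label, names(species_map))
  if (length(missing)) {
    stop("species unknown for leaves: ", paste(missing, collapse = ", "))
  }
  rooted <- phangorn::midpoint(tree, node.labels = "support")
  n_tip <- length(rooted$tip.label)
  root <- n_tip + 1L
  sup <- suppressWarnings(as.numeric(rooted$node.label))
  candidates <- integer(0)
  clade_tips <- phangorn::Descendants(rooted, (n_tip + 1L):(n_tip + rooted$Nnode),
                                      "tips")
  for (nd in (n_tip + 1L):(n_tip + rooted$Nnode)) {
    tips <- rooted$tip.label[clade_tips[[nd - n_tip]]]
    if (length(tips) < 2L) next
    spp <- unique(species_map[tips])
    if (length(spp) != 1L) next
    if (!is.null(focal) && spp != focal) next
    s <- sup[nd - n_tip]
    if (is.na(s) || s <= support_threshold) next
    candidates <- c(candidates, nd)
  }
  # maximality: drop candidates with a candidate ancestor
  keep <- vapply(candidates, function(nd) {
    anc <- phangorn::Ancestors(rooted, nd, "all")
    !any(anc %in% candidates)
  }, logical(1))
  candidates <- candidates[keep]
  clades <- lapply(candidates, function(nd) {
    sort(rooted$tip.label[clade_tips[[nd - n_tip]]])
  })
  supports <- sup[candidates - n_tip]
  species <- vapply(clades, function(t) unname(species_map[t[1]]),
                    character(1))
  n_genes <- sum(lengths(clades))
  denom <- if (is.null(focal)) n_tip else sum(species_map[tree$tip.label] == focal)
  structure(list(clades = clades, supports = supports, species = species,
                 n_clades = length(clades), n_genes = n_genes,
                 mean_paralogs = if (length(clades)) {
                   round_half_up(n_genes / length(clades), 2)
                 } else NA_real_,
                 proportion = proportion_pct(n_genes, denom),
                 support_threshold = support_threshold, focal = focal),
            class = "species_clade_report")
}

#' @export
print.species_clade_report <- function(x, ...) {
  cat(sprintf(
    "species-specific clades (support > %g%s): %d clades, %d genes, %.2f paralogs/clade, %.2f%%\n",
    x$support_threshold,
    if (is.null(x$focal)) "" else paste0(", species ", x$focal),
    x$n_clades, x$n_genes,
    if (is.na(x$mean_paralogs)) 0 else x$mean_paralogs, x$proportion))
  invisible(x)
}

#' Monophyly of a leaf set
#'
#' Checks whether some edge bipartition of the (unrooted) tree separates
#' exactly the given members from the rest, and reports that bipartition's
#' support when node labels carry supports.
#'
#' @param tree An `ape::phylo` tree.
#' @param members Leaf labels (subset of the tree's tips).
#' @return List with `is_monophyletic` and `support` (`NA` when the tree is
#'   unannotated or the set spans a trivial bipartition).
#' @export
clade_monophyly <- function(tree, members) {
  stopifnot(all(members %in% tree$tip.label))
  tips <- tree$tip.label
  members <- sort(unique(members))
  if (length(members) <= 1L || length(members) >= length(tips)) {
    return(list(is_monophyletic = TRUE, support = NA_real_))
  }
  ref <- sort(tips)[1]
  side <- if (ref %in% members) sort(setdiff(tips, members)) else members
  if (length(side) < 2L) {
    # the split is a pendant edge: trivially monophyletic
    return(list(is_monophyletic = TRUE, support = NA_real_))
  }
  key <- paste(side, collapse = "\r")
  bip <- tree_bipartitions(tree)
  hit <- names(bip)[bip == key]
  if (!length(hit)) return(list(is_monophyletic = FALSE, support = NA_real_))
  support <- NA_real_
  if (!is.null(tree$node.label)) {
    nd <- as.integer(hit[1]) - length(tips)
    support <- suppressWarnings(as.numeric(tree$node.label[nd]))
  }
  list(is_monophyletic = TRUE, support = support)
}
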