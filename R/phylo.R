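# Distance computation, the bundled neighbor-joining baseline, outgroup
# rooting and tree metrics. Externally computed trees (e.g. maximum
# likelihood) are accepted wherever a tree is consumed; the NJ path keeps
# the pipeline self-contained.

#' Build an alignment from records or strings
#'
#' An alignment is a named character vector of equal-length residue rows
#' (gaps as `-`). Records of unequal length are right-padded with gaps to
#' the longest row with a warning: that is only a faithful alignment for
#' co-simulated (indel-free) sequences such as the simulator's output;
#' real data should come pre-aligned.
#'
#' @param x an `mmp_records` data frame or a named character vector.
#' @return an `mmp_alignment` named character vector.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "mmp_records") || is.data.frame(x)) {
    rows <- x$residues
    names(rows) <- x$seq_id
  } else {
    rows <- x
  }
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows need unique names")
  if (length(rows) < 2L) stop("an alignment needs >= 2 rows")
  w <- nchar(rows)
  if (length(unique(w)) > 1L) {
    warning("unequal row lengths; right-padding with gaps")
    pad <- max(w) - w
    nm <- names(rows)
    rows <- paste0(rows, vapply(pad, function(k)
      paste(rep("-", k), collapse = ""), character(1)))
    names(rows) <- nm
  }
  class(rows) <- "mmp_alignment"
  rows
}

# integer encoding: 0 = non-comparable (gap/X/B/Z and anything else),
# 1..20 = amino acids, selenocysteine folded into C for distance purposes
.encode_alignment <- function(aln) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  codes <- matrix(0L, nrow = length(aln), ncol = nchar(aln[[1L]]))
  map <- stats::setNames(seq_along(aa), aa)
  map["U"] <- map[["C"]]
  for (i in seq_along(aln)) {
    ch <- strsplit(toupper(aln[[i]]), "")[[1L]]
    v <- map[ch]
    v[is.na(v)] <- 0L
    codes[i, ] <- v
  }
  rownames(codes) <- names(aln)
  codes
}

#' Pairwise p-distance of an alignment
#'
#' Proportion of mismatching sites over comparable columns, where a column
#' is comparable for a pair when both rows carry an unambiguous residue
#' (gaps and X/B/Z are skipped pairwise — pairwise deletion, not complete
#' deletion, so ragged fragments still receive distances).
#'
#' @param alignment an `mmp_alignment` (or anything [as_alignment()]
#'   accepts).
#' @param gap_policy only `"pairwise_deletion"` is implemented.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment, gap_policy = "pairwise_deletion") {
  gap_policy <- match.arg(gap_policy, "pairwise_deletion")
  aln <- as_alignment(alignment)
  codes <- .encode_alignment(aln)
  cnt <- .pdist_counts(codes)
  if (any(cnt$comparable[upper.tri(cnt$comparable)] == 0)) {
    idx <- which(cnt$comparable == 0 & upper.tri(cnt$comparable),
                 arr.ind = TRUE)[1L, ]
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 names(aln)[idx[1L]], names(aln)[idx[2L]]))
  }
  d <- cnt$mismatch / pmax(cnt$comparable, 1)
  diag(d) <- 0
  dimnames(d) <- list(names(aln), names(aln))
  d
}

#' Poisson correction of a 20-state p-distance
#'
#' Inverts the expected proportion of visible differences under the
#' 20-state equal-rates substitution model:
#' `d = -(19/20) * log(1 - (20/19) * p)`. Monotone increasing in `p`;
#' saturates as `p` approaches 19/20.
#'
#' @param p numeric vector of p-distances in `[0, 19/20)`.
#' @return corrected distances (expected substitutions per site).
#' @export
jc20_correct <- function(p) {
  if (any(p < 0)) stop("p-distance cannot be negative")
  if (any(p >= 19 / 20))
    stop("p >= 19/20: distance saturated, correction undefined")
  -(19 / 20) * log(1 - (20 / 19) * p)
}

#' Neighbor-joining baseline tree
#'
#' Standard neighbor joining on a distance matrix; negative estimated
#' branch lengths are clamped to 0 (without redistribution) so the
#' non-negativity invariant of downstream patristic distances holds. NJ is
#' consistent on additive matrices: the generating topology is recovered
#' exactly.
#'
#' @param D symmetric distance matrix (or `dist`) over >= 3 ids.
#' @return an unrooted `"phylo"` tree.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs >= 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix needs row names")
  tree <- ape::nj(as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Root a tree on an outgroup leaf
#'
#' Places the root at the midpoint of the outgroup's pendant edge, so the
#' outgroup is one child of the root and every leaf-to-leaf patristic
#' distance is unchanged.
#'
#' @param tree a `"phylo"` tree.
#' @param outgroup_leaf leaf name present in the tree.
#' @return a rooted `"phylo"` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_leaf) {
  tip <- match(outgroup_leaf, tree$tip.label)
  if (is.na(tip)) stop("outgroup leaf not in tree: ", outgroup_leaf)
  pendant <- tree$edge.length[tree$edge[, 2L] == tip]
  rooted <- ape::root(tree, outgroup = outgroup_leaf, resolve.root = TRUE)
  # ape::root leaves the root at one end of the outgroup's former pendant
  # edge (a zero-length child edge); move it to the midpoint of that
  # pendant edge, which preserves every leaf-to-leaf patristic distance
  root_node <- length(rooted$tip.label) + 1L
  ce <- which(rooted$edge[, 1L] == root_node)
  if (length(ce) == 2L) {
    total <- sum(rooted$edge.length[ce])
    rtip <- match(outgroup_leaf, rooted$tip.label)
    tip_side <- rooted$edge[ce, 2L] == rtip
    rooted$edge.length[ce[tip_side]] <- pendant / 2
    rooted$edge.length[ce[!tip_side]] <- total - pendant / 2
  }
  rooted
}

.edge_length_lookup <- function(tree) {
  # child node -> incoming edge length
  out <- numeric(max(tree$edge))
  out[tree$edge[, 2L]] <- tree$edge.length
  out
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths on the unique path between the leaves.
#'
#' @param tree a `"phylo"` tree.
#' @param leaf_a,leaf_b leaf names.
#' @return non-negative numeric scalar.
#' @seealso [patristic_matrix()] for all pairs at once.
#' @export
patristic_distance <- function(tree, leaf_a, leaf_b) {
  ia <- match(leaf_a, tree$tip.label)
  ib <- match(leaf_b, tree$tip.label)
  if (is.na(ia)) stop("unknown leaf: ", leaf_a)
  if (is.na(ib)) stop("unknown leaf: ", leaf_b)
  if (ia == ib) return(0)
  path <- ape::nodepath(tree, ia, ib)
  lens <- .edge_length_lookup(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  # each node on the path contributes its incoming edge, except the path's
  # apex (the one node whose parent is not itself on the path)
  contributes <- vapply(path, function(nd) {
    p <- parent[nd]
    p != 0L && p %in% path
  }, logical(1))
  sum(lens[path[contributes]])
}

#' All-pairs patristic distance matrix
#'
#' @param tree a `"phylo"` tree.
#' @return symmetric matrix over the tree's leaf names.
#' @export
patristic_matrix <- function(tree) {
  stats::cophenetic(tree)
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree a rooted `"phylo"` tree (the MRCA is undefined on unrooted
#'   trees).
#' @param leaves non-empty character vector of leaf names.
#' @return internal node number (or the tip index for a single leaf).
#' @export
tree_mrca <- function(tree, leaves) {
  if (!ape::is.rooted(tree)) stop("MRCA undefined on an unrooted tree")
  if (length(leaves) == 0L) stop("need at least one leaf")
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx)) stop("unknown leaf: ", leaves[is.na(idx)][1L])
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Leaves descending from a node
#'
#' @param tree a `"phylo"` tree.
#' @param node node number (a tip index returns that leaf itself).
#' @return character vector of leaf names.
#' @export
clade_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tips <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
  tree$tip.label[tips]
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions between two
#' trees on the same leaf set; 0 means identical unrooted topology. Used
#' as a test metric throughout.
#'
#' @param tree1,tree2 `"phylo"` trees with identical leaf sets.
#' @return non-negative integer.
#' @export
rf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(tree1), ape::unroot(tree2)))
}
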