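# Automatic formalization of phylogeny-guided class (re)annotation: each
# leaf's clade neighbourhood votes on its class. The manual step it
# replaces was visual inspection of class-coloured clades; the
# k-nearest-ancestral-vote rule is this package's reproducible surrogate.

.as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    out <- labels$label
    names(out) <- labels$seq_id
    return(out)
  }
  if (is.null(names(labels))) stop("labels need names (seq_ids)")
  labels
}

.is_concrete <- function(lab) {
  !is.na(lab) & !(lab %in% c("GENERIC", "UNASSIGNED"))
}

#' Ancestral-neighbourhood class vote for one leaf
#'
#' Walks the leaf's ancestors from its parent toward the root, accumulating
#' concretely labelled leaves (the query leaf, generic/unassigned leaves
#' and the outgroup never vote) until at least `k` votes are collected or
#' the root is reached. Returns the modal label, its fraction of the votes
#' and the number of votes counted; an exact tie between modal labels
#' yields no winner.
#'
#' @param tree a rooted `"phylo"` tree.
#' @param labels named character vector (seq_id -> label) or a leaf table
#'   with `seq_id`/`label` columns.
#' @param leaf the query leaf name.
#' @param k target number of votes (default 10).
#' @param exclude leaf names that never vote (e.g. the outgroup).
#' @return list with `label` (character or `NA` when no winner),
#'   `fraction`, `votes_counted`.
#' @export
neighbor_vote <- function(tree, labels, leaf, k = 10L, exclude = character(0)) {
  labels <- .as_label_vector(labels)
  tip <- match(leaf, tree$tip.label)
  if (is.na(tip)) stop("leaf not in tree: ", leaf)
  desc <- phangorn::Descendants(tree, type = "tips")
  voter <- .is_concrete(labels[tree$tip.label]) &
    !(tree$tip.label %in% exclude)
  .vote_one(tree, labels, tip, k, voter, desc)
}

# shared vote kernel; `voter` flags tips allowed to vote (the query tip is
# excluded here), `desc` is the precomputed tips-under-node list, `anc`
# the tip's root-ward ancestor chain (computed if not supplied)
.vote_one <- function(tree, labels, tip, k, voter, desc, anc = NULL) {
  if (is.null(anc)) anc <- phangorn::Ancestors(tree, tip, type = "all")
  voter[tip] <- FALSE
  votes <- character(0)
  seen <- rep(FALSE, length(tree$tip.label))
  seen[tip] <- TRUE
  for (node in anc) {
    tips_here <- desc[[node]]
    new <- tips_here[!seen[tips_here]]
    seen[new] <- TRUE
    ok <- new[voter[new]]
    if (length(ok))
      votes <- c(votes, unname(labels[tree$tip.label[ok]]))
    if (length(votes) >= k) break
  }
  if (length(votes) == 0L)
    return(list(label = NA_character_, fraction = 0, votes_counted = 0L))
  tab <- sort(table(votes), decreasing = TRUE)
  top <- tab[1L]
  winner <- if (sum(tab == top) > 1L) NA_character_ else names(tab)[1L]
  list(label = winner, fraction = as.numeric(top) / length(votes),
       votes_counted = length(votes))
}

#' Clade-vote class annotation and reannotation
#'
#' Single deterministic pass over the leaves; every vote is computed
#' against the *prior* labels, so the outcome does not depend on leaf
#' iteration order and changes never cascade. For each leaf:
#' \itemize{
#'   \item prior `GENERIC`/`UNASSIGNED`, winning vote fraction `>= f`:
#'     the leaf receives the winning class (`class_annotation`);
#'   \item prior concrete class differing from the winner at fraction
#'     `>= f`: relabelled (`reannotation`) — unless the prior class has at
#'     most `min_class_size` members, in which case the leaf is only
#'     `flagged` and keeps its label (rare-class protection: genuinely
#'     rare classes, e.g. a singleton collagenase, must not be absorbed
#'     by their surrounding clade);
#'   \item otherwise `unchanged`.
#' }
#'
#' @param tree a rooted `"phylo"` tree.
#' @param labels named character vector or leaf table of prior labels.
#' @param k,f vote parameters: neighbourhood size and minimum winning
#'   fraction.
#' @param min_class_size classes at or below this size are never
#'   auto-relabelled.
#' @param outgroup leaf name(s) that never vote and are never relabelled.
#' @return an `mmp_annotation` list with `labels` (updated vector),
#'   `leaves` (per-leaf data frame: `seq_id`, `prior`, `final`,
#'   `change_kind`, `vote_fraction`, `votes_counted`) and `report`
#'   (see [annotation_report()]).
#' @export
annotate <- function(tree, labels, k = 10L, f = 0.8, min_class_size = 3L,
                     outgroup = character(0)) {
  if (!ape::is.rooted(tree)) stop("annotation needs a rooted tree")
  prior <- .as_label_vector(labels)
  leaves <- setdiff(tree$tip.label, outgroup)
  missing <- setdiff(leaves, names(prior))
  if (length(missing)) stop("no prior label for leaf: ", missing[1L])
  class_size <- table(prior[leaves][.is_concrete(prior[leaves])])
  res <- data.frame(seq_id = leaves, prior = unname(prior[leaves]),
                    final = unname(prior[leaves]), change_kind = "unchanged",
                    vote_fraction = 0, votes_counted = 0L,
                    stringsAsFactors = FALSE)
  desc <- phangorn::Descendants(tree, type = "tips")
  base_voter <- .is_concrete(prior[tree$tip.label]) &
    !(tree$tip.label %in% outgroup)
  tip_idx <- match(leaves, tree$tip.label)
  anc_all <- phangorn::Ancestors(tree, type = "all")
  for (i in seq_along(leaves)) {
    v <- .vote_one(tree, prior, tip_idx[i], k, base_voter, desc,
                   anc = anc_all[[tip_idx[i]]])
    res$vote_fraction[i] <- v$fraction
    res$votes_counted[i] <- v$votes_counted
    if (is.na(v$label) || v$fraction < f) next
    p <- res$prior[i]
    if (!.is_concrete(p)) {
      res$final[i] <- v$label
      res$change_kind[i] <- "class_annotation"
    } else if (p != v$label) {
      if (class_size[[p]] <= min_class_size) {
        res$change_kind[i] <- "flagged"
      } else {
        res$final[i] <- v$label
        res$change_kind[i] <- "reannotation"
      }
    }
  }
  updated <- prior
  updated[res$seq_id] <- res$final
  out <- list(labels = updated, leaves = res,
              report = annotation_report(res))
  class(out) <- "mmp_annotation"
  out
}

#' Per-class annotation report
#'
#' Aggregates the per-leaf annotation outcomes by *final* class: total
#' count, class-annotation count (generic-to-concrete assignments) and
#' reannotation count (concrete-to-concrete corrections), plus an overall
#' totals row. Per-class counts sum to the totals row by construction.
#'
#' @param leaves per-leaf annotation data frame, see [annotate()].
#' @return data frame with columns `class`, `group`, `n`,
#'   `class_annotation`, `reannotation`.
#' @export
annotation_report <- function(leaves) {
  concrete <- leaves[.is_concrete(leaves$final), , drop = FALSE]
  cls <- sort(unique(concrete$final))
  rows <- lapply(cls, function(cc) {
    sub <- concrete[concrete$final == cc, , drop = FALSE]
    data.frame(class = cc, group = mmp_group(cc), n = nrow(sub),
               class_annotation = sum(sub$change_kind == "class_annotation"),
               reannotation = sum(sub$change_kind == "reannotation"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  total <- data.frame(class = "Total", group = "", n = sum(out$n),
                      class_annotation = sum(out$class_annotation),
                      reannotation = sum(out$reannotation),
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' @export
print.mmp_annotation <- function(x, ...) {
  tot <- x$report[x$report$class == "Total", ]
  cat(sprintf(
    "<mmp_annotation> %d leaves: %d class annotations, %d reannotations, %d flagged\n",
    nrow(x$leaves), tot$class_annotation, tot$reannotation,
    sum(x$leaves$change_kind == "flagged")))
  invisible(x)
}

#' Monophyly diagnostic: clade purity of a class
#'
#' Fraction of the leaves under the MRCA of a class's leaves that belong
#' to the class; 1 means the class is perfectly monophyletic.
#'
#' @param tree a rooted `"phylo"` tree.
#' @param labels named character vector or leaf table.
#' @param cls a concrete class label present among the labels.
#' @return numeric in `[0, 1]`.
#' @export
clade_purity <- function(tree, labels, cls) {
  labels <- .as_label_vector(labels)
  members <- names(labels)[labels == cls & !is.na(labels)]
  members <- intersect(members, tree$tip.label)
  if (length(members) == 0L) stop("no leaves of class ", cls)
  node <- tree_mrca(tree, members)
  under <- clade_leaves(tree, node)
  length(intersect(under, members)) / length(under)
}

.group_colors <- c(collagenase = "#e41a1c", gelatinase = "#377eb8",
                   stromelysin = "#4daf4a", transmembrane = "#984ea3",
                   other = "#ff7f00", none = "#999999")

#' Export an iTOL-style colour-strip annotation file
#'
#' One `leaf<TAB>hex colour` line per leaf, coloured by functional group,
#' for visual inspection of class clades in tree viewers.
#'
#' @param labels named character vector or leaf table.
#' @param path output path.
#' @export
itol_color_strip <- function(labels, path) {
  labels <- .as_label_vector(labels)
  grp <- mmp_group(labels)
  col <- .group_colors[grp]
  utils::write.table(data.frame(names(labels), unname(col)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
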