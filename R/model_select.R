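# Model-organism proximity inference: within each scoped MMP class, rank
# candidate organisms by evolutionary distance to the reference species
# (Homo sapiens by default), the criterion used to shortlist animal models
# for restorative-dentistry research.

#' Scope of the model-organism analysis
#'
#' Defaults to the dentistry-relevant scope: the collagenase and gelatinase
#' classes and the seven organisms most used in dental research, with Homo
#' sapiens as the reference.
#'
#' @param classes concrete MMP classes to rank within.
#' @param organisms binomial species names considered as candidates.
#' @param reference the reference organism; must be among `organisms`.
#' @return an `mmp_scope` list.
#' @export
scope_config <- function(classes = c("MMP-1", "MMP-8", "MMP-13",
                                     "MMP-2", "MMP-9"),
                         organisms = c("Homo sapiens", "Bos taurus",
                                       "Mus musculus", "Rattus norvegicus",
                                       "Canis lupus",
                                       "Oryctolagus cuniculus",
                                       "Sus scrofa"),
                         reference = "Homo sapiens") {
  if (!.binomial(reference) %in% .binomial(organisms))
    stop("reference organism must be among the scoped organisms")
  out <- list(classes = classes, organisms = organisms,
              reference = reference)
  class(out) <- "mmp_scope"
  out
}

# species-level binomial: first two whitespace-separated words, lower-cased
# (subspecies epithets such as "Canis lupus familiaris" are ignored)
.binomial <- function(x) {
  x <- trimws(as.character(x))
  tolower(vapply(strsplit(x, "\\s+"), function(w)
    paste(w[seq_len(min(2L, length(w)))], collapse = " "), character(1)))
}

#' Restrict a leaf table to the analysis scope
#'
#' Keeps leaves whose class is scoped and whose organism matches a scoped
#' organism at the species level (case-insensitive binomial match;
#' subspecies suffixes ignored). Per-(class, organism) retention counts are
#' attached as the `"retained"` attribute.
#'
#' @param leaf_table data frame with `seq_id`, `label`, `organism` columns
#'   (see [leaf_labels()]).
#' @param scope an `mmp_scope`, see [scope_config()].
#' @return the filtered leaf table.
#' @export
restrict_scope <- function(leaf_table, scope = scope_config()) {
  org_match <- .binomial(leaf_table$organism) %in% .binomial(scope$organisms)
  keep <- leaf_table$label %in% scope$classes & org_match &
    !is.na(leaf_table$organism)
  out <- leaf_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained") <- if (nrow(out))
    table(class = out$label, organism = .binomial(out$organism))
  else NULL
  out
}

.tie_ranks <- function(d, rel_tol) {
  # dense tie-group ranks over ascending distances; two organisms share a
  # group when their distances differ by <= rel_tol (relative to the group
  # leader, with an absolute floor of rel_tol for distances near zero)
  rank <- integer(length(d))
  g <- 0L
  leader <- -Inf
  for (i in seq_along(d)) {
    if (g == 0L || d[i] - leader > rel_tol * max(1, abs(leader))) {
      g <- g + 1L
      leader <- d[i]
    }
    rank[i] <- g
  }
  rank
}

#' Rank candidate organisms by proximity to the reference
#'
#' For each scoped class, the distance of organism `O` to the reference is
#' the minimum over all (O-leaf, reference-leaf) pairs *within that class*
#' of the leaf-to-leaf tree distance — a single closest ortholog pair is
#' the natural reading of "closest organism" (average linkage is available
#' via `linkage = "average"`). Each class is evaluated on its own pruned
#' subtree, which preserves leaf-to-leaf distances. Organisms whose
#' distances coincide within `rel_tol` share a tie-group rank (joint
#' second, etc.); organisms with no leaf in a class are reported absent,
#' never silently dropped. A class without reference leaves or without
#' candidate leaves is recorded as non-rankable with a reason, not an
#' error.
#'
#' @param tree a `"phylo"` tree containing the scoped leaves.
#' @param leaf_table data frame with `seq_id`, `label`, `organism`.
#' @param scope an `mmp_scope`.
#' @param metric `"patristic"` (sum of branch lengths on the path) or
#'   `"topological"` (number of internal nodes on the path; sister leaves
#'   are at 1).
#' @param linkage `"min"` (default) or `"average"` over leaf pairs.
#' @param rel_tol relative tolerance for tie grouping.
#' @return an `mmp_proximity` list: per class a `ranking` data frame
#'   (`organism`, `distance`, `rank`), the `absent` organisms and a
#'   `rankable` flag with `reason`.
#' @export
organism_proximity <- function(tree, leaf_table, scope = scope_config(),
                               metric = c("patristic", "topological"),
                               linkage = c("min", "average"),
                               rel_tol = 1e-9) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  scoped <- restrict_scope(leaf_table, scope)
  scoped <- scoped[scoped$seq_id %in% tree$tip.label, , drop = FALSE]
  ref_bin <- .binomial(scope$reference)
  org_bin <- .binomial(scope$organisms)
  per_class <- stats::setNames(vector("list", length(scope$classes)),
                               scope$classes)
  for (cls in scope$classes) {
    sub <- scoped[scoped$label == cls, , drop = FALSE]
    present <- unique(.binomial(sub$organism))
    absent <- scope$organisms[!org_bin %in% present]
    entry <- list(ranking = data.frame(organism = character(0),
                                       distance = numeric(0),
                                       rank = integer(0)),
                  absent = absent, rankable = FALSE, reason = NULL)
    ref_leaves <- sub$seq_id[.binomial(sub$organism) == ref_bin]
    cand <- sub[.binomial(sub$organism) != ref_bin, , drop = FALSE]
    if (length(ref_leaves) == 0L) {
      entry$reason <- "reference organism absent from class"
    } else if (nrow(cand) == 0L) {
      entry$reason <- "no candidate organisms"
    } else {
      st <- ape::keep.tip(tree, sub$seq_id)
      if (metric == "topological") {
        st$edge.length <- rep(1, nrow(st$edge))
        D <- patristic_matrix(st) - 1
        diag(D) <- 0
      } else {
        D <- patristic_matrix(st)
      }
      cand_orgs <- scope$organisms[org_bin %in% .binomial(cand$organism) &
                                     org_bin != ref_bin]
      d <- vapply(cand_orgs, function(o) {
        o_leaves <- cand$seq_id[.binomial(cand$organism) == .binomial(o)]
        block <- D[o_leaves, ref_leaves, drop = FALSE]
        if (linkage == "min") min(block) else mean(block)
      }, numeric(1))
      ord <- order(d, cand_orgs)
      ranking <- data.frame(organism = cand_orgs[ord],
                            distance = unname(d[ord]),
                            rank = .tie_ranks(unname(d[ord]), rel_tol),
                            stringsAsFactors = FALSE)
      entry$ranking <- ranking
      entry$rankable <- TRUE
    }
    per_class[[cls]] <- entry
  }
  out <- list(per_class = per_class, metric = metric, linkage = linkage,
              scope = scope)
  class(out) <- "mmp_proximity"
  out
}

#' Topological proximity ranking
#'
#' [organism_proximity()] with the edge-count metric (internal nodes on
#' the leaf-to-leaf path). When the two metrics disagree the disagreement
#' is simply visible across the two reports; it is reported, not resolved.
#'
#' @inheritParams organism_proximity
#' @export
topological_proximity <- function(tree, leaf_table, scope = scope_config(),
                                  linkage = c("min", "average"),
                                  rel_tol = 1e-9) {
  organism_proximity(tree, leaf_table, scope, metric = "topological",
                     linkage = linkage, rel_tol = rel_tol)
}

#' @export
print.mmp_proximity <- function(x, ...) {
  cat(sprintf("<mmp_proximity> metric=%s, linkage=%s\n", x$metric,
              x$linkage))
  for (cls in names(x$per_class)) {
    e <- x$per_class[[cls]]
    if (!e$rankable) {
      cat(sprintf("  %-8s not rankable (%s)\n", cls, e$reason))
    } else {
      first <- e$ranking[e$ranking$rank == 1L, ]
      cat(sprintf("  %-8s closest: %s (%.4g)\n", cls,
                  paste(first$organism, collapse = " / "),
                  first$distance[1L]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.mmp_proximity <- function(x, ...) {
  rows <- lapply(names(x$per_class), function(cls) {
    e <- x$per_class[[cls]]
    main <- if (e$rankable) {
      data.frame(class = cls, organism = e$ranking$organism,
                 distance = e$ranking$distance, rank = e$ranking$rank,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(class = cls,
                 organism = paste0("(", e$reason, ")"),
                 distance = NA_real_, rank = NA_integer_,
                 stringsAsFactors = FALSE)
    }
    if (length(e$absent)) {
      main <- rbind(main, data.frame(
        class = cls, organism = paste0(e$absent, " [absent]"),
        distance = NA_real_, rank = NA_integer_, stringsAsFactors = FALSE))
    }
    main
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
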