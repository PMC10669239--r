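# Fixture builders and independent brute-force oracles. The oracles
# deliberately share no code with the package internals.

# build an mmp_records-shaped data frame directly (tests that exercise the
# FASTA reader itself go through files instead)
make_records <- function(residues, accession = sprintf("A%02d", seq_along(residues)),
                         seq_id = accession, description = "",
                         organism = NA_character_) {
  df <- data.frame(seq_id = seq_id,
                   db_tag = rep_len("synthetic", length(residues)),
                   accession = accession,
                   entry_name = paste0(accession, "_TEST"),
                   description = rep_len(description, length(residues)),
                   organism = rep_len(organism, length(residues)),
                   taxid = NA_integer_, gene = NA_character_,
                   residues = toupper(residues),
                   stringsAsFactors = FALSE)
  df$length <- nchar(gsub("-", "", df$residues, fixed = TRUE))
  class(df) <- c("mmp_records", "data.frame")
  df
}

make_hits <- function(seq_id, cdd_id, qstart = 1L, qend = 10L) {
  data.frame(seq_id = seq_id, cdd_id = cdd_id,
             family = mmphylo::cdd_family(cdd_id),
             bitscore = 100, evalue = 1e-30,
             qstart = qstart, qend = qend, stringsAsFactors = FALSE)
}

# --- independent reapplication of the three curation rules ---------------
# CDD identifier sets frozen here independently of the package constant
.oracle_families <- list(
  matrixin = c("CDD:395334", "CDD:239819", "CDD:239806", "CDD:239805",
               "CDD:239804", "CDD:239803", "CDD:239796", "CDD:238124",
               "CDD:214576"),
  hemopexin = c("CDD:395000", "CDD:238046"),
  pg_binding = "CDD:396175",
  fibronectin = "CDD:128373")

naive_stage_counts <- function(records, hits, window = 0.5,
                               min_families = 3) {
  len <- nchar(gsub("-", "", records$residues))
  m <- mean(len)
  keep1 <- len >= (1 - window) * m & len <= (1 + window) * m
  r1 <- records[keep1, , drop = FALSE]
  fam_of <- function(id) {
    for (f in names(.oracle_families))
      if (id %in% .oracle_families[[f]]) return(f)
    NA_character_
  }
  hit_fams <- vapply(hits$cdd_id, fam_of, character(1))
  nfam <- vapply(r1$seq_id, function(s) {
    length(unique(stats::na.omit(hit_fams[hits$seq_id == s])))
  }, numeric(1))
  r2 <- r1[nfam >= min_families, , drop = FALSE]
  keep3 <- !duplicated(toupper(r2$residues))
  c(input = nrow(records), length = nrow(r1), domains = nrow(r2),
    dedup = sum(keep3))
}

# --- brute-force patristic oracle: breadth-first path search over an -----
# undirected weighted adjacency list built from the edge table
naive_patristic <- function(tree, a, b) {
  ia <- which(tree$tip.label == a)
  ib <- which(tree$tip.label == b)
  if (ia == ib) return(0)
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  dist <- rep(NA_real_, nn)
  dist[ia] <- 0
  queue <- ia
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + adj[[u]][r, 2]
        queue <- c(queue, v)
      }
    }
  }
  dist[ib]
}

random_bl_tree <- function(n, lo = 0.05, hi = 2) {
  ape::rtree(n, br = function(k) stats::runif(k, lo, hi))
}

# simulator configuration used by the reannotation-recovery experiments:
# 8 classes x 10 organisms x 3 gene copies = 30 leaves per class, label
# corruption only, clade separation >= 5x the intra-class depth
recovery_params <- function(seed) {
  mmphylo::sim_params(
    seed = seed,
    classes = c("MMP-1", "MMP-2", "MMP-3", "MMP-8", "MMP-9", "MMP-10",
                "MMP-13", "MMP-14"),
    distractor_classes = character(0),
    organisms = c("Homo sapiens", "Bos taurus", "Mus musculus",
                  "Rattus norvegicus", "Canis lupus",
                  "Oryctolagus cuniculus", "Sus scrofa",
                  "Felis catus", "Equus caballus", "Ovis aries"),
    class_stem = 0.75,
    fragment_rate = 0, duplicate_rate = 0,
    mislabel_rate = 0.05, generic_rate = 0.10)
}

# one reannotation-recovery replicate: simulate, estimate the tree the way
# the pipeline does, annotate, score against truth
run_recovery_replicate <- function(seed) {
  ds <- mmphylo::generate_dataset(recovery_params(seed))
  aln <- suppressWarnings(mmphylo::as_alignment(ds$records))
  tr <- mmphylo::root_with_outgroup(
    mmphylo::nj_tree(mmphylo::p_distance(aln)), "A0A087RZB5")
  lab <- mmphylo::leaf_labels(ds$records)
  ann <- mmphylo::annotate(tr, lab, outgroup = "A0A087RZB5")
  tru <- ds$truth[ds$truth$class != "OUTGROUP", ]
  fin <- ann$leaves$final[match(tru$seq_id, ann$leaves$seq_id)]
  mis <- !is.na(tru$mislabel_to)
  clean <- !mis & !tru$generic
  c(mis_total = sum(mis),
    mis_corrected = sum(fin[mis] == tru$class[mis]),
    clean_total = sum(clean),
    clean_changed = sum(fin[clean] != tru$class[clean]))
}

# one planted-model-organism replicate at full simulator defaults:
# generate -> curate -> NJ -> root -> annotate -> proximity; returns TRUE
# when the planted organism is ranked strictly first for every scoped class
run_planted_replicate <- function(seed) {
  ds <- mmphylo::generate_dataset(mmphylo::sim_params(seed = seed))
  cur <- suppressMessages(mmphylo::run_curation(ds$records, ds$hits))
  aln <- suppressWarnings(mmphylo::as_alignment(cur$records))
  tr <- mmphylo::root_with_outgroup(
    mmphylo::nj_tree(mmphylo::p_distance(aln)), "A0A087RZB5")
  lab <- mmphylo::leaf_labels(cur$records)
  ann <- mmphylo::annotate(tr, lab, outgroup = "A0A087RZB5")
  fl <- data.frame(seq_id = ann$leaves$seq_id, label = ann$leaves$final,
                   organism = lab$organism[match(ann$leaves$seq_id,
                                                 lab$seq_id)],
                   stringsAsFactors = FALSE)
  prox <- mmphylo::organism_proximity(tr, fl)
  planted <- ds$truth[match(names(prox$per_class), ds$truth$class),
                      "planted_nearest"]
  ok <- vapply(seq_along(prox$per_class), function(i) {
    e <- prox$per_class[[i]]
    if (!e$rankable) return(FALSE)
    first <- e$ranking$organism[e$ranking$rank == 1L]
    length(first) == 1L && first == planted[i]
  }, logical(1))
  all(ok)
}
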