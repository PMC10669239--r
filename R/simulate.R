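# Simulator of class-structured MMP-like gene families with ground truth.
# A single clock-like family tree carries one clade per MMP class (plus
# matrilysin-like distractor classes); inside each class clade the scoped
# organisms sit on a caterpillar species tree whose join order encodes a
# per-class planted nearest organism to the reference, and within-species
# gene duplication adds small cherries. Sequences evolve along the tree
# under a 20-state Poisson substitution model; corruption injection then
# emulates the defects of uncurated public data (fragments, exact
# duplicates, mislabels, generic labels), every action recorded in a
# manifest.

.default_taxids <- c("Homo sapiens" = 9606, "Bos taurus" = 9913,
                     "Mus musculus" = 10090, "Rattus norvegicus" = 10116,
                     "Canis lupus" = 9612, "Oryctolagus cuniculus" = 9986,
                     "Sus scrofa" = 9823)

.default_orgcodes <- c("Homo sapiens" = "HUMAN", "Bos taurus" = "BOVIN",
                       "Mus musculus" = "MOUSE",
                       "Rattus norvegicus" = "RAT",
                       "Canis lupus" = "CANLF",
                       "Oryctolagus cuniculus" = "RABIT",
                       "Sus scrofa" = "PIG")

.generic_phrases <- c("Zinc-dependent protein", "Metalloproteinase",
                      "Matrix metallopeptidase", "Uncharacterized protein")

.outgroup_id <- "A0A087RZB5"

#' Simulation parameters
#'
#' The defaults define the simulated study conditions: the seven
#' dentistry-relevant organisms on a shared clock-like species tree with
#' three gene copies per (class, organism), all 21 MMP classes plus two
#' matrilysin-like distractor classes (two-domain architecture, removed by
#' the architecture filter by construction), 450-site sequences (the scale
#' of a curated MMP after trimming), and corruption rates of 5% fragments,
#' 5% exact duplicates, 5% mislabels and 10% generic labels. Each class
#' designates a planted nearest organism to the reference; by default
#' Oryctolagus cuniculus, with Canis lupus for MMP-13 and Rattus
#' norvegicus for MMP-2.
#'
#' Branch-length units are expected substitutions per site: gene cherries
#' at depth `cherry_depth`, successive species joins every `species_step`,
#' class clades hung on a backbone (`class_stem` stems, `backbone_step`
#' increments) deep enough that classes form well-separated clades, and
#' the Archaeal outgroup on a long `outgroup_branch`.
#'
#' @param ... overrides of any default field.
#' @return an `mmp_sim_params` list.
#' @export
sim_params <- function(...) {
  p <- list(
    organisms = names(.default_taxids),
    reference = "Homo sapiens",
    classes = c(mmp_classes(), "MMP-7", "MMP-26"),
    distractor_classes = c("MMP-7", "MMP-26"),
    planted_nearest = NULL, # filled below
    sites = 450L,
    mu = 1,
    class_rate = NULL,      # named multiplier per class, default all 1
    rate_jitter_sd = 0.1,
    cherry_depth = 0.015,
    species_step = 0.03,
    class_stem = 0.55,
    backbone_step = 0.03,
    outgroup_branch = 1.5,
    fragment_rate = 0.05,
    duplicate_rate = 0.05,
    mislabel_rate = 0.05,
    generic_rate = 0.10,
    leaves_per = 3L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown sim parameter: ", unknown[1L])
  p[names(over)] <- over
  if (is.null(p$planted_nearest)) {
    pn <- rep("Oryctolagus cuniculus", length(p$classes))
    names(pn) <- p$classes
    pn[names(pn) == "MMP-13"] <- "Canis lupus"
    pn[names(pn) == "MMP-2"] <- "Rattus norvegicus"
    p$planted_nearest <- pn
  }
  if (is.null(p$class_rate)) {
    p$class_rate <- stats::setNames(rep(1, length(p$classes)), p$classes)
  }
  rates <- c(p$fragment_rate, p$duplicate_rate, p$mislabel_rate,
             p$generic_rate)
  if (any(rates < 0 | rates > 1)) stop("corruption rates must lie in [0, 1]")
  if (!p$reference %in% p$organisms)
    stop("reference organism must be simulated")
  if (is.null(p$seed)) stop("a seed is mandatory")
  class(p) <- "mmp_sim_params"
  p
}

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Evolve a sequence along one branch
#'
#' 20-state Poisson model: each site substitutes independently with
#' probability `p(t) = (19/20) * (1 - exp(-(20/19) * mu * t))`, the
#' replacement drawn uniformly from the 19 alternative residues. At
#' `t = 0` the child equals the parent; as `t` grows the expected
#' mismatch fraction saturates at 19/20.
#'
#' @param parent parent residues (single string).
#' @param t branch length (expected substitutions per site at `mu = 1`);
#'   must be non-negative.
#' @param mu rate multiplier.
#' @return child residues (single string).
#' @export
evolve_sequence <- function(parent, t, mu = 1) {
  if (t < 0) stop("branch length must be non-negative")
  codes <- match(strsplit(toupper(parent), "")[[1L]], .aa20)
  if (anyNA(codes)) stop("parent sequence must be over the 20 amino acids")
  paste(.aa20[.evolve_codes(codes, t, mu)], collapse = "")
}

.evolve_codes <- function(codes, t, mu) {
  p <- (19 / 20) * (1 - exp(-(20 / 19) * mu * t))
  hit <- which(stats::runif(length(codes)) < p)
  if (length(hit)) {
    off <- sample.int(19L, length(hit), replace = TRUE)
    codes[hit] <- ((codes[hit] - 1L + off) %% 20L) + 1L
  }
  codes
}

# --- tree assembly -------------------------------------------------------
# Subtrees are carried as (newick fragment, height) pairs; joining two
# subtrees at height H extends each fragment by H - height. All heights are
# measured from the leaves, so the assembled family tree is clock-like
# before jitter.

.join_at <- function(a, b, H) {
  list(str = sprintf("(%s:%.10g,%s:%.10g)", a$str, H - a$h, b$str, H - b$h),
       h = H)
}

.cherry <- function(ids, depth) {
  if (length(ids) == 1L) return(list(str = ids, h = 0))
  list(str = paste0("(", paste(sprintf("%s:%.10g", ids, depth),
                               collapse = ","), ")"),
       h = depth)
}

# caterpillar species tree of one class: reference and planted organism
# join first, remaining organisms at successive depths in fixed order;
# per-(class, organism) gene cherries at depth cherry_depth; all heights
# scaled by the class rate multiplier
.class_subtree <- function(class, params, acc_of) {
  r <- params$class_rate[[class]]
  planted <- params$planted_nearest[[class]]
  others <- setdiff(params$organisms, c(params$reference, planted))
  others <- sort(others)
  ord <- c(params$reference, planted, others)
  eps <- params$cherry_depth * r
  sub <- .cherry(acc_of(class, ord[1L]), eps)
  for (i in seq_along(ord)[-1L]) {
    H <- params$species_step * (i - 1L) * r
    sub <- .join_at(sub, .cherry(acc_of(class, ord[i]), eps), H)
  }
  sub
}

#' Build the true family gene tree
#'
#' Assembles the composite clock-like tree: one caterpillar-with-cherries
#' clade per class, classes hung on a caterpillar backbone, the outgroup
#' leaf on a long pendant branch at the root. Per-branch log-normal rate
#' jitter (sd `rate_jitter_sd` on the log scale) is applied to every edge.
#'
#' @param params an `mmp_sim_params`.
#' @param seed optional seed (set when called standalone; [generate_dataset()]
#'   seeds once for the whole run).
#' @return list with `tree` (a `"phylo"`; leaf names are accessions, the
#'   outgroup leaf is the Archaeal accession) and `registry` (data frame
#'   `seq_id`, `class`, `organism`).
#' @export
simulate_gene_tree <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counter <- 0L
  registry <- list()
  acc_of <- function(class, organism) {
    ids <- sprintf("SYN%05d", counter + seq_len(params$leaves_per))
    counter <<- counter + params$leaves_per
    registry[[length(registry) + 1L]] <<- data.frame(
      seq_id = ids, class = class, organism = organism,
      stringsAsFactors = FALSE)
    ids
  }
  subs <- lapply(params$classes, .class_subtree, params = params,
                 acc_of = acc_of)
  hmax <- max(vapply(subs, `[[`, numeric(1), "h"))
  fam <- subs[[1L]]
  for (k in seq_along(subs)[-1L]) {
    H <- hmax + params$class_stem + (k - 2L) * params$backbone_step
    fam <- .join_at(fam, subs[[k]], H)
  }
  root_h <- fam$h + 0.05
  txt <- sprintf("(%s:%.10g,%s:%.10g);", fam$str, root_h - fam$h,
                 .outgroup_id, root_h + params$outgroup_branch)
  tree <- ape::read.tree(text = txt)
  if (params$rate_jitter_sd > 0) {
    tree$edge.length <- tree$edge.length *
      exp(stats::rnorm(nrow(tree$edge), 0, params$rate_jitter_sd))
  }
  list(tree = tree, registry = do.call(rbind, registry))
}

# evolve a root sequence down a phylo tree; returns leaf sequences as a
# named character vector of strings
.evolve_along <- function(tree, root_codes, mu) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  nnode <- max(tree$edge)
  seqs <- vector("list", nnode)
  root <- length(tree$tip.label) + 1L
  seqs[[root]] <- root_codes
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    seqs[[child]] <- .evolve_codes(seqs[[par]], tree$edge.length[e], mu)
  }
  ntip <- length(tree$tip.label)
  out <- vapply(seq_len(ntip), function(i)
    paste(.aa20[seqs[[i]]], collapse = ""), character(1))
  names(out) <- tree$tip.label
  out
}

.records_from_registry <- function(registry, seqs, params) {
  n <- nrow(registry)
  num <- sub("^MMP-", "", registry$class)
  desc <- sprintf("Matrix metalloproteinase-%s (MMP-%s)", num, num)
  code <- .default_orgcodes[registry$organism]
  code[is.na(code)] <- toupper(substr(gsub("\\s", "", registry$organism[
    is.na(code)]), 1L, 5L))
  taxid <- .default_taxids[registry$organism]
  if (any(is.na(taxid))) {
    extra <- unique(registry$organism[is.na(taxid)])
    fake <- stats::setNames(500000L + seq_along(extra) * 7L, extra)
    taxid[is.na(taxid)] <- fake[registry$organism[is.na(taxid)]]
  }
  df <- data.frame(
    seq_id = registry$seq_id, db_tag = "synthetic",
    accession = registry$seq_id,
    entry_name = paste0(registry$seq_id, "_", unname(code)),
    description = desc, organism = registry$organism,
    taxid = as.integer(unname(taxid)),
    gene = paste0("MMP", num),
    residues = unname(seqs[registry$seq_id]),
    stringsAsFactors = FALSE)
  df$length <- nchar(df$residues)
  .new_records(df)
}

.truth_skeleton <- function(registry, params) {
  data.frame(
    seq_id = registry$seq_id, accession = registry$seq_id,
    class = registry$class, group = mmp_group(registry$class),
    organism = registry$organism,
    planted_nearest = unname(params$planted_nearest[registry$class]),
    is_distractor = registry$class %in% params$distractor_classes,
    orig_length = params$sites,
    fragment = FALSE, frag_start = NA_integer_, frag_end = NA_integer_,
    duplicate_of = NA_character_, mislabel_to = NA_character_,
    generic = FALSE, stringsAsFactors = FALSE)
}

#' Simulate one class's gene family
#'
#' Builds the class gene tree (caterpillar species tree with duplication
#' cherries, class rate multiplier, per-branch jitter), evolves sequences
#' from a random (or supplied) root sequence, and returns records, truth
#' manifest and the generating tree. Used standalone for focused
#' experiments; [generate_dataset()] assembles all classes on one shared
#' backbone instead so inter-class structure is controlled.
#'
#' @param class class name (must appear in `params$classes`).
#' @param params an `mmp_sim_params`.
#' @param root_seq optional root residue string of length `params$sites`.
#' @param seed optional seed.
#' @return list with `records`, `truth`, `tree`.
#' @export
simulate_family <- function(class, params = sim_params(), root_seq = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!class %in% params$classes) stop("unknown class: ", class)
  counter <- 0L
  registry <- list()
  acc_of <- function(cls, organism) {
    ids <- sprintf("SYN%05d", counter + seq_len(params$leaves_per))
    counter <<- counter + params$leaves_per
    registry[[length(registry) + 1L]] <<- data.frame(
      seq_id = ids, class = cls, organism = organism,
      stringsAsFactors = FALSE)
    ids
  }
  sub <- .class_subtree(class, params, acc_of)
  txt <- paste0(sub$str, ";")
  tree <- ape::read.tree(text = txt)
  if (params$rate_jitter_sd > 0)
    tree$edge.length <- tree$edge.length *
      exp(stats::rnorm(nrow(tree$edge), 0, params$rate_jitter_sd))
  registry <- do.call(rbind, registry)
  root_codes <- if (is.null(root_seq)) {
    sample.int(20L, params$sites, replace = TRUE)
  } else {
    match(strsplit(toupper(root_seq), "")[[1L]], .aa20)
  }
  seqs <- .evolve_along(tree, root_codes, params$mu)
  list(records = .records_from_registry(registry, seqs, params),
       truth = .truth_skeleton(registry, params), tree = tree)
}

#' Inject dataset corruptions
#'
#' Emulates the defects that motivate curation of public sequence data:
#' \itemize{
#'   \item fragments — truncation to a uniformly chosen 10--40% span,
#'     guaranteed below the default length window by construction;
#'   \item exact duplicates — a copy of a record under a new accession;
#'   \item mislabels — the description's class token swapped to a
#'     different concrete class;
#'   \item generic labels — the description replaced by a family-level
#'     phrase such as "Zinc-dependent protein".
#' }
#' Fragment, mislabel and generic sets are drawn disjointly; duplicates
#' are drawn independently and copy the (possibly already corrupted)
#' record. Every action is recorded in the truth manifest. The outgroup
#' record is never corrupted.
#'
#' @param records an `mmp_records` data frame.
#' @param truth the matching truth manifest.
#' @param params an `mmp_sim_params` (the four rates are read from it).
#' @param seed optional seed.
#' @return list with updated `records` and `truth`.
#' @export
inject_corruptions <- function(records, truth, params = sim_params(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(records) == nrow(truth),
            all(records$seq_id == truth$seq_id))
  base <- which(truth$class != "OUTGROUP")
  n <- length(base)
  n_frag <- round(params$fragment_rate * n)
  n_mis <- round(params$mislabel_rate * n)
  n_gen <- round(params$generic_rate * n)
  n_dup <- round(params$duplicate_rate * n)
  if (n_frag + n_mis + n_gen > n)
    stop("fragment + mislabel + generic rates exceed 1")
  perm <- sample(base)
  idx_frag <- perm[seq_len(n_frag)]
  idx_mis <- perm[n_frag + seq_len(n_mis)]
  idx_gen <- perm[n_frag + n_mis + seq_len(n_gen)]

  for (i in idx_frag) {
    len <- records$length[i]
    flen <- max(1L, round(stats::runif(1, 0.1, 0.4) * len))
    fstart <- sample.int(len - flen + 1L, 1L)
    records$residues[i] <- substr(records$residues[i], fstart,
                                  fstart + flen - 1L)
    records$length[i] <- flen
    truth$fragment[i] <- TRUE
    truth$frag_start[i] <- fstart
    truth$frag_end[i] <- fstart + flen - 1L
  }
  # mislabel targets are drawn from the concrete classes present in this
  # dataset: a mislabel in curated data is some other populated class, and
  # swaps into absent classes would exercise the rare-class flagging path
  # instead of reannotation
  concrete <- setdiff(params$classes, params$distractor_classes)
  for (i in idx_mis) {
    target <- sample(setdiff(concrete, truth$class[i]), 1L)
    num <- sub("^MMP-", "", target)
    records$description[i] <-
      sprintf("Matrix metalloproteinase-%s (MMP-%s)", num, num)
    records$gene[i] <- paste0("MMP", num)
    truth$mislabel_to[i] <- target
  }
  if (n_gen > 0) {
    phrases <- sample(.generic_phrases, n_gen, replace = TRUE)
    records$description[idx_gen] <- phrases
    records$gene[idx_gen] <- NA_character_
    truth$generic[idx_gen] <- TRUE
  }
  if (n_dup > 0) {
    idx_dup <- sample(base, n_dup)
    dup_rec <- records[idx_dup, , drop = FALSE]
    dup_tru <- truth[idx_dup, , drop = FALSE]
    new_acc <- sprintf("DUP%05d", seq_len(n_dup))
    dup_tru$duplicate_of <- dup_rec$accession
    dup_rec$seq_id <- new_acc
    dup_rec$accession <- new_acc
    dup_rec$entry_name <- paste0(new_acc, sub("^[^_]+", "", dup_rec$entry_name))
    dup_tru$seq_id <- new_acc
    dup_tru$accession <- new_acc
    records <- .new_records(rbind(records, dup_rec))
    truth <- rbind(truth, dup_tru)
    rownames(truth) <- NULL
  }
  list(records = records, truth = truth)
}

# per-class domain architecture as fractions of the full-length frame
.architecture <- function(group, is_distractor, L) {
  span <- function(a, b, id) list(start = max(1L, as.integer(round(a * L))),
                                  end = min(L, as.integer(round(b * L))),
                                  cdd = id)
  doms <- list(span(0.07, 0.24, "CDD:396175"),  # pg_binding propeptide
               span(0.27, 0.62, "CDD:395334"))  # matrixin catalytic
  if (!is_distractor) {
    doms <- c(doms, list(span(0.67, 0.98, "CDD:395000"))) # hemopexin
    if (identical(group, "gelatinase")) {
      doms <- c(doms, list(span(0.36, 0.44, "CDD:128373"),
                           span(0.46, 0.54, "CDD:128373"),
                           span(0.56, 0.64, "CDD:128373")))
    }
  }
  doms
}

#' Emit the domain-hit table for simulated records
#'
#' Architectures follow the MMP domain layout: propeptide (pg-binding),
#' catalytic (matrixin) and hemopexin domains for every class, plus three
#' fibronectin type II repeats inside the catalytic region for
#' gelatinases; matrilysin-like distractors carry only the propeptide and
#' catalytic domains (two families, guaranteed removal at the default
#' three-family threshold). Fragments keep only the hits whose
#' coordinates fall fully inside the retained span, shifted to the
#' fragment frame. Duplicates inherit their source's architecture under
#' their own seq_id.
#'
#' @param records an `mmp_records` data frame.
#' @param truth the matching truth manifest.
#' @param seed optional seed (scores are drawn from the RNG).
#' @return a domain-hit data frame in the [read_domain_hits()] shape.
#' @export
emit_domain_hits <- function(records, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(records$seq_id == truth$seq_id))
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    grp <- if (truth$class[i] == "OUTGROUP") "none" else truth$group[i]
    doms <- .architecture(grp, truth$is_distractor[i], truth$orig_length[i])
    if (truth$fragment[i]) {
      fs <- truth$frag_start[i]
      fe <- truth$frag_end[i]
      doms <- Filter(function(d) d$start >= fs && d$end <= fe, doms)
      doms <- lapply(doms, function(d) {
        d$start <- d$start - fs + 1L
        d$end <- d$end - fs + 1L
        d
      })
    }
    if (length(doms) == 0L) next
    rows[[i]] <- data.frame(
      seq_id = records$seq_id[i],
      cdd_id = vapply(doms, `[[`, character(1), "cdd"),
      qstart = vapply(doms, `[[`, integer(1), "start"),
      qend = vapply(doms, `[[`, integer(1), "end"),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                           list(make.row.names = FALSE)))
  n <- nrow(hits)
  data.frame(seq_id = hits$seq_id, cdd_id = hits$cdd_id,
             family = cdd_family(hits$cdd_id),
             bitscore = round(stats::runif(n, 100, 300), 1),
             evalue = signif(10^stats::runif(n, -80, -20), 3),
             qstart = hits$qstart, qend = hits$qend,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Seeds the RNG once, builds the family tree, evolves sequences from a
#' random root, converts leaves to UniProt-style synthetic records,
#' appends the verbatim Archaeal outgroup record, injects corruptions and
#' emits the matching domain-hit table. Identical parameters and seed
#' reproduce all outputs byte-identically.
#'
#' @param params an `mmp_sim_params` (the seed lives in it).
#' @param dir optional output directory; when given, writes
#'   `sequences.fasta`, `domain_hits.tsv`, `truth.tsv` and
#'   `true_tree.nwk` there.
#' @return list with `records`, `hits`, `truth`, `tree` (the true,
#'   uncorrupted gene tree) and `params`.
#' @export
generate_dataset <- function(params = sim_params(), dir = NULL) {
  set.seed(params$seed)
  gt <- simulate_gene_tree(params)
  root_codes <- sample.int(20L, params$sites, replace = TRUE)
  seqs <- .evolve_along(gt$tree, root_codes, params$mu)
  seqs <- seqs[setdiff(names(seqs), .outgroup_id)]
  records <- .records_from_registry(gt$registry, seqs, params)
  truth <- .truth_skeleton(gt$registry, params)
  og <- outgroup_record()
  records <- .new_records(rbind(records, og))
  truth <- rbind(truth, data.frame(
    seq_id = og$seq_id, accession = og$accession, class = "OUTGROUP",
    group = "none", organism = og$organism, planted_nearest = NA_character_,
    is_distractor = FALSE, orig_length = og$length, fragment = FALSE,
    frag_start = NA_integer_, frag_end = NA_integer_,
    duplicate_of = NA_character_, mislabel_to = NA_character_,
    generic = FALSE, stringsAsFactors = FALSE))
  rownames(truth) <- NULL
  cor <- inject_corruptions(records, truth, params)
  hits <- emit_domain_hits(cor$records, cor$truth)
  out <- list(records = cor$records, hits = hits, truth = cor$truth,
              tree = gt$tree, params = params)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$records, file.path(dir, "sequences.fasta"))
    write_domain_hits(out$hits, file.path(dir, "domain_hits.tsv"))
    utils::write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_newick(out$tree, file.path(dir, "true_tree.nwk"))
  }
  out
}

#' Stage survivor counts predicted by the truth manifest
#'
#' From the corruption flags alone (no filtering re-run): fragments and
#' their duplicates fall below the length window by construction;
#' distractor-class records (and their duplicates) lack the three-family
#' architecture; duplicates of surviving records are collapsed by exact
#' deduplication. Valid whenever fragments are cut to 10--40% spans and
#' the fragment rate is moderate (the corrupted mean still brackets
#' full-length records), as under the default parameters.
#'
#' @param truth a truth manifest.
#' @return named integer vector `input`, `length`, `domains`, `dedup`.
#' @export
predicted_stage_counts <- function(truth) {
  n <- nrow(truth)
  frag <- truth$fragment
  distr <- !frag & truth$is_distractor
  dup <- !frag & !truth$is_distractor & !is.na(truth$duplicate_of)
  c(input = n,
    length = n - sum(frag),
    domains = n - sum(frag) - sum(distr),
    dedup = n - sum(frag) - sum(distr) - sum(dup))
}
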