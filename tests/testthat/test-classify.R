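# fixture: a rooted tree with two well-separated class clades plus an
# outgroup; clade_a / clade_b leaves are named a1..aN / b1..bN
two_clade_tree <- function(na = 12, nb = 12) {
  clade <- function(pref, n)
    paste0("(", paste(sprintf("%s%d:0.1", pref, seq_len(n)),
                      collapse = ","), ")")
  txt <- sprintf("((%s:1,%s:1):1,OG:5);", clade("a", na), clade("b", nb))
  ape::read.tree(text = txt)
}

test_that("a unanimous clade vote returns the surrounding class", {
  tr <- two_clade_tree()
  labels <- stats::setNames(
    c(rep("MMP-2", 12), rep("MMP-9", 12), NA),
    tr$tip.label)
  labels["a1"] <- "GENERIC"
  v <- neighbor_vote(tr, labels, "a1", exclude = "OG")
  expect_equal(v$label, "MMP-2")
  expect_equal(v$fraction, 1)
  expect_gte(v$votes_counted, 10)
})

test_that("a vote with no concrete neighbours anywhere is vacuous", {
  tr <- two_clade_tree(3, 3)
  labels <- stats::setNames(rep("GENERIC", 7), tr$tip.label)
  v <- neighbor_vote(tr, labels, "a1", exclude = "OG")
  expect_true(is.na(v$label))
  expect_equal(v$votes_counted, 0L)
})

test_that("an exact 5/5 split among the first ten voters is a tie", {
  inner <- paste0("((", paste(sprintf("c%d:1", 1:5), collapse = ","),
                  "):1,(", paste(sprintf("d%d:1", 1:5), collapse = ","),
                  "):1)")
  txt <- sprintf("((q:1,%s:1):1,(e1:1,e2:1):1);", inner)
  tr <- ape::read.tree(text = txt)
  labels <- stats::setNames(rep("UNASSIGNED", length(tr$tip.label)),
                            tr$tip.label)
  labels[sprintf("c%d", 1:5)] <- "MMP-1"
  labels[sprintf("d%d", 1:5)] <- "MMP-8"
  labels[c("e1", "e2")] <- "MMP-1"
  v <- neighbor_vote(tr, labels, "q")
  expect_true(is.na(v$label))
  expect_equal(v$votes_counted, 10L)
})

test_that("consistently labelled clades are a fixed point of annotation", {
  tr <- two_clade_tree()
  labels <- stats::setNames(c(rep("MMP-2", 12), rep("MMP-9", 12), NA),
                            tr$tip.label)
  ann <- annotate(tr, labels[!is.na(labels)], outgroup = "OG")
  expect_true(all(ann$leaves$change_kind == "unchanged"))
  tot <- ann$report[ann$report$class == "Total", ]
  expect_equal(tot$class_annotation, 0)
  expect_equal(tot$reannotation, 0)
})

test_that("a mislabeled leaf inside a pure clade is reannotated", {
  tr <- two_clade_tree()
  labels <- stats::setNames(c(rep("MMP-2", 12), rep("MMP-9", 12), NA),
                            tr$tip.label)
  labels["a3"] <- "MMP-9" # planted mislabel inside the MMP-2 clade
  ann <- annotate(tr, labels[!is.na(labels)], outgroup = "OG")
  row <- ann$leaves[ann$leaves$seq_id == "a3", ]
  expect_equal(row$change_kind, "reannotation")
  expect_equal(row$final, "MMP-2")
  expect_equal(row$vote_fraction, 1)
  # everything else untouched
  expect_true(all(ann$leaves$change_kind[ann$leaves$seq_id != "a3"] ==
                    "unchanged"))
})

test_that("generic labels are upgraded by class annotation", {
  tr <- two_clade_tree()
  labels <- stats::setNames(c(rep("MMP-2", 12), rep("MMP-9", 12), NA),
                            tr$tip.label)
  labels[c("b2", "b5")] <- "GENERIC"
  ann <- annotate(tr, labels[!is.na(labels)], outgroup = "OG")
  rows <- ann$leaves[ann$leaves$seq_id %in% c("b2", "b5"), ]
  expect_true(all(rows$change_kind == "class_annotation"))
  expect_true(all(rows$final == "MMP-9"))
})

test_that("rare classes are flagged, never absorbed", {
  tr <- two_clade_tree()
  labels <- stats::setNames(c(rep("MMP-1", 12), rep("MMP-9", 12), NA),
                            tr$tip.label)
  labels["a7"] <- "MMP-18" # singleton class inside the collagenase clade
  ann <- annotate(tr, labels[!is.na(labels)], outgroup = "OG")
  row <- ann$leaves[ann$leaves$seq_id == "a7", ]
  expect_equal(row$change_kind, "flagged")
  expect_equal(row$final, "MMP-18")
  expect_true("MMP-18" %in% ann$report$class)
})

test_that("annotation is a single pass against prior labels only", {
  tr <- two_clade_tree()
  labels <- stats::setNames(c(rep("MMP-2", 12), rep("MMP-9", 12), NA),
                            tr$tip.label)
  labels[c("a3", "a4")] <- "MMP-9"
  ann1 <- annotate(tr, labels[!is.na(labels)], outgroup = "OG")
  # shuffling the label vector (names kept) changes nothing
  shuffled <- sample(labels[!is.na(labels)])
  ann2 <- annotate(tr, shuffled, outgroup = "OG")
  o1 <- ann1$leaves[order(ann1$leaves$seq_id), ]
  o2 <- ann2$leaves[order(ann2$leaves$seq_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("per-class flows conserve totals", {
  tr <- two_clade_tree()
  labels <- stats::setNames(c(rep("MMP-2", 12), rep("MMP-9", 12), NA),
                            tr$tip.label)
  labels["a3"] <- "MMP-9"
  labels["b1"] <- "GENERIC"
  ann <- annotate(tr, labels[!is.na(labels)], outgroup = "OG")
  rep_ <- ann$report
  per <- rep_[rep_$class != "Total", ]
  tot <- rep_[rep_$class == "Total", ]
  expect_equal(sum(per$n), tot$n)
  expect_equal(sum(per$class_annotation), tot$class_annotation)
  expect_equal(sum(per$reannotation), tot$reannotation)
  # inflow/outflow bookkeeping: final counts = prior + inflow - outflow
  prior_tab <- table(ann$leaves$prior)
  for (cc in per$class) {
    inflow <- sum(ann$leaves$final == cc & ann$leaves$prior != cc)
    outflow <- sum(ann$leaves$prior == cc & ann$leaves$final != cc)
    prior_n <- if (cc %in% names(prior_tab)) prior_tab[[cc]] else 0L
    expect_equal(per$n[per$class == cc], prior_n + inflow - outflow)
  }
})

test_that("raising the vote threshold never increases changed labels", {
  set.seed(31)
  ds <- generate_dataset(recovery_params(31))
  aln <- suppressWarnings(as_alignment(ds$records))
  tr <- root_with_outgroup(nj_tree(p_distance(aln)), "A0A087RZB5")
  lab <- leaf_labels(ds$records)
  changed <- vapply(c(0.6, 0.7, 0.8, 0.9), function(f) {
    ann <- annotate(tr, lab, f = f, outgroup = "A0A087RZB5")
    sum(ann$leaves$change_kind %in% c("class_annotation", "reannotation"))
  }, numeric(1))
  expect_true(all(diff(changed) <= 0))
})

test_that("clade purity measures monophyly", {
  tr <- two_clade_tree(3, 3)
  labels <- stats::setNames(c(rep("MMP-2", 3), rep("MMP-9", 3), NA),
                            tr$tip.label)
  expect_equal(clade_purity(tr, labels[!is.na(labels)], "MMP-2"), 1)
  # class spread over both clades: MRCA subtends all 6 leaves
  labels2 <- labels
  labels2[c("a1", "a2", "b1")] <- "MMP-3"
  expect_equal(clade_purity(tr, labels2[!is.na(labels2)], "MMP-3"), 0.5)
  labels3 <- labels
  labels3["a1"] <- "MMP-18"
  expect_equal(clade_purity(tr, labels3[!is.na(labels3)], "MMP-18"), 1)
  expect_error(clade_purity(tr, labels[!is.na(labels)], "MMP-20"),
               "no leaves")
})

test_that("label parsing recognises class tokens and generic phrases", {
  expect_equal(parse_class_label(c(
    "Matrix metalloproteinase-13 (MMP-13)",
    "Interstitial collagenase MMP 1",
    "Zinc-dependent protein",
    "Completely unrelated enzyme")),
    c("MMP-13", "MMP-1", "GENERIC", "UNASSIGNED"))
  expect_equal(mmp_group(c("MMP-1", "MMP-2", "MMP-3", "MMP-14", "MMP-12",
                           "GENERIC")),
               c("collagenase", "gelatinase", "stromelysin",
                 "transmembrane", "other", "none"))
})
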