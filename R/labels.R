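#' MMP class labels and functional groups
#'
#' The class universe covers the 21 mammalian MMP classes recovered in
#' curated family sets (matrilysins MMP-7/26, MMP-22 and MMP-23 are absent
#' from it; sequences of those classes lack the three-domain core
#' architecture or are not retrieved at all). Two sentinel labels complete
#' the universe: `"GENERIC"` for descriptions that only carry a family-level
#' phrase (e.g. "Zinc-dependent protein") and `"UNASSIGNED"` for
#' descriptions carrying neither a class token nor a family keyword.
#'
#' @return `mmp_classes()` returns the 21 concrete class names.
#' @export
mmp_classes <- function() {
  paste0("MMP-", c(1, 2, 3, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18,
                   19, 20, 21, 24, 25, 27, 28))
}

.mmp_group_table <- c(
  "MMP-1" = "collagenase", "MMP-8" = "collagenase", "MMP-13" = "collagenase",
  "MMP-18" = "collagenase",
  "MMP-2" = "gelatinase", "MMP-9" = "gelatinase",
  "MMP-3" = "stromelysin", "MMP-10" = "stromelysin", "MMP-11" = "stromelysin",
  "MMP-14" = "transmembrane", "MMP-15" = "transmembrane",
  "MMP-16" = "transmembrane", "MMP-17" = "transmembrane",
  "MMP-24" = "transmembrane", "MMP-25" = "transmembrane",
  "MMP-12" = "other", "MMP-19" = "other", "MMP-20" = "other",
  "MMP-21" = "other", "MMP-27" = "other", "MMP-28" = "other"
)

#' Functional group of an MMP class
#'
#' Deterministic map from class to group: collagenases (MMP-1/8/13/18),
#' gelatinases (MMP-2/9), stromelysins (MMP-3/10/11), transmembrane
#' (MMP-14/15/16/17/24/25) and other (MMP-12/19/20/21/27/28). Sentinel
#' labels (`GENERIC`, `UNASSIGNED`) map to `"none"`; concrete tokens outside
#' the 21-class universe (e.g. matrilysin MMP-7 distractors emitted by the
#' simulator) map to `"other"`.
#'
#' @param mmp character vector of class labels.
#' @return character vector of groups.
#' @export
mmp_group <- function(mmp) {
  out <- unname(.mmp_group_table[mmp])
  sentinel <- mmp %in% c("GENERIC", "UNASSIGNED") | is.na(mmp)
  out[sentinel] <- "none"
  out[is.na(out) & !sentinel] <- "other"
  out
}

#' Keywords that mark a generic (family-level) annotation
#'
#' Matched case-insensitively against a description when no explicit MMP-N
#' token parses from it; a match yields the `GENERIC` label, otherwise the
#' record is `UNASSIGNED`.
#'
#' @export
generic_keywords <- function() {
  c("zinc", "metalloproteinase", "metallopeptidase", "matrix",
    "uncharacterized")
}

#' Parse a class label from a free-text description
#'
#' Recognises `MMP-N`, `MMP N`, `MMPN` and `metalloproteinase-N` tokens
#' (case-insensitive). When no token parses, descriptions containing a
#' generic keyword become `GENERIC`, everything else `UNASSIGNED`.
#'
#' @param description character vector of free-text protein descriptions.
#' @param keywords generic keyword list, see [generic_keywords()].
#' @return character vector of labels over `mmp_classes()` plus
#'   `GENERIC`/`UNASSIGNED` (plus out-of-universe `MMP-N` tokens verbatim).
#' @export
parse_class_label <- function(description, keywords = generic_keywords()) {
  description <- as.character(description)
  out <- rep("UNASSIGNED", length(description))
  m <- regexpr("(MMP[-_ ]?|metalloproteinase[- ])([0-9]+)",
               description, ignore.case = TRUE, perl = TRUE)
  hit <- m > 0
  if (any(hit)) {
    tok <- regmatches(description, m)
    num <- sub("^.*?([0-9]+)$", "\\1", tok)
    out[hit] <- paste0("MMP-", as.integer(num))
  }
  if (any(!hit)) {
    pat <- paste(keywords, collapse = "|")
    gen <- !hit & grepl(pat, description, ignore.case = TRUE)
    out[gen] <- "GENERIC"
  }
  out
}

#' Leaf-label table from a record collection
#'
#' Derives the prior class label of every sequence from its description and
#' pairs it with the organism, in the shape consumed by [annotate()] and
#' [organism_proximity()].
#'
#' @param records an `mmp_records` data frame, see [read_fasta()].
#' @param keywords generic keyword list.
#' @return data frame with columns `seq_id`, `label`, `group`, `organism`.
#' @export
leaf_labels <- function(records, keywords = generic_keywords()) {
  lab <- parse_class_label(records$description, keywords)
  data.frame(seq_id = records$seq_id, label = lab, group = mmp_group(lab),
             organism = records$organism, stringsAsFactors = FALSE)
}
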