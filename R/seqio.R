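# Readers/writers for the external formats: UniProt-dialect FASTA,
# RPSBlast-style domain-hit tables, newick trees and the report tables.

.residue_alphabet <- "ACDEFGHIKLMNPQRSTVWYXBZU-"

#' Conserved-domain family map
#'
#' The constant map from CDD identifiers to the four diagnostic MMP domain
#' families: the catalytic matrixin domain, the C-terminal hemopexin
#' repeats, the N-terminal propeptide (pg-binding) and the fibronectin
#' type II repeats found only in gelatinases. Identifiers outside the map
#' belong to family `"other"` and never count toward the architecture
#' filter.
#'
#' @return named list of character vectors of `CDD:<integer>` identifiers.
#' @export
domain_family_map <- function() {
  list(
    matrixin = paste0("CDD:", c(395334, 239819, 239806, 239805, 239804,
                                239803, 239796, 238124, 214576)),
    hemopexin = c("CDD:395000", "CDD:238046"),
    pg_binding = "CDD:396175",
    fibronectin = "CDD:128373"
  )
}

#' Map CDD identifiers to domain families
#'
#' @param cdd_id character vector of `CDD:<integer>` identifiers.
#' @return character vector over `{matrixin, hemopexin, pg_binding,
#'   fibronectin, other}`.
#' @export
cdd_family <- function(cdd_id) {
  map <- domain_family_map()
  lut <- rep(names(map), lengths(map))
  names(lut) <- unlist(map, use.names = FALSE)
  out <- unname(lut[cdd_id])
  out[is.na(out)] <- "other"
  out
}

.new_records <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("mmp_records", "data.frame")
  df
}

.validate_residues <- function(residues, seq_id) {
  bad <- regexpr(sprintf("[^%s]", .residue_alphabet), residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("illegal residue character '%s' at position %d in '%s'",
                 substr(residues[i], bad[i], bad[i]), bad[i], seq_id[i]))
  }
}

# Parse UniProt-style header lines (the ">" already stripped). Accepts both
# "OS=x" and the spaced "OS = x" form. Fields that do not parse are left
# absent (NA), never fabricated.
.parse_uniprot_headers <- function(headers) {
  n <- length(headers)
  out <- data.frame(seq_id = character(n), db_tag = NA_character_,
                    accession = NA_character_, entry_name = NA_character_,
                    description = "", organism = NA_character_,
                    taxid = NA_integer_, gene = NA_character_,
                    stringsAsFactors = FALSE)
  first_tok <- sub("\\s.*$", "", headers)
  rest <- sub("^\\S+\\s*", "", headers)
  m <- regexec("^(sp|tr|synthetic)\\|([^|]+)\\|(\\S+)$", first_tok)
  parts <- regmatches(first_tok, m)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) == 4L) {
      out$db_tag[i] <- p[2L]
      out$accession[i] <- p[3L]
      out$entry_name[i] <- p[4L]
      out$seq_id[i] <- p[3L]
    } else {
      out$seq_id[i] <- first_tok[i]
      out$accession[i] <- first_tok[i]
    }
  }
  # field tokens terminate the description / previous field value
  field_pat <- "\\s+(OS|OX|GN|PE|SV)\\s*=\\s*"
  desc <- sub(sprintf("%s.*$", field_pat), "", rest)
  out$description <- desc
  grab <- function(key) {
    pat <- sprintf(".*\\b%s\\s*=\\s*(.*?)(\\s+(OS|OX|GN|PE|SV)\\s*=.*)?$", key)
    val <- ifelse(grepl(sprintf("\\b%s\\s*=", key), rest),
                  sub(pat, "\\1", rest), NA_character_)
    trimws(val)
  }
  out$organism <- grab("OS")
  ox <- grab("OX")
  suppressWarnings(out$taxid <- as.integer(ox))
  out$gene <- grab("GN")
  out
}

#' Read a protein FASTA file
#'
#' @param path path to a FASTA file.
#' @param dialect `"uniprot"` parses `db|accession|entry` ids and the
#'   `OS=`/`OX=`/`GN=` metadata fields (spaced `OS = x` accepted);
#'   `"plain"` takes the first whitespace-delimited token as the id and
#'   leaves all metadata absent.
#' @return an `mmp_records` data frame with columns `seq_id`, `db_tag`,
#'   `accession`, `entry_name`, `description`, `organism`, `taxid`, `gene`,
#'   `residues`, `length`. Residues are upper-cased on read; record order is
#'   preserved.
#' @export
read_fasta <- function(path, dialect = c("uniprot", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no FASTA records in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  headers <- sub("^>\\s*", "", lines[starts])
  residues <- vapply(seq_along(starts), function(i) {
    if (ends[i] < starts[i] + 1L) return("")
    paste(lines[(starts[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  residues <- toupper(gsub("\\s", "", residues))
  if (any(residues == ""))
    stop("record without residues: ", headers[residues == ""][1L])
  if (dialect == "uniprot") {
    df <- .parse_uniprot_headers(headers)
  } else {
    ids <- sub("\\s.*$", "", headers)
    desc <- trimws(sub("^\\S+\\s*", "", headers))
    df <- data.frame(seq_id = ids, db_tag = NA_character_,
                     accession = ids, entry_name = NA_character_,
                     description = desc, organism = NA_character_,
                     taxid = NA_integer_, gene = NA_character_,
                     stringsAsFactors = FALSE)
  }
  dup <- duplicated(df$seq_id)
  if (any(dup)) stop("duplicate seq_id: ", df$seq_id[dup][1L])
  .validate_residues(residues, df$seq_id)
  df$residues <- residues
  df$length <- nchar(gsub("-", "", residues, fixed = TRUE))
  .new_records(df)
}

.format_header <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (!is.na(r$db_tag) && !is.na(r$entry_name)) {
      h <- sprintf("%s|%s|%s", r$db_tag, r$accession, r$entry_name)
    } else {
      h <- r$seq_id
    }
    if (nzchar(r$description) && !is.na(r$description))
      h <- paste(h, r$description)
    if (!is.na(r$organism)) h <- paste0(h, " OS=", r$organism)
    if (!is.na(r$taxid)) h <- paste0(h, " OX=", r$taxid)
    if (!is.na(r$gene)) h <- paste0(h, " GN=", r$gene)
    h
  }, character(1))
}

#' Write records to FASTA
#'
#' Round trip through [read_fasta()] reproduces seq_ids and residues
#' byte-identically (metadata spacing is normalised to the unspaced
#' `OS=x` form).
#'
#' @param records an `mmp_records` data frame.
#' @param path output path.
#' @param width line width for residues; `Inf` writes one line per record.
#' @export
write_fasta <- function(records, path, width = 60L) {
  headers <- paste0(">", .format_header(records))
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    s <- records$residues[i]
    if (is.finite(width) && nchar(s) > width) {
      pos <- seq(1L, nchar(s), by = width)
      s <- substring(s, pos, pmin(pos + width - 1L, nchar(s)))
    }
    out <- c(out, headers[i], s)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an RPSBlast-style tabular domain-hit file
#'
#' Expects BLAST outfmt-6-like tab-separated columns in the order
#' `seq_id`, `cdd_id`, percent identity, alignment length, `qstart`,
#' `qend`, `evalue`, `bitscore`; extra trailing columns are tolerated and
#' ignored. The domain family is assigned from [domain_family_map()];
#' unmapped CDD identifiers are retained with family `"other"`.
#'
#' @param path path to the tab-separated hit table (no header line).
#' @return data frame with columns `seq_id`, `cdd_id`, `family`,
#'   `bitscore`, `evalue`, `qstart`, `qend`.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(seq_id = character(0), cdd_id = character(0),
                      family = character(0), bitscore = numeric(0),
                      evalue = numeric(0), qstart = integer(0),
                      qend = integer(0), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty domain-hit file: ", path)
    return(empty)
  }
  raw <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           quote = "", comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 8L) stop("expected >= 8 tab-separated columns, got ",
                           ncol(raw))
  hits <- data.frame(seq_id = as.character(raw[[1L]]),
                     cdd_id = as.character(raw[[2L]]),
                     family = cdd_family(as.character(raw[[2L]])),
                     bitscore = as.numeric(raw[[8L]]),
                     evalue = as.numeric(raw[[7L]]),
                     qstart = as.integer(raw[[5L]]),
                     qend = as.integer(raw[[6L]]),
                     stringsAsFactors = FALSE)
  bad <- which(hits$qend < hits$qstart)
  if (length(bad))
    stop(sprintf("malformed coordinates (qend < qstart) at line %d", bad[1L]))
  hits
}

#' Write a domain-hit table
#'
#' Inverse of [read_domain_hits()]; percent identity and alignment length
#' are emitted as placeholder columns (100, qend - qstart + 1).
#'
#' @param hits data frame as returned by [read_domain_hits()].
#' @param path output path.
#' @export
write_domain_hits <- function(hits, path) {
  df <- data.frame(hits$seq_id, hits$cdd_id, 100,
                   hits$qend - hits$qstart + 1L, hits$qstart, hits$qend,
                   hits$evalue, hits$bitscore)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a newick tree
#'
#' One tree per file. Missing branch lengths default to 0 with a warning;
#' duplicate leaf names and unbalanced parentheses are errors (the latter
#' reported with the character offset of the imbalance). Support values, if
#' present as internal node labels, are preserved but never computed.
#'
#' @param path path to a newick file.
#' @return an [ape::read.tree()] `"phylo"` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("unbalanced parentheses at character offset %d", i))
  }
  if (depth != 0L)
    stop(sprintf("unbalanced parentheses at character offset %d",
                 length(chars)))
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse newick in ", path)
  dup <- duplicated(tree$tip.label)
  if (any(dup)) stop("duplicate leaf names: ", tree$tip.label[dup][1L])
  if (is.null(tree$edge.length)) {
    warning("no branch lengths in ", path, "; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree
}

#' Write a newick tree
#'
#' Branch lengths are written with 10 significant digits so round trips
#' preserve them.
#'
#' @param tree a `"phylo"` tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

# half-away-from-zero rounding for report display (base round() is
# round-half-even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Write a report table
#'
#' Tab-separated with one header line and a fixed column order per kind:
#' \describe{
#'   \item{stage_stats}{`stage, n, min, max, mean, sd` — mean and sd are
#'     rounded to the nearest integer (half away from zero) for display;
#'     full precision is retained in the in-memory objects.}
#'   \item{annotation}{`class, group, n, class_annotation, reannotation` —
#'     zero change counts are printed as `-`.}
#'   \item{proximity}{`class, organism, distance, rank` — non-rankable
#'     classes get a single `no candidate organisms` row; organisms absent
#'     from a class are listed with empty distance/rank.}
#' }
#'
#' @param table a data frame with the columns of the given kind (helpers
#'   [stage_stats_table()] and the `as.data.frame()` methods of the report
#'   objects produce them).
#' @param path output path.
#' @param kind one of `"stage_stats"`, `"annotation"`, `"proximity"`.
#' @export
write_report <- function(table, path, kind = c("stage_stats", "annotation",
                                               "proximity")) {
  if (length(kind) != 1L || !kind %in% c("stage_stats", "annotation",
                                         "proximity"))
    stop("unknown report kind: ", paste(kind, collapse = "/"))
  if (nrow(table) == 0L) stop("empty report table")
  cols <- switch(kind,
    stage_stats = c("stage", "n", "min", "max", "mean", "sd"),
    annotation = c("class", "group", "n", "class_annotation", "reannotation"),
    proximity = c("class", "organism", "distance", "rank"))
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("missing columns for kind '", kind, "': ",
         paste(missing, collapse = ", "))
  out <- table[, cols, drop = FALSE]
  if (kind == "stage_stats") {
    out$mean <- .round_half_away(out$mean)
    out$sd <- .round_half_away(out$sd)
  }
  if (kind == "annotation") {
    for (cc in c("class_annotation", "reannotation")) {
      v <- out[[cc]]
      out[[cc]] <- ifelse(!is.na(v) & v == 0, "-", as.character(v))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' The bundled Archaeal outgroup record
#'
#' The Marine Group I thaumarchaeote interstitial-collagenase-like sequence
#' (UniProt A0A087RZB5) used to root the MMP phylogeny; shipped as a
#' plain-text fixture and appended to every simulated dataset.
#'
#' @return a one-row `mmp_records` data frame.
#' @export
outgroup_record <- function() {
  path <- system.file("extdata", "outgroup_archaea.fasta",
                      package = "mmphylo", mustWork = TRUE)
  read_fasta(path, dialect = "uniprot")
}

#' @export
print.mmp_records <- function(x, ...) {
  cat(sprintf("<mmp_records> %d sequences, lengths %d-%d\n",
              nrow(x), min(x$length), max(x$length)))
  invisible(x)
}
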