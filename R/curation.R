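# The three-step curation cascade: length window -> conserved-domain
# architecture -> exact-duplicate removal, with per-stage statistics and
# removal traces.

#' Length statistics of a record collection
#'
#' Minimum, maximum, full-precision mean and sample (n-1) standard
#' deviation of the ungapped sequence lengths; the numbers behind the
#' per-stage statistics report.
#'
#' @param records an `mmp_records` data frame.
#' @return an `mmp_length_stats` list with `n`, `min_len`, `max_len`,
#'   `mean_len`, `sd_len` (`sd_len` is 0 when `n == 1`).
#' @export
compute_length_stats <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot compute length statistics of an empty record set")
  len <- records$length
  out <- list(n = length(len), min_len = min(len), max_len = max(len),
              mean_len = mean(len),
              sd_len = if (length(len) == 1L) 0 else stats::sd(len))
  class(out) <- "mmp_length_stats"
  out
}

#' @export
print.mmp_length_stats <- function(x, ...) {
  cat(sprintf("n=%d  min=%d  max=%d  mean=%.2f  sd=%.2f\n",
              x$n, x$min_len, x$max_len, x$mean_len, x$sd_len))
  invisible(x)
}

.stage_trace <- function(stage, n_in, kept, removed) {
  out <- list(stage = stage, n_in = n_in, n_out = nrow(kept),
              stats = if (nrow(kept)) compute_length_stats(kept) else NULL,
              removed = removed)
  stopifnot(out$n_out + nrow(removed) == n_in)
  class(out) <- "mmp_stage_trace"
  out
}

#' @export
print.mmp_stage_trace <- function(x, ...) {
  cat(sprintf("stage '%s': %d -> %d (%d removed)\n",
              x$stage, x$n_in, x$n_out, nrow(x$removed)))
  invisible(x)
}

#' Length-window filter
#'
#' Keeps sequences whose ungapped length lies within `window` (default 50%)
#' of the mean length, bounds inclusive. The mean is computed on the full
#' input at full precision, never on a rounded display value, and the
#' filter is applied exactly once per pipeline run (re-running would move
#' the mean and therefore the window).
#'
#' @param records an `mmp_records` data frame.
#' @param window half-width of the window as a fraction of the mean,
#'   `0 < window < 1`.
#' @return list with `records` (survivors, input order preserved) and
#'   `trace` (an `mmp_stage_trace`).
#' @export
filter_by_length <- function(records, window = 0.5) {
  if (nrow(records) == 0L) stop("empty record set")
  if (!is.numeric(window) || window <= 0 || window >= 1)
    stop("window must lie in (0, 1)")
  m <- mean(records$length)
  lo <- (1 - window) * m
  hi <- (1 + window) * m
  keep <- records$length >= lo & records$length <= hi
  if (!any(keep))
    stop(sprintf(
      "length filter removed every record (mean %.2f, window [%.2f, %.2f])",
      m, lo, hi))
  removed <- data.frame(
    seq_id = records$seq_id[!keep],
    reason = sprintf("length %d outside [%.2f, %.2f]",
                     records$length[!keep], lo, hi),
    stringsAsFactors = FALSE)
  list(records = .new_records(records[keep, , drop = FALSE]),
       trace = .stage_trace("length filter", nrow(records),
                            records[keep, , drop = FALSE], removed))
}

#' Conserved-domain architecture filter
#'
#' Keeps sequences with hits in at least `min_families` *distinct* domain
#' families among matrixin, hemopexin, pg-binding and fibronectin
#' (family `"other"` hits never count). Counting distinct families rather
#' than raw hits is what excludes two-domain architectures such as the
#' matrilysins at the default threshold of 3.
#'
#' @param records an `mmp_records` data frame.
#' @param hits a domain-hit data frame, see [read_domain_hits()]. Hits
#'   whose `seq_id` refers to no supplied record are dropped with a
#'   warning.
#' @param min_families minimum number of distinct families, at most 4.
#' @return list with `records` and `trace` as in [filter_by_length()].
#' @export
filter_by_domains <- function(records, hits, min_families = 3L) {
  if (min_families > 4L)
    stop("min_families > 4 is unsatisfiable: only 4 diagnostic families exist")
  dangling <- !(hits$seq_id %in% records$seq_id)
  if (any(dangling)) {
    message(sum(dangling), " domain hits refer to unknown sequences; ignored")
    hits <- hits[!dangling, , drop = FALSE]
  }
  counted <- hits[hits$family != "other", , drop = FALSE]
  fam_count <- integer(nrow(records))
  names(fam_count) <- records$seq_id
  if (nrow(counted)) {
    tab <- tapply(counted$family, counted$seq_id,
                  function(f) length(unique(f)))
    fam_count[names(tab)] <- as.integer(tab)
  }
  keep <- fam_count >= min_families
  removed <- data.frame(
    seq_id = records$seq_id[!keep],
    reason = sprintf("%d distinct domain families < %d",
                     fam_count[!keep], min_families),
    stringsAsFactors = FALSE)
  list(records = .new_records(records[keep, , drop = FALSE]),
       trace = .stage_trace("domain filter", nrow(records),
                            records[keep, , drop = FALSE], removed))
}

#' Duplicate removal (100% identity)
#'
#' In `exact` mode, records with identical residue strings
#' (case-insensitive) are collapsed to the one with the lexicographically
#' smallest accession, making the output independent of input order. In
#' `substring` mode, records whose residues are a proper substring of a
#' kept record's are additionally removed (the behaviour of identity-level
#' clustering tools that absorb contained fragments).
#'
#' @param records an `mmp_records` data frame.
#' @param mode `"exact"` (default) or `"substring"`.
#' @return list with `records` and `trace`; removal reasons name the
#'   retained representative.
#' @export
deduplicate <- function(records, mode = c("exact", "substring")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("empty record set")
  res <- toupper(records$residues)
  grp <- match(res, res)
  keep <- logical(nrow(records))
  rep_of <- character(nrow(records))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    winner <- idx[order(records$accession[idx])][1L]
    keep[winner] <- TRUE
    rep_of[idx] <- records$accession[winner]
  }
  reason <- sprintf("duplicate of %s", rep_of)
  if (mode == "substring") {
    kept_idx <- which(keep)
    kept_res <- res[kept_idx]
    ord <- order(-nchar(kept_res), records$accession[kept_idx])
    for (i in ord) {
      if (!keep[kept_idx[i]]) next
      for (j in ord) {
        if (i == j || !keep[kept_idx[j]]) next
        if (nchar(kept_res[j]) < nchar(kept_res[i]) &&
            grepl(kept_res[j], kept_res[i], fixed = TRUE)) {
          keep[kept_idx[j]] <- FALSE
          reason[kept_idx[j]] <- sprintf("substring of %s",
                                         records$accession[kept_idx[i]])
        }
      }
    }
  }
  removed <- data.frame(seq_id = records$seq_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  list(records = .new_records(records[keep, , drop = FALSE]),
       trace = .stage_trace("duplicate removal", nrow(records),
                            records[keep, , drop = FALSE], removed))
}

#' Run the three-step curation cascade
#'
#' Applies, in this fixed order and each exactly once: the length-window
#' filter, the conserved-domain architecture filter and duplicate removal.
#' The four emitted traces (input + three stages) carry the per-stage
#' statistics of the stage-statistics report.
#'
#' @param records an `mmp_records` data frame.
#' @param hits a domain-hit data frame.
#' @param window,min_families,dedup_mode stage parameters, see the stage
#'   functions.
#' @return an `mmp_curation` list with `records` (final survivors) and
#'   `traces` (named list `input`, `length`, `domains`, `dedup`).
#' @export
run_curation <- function(records, hits, window = 0.5, min_families = 3L,
                         dedup_mode = c("exact", "substring")) {
  dedup_mode <- match.arg(dedup_mode)
  input_trace <- .stage_trace("input", nrow(records), records,
                              data.frame(seq_id = character(0),
                                         reason = character(0)))
  s1 <- filter_by_length(records, window)
  s2 <- filter_by_domains(s1$records, hits, min_families)
  s3 <- deduplicate(s2$records, dedup_mode)
  counts <- c(input_trace$n_out, s1$trace$n_out, s2$trace$n_out,
              s3$trace$n_out)
  stopifnot(!is.unsorted(rev(counts)))
  out <- list(records = s3$records,
              traces = list(input = input_trace, length = s1$trace,
                            domains = s2$trace, dedup = s3$trace))
  class(out) <- "mmp_curation"
  out
}

#' @export
print.mmp_curation <- function(x, ...) {
  cat("<mmp_curation>\n")
  for (tr in x$traces)
    cat(sprintf("  %-18s n=%d\n", tr$stage, tr$n_out))
  invisible(x)
}

#' Stage-statistics table of a curation run
#'
#' One row per stage (input + three filters) in the shape of the
#' stage-statistics report: `stage, n, min, max, mean, sd` at full
#' precision (display rounding happens in [write_report()]).
#'
#' @param curation an `mmp_curation` object or a list of stage traces.
#' @return data frame, one row per stage.
#' @export
stage_stats_table <- function(curation) {
  traces <- if (inherits(curation, "mmp_curation")) curation$traces
            else curation
  rows <- lapply(traces, function(tr) {
    s <- tr$stats
    data.frame(stage = tr$stage, n = tr$n_out,
               min = if (is.null(s)) NA_integer_ else s$min_len,
               max = if (is.null(s)) NA_integer_ else s$max_len,
               mean = if (is.null(s)) NA_real_ else s$mean_len,
               sd = if (is.null(s)) NA_real_ else s$sd_len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
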