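rec_of_lengths <- function(lens) {
  make_records(vapply(lens, function(k) strrep("M", k), character(1)))
}

test_that("length statistics match closed forms", {
  s <- compute_length_stats(rec_of_lengths(c(100, 200, 300)))
  expect_equal(s$n, 3L)
  expect_equal(s$min_len, 100L)
  expect_equal(s$max_len, 300L)
  expect_equal(s$mean_len, 200)
  expect_equal(s$sd_len, 100) # sample sd of {100,200,300}
  s1 <- compute_length_stats(rec_of_lengths(42))
  expect_equal(c(s1$min_len, s1$max_len, s1$mean_len, s1$sd_len),
               c(42, 42, 42, 0))
  expect_error(compute_length_stats(rec_of_lengths(42)[0, ]), "empty")
})

test_that("length window keeps exactly the records inside mean +/- 50%", {
  r <- rec_of_lengths(c(400, 500, 600, 50)) # mean 387.5 -> [193.75, 581.25]
  out <- filter_by_length(r)
  expect_equal(out$records$length, c(400L, 500L))
  expect_equal(out$trace$removed$seq_id, r$seq_id[c(3, 4)])
  # uniform lengths survive any window
  r2 <- rec_of_lengths(rep(777, 5))
  expect_equal(nrow(filter_by_length(r2, 0.01)$records), 5L)
  # a window that empties the set is an error, not silent vacuity
  r3 <- rec_of_lengths(c(10, 100, 100, 100, 1000)) # mean 262 -> [131, 393]
  expect_error(filter_by_length(r3), "removed every record")
  expect_error(filter_by_length(r, window = 0), "window")
})

test_that("domain filter counts distinct families, never raw hits", {
  r <- make_records(rep(strrep("M", 100), 3), accession = c("A1", "A2", "A3"))
  h <- rbind(
    make_hits("A1", c("CDD:396175", "CDD:395334", "CDD:395000")),
    make_hits("A2", c("CDD:396175", "CDD:395334")),            # matrilysin-like
    make_hits("A3", rep("CDD:395334", 5)))                     # 5 hits, 1 family
  out <- filter_by_domains(r, h)
  expect_equal(out$records$seq_id, "A1")
  expect_equal(sort(out$trace$removed$seq_id), c("A2", "A3"))
  expect_match(out$trace$removed$reason[out$trace$removed$seq_id == "A3"],
               "1 distinct")
  # family=other hits never count
  h2 <- make_hits("A2", c("CDD:396175", "CDD:395334", "CDD:999999"))
  expect_equal(nrow(filter_by_domains(r[2, ], h2)$records), 0L)
  expect_error(filter_by_domains(r, h, min_families = 5), "unsatisfiable")
  expect_message(filter_by_domains(r[1, ], h), "unknown sequences")
})

test_that("deduplication keeps the smallest accession and names it in reasons", {
  r <- make_records(c("MKLV", "MKLV"), accession = c("B2", "A1"))
  out <- deduplicate(r)
  expect_equal(out$records$accession, "A1")
  expect_equal(out$trace$removed$seq_id, "B2")
  expect_equal(out$trace$removed$reason, "duplicate of A1")
  # distinct records pass through untouched
  r2 <- make_records(c("MKL", "MKV", "MKI"))
  expect_equal(deduplicate(r2)$records$seq_id, r2$seq_id)
  # substring mode additionally absorbs contained fragments
  r3 <- make_records(c("MKL", "MKLA", "MKL"), accession = c("C1", "C2", "C3"))
  out3 <- deduplicate(r3, mode = "substring")
  expect_equal(out3$records$residues, "MKLA")
})

test_that("exact dedup output never contains two equal residue strings", {
  set.seed(5)
  aa <- c("M", "K", "L", "V")
  pool <- replicate(400, paste(sample(aa, 4, replace = TRUE), collapse = ""))
  r <- make_records(pool)
  out <- deduplicate(r)$records$residues
  # brute-force all-pairs check
  clashes <- 0L
  for (i in seq_along(out))
    for (j in seq_len(i - 1L))
      if (out[i] == out[j]) clashes <- clashes + 1L
  expect_identical(clashes, 0L)
  expect_lt(length(out), length(pool)) # the 4-mer pool must collide
})

test_that("cascade runs length -> domains -> dedup with conserved counts", {
  set.seed(9)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- vapply(1:30, function(i)
    paste(sample(aa, 100, replace = TRUE), collapse = ""), character(1))
  # a fragment (too short), a duplicate pair, a two-family architecture
  resid <- c(base, substr(base[1], 1, 12), base[2])
  r <- make_records(resid, accession = sprintf("S%03d", seq_along(resid)))
  h <- do.call(rbind, lapply(r$seq_id, function(s)
    make_hits(s, c("CDD:396175", "CDD:395334", "CDD:395000"))))
  h <- h[!(h$seq_id == "S003" & h$cdd_id == "CDD:395000"), ] # S003 2 families
  cur <- run_curation(r, h)
  counts <- vapply(cur$traces, `[[`, integer(1), "n_out")
  expect_equal(unname(counts), c(32L, 31L, 30L, 29L))
  # conservation at every stage
  for (tr in cur$traces[-1])
    expect_equal(tr$n_out + nrow(tr$removed), tr$n_in)
  expect_equal(unname(counts),
               unname(naive_stage_counts(r, h)))
  # a clean set passes through all three stages unchanged
  clean <- make_records(base, accession = sprintf("C%03d", seq_along(base)))
  hc <- do.call(rbind, lapply(clean$seq_id, function(s)
    make_hits(s, c("CDD:396175", "CDD:395334", "CDD:395000"))))
  cur2 <- run_curation(clean, hc)
  expect_identical(cur2$records$seq_id, clean$seq_id)
})

test_that("stage outcomes are invariant under input permutation", {
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  resid <- vapply(1:20, function(i)
    paste(sample(aa, sample(c(50, 100, 110), 1), replace = TRUE),
          collapse = ""), character(1))
  resid[5] <- resid[4] # duplicate pair
  r <- make_records(resid, accession = sprintf("P%03d", seq_along(resid)))
  h <- do.call(rbind, lapply(r$seq_id, function(s)
    make_hits(s, c("CDD:396175", "CDD:395334", "CDD:395000"))))
  cur_a <- run_curation(r, h)
  perm <- sample(nrow(r))
  r_b <- r[perm, , drop = FALSE]
  class(r_b) <- class(r)
  cur_b <- run_curation(r_b, h)
  expect_setequal(cur_a$records$seq_id, cur_b$records$seq_id)
  # survivor order preserves the (permuted) input order
  expect_identical(cur_b$records$seq_id,
                   r_b$seq_id[r_b$seq_id %in% cur_b$records$seq_id])
})

test_that("stage statistics table has the four-row report shape", {
  set.seed(2)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  r <- make_records(vapply(1:10, function(i)
    paste(sample(aa, 80, replace = TRUE), collapse = ""), character(1)))
  h <- do.call(rbind, lapply(r$seq_id, function(s)
    make_hits(s, c("CDD:396175", "CDD:395334", "CDD:395000"))))
  tab <- stage_stats_table(run_curation(r, h))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$stage[1], "input")
  expect_true(all(diff(tab$n) <= 0))
})
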