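test_that("the bundled Archaeal outgroup header parses to its UniProt fields", {
  og <- outgroup_record()
  expect_equal(og$db_tag, "tr")
  expect_equal(og$accession, "A0A087RZB5")
  expect_equal(og$entry_name, "A0A087RZB5_9ARCH")
  expect_equal(og$organism, "Marine Group I thaumarchaeote SCGC AAA799-P11")
  expect_equal(og$taxid, 1502295L)
  expect_equal(og$gene, "AAA799P11_00940")
  expect_equal(og$length, 345L)
  expect_match(og$description, "interstitial collagenase")
})

test_that("uniprot headers parse with both spaced and unspaced field forms", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">sp|P03956|MMP1_HUMAN Interstitial collagenase OS=Homo sapiens OX=9606 GN=MMP1 PE=1 SV=3",
    "MKWLPA",
    ">tr|Q99999|Q99999_BOVIN Matrix metalloproteinase OS = Bos taurus OX = 9913",
    "MKWLPG"), f)
  r <- read_fasta(f, dialect = "uniprot")
  expect_equal(r$seq_id, c("P03956", "Q99999"))
  expect_equal(r$db_tag, c("sp", "tr"))
  expect_equal(r$organism, c("Homo sapiens", "Bos taurus"))
  expect_equal(r$taxid, c(9606L, 9913L))
  expect_equal(r$gene, c("MMP1", NA))
  expect_equal(r$description,
               c("Interstitial collagenase", "Matrix metalloproteinase"))
})

test_that("plain dialect keeps the first token and leaves metadata absent", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1", "MKL"), f)
  r <- read_fasta(f, dialect = "plain")
  expect_equal(r$seq_id, "seq1")
  expect_true(is.na(r$organism) && is.na(r$taxid) && is.na(r$gene))
})

test_that("fasta reader enforces its error contracts", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "no FASTA records")
  writeLines(c(">a", "MKL", ">a", "MKV"), f)
  expect_error(read_fasta(f, "plain"), "duplicate seq_id: a")
  writeLines(c(">b", "MK1L"), f)
  expect_error(read_fasta(f, "plain"), "illegal residue character '1' at position 3")
})

test_that("fasta round trip is lossless for ids and residues", {
  set.seed(42)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  recs <- make_records(
    vapply(1:25, function(i)
      paste(sample(aa, sample(30:200, 1), replace = TRUE), collapse = ""),
      character(1)),
    description = "Matrix metalloproteinase-9 (MMP-9)",
    organism = "Homo sapiens")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f, dialect = "uniprot")
  expect_identical(back$seq_id, recs$seq_id)
  expect_identical(back$residues, recs$residues)
  expect_identical(back$description, recs$description)
})

test_that("domain-hit parsing assigns families and tolerates extra columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "s1\tCDD:395334\t98.2\t160\t120\t280\t1e-60\t210\textra\tcols",
    "s1\tCDD:999999\t90.0\t50\t10\t60\t1e-10\t80",
    "s2\tCDD:396175\t95.0\t80\t30\t110\t1e-40\t150"), f)
  h <- read_domain_hits(f)
  expect_equal(h$family, c("matrixin", "other", "pg_binding"))
  expect_equal(h$qstart, c(120L, 10L, 30L))
  writeLines("s1\tCDD:395334\t98.2\t160\t280\t120\t1e-60\t210", f)
  expect_error(read_domain_hits(f), "qend < qstart.*line 1")
  writeLines(character(0), f)
  expect_warning(h0 <- read_domain_hits(f), "empty")
  expect_equal(nrow(h0), 0L)
})

test_that("the domain family map is disjoint and complete", {
  map <- domain_family_map()
  ids <- unlist(map, use.names = FALSE)
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(unname(lengths(map)[c("matrixin", "hemopexin", "pg_binding",
                                     "fibronectin")]), c(9L, 2L, 1L, 1L))
  expect_equal(cdd_family(c("CDD:395334", "CDD:128373", "CDD:1")),
               c("matrixin", "fibronectin", "other"))
})

test_that("newick io round-trips topology and branch lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:2,C:3):4);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(patristic_distance(tr, "A", "B"), 7)
  # round trip
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_equal(rf_distance(tr, tr2), 0L)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))
  # defaults and errors
  writeLines("(A,B);", f)
  expect_warning(t0 <- read_newick(f), "defaulting to 0")
  expect_equal(t0$edge.length, c(0, 0))
  writeLines("(A:1,(B:2,C:3):4));", f)
  expect_error(read_newick(f), "unbalanced parentheses at character offset 18")
  writeLines("(A:1,(A:2,C:3):4);", f)
  expect_error(read_newick(f), "duplicate leaf names")
})

test_that("newick round trips preserve random trees to 10 significant digits", {
  set.seed(11)
  for (i in 1:10) {
    tr <- random_bl_tree(sample(4:20, 1))
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, f)
    back <- read_newick(f)
    expect_equal(rf_distance(tr, back), 0L)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("stage_stats report rows follow the fixed layout and rounding", {
  recs <- make_records(c(strrep("M", 100), strrep("K", 200), strrep("L", 300)))
  tab <- data.frame(stage = "input", n = 3, min = 100, max = 300,
                    mean = 200, sd = 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, f, "stage_stats")
  lines <- readLines(f)
  expect_equal(lines[1], "stage\tn\tmin\tmax\tmean\tsd")
  expect_equal(lines[2], "input\t3\t100\t300\t200\t100")
  # half-away-from-zero display rounding
  tab$mean <- 200.5
  write_report(tab, f, "stage_stats")
  expect_match(readLines(f)[2], "\t201\t")
  expect_error(write_report(tab, f, "nope"), "unknown report kind")
})

test_that("annotation report uses the dash convention for zero changes", {
  tab <- data.frame(class = c("MMP-2", "Total"), group = c("gelatinase", ""),
                    n = c(5, 5), class_annotation = c(0, 0),
                    reannotation = c(0, 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, f, "annotation")
  lines <- readLines(f)
  expect_equal(lines[2], "MMP-2\tgelatinase\t5\t-\t-")
})

test_that("proximity report records degenerate classes explicitly", {
  tab <- data.frame(class = "MMP-9", organism = "(no candidate organisms)",
                    distance = NA_real_, rank = NA_integer_)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, f, "proximity")
  expect_match(readLines(f)[2], "no candidate organisms")
})
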