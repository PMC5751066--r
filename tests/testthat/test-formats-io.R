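# Readers/writers: direct mappings, error contracts, and lossless
# round-trips.

test_that("FASTA parsing concatenates wrapped lines and validates input", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 desc", "ACGT", "ACGT"), path)
  x <- read_fasta(path)
  expect_equal(x$id, "s1")
  expect_equal(x$description, "desc")
  expect_equal(nchar(x$sequence), 8L)

  writeLines(c(">s1", ">s2", "AC"), path)
  expect_error(read_fasta(path), "empty sequence")

  writeLines(c(">s1", "ACXT"), path)
  expect_error(read_fasta(path), "outside alphabet.*line 2")

  writeLines(character(0), path)
  expect_error(read_fasta(path), "empty")

  writeLines(c("ACGT", ">s1"), path)
  expect_error(read_fasta(path), "begin with '>'")
})

test_that("FASTA write/read round-trips mixed-case records exactly", {
  x <- data.frame(id = c("a", "b", "c"), description = c("one", "", "three"),
                  sequence = c("acgtACGTnN", strrep("ACGTG", 40), "t"),
                  stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(x, path, width = 60L)
  expect_identical(read_fasta(path), x)
  # wrapping at 60 columns
  expect_true(all(nchar(readLines(path)) <= 61L))
})

test_that("tabular alignment parsing maps fields positionally and infers strand", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "m1\ts1\t98.5\t200\t3\t0\t1\t200\t1001\t1200\t1e-50\t380",
               "m1\ts1\t100.0\t80\t0\t0\t1\t80\t500\t421\t0.0\t160"), path)
  h <- read_alignment_tabular(path)
  expect_equal(nrow(h), 2L)
  expect_equal(h$percent_identity, c(98.5, 100))
  expect_equal(hit_strand(h), c("+", "-"))
  expect_equal(h$bit_score, c(380, 160))

  writeLines("m1\ts1\t98.5\t200\t3\t0\t1\t200\t1001\t1200\t1e-50", path)
  expect_error(read_alignment_tabular(path), "12 tab-separated.*line 1")
  writeLines("m1\ts1\tx\t200\t3\t0\t1\t200\t1001\t1200\t1e-50\t380", path)
  expect_error(read_alignment_tabular(path), "non-numeric")
})

test_that("RH map parsing enforces uniqueness and group domain", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\trh_group\tposition_index",
               "m1\tSQ1\t0", "m2\tSQ1\t1", "m3\tSQ2\t0"), path)
  x <- read_rh_map(path)
  expect_equal(nrow(x), 3L)
  expect_equal(length(unique(x$rh_group)), 2L)

  writeLines(c("marker_id\trh_group\tposition_index",
               "m1\tSQ1\t0", "m1\tSQ2\t1"), path)
  expect_error(read_rh_map(path), "duplicate marker")

  writeLines(c("marker_id\trh_group\tposition_index", "m1\tSQ99\t0"), path)
  expect_error(read_rh_map(path, valid_groups = paste0("SQ", 1:24)),
               "unknown group")

  writeLines("marker_id\trh_group\tposition_index", path)
  expect_equal(nrow(read_rh_map(path)), 0L)
})

test_that("DE table parsing keeps missing padj as NA and bounds p in [0,1]", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\tlog2FC\tpvalue\tpadj",
               "t1\t2.5\t1e-6\t1e-4", "t2\t-1.0\t0.2\tNA"), path)
  x <- read_de_table(path)
  expect_equal(x$p_adjusted, c(1e-4, NA))
  writeLines(c("feature\tlog2FC\tpvalue\tpadj", "t1\t2.5\t1e-6\t1.5"), path)
  expect_error(read_de_table(path), "outside \\[0,1\\]")
})

test_that("GO annotation parsing validates ids and de-duplicates terms", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t1\tGO:0000001;GO:0000002", "t2\tGO:0000001;GO:0000001"), path)
  x <- read_go_annotations(path)
  expect_equal(sum(x$feature_id == "t1"), 2L)
  expect_equal(sum(x$feature_id == "t2"), 1L)
  writeLines("t1\tGO:12", path)
  expect_error(read_go_annotations(path), "GO:12")
})

test_that("all tabular writers round-trip randomly generated records exactly", {
  withr::local_seed(42)
  path <- withr::local_tempfile()

  fa <- random_fasta(200)
  write_fasta(fa, path)
  expect_identical(read_fasta(path), fa)

  n <- 500
  hits <- data.frame(
    query_id = sprintf("q%03d", sample.int(200, n, replace = TRUE)),
    subject_id = sprintf("s%03d", sample.int(50, n, replace = TRUE)),
    percent_identity = round(stats::runif(n, 50, 100), 2),
    alignment_length = sample.int(5000, n),
    mismatches = sample.int(50, n, replace = TRUE),
    gap_opens = sample.int(5, n, replace = TRUE),
    q_start = sample.int(100, n, replace = TRUE),
    stringsAsFactors = FALSE)
  hits$q_end <- hits$q_start + hits$alignment_length
  hits$s_start <- sample.int(100000, n)
  hits$s_end <- ifelse(stats::runif(n) < 0.5,
                       hits$s_start + hits$alignment_length,
                       pmax(1L, hits$s_start - hits$alignment_length))
  hits$e_value <- 10^stats::runif(n, -180, 0)
  hits$bit_score <- round(stats::runif(n, 30, 2000), 1)
  write_alignment_tabular(hits, path)
  back <- read_alignment_tabular(path)
  rownames(hits) <- rownames(back) <- NULL
  expect_identical(back, hits)

  rh <- data.frame(marker_id = sprintf("m%04d", 1:300),
                   rh_group = sample(paste0("SQ", 1:24), 300, replace = TRUE),
                   position_index = sample(0:99, 300, replace = TRUE),
                   stringsAsFactors = FALSE)
  write_rh_map(rh, path)
  expect_identical(read_rh_map(path), rh)

  de <- data.frame(feature_id = sprintf("t%04d", 1:300),
                   log2_fold_change = round(stats::rnorm(300, 0, 3), 6),
                   p_value = stats::runif(300),
                   p_adjusted = ifelse(stats::runif(300) < 0.1, NA,
                                       stats::runif(300)),
                   stringsAsFactors = FALSE)
  write_de_table(de, path)
  expect_identical(read_de_table(path), de)

  ann <- unique(data.frame(
    feature_id = sprintf("t%03d", sort(sample.int(100, 400, replace = TRUE))),
    term = sprintf("GO:%07d", sample.int(50, 400, replace = TRUE)),
    stringsAsFactors = FALSE))
  write_go_annotations(ann, path)
  back <- read_go_annotations(path)
  key <- function(x) x[order(x$feature_id, x$term), ]
  expect_equal(key(back), key(ann), ignore_attr = TRUE)
})

test_that("parsers account for every input line (none silently dropped)", {
  path <- withr::local_tempfile()
  lines <- c("# a comment",
             "m1\ts1\t98.5\t200\t3\t0\t1\t200\t1001\t1200\t1e-50\t380",
             "# another",
             "m2\ts2\t97.0\t100\t3\t0\t1\t100\t11\t110\t1e-20\t180")
  writeLines(lines, path)
  h <- read_alignment_tabular(path)
  n_comments <- sum(startsWith(lines, "#"))
  expect_equal(nrow(h) + n_comments, length(lines))
})
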