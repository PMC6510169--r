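test_that("read_fasta parses well-formed records and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 desc here", "ACDE", ">p2", "gg", "HH"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$residues, c("ACDE", "GGHH"))  # multi-line, upper-cased

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)
})

test_that("read_fasta reports a sequence line before any header by line number", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACDE", ">p1", "GG"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("reader is permissive about duplicate ids; the dataset is strict", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDE", ">p1", "GGGG"), f)
  recs <- read_fasta(f)
  expect_equal(nrow(recs), 2L)
  expect_error(
    labeled_dataset(recs$id, recs$residues, c("ion", "ion"), scheme = "ion"),
    "duplicate")
})

test_that("fasta round trip is identity on (id, residues)", {
  set.seed(5)
  seqs <- data.frame(
    id = sprintf("seq%02d", 1:8),
    residues = vapply(sample(10:200, 8), random_seq, ""),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(back, seqs)
  # cross-check the reader against an independent FASTA implementation
  ref <- Biostrings::readAAStringSet(f)
  expect_equal(names(ref), seqs$id)
  expect_equal(unname(as.character(ref)), seqs$residues)
})

test_that("validation enforces the 20-letter alphabet and minimum length", {
  expect_true(validate_sequence("ACDEFGHIKLMNPQRSTVWY")$accept)
  v <- validate_sequence("ACXDE")
  expect_false(v$accept)
  expect_match(v$reason, "ambiguous residue X")
  expect_equal(validate_sequence("")$reason, "empty sequence")
  for (bad in c("B", "Z", "J", "O", "U")) {
    expect_false(validate_sequence(paste0("ACDEFGHIK", bad))$accept)
  }
  expect_false(validate_sequence("ACDEFGHIK")$accept)      # length 9 < 10
  expect_true(validate_sequence("ACDEFGHIKL")$accept)      # length 10
  expect_true(validate_sequence("ACDE", min_length = 4)$accept)
})

test_that("load_labeled_dataset keeps only validated sequences and logs counts", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  good <- replicate(5, random_seq(30))
  good_x <- good
  good_x[3] <- paste0(substr(good_x[3], 1, 10), "X", substr(good_x[3], 12, 30))
  write_fasta(data.frame(id = paste0("a", 1:5), residues = good_x), f1)
  write_fasta(data.frame(id = paste0("b", 1:3),
                         residues = replicate(3, random_seq(40))), f2)
  msgs <- capture_messages(
    d <- load_labeled_dataset(c(ion = f1, `non-ion` = f2), scheme = "ion"))
  expect_s3_class(d, "icp_dataset")
  expect_equal(sum(d$label == "ion"), 4L)       # the X-bearing record dropped
  expect_equal(sum(d$label == "non-ion"), 3L)
  expect_true(any(grepl("kept 4, dropped 1", msgs)))
  expect_true(all(vapply(d$residues,
                         function(s) validate_sequence(s)$accept, logical(1))))
})

test_that("labels outside the declared scheme are configuration errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(id = "p1", residues = random_seq(30)), f)
  expect_error(load_labeled_dataset(c(mystery = f), scheme = "ion"),
               "not in scheme")
  map <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel", "p1\tmystery"), map)
  expect_error(load_labeled_dataset(f, label_map = map, scheme = "ion"),
               "not in scheme")
})

test_that("a label map must cover every record", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(id = c("p1", "p2"),
                         residues = replicate(2, random_seq(30))), f)
  map <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel", "p1\tion"), map)
  expect_error(load_labeled_dataset(f, label_map = map, scheme = "ion"),
               "no label")
})
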