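adapter3 <- "TCGTATGCCGTCTTCTGCTTG"

test_that("3' adapter trimming removes the best prefix occurrence", {
  reads <- make_reads(c(
    paste0("ACGTACGT", substr(adapter3, 1, 10)),  # exact adapter suffix
    adapter3,                                      # read is pure adapter
    "ACGTACGTACGTACGTACGT"))                       # no adapter at all
  out <- trim_adapters(reads, adapter3)
  expect_equal(out$seq, c("ACGTACGT", ""))
  expect_equal(out$id, c("r1", "r2")) # adapter-free read dropped, order kept

  # one mismatch inside a 10-nt overlap at rate 0.1 is still trimmed
  ad10 <- strsplit(substr(adapter3, 1, 10), "")[[1]]
  ad10[4] <- setdiff(c("A", "C", "G", "T"), ad10[4])[1]
  read <- paste0("ACGTACGT", paste(ad10, collapse = ""))
  out <- trim_adapters(make_reads(read), adapter3, max_mismatch_rate = 0.1)
  expect_equal(out$seq, "ACGTACGT")
  # ...but not at rate 0
  expect_equal(nrow(trim_adapters(make_reads(read), adapter3,
                                  max_mismatch_rate = 0)), 0)
  expect_error(trim_adapters(make_reads("ACGT"), ""), "adapter3")
})

test_that("5' adapter residue is removed from the insert front", {
  a5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  insert <- "TGACAGAAGAGAGGGAGCAC"
  read <- paste0(substr(a5, nchar(a5) - 7, nchar(a5)), insert,
                 substr(adapter3, 1, 8))
  out <- trim_adapters(make_reads(read), adapter3, adapter5 = a5)
  expect_equal(out$seq, insert)
})

test_that("adapter trimming is idempotent on adapter-free trimmed reads", {
  set.seed(1)
  seqs <- vapply(rep(22, 25), rand_seq, character(1))
  reads <- make_reads(paste0(seqs, adapter3))
  once <- trim_adapters(reads, adapter3)
  expect_equal(once$seq, seqs)
  # a second pass must not find adapter again (unless present by chance,
  # excluded here by construction)
  keep <- !vapply(once$seq, function(s)
    grepl(substr(adapter3, 1, 6), s, fixed = TRUE), logical(1))
  twice <- trim_adapters(once[keep, ], adapter3)
  expect_equal(nrow(twice), 0) # trimmed reads have no 3' adapter left
})

test_that("quality filter removes low-quality and N-containing reads", {
  reads <- make_reads(c("ACGTACGTACGTACGTAC", "ACGNACGTACGTACGTAC",
                        "ACGTACGTACGTACGTAC"),
                      qual = c(strrep("I", 18), strrep("I", 18),
                               strrep("#", 18)))
  out <- quality_filter(reads, min_mean_quality = 20, max_n_fraction = 0)
  expect_equal(out$id, "r1")
  # FASTA-style input (no qualities): N-content filtering only
  out2 <- quality_filter(make_reads(c("ACGT", "ACNT")))
  expect_equal(out2$seq, "ACGT")
  # all perfect reads pass untouched
  perfect <- make_reads(rep("ACGTACGT", 5), qual = rep(strrep("I", 8), 5))
  expect_equal(quality_filter(perfect), perfect)
})

test_that("length filter enforces inclusive bounds and is idempotent", {
  reads <- make_reads(c(rand_seq(17), rand_seq(18), rand_seq(24),
                        rand_seq(30), rand_seq(31)))
  out <- length_filter(reads, 18, 30)
  expect_equal(nchar(out$seq), c(18, 24, 30))
  expect_equal(length_filter(out, 18, 30), out)
  # 15 nt retained under the wider gel-purification bounds
  expect_equal(nrow(length_filter(make_reads(rand_seq(15)), 15, 30)), 1)
  expect_error(length_filter(reads, 30, 18), "min_len")
})

test_that("poly-A artifacts are dropped", {
  tags <- make_reads(c("AAAAAAAAAAAAAAAAAAAAA",      # >= 80% A
                       "ACGTACGTACGTAAAAAAAA",        # terminal 8-A run
                       "ACGTACGTACGTACGTACGT"))
  out <- filter_polya(tags)
  expect_equal(out$seq, "ACGTACGTACGTACGTACGT")
})

test_that("read collapsing conserves counts and orders deterministically", {
  reads <- make_reads(c("ACGT", "ACGT", "ACGA"))
  tags <- collapse_reads(reads)
  expect_equal(tags$sequence, c("ACGT", "ACGA"))
  expect_equal(tags$read_count, c(2L, 1L))
  # n distinct reads -> n singleton tags
  set.seed(2)
  distinct <- make_reads(vapply(rep(20, 10), rand_seq, character(1)))
  expect_equal(collapse_reads(distinct)$read_count, rep(1L, 10))
  # conservation for arbitrary multiplicity profiles
  set.seed(3)
  pool <- vapply(rep(21, 15), rand_seq, character(1))
  draw <- sample(pool, 500, replace = TRUE)
  tags <- collapse_reads(make_reads(draw))
  expect_equal(sum(tags$read_count), 500L)
  expect_equal(sort(tags$read_count, decreasing = TRUE), tags$read_count)
  truth <- table(draw)
  expect_equal(tags$read_count, as.integer(truth[tags$sequence]))
})

test_that("length distribution is read-count weighted and conserving", {
  tags <- data.frame(sequence = c(rand_seq(21), rand_seq(24), rand_seq(24)),
                     length = c(21L, 24L, 24L),
                     read_count = c(5L, 10L, 2L), stringsAsFactors = FALSE)
  h <- length_distribution(tags)
  expect_equal(h$redundant_count[h$length == 21], 5L)
  expect_equal(sum(h$redundant_count), 17L)
  expect_equal(sum(h$redundant_fraction), 1, tolerance = 1e-9)
  one <- length_distribution(data.frame(sequence = rand_seq(21),
                                        length = 21L, read_count = 5L))
  expect_equal(one$redundant_fraction[one$length == 21], 1)
  expect_error(length_distribution(tags[0, ]), "empty")
})

test_that("collapsed FASTA round-trips through the tag dialect", {
  tags <- collapse_reads(make_reads(c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                                      "TTTTACGTACGTACGTAC")))
  f <- tempfile(fileext = ".fa")
  write_collapsed_fasta(tags, f)
  back <- read_collapsed_fasta(f)
  expect_equal(back, tags)
})

test_that("FASTQ reading keeps ids, sequences and qualities aligned", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "TTGGCCAA", "+", "IIII#III"), f)
  r <- read_reads(f)
  expect_equal(r$seq, c("ACGTACGT", "TTGGCCAA"))
  expect_equal(r$qual, c("IIIIIIII", "IIII#III"))
})
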