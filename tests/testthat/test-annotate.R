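test_that("genome mapping records every exact occurrence on both strands", {
  set.seed(10)
  chrom <- rand_seq(5000)
  tag1 <- substr(chrom, 101, 121)                 # forward, start 101
  tag2 <- revcomp(substr(chrom, 301, 322))        # reverse strand
  tag3 <- rand_seq(21)                            # absent (w.h.p.)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  tags <- data.frame(sequence = c(tag1, tag2, tag3),
                     length = nchar(c(tag1, tag2, tag3)),
                     read_count = c(3L, 2L, 1L), stringsAsFactors = FALSE)
  mapped <- map_to_genome(tags, genome)
  expect_equal(mapped$loci[[1]]$start[1], 101)
  expect_equal(mapped$loci[[1]]$strand[1], "+")
  expect_equal(mapped$loci[[2]]$strand[1], "-")
  expect_equal(mapped$loci[[2]]$start[1], 301)
  expect_error(map_to_genome(tags, Biostrings::DNAStringSet()), "empty")
})

test_that("genome mapping agrees with a naive both-strand scan", {
  set.seed(11)
  chrom <- rand_seq(20000)
  # plant one tag at three loci (mixed strands)
  planted <- rand_seq(22)
  ch <- strsplit(chrom, "")[[1]]
  ch[1001:1022] <- strsplit(planted, "")[[1]]
  ch[5001:5022] <- strsplit(planted, "")[[1]]
  ch[9001:9022] <- strsplit(revcomp(planted), "")[[1]]
  chrom <- paste(ch, collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  seqs <- c(planted, substr(chrom, 2501, 2520),
            vapply(rep(20, 8), rand_seq, character(1)))
  tags <- data.frame(sequence = seqs, length = nchar(seqs),
                     read_count = rep(1L, length(seqs)),
                     stringsAsFactors = FALSE)
  mapped <- map_to_genome(tags, genome)
  expect_equal(mapped$n_loci[1], 3L)
  for (i in seq_len(nrow(tags))) {
    oracle <- oracle_scan_genome(tags$sequence[i], chrom)
    got <- mapped$loci[[i]]
    row.names(oracle) <- row.names(got) <- NULL
    expect_equal(got, oracle, info = paste("tag", i))
  }
})

make_toy_annotation <- function() {
  set.seed(12)
  chrom <- rand_seq(4000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  tracks <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(101, 101, 501, 901, 1301),
                     end = c(300, 300, 700, 1100, 1500)),
    strand = c("+", "+", "+", "-", "+"),
    category = c("rRNA", "exon", "exon", "exon", "intron"))
  list(chrom = chrom, genome = genome, tracks = tracks)
}

test_that("category precedence and strandedness drive classification", {
  toy <- make_toy_annotation()
  seqs <- c(substr(toy$chrom, 150, 170),          # rRNA + exon -> rRNA
            substr(toy$chrom, 550, 570),          # exon, same strand
            revcomp(substr(toy$chrom, 600, 620)), # exon, opposite strand
            substr(toy$chrom, 950, 970),          # '-' exon, read on + strand
            substr(toy$chrom, 1350, 1370),        # intron sense
            substr(toy$chrom, 2001, 2021))        # no features -> unann
  tags <- data.frame(sequence = seqs, length = nchar(seqs),
                     read_count = rep(1L, 6), stringsAsFactors = FALSE)
  tags <- map_to_genome(tags, toy$genome)
  out <- classify_tags(tags, toy$tracks, sirna_rule = FALSE)
  expect_equal(out$category,
               c("rRNA", "exon_sense", "exon_antisense", "exon_antisense",
                 "intron_sense", "unann"))
  # sequence-based miRNA assignment outranks everything
  out2 <- classify_tags(tags, toy$tracks, known_mirna_hits = seqs[1],
                        sirna_rule = FALSE)
  expect_equal(out2$category[1], "miRNA")
  # unknown track category is a configuration error
  bad <- toy$tracks
  bad$category[1] <- "mystery"
  expect_error(classify_tags(tags, bad), "unknown track category")
})

test_that("siRNA rule requires an opposite-strand overlapping partner tag", {
  toy <- make_toy_annotation()
  fwd <- substr(toy$chrom, 2101, 2121)
  rev <- revcomp(substr(toy$chrom, 2110, 2130))
  lone <- substr(toy$chrom, 2501, 2521)
  tags <- data.frame(sequence = c(fwd, rev, lone), length = 21L,
                     read_count = 1L, stringsAsFactors = FALSE)
  tags <- map_to_genome(tags, toy$genome)
  out <- classify_tags(tags, toy$tracks, sirna_rule = TRUE)
  expect_equal(out$category, c("siRNA", "siRNA", "unann"))
  off <- classify_tags(tags, toy$tracks, sirna_rule = FALSE)
  expect_equal(off$category, c("unann", "unann", "unann"))
})

test_that("category summary partitions tags and closes its totals", {
  x <- data.frame(category = c("miRNA", "miRNA", "rRNA", "unann"),
                  read_count = c(10L, 5L, 3L, 2L))
  s <- summarize_categories(x)
  tot <- s[s$category == "total", ]
  expect_equal(tot$unique_count, 4L)
  expect_equal(tot$redundant_count, 20)
  expect_equal(s$unique_count[s$category == "miRNA"], 2L)
  expect_equal(s$redundant_percent[s$category == "miRNA"], 75)
  expect_equal(sum(s$unique_count[s$category != "total"]), tot$unique_count)
  # single-category input -> 100.00%
  one <- summarize_categories(data.frame(category = "tRNA", read_count = 7L))
  expect_equal(one$redundant_percent[one$category == "tRNA"], 100)
})
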