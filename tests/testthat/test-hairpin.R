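# A clean synthetic hairpin: 22-nt mature on the 5p arm, perfect star.
perfect_hairpin <- function(mature = "TGACAGAAGAGAGGGAGCACAT", ext = 10,
                            loop = "ACACACAC") {
  set.seed(99)
  e5 <- rand_seq(ext); e3 <- rand_seq(ext)
  list(seq = paste0(e5, mature, loop, revcomp(mature), e3),
       mature_start = ext + 1L,
       mature_end = ext + nchar(mature),
       star_start = ext + nchar(mature) + nchar(loop) + 1L)
}

test_that("window excision enumerates strand-aware flank combinations", {
  set.seed(40)
  chrom <- rand_seq(3000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  locus <- data.frame(chrom = "chr1", start = 1000L, end = 1021L,
                      strand = "+", stringsAsFactors = FALSE)
  w <- excise_precursor_windows(locus, genome, max_flank = 60, step = 20)
  expect_equal(nrow(w), (60 / 20 + 1)^2 - 1) # interior locus
  expect_true(any(w$start == 940 & w$end == 1081))
  i <- which(w$start == 940 & w$end == 1081)
  expect_equal(substr(w$seq[i], w$mature_start[i], w$mature_end[i]),
               substr(chrom, 1000, 1021))
  # minus strand: window sequence is reverse complemented
  locus$strand <- "-"
  wm <- excise_precursor_windows(locus, genome, max_flank = 40, step = 20)
  j <- which(wm$start == 980 & wm$end == 1041)
  expect_equal(substr(wm$seq[j], wm$mature_start[j], wm$mature_end[j]),
               revcomp(substr(chrom, 1000, 1021)))
  # clipping at the chromosome start
  edge <- data.frame(chrom = "chr1", start = 5L, end = 26L, strand = "+")
  we <- excise_precursor_windows(edge, genome, max_flank = 40, step = 20)
  expect_true(all(we$start >= 1))
  expect_error(excise_precursor_windows(
    data.frame(chrom = "chr1", start = 4000L, end = 4021L, strand = "+"),
    genome), "outside")
})

test_that("a planted hairpin is accepted and its star is recovered", {
  hp <- perfect_hairpin()
  f <- fold(hp$seq)
  L <- hp$mature_end - hp$mature_start + 1
  lib <- data.frame(
    sequence = substr(hp$seq, hp$star_start + 2, hp$star_start + L + 1),
    length = 22L, read_count = 9L, stringsAsFactors = FALSE)
  cand <- evaluate_candidate(f, hp$mature_start, hp$mature_end, lib)
  expect_true(cand$accepted)
  expect_equal(cand$arm, "5p")
  expect_equal(cand$star_reads, 9L)
  expect_equal(cand$star_seq, lib$sequence)
  # star evidence is recorded, not gated: absent star still accepts
  cand2 <- evaluate_candidate(f, hp$mature_start, hp$mature_end,
                              lib[0, , drop = FALSE])
  expect_true(cand2$accepted)
  expect_equal(cand2$star_reads, 0L)
})

test_that("candidates failing individual criteria are rejected", {
  hp <- perfect_hairpin()
  f <- fold(hp$seq)
  # MFE threshold
  strict <- hairpin_criteria(mfe_threshold = -500)
  expect_false(evaluate_candidate(f, hp$mature_start, hp$mature_end,
                                  criteria = strict)$accepted)
  # precursor length bounds
  short <- hairpin_criteria(min_len = 200)
  c2 <- evaluate_candidate(f, hp$mature_start, hp$mature_end,
                           criteria = short)
  expect_false(c2$accepted)
  expect_false(c2$criteria_flags[["length"]])
  # mature span inside the terminal loop fails the arm criterion
  loop_span <- evaluate_candidate(f, hp$mature_end + 2, hp$mature_end + 6)
  expect_false(loop_span$criteria_flags[["arm"]])
  expect_error(evaluate_candidate(f, 0, 10), "outside")
})

test_that("best-candidate selection is deterministic with documented ties", {
  hp <- perfect_hairpin()
  f <- fold(hp$seq)
  a <- evaluate_candidate(f, hp$mature_start, hp$mature_end)
  b <- a; b$mfe <- a$mfe + 5
  pick <- select_best_candidate(list(b, a), starts = c(1, 2))
  expect_equal(pick$mfe, a$mfe)
  expect_null(select_best_candidate(list()))
  rej <- a; rej$accepted <- FALSE
  expect_null(select_best_candidate(list(rej)))
  expect_equal(select_best_candidate(list(b, a), starts = c(1, 2))$mfe,
               select_best_candidate(list(b, a), starts = c(1, 2))$mfe)
})

test_that("star geometry round-trips within the overhang arithmetic", {
  hp <- perfect_hairpin()
  f <- fold(hp$seq)
  star <- star_sequence(f, hp$mature_start, hp$mature_end)
  L <- hp$mature_end - hp$mature_start + 1
  expect_equal(star$start, hp$star_start + 2)
  expect_equal(star$end, hp$star_start + L + 1)
  # star of the star lands back on the mature, shifted by the overhangs
  back <- star_sequence(f, star$start, star$end)
  expect_lte(abs(back$start - hp$mature_start), 2)
  expect_lte(abs(back$end - hp$mature_end), 2)
})

test_that("5' nucleotide composition tallies the mature starts", {
  comp <- five_prime_composition(c("TACG", "TGGA", "ACGT", "TTTT"))
  expect_equal(comp$count[comp$base == "T"], 3L)
  expect_equal(sum(comp$fraction), 1)
  allT <- five_prime_composition(c("TAA", "TCC"))
  expect_equal(allT$fraction[allT$base == "T"], 1)
})

test_that("novelty classification is tiered: other species > vitis > new", {
  vitis <- data.frame(sequence = "TGACAGAAGAGAGGGAGCAC")
  other <- data.frame(sequence = "TTGGATTGAAGGGAGCTCTA")
  cands <- c("TGACAGAAGAGAGGGAGCAC",   # identical to a vitis sequence
             "TTGGATTGAAGGGAGCTCTA",   # matches outside the genus
             "CCCCCGGGGGAAAAATTTTT")   # matches nothing
  got <- classify_novelty(cands, vitis, other)
  expect_equal(got, c("vitis_specific", "shared", "species_specific"))
  expect_equal(classify_novelty(cands, vitis[0, , drop = FALSE],
                                other[0, , drop = FALSE]),
               rep("species_specific", 3))
})
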