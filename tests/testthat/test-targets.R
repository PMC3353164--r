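MIR <- "TGACAGAAGAGAGGGAGCACA" # 21 nt

test_that("duplex scoring matches the penalty table at every position", {
  site <- revcomp(MIR)
  perfect <- align_duplex(MIR, site)
  expect_equal(score_duplex(perfect), 0)
  # independent recomputation: substitute every base at every target slot
  bases <- c("A", "C", "G", "T")
  pairs_with <- function(m, t)
    (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G") |
    (m == "G" & t == "T") | (m == "T" & t == "G")
  is_gu <- function(m, t) (m == "G" & t == "T") | (m == "T" & t == "G")
  mch <- strsplit(MIR, "")[[1]]
  for (pos in seq_len(nchar(MIR))) {
    for (b in bases) {
      sch <- strsplit(site, "")[[1]]
      sch[nchar(MIR) - pos + 1] <- b # target base facing miRNA position pos
      aln <- align_duplex(MIR, paste(sch, collapse = ""))
      exp_pen <- if (pairs_with(mch[pos], b)) {
        if (is_gu(mch[pos], b)) 0.5 else 0
      } else 1
      if (pos >= 2 && pos <= 13) exp_pen <- exp_pen * 2
      expect_equal(score_duplex(aln), exp_pen,
                   info = sprintf("pos %d base %s", pos, b))
    }
  }
})

test_that("worked scoring examples: G:U outside and mismatch inside 2-13", {
  site <- strsplit(revcomp(MIR), "")[[1]]
  # G:U at miRNA position 15 (T facing G pairs as wobble)
  gu <- site; stopifnot(MIR != "")
  m15 <- substr(MIR, 15, 15)
  gu[nchar(MIR) - 15 + 1] <- if (m15 == "G") "T" else "G"
  a_gu <- align_duplex(MIR, paste(gu, collapse = ""))
  expect_equal(sum(a_gu$state == "GU"), 1)
  expect_equal(score_duplex(a_gu), 0.5)
  # mismatch at position 5 is doubled
  mm <- site
  m5 <- substr(MIR, 5, 5)
  mm[nchar(MIR) - 5 + 1] <- c(A = "C", C = "A", G = "A", T = "C")[[m5]]
  a_mm <- align_duplex(MIR, paste(mm, collapse = ""))
  expect_equal(score_duplex(a_mm), 2)
  # bulges cost 1, doubled in the 5'-proximal region
  a_bm <- align_duplex(MIR, paste(site[-3], collapse = ""),
                       bulge = list(side = "mirna", pos = 15))
  expect_equal(sum(a_bm$state == "bulge_mirna"), 1)
})

test_that("transcript scanning finds planted sites at the right thresholds", {
  set.seed(50)
  tx <- rand_seq(400)
  site <- revcomp(MIR)
  # plant a perfect site at 101 and a seed-mismatched site at 301
  substr(tx, 101, 100 + nchar(site)) <- site
  seedmm <- strsplit(site, "")[[1]]
  k <- nchar(MIR) - 5 + 1 # faces miRNA position 5
  m5 <- substr(MIR, 5, 5)
  seedmm[k] <- c(A = "C", C = "A", G = "A", T = "C")[[m5]]
  substr(tx, 301, 300 + nchar(site)) <- paste(seedmm, collapse = "")
  hits <- scan_transcripts(MIR, c(tx1 = tx), max_score = 4, max_bulges = 0)
  expect_equal(hits$start[hits$score == 0], 101)
  expect_true(any(hits$start == 301 & hits$score == 2))
  # threshold behavior: the mismatched site disappears below its score
  strict <- scan_transcripts(MIR, c(tx1 = tx), max_score = 1.5,
                             max_bulges = 0)
  expect_false(any(strict$start == 301))
  expect_true(any(strict$start == 101))
})

test_that("scanning at score 0 equals exact reverse-complement search", {
  set.seed(51)
  for (k in 1:5) {
    tx <- rand_seq(300)
    n_sites <- sample(0:2, 1)
    starts <- sort(sample(seq(1, 270, by = 30), n_sites))
    for (s in starts) substr(tx, s, s + nchar(MIR) - 1) <- revcomp(MIR)
    hits <- scan_transcripts(MIR, c(t = tx), max_score = 0, max_bulges = 0)
    naive <- which(substring(tx, 1:(nchar(tx) - nchar(MIR) + 1),
                             nchar(MIR):nchar(tx)) == revcomp(MIR))
    expect_setequal(hits$start, naive)
  }
})

test_that("random 1-kb transcripts essentially never hit at score <= 1", {
  set.seed(52)
  n_hits <- vapply(1:5, function(k)
    nrow(scan_transcripts(rand_seq(21), c(t = rand_seq(1000)),
                          max_score = 1, max_bulges = 0)), integer(1))
  expect_equal(sum(n_hits), 0L)
})

test_that("cleavage prediction follows the pairing table across the site", {
  set.seed(53)
  tx <- rand_seq(300)
  substr(tx, 101, 100 + nchar(MIR)) <- revcomp(MIR)
  hit <- scan_transcripts(MIR, c(t = tx), max_score = 0, max_bulges = 0)
  expect_equal(hit$start, 101)
  expect_equal(hit$end, 121)
  c10 <- predict_cleavage(hit[1, ], 10)
  c9 <- predict_cleavage(hit[1, ], 9)
  expect_equal(c10$position, 112) # brute-force: pos k pairs end - k + 1
  expect_equal(c9$position, 113)
  expect_false(c10$flagged)
  # round-trip: the returned base is complementary to the anchor base
  aln <- hit$alignment[[1]]
  row <- aln[aln$position == 10 & !is.na(aln$position), ]
  expect_equal(row$transcript_pos, 112)
  expect_equal(chartr("ACGT", "TGCA", row$mirna_base), row$target_base)
  expect_error(predict_cleavage(hit[1, ], 11), "anchor")
})

test_that("region labels come from the site midpoint against the CDS", {
  hit <- data.frame(transcript_id = "t1", start = 150, end = 170)
  model <- data.frame(transcript_id = "t1", cds_start = 100, cds_end = 400)
  expect_equal(annotate_region(hit, model), "CDS")
  expect_equal(annotate_region(data.frame(transcript_id = "t1", start = 10,
                                          end = 30), model), "5UTR")
  expect_equal(annotate_region(data.frame(transcript_id = "t1", start = 500,
                                          end = 520), model), "3UTR")
  # straddling site: midpoint decides (401 lies past the CDS end)
  expect_equal(annotate_region(data.frame(transcript_id = "t1", start = 390,
                                          end = 412), model), "3UTR")
  expect_equal(annotate_region(hit, NULL), "unknown")
})

test_that("the pretty-printer mirrors dash/circle/X notation", {
  aln <- align_duplex("TGACAG", "CTGTCA")
  out <- format_duplex(aln)
  expect_length(out, 3)
  expect_match(out[2], "\\|")
})
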