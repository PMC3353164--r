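WT <- "TGACAGAAGAGAGGGAGCAC"

test_that("wild-type selection prefers the exact known sequence", {
  grp <- data.frame(sequence = c("AAAAAAAAAAAAAAAAAAAA", WT),
                    read_count = c(500L, 3L), stringsAsFactors = FALSE)
  expect_equal(select_wildtype(grp, WT)$sequence, WT)
  # without an exact match, highest count wins; ties break lexicographically
  grp2 <- data.frame(sequence = c("CCCC", "AAAA", "GGGG"),
                     read_count = c(50L, 3L, 50L), stringsAsFactors = FALSE)
  expect_equal(select_wildtype(grp2, WT)$sequence, "CCCC")
  one <- data.frame(sequence = "ACGT", read_count = 1L)
  expect_equal(select_wildtype(one, WT)$sequence, "ACGT")
  expect_null(select_wildtype(grp2[0, ], WT))
})

test_that("miR-SNP calls require exactly one substitution at equal length", {
  var <- WT
  substr(var, 9, 9) <- "C"
  call <- call_mir_snp(WT, var, 3L)
  expect_equal(call$kind, "miR-SNP")
  expect_equal(call$snp_position, 9L)
  expect_equal(call$ref_base, "G")
  expect_equal(call$alt_base, "C")
  expect_null(call_mir_snp(WT, WT))
  two <- var
  substr(two, 15, 15) <- "T"
  expect_null(call_mir_snp(WT, two))
  expect_null(call_mir_snp(WT, substr(WT, 2, nchar(WT)))) # length differs
})

test_that("miR-LD calls are substitution-free terminal shifts", {
  ext <- paste0("T", WT)
  call <- call_mir_ld(WT, ext)
  expect_equal(call$kind, "miR-LD")
  expect_equal(c(call$delta5, call$delta3), c(1L, 0L))
  trunc <- substr(WT, 1, nchar(WT) - 2)
  call2 <- call_mir_ld(WT, trunc)
  expect_equal(c(call2$delta5, call2$delta3), c(0L, -2L))
  # shift + substitution fits neither class
  shifted <- paste0("T", WT)
  substr(shifted, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(shifted, 10, 10))[1]
  expect_null(call_mir_ld(WT, shifted))
  expect_null(call_mir_snp(WT, shifted))
  # shifts beyond the cap are distinct sequences, not length variants
  far <- paste0("TTTTT", WT)
  expect_null(call_mir_ld(WT, far, max_shift_total = 4))
})

test_that("variant scanning separates SNP, LD and other, exclusively", {
  snp <- WT; substr(snp, 5, 5) <- "T"
  ld <- substr(WT, 1, nchar(WT) - 1)
  both <- paste0("A", WT); substr(both, 8, 8) <- "T"
  a <- data.frame(
    sequence = c(WT, snp, ld, both),
    read_count = c(100L, 3L, 4L, 2L),
    known_id = "vvi-miR156a", family = "miR156", known_seq = WT,
    substitutions = c(0L, 1L, 0L, 1L), offset5 = 0L, offset3 = 0L,
    stringsAsFactors = FALSE)
  vs <- scan_variants(a)
  expect_equal(nrow(vs$calls), 2L)
  expect_setequal(vs$calls$kind, c("miR-SNP", "miR-LD"))
  expect_equal(vs$wildtypes$wildtype_seq, WT)
  expect_equal(vs$per_mirna$n_other, 1L)
  # no (wildtype, variant) pair can yield both call kinds
  expect_equal(anyDuplicated(vs$calls$variant_seq), 0L)
  # read support threshold suppresses weak variants
  vs2 <- scan_variants(a, min_reads = 4)
  expect_equal(vs2$calls$kind, "miR-LD")
})

test_that("SNP family distribution counts members and types", {
  calls <- data.frame(
    kind = "miR-SNP",
    wildtype_id = c("va-miR160a", "va-miR160a", "va-miR160b", "va-miR156a"),
    wildtype_seq = "x", variant_seq = c("v1", "v2", "v3", "v4"),
    read_count = 1L, snp_position = 1L, ref_base = "A", alt_base = "C",
    delta5 = NA_integer_, delta3 = NA_integer_, stringsAsFactors = FALSE)
  d <- snp_family_distribution(calls)
  expect_equal(d$family[1], "miR160") # largest total first
  expect_equal(d$members_with_snp[d$family == "miR160"], 2L)
  expect_equal(d$total_snp_types[d$family == "miR160"], 3L)
  empty <- snp_family_distribution(calls[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("SNP-vs-duplex classification matches the pairing truth table", {
  # exhaustive: every wild-type state x every alternative base
  bases <- c("A", "C", "G", "T")
  pairs_with <- function(m, t) {
    (m == "A" & t == "T") | (m == "T" & t == "A") |
      (m == "G" & t == "C") | (m == "C" & t == "G") |
      (m == "G" & t == "T") | (m == "T" & t == "G")
  }
  for (mb in bases) for (tb in bases) for (alt in setdiff(bases, mb)) {
    duplex <- data.frame(position = 1L, mirna_base = mb, target_base = tb,
                         state = ifelse(pairs_with(mb, tb),
                                        ifelse((mb == "G" & tb == "T") |
                                                 (mb == "T" & tb == "G"),
                                               "GU", "match"), "mismatch"),
                         stringsAsFactors = FALSE)
    call <- data.frame(snp_position = 1L, alt_base = alt,
                       stringsAsFactors = FALSE)
    got <- snp_vs_duplex(call, duplex)
    if (pairs_with(mb, tb)) {
      expect_equal(got$classification,
                   if (pairs_with(alt, tb)) "pairing_retained" else
                     "creates_new_mismatch")
    } else {
      expect_equal(got$classification, "at_existing_mismatch")
      expect_equal(got$pairing_gained, pairs_with(alt, tb))
    }
  }
  # beyond the duplex
  duplex <- data.frame(position = 1:20, mirna_base = "A", target_base = "T",
                       state = "match", stringsAsFactors = FALSE)
  out <- snp_vs_duplex(data.frame(snp_position = 25L, alt_base = "G"), duplex)
  expect_equal(out$classification, "outside_duplex")
})
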