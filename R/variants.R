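#' Select the wild-type tag of a conserved miRNA group
#'
#' The wild type is the tag exactly equal to the known mature sequence when
#' present; otherwise the highest-read-count tag (ties broken
#' lexicographically by sequence).
#'
#' @param group data.frame of tags assigned to one known mature (columns
#'   `sequence`, `read_count`).
#' @param known_seq the known mature sequence.
#' @return the wild-type row of `group` (or NULL for an empty group).
#' @export
select_wildtype <- function(group, known_seq) {
  if (is.null(group) || nrow(group) == 0) return(NULL)
  exact <- which(group$sequence == norm_seq(known_seq))
  i <- if (length(exact)) {
    exact[1]
  } else {
    ord <- order(-group$read_count, group$sequence)
    ord[1]
  }
  group[i, , drop = FALSE]
}

#' Call a miR-SNP (single-substitution variant)
#'
#' A miR-SNP requires equal length and Hamming distance exactly 1; the
#' substituted position is reported 1-based from the miRNA 5' end.
#'
#' @param wildtype_seq,variant_seq sequences to compare.
#' @param read_count redundancy of the variant tag.
#' @return one-row data.frame (see [scan_variants()] for columns) or NULL
#'   when the pair does not qualify.
#' @export
call_mir_snp <- function(wildtype_seq, variant_seq, read_count = 1L) {
  w <- norm_seq(wildtype_seq); v <- norm_seq(variant_seq)
  if (!nzchar(w) || !nzchar(v)) stop("empty sequence", call. = FALSE)
  if (nchar(w) != nchar(v)) return(NULL)
  vw <- strsplit(w, "")[[1]]; vv <- strsplit(v, "")[[1]]
  diff <- which(vw != vv)
  if (length(diff) != 1L) return(NULL)
  data.frame(kind = "miR-SNP", wildtype_seq = w, variant_seq = v,
             read_count = read_count, snp_position = diff,
             ref_base = vw[diff], alt_base = vv[diff],
             delta5 = NA_integer_, delta3 = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Call a miR-LD (terminal length-difference variant)
#'
#' A miR-LD requires an ungapped alignment of the variant within/around the
#' wild type whose overlap is substitution-free, with non-zero terminal
#' shifts. `delta5`/`delta3` are signed: positive means the variant extends
#' beyond the wild type at that end, negative that it is truncated. Variants
#' whose total shift exceeds `max_shift_total` are treated as distinct
#' sequences, not length variants.
#'
#' @inheritParams call_mir_snp
#' @param max_shift_total cap on `|delta5| + |delta3|` (default 4).
#' @return one-row data.frame or NULL.
#' @export
call_mir_ld <- function(wildtype_seq, variant_seq, read_count = 1L,
                        max_shift_total = 4) {
  w <- norm_seq(wildtype_seq); v <- norm_seq(variant_seq)
  if (!nzchar(w) || !nzchar(v)) stop("empty sequence", call. = FALSE)
  if (w == v) return(NULL)
  lw <- nchar(w); lv <- nchar(v)
  vw <- strsplit(w, "")[[1]]; vv <- strsplit(v, "")[[1]]
  best <- NULL
  for (o in (-(lw - 1)):(lv - 1)) {
    # variant position i aligns wild-type position i - o
    i1 <- max(1, 1 + o); i2 <- min(lv, lw + o)
    if (i2 < i1) next
    if (any(vv[i1:i2] != vw[(i1 - o):(i2 - o)])) next
    d5 <- (i1 - 1) - (i1 - o - 1)       # variant 5' overhang - WT 5' overhang
    d3 <- (lv - i2) - (lw - (i2 - o))
    if (d5 == 0 && d3 == 0) next
    shift <- abs(d5) + abs(d3)
    if (shift > max_shift_total) next
    ov <- i2 - i1 + 1
    if (is.null(best) || ov > best$ov ||
        (ov == best$ov && shift < best$shift)) {
      best <- list(ov = ov, shift = shift, d5 = d5, d3 = d3)
    }
  }
  if (is.null(best)) return(NULL)
  data.frame(kind = "miR-LD", wildtype_seq = w, variant_seq = v,
             read_count = read_count, snp_position = NA_integer_,
             ref_base = NA_character_, alt_base = NA_character_,
             delta5 = best$d5, delta3 = best$d3, stringsAsFactors = FALSE)
}

#' Scan a conserved-assignment table for miRNA variants
#'
#' For every known mature miRNA with assigned tags, the wild type is selected
#' ([select_wildtype()]) and every other tag in the group is tested first as
#' a miR-SNP, then as a miR-LD. Tags combining a terminal shift and a
#' substitution fit neither class and land in the `other` bucket. SNP and LD
#' calls are mutually exclusive per (wild type, variant) pair by
#' construction.
#'
#' @param assignments data.frame from [match_known()].
#' @param min_reads minimum read support for a variant call (default 1).
#' @param max_shift_total see [call_mir_ld()].
#' @return list with `calls` (variant table; columns `kind`, `wildtype_id`,
#'   `wildtype_seq`, `variant_seq`, `read_count`, `snp_position`,
#'   `ref_base`, `alt_base`, `delta5`, `delta3`), `wildtypes` (per-miRNA
#'   wild-type table with `n_variant_tags`), and `per_mirna` (counts of SNP,
#'   LD and other variant types per miRNA).
#' @export
scan_variants <- function(assignments, min_reads = 1, max_shift_total = 4) {
  calls <- list(); wts <- list(); per <- list()
  for (id in sort(unique(assignments$known_id))) {
    grp <- assignments[assignments$known_id == id, , drop = FALSE]
    wt <- select_wildtype(grp, grp$known_seq[1])
    others <- grp[grp$sequence != wt$sequence, , drop = FALSE]
    n_snp <- 0L; n_ld <- 0L; n_other <- 0L
    if (nrow(others)) {
      for (k in seq_len(nrow(others))) {
        if (others$read_count[k] < min_reads) next
        cl <- call_mir_snp(wt$sequence, others$sequence[k],
                           others$read_count[k])
        if (is.null(cl))
          cl <- call_mir_ld(wt$sequence, others$sequence[k],
                            others$read_count[k], max_shift_total)
        if (is.null(cl)) {
          n_other <- n_other + 1L
        } else {
          cl$wildtype_id <- id
          calls[[length(calls) + 1L]] <- cl
          if (cl$kind == "miR-SNP") n_snp <- n_snp + 1L else n_ld <- n_ld + 1L
        }
      }
    }
    wts[[length(wts) + 1L]] <- data.frame(
      wildtype_id = id, wildtype_seq = wt$sequence,
      read_count = wt$read_count, n_variant_tags = nrow(others),
      stringsAsFactors = FALSE)
    per[[length(per) + 1L]] <- data.frame(
      wildtype_id = id, n_snp_types = n_snp, n_ld_types = n_ld,
      n_other = n_other, stringsAsFactors = FALSE)
  }
  empty_calls <- data.frame(kind = character(), wildtype_seq = character(),
                            variant_seq = character(), read_count = integer(),
                            snp_position = integer(), ref_base = character(),
                            alt_base = character(), delta5 = integer(),
                            delta3 = integer(), wildtype_id = character(),
                            stringsAsFactors = FALSE)
  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls
  cols <- c("kind", "wildtype_id", "wildtype_seq", "variant_seq",
            "read_count", "snp_position", "ref_base", "alt_base",
            "delta5", "delta3")
  calls <- calls[, cols, drop = FALSE]
  row.names(calls) <- NULL
  list(calls = calls,
       wildtypes = do.call(rbind, wts),
       per_mirna = do.call(rbind, per))
}

#' Family-level distribution of miR-SNPs
#'
#' @param calls variant call table from [scan_variants()].
#' @return data.frame per family: `family`, `members_with_snp` (distinct
#'   miRNAs carrying at least one SNP), `total_snp_types`, sorted by
#'   descending total.
#' @export
snp_family_distribution <- function(calls) {
  snp <- calls[calls$kind == "miR-SNP", , drop = FALSE]
  if (nrow(snp) == 0) {
    return(data.frame(family = character(), members_with_snp = integer(),
                      total_snp_types = integer(), stringsAsFactors = FALSE))
  }
  snp$family <- mir_family(snp$wildtype_id)
  fam <- unique(snp$family)
  out <- data.frame(
    family = fam,
    members_with_snp = vapply(fam, function(f)
      length(unique(snp$wildtype_id[snp$family == f])), integer(1)),
    total_snp_types = vapply(fam, function(f)
      sum(snp$family == f), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$total_snp_types, out$family), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Classify a miR-SNP site against a miRNA:target duplex
#'
#' Decides how the substitution relates to the duplex the wild-type miRNA
#' forms with a target: `creates_new_mismatch` when the wild-type position
#' paired (Watson-Crick or G:U) and the variant base no longer pairs;
#' `at_existing_mismatch` when the position was already a mismatch (or a
#' bulged miRNA base); `pairing_retained` when a paired position still pairs
#' after the substitution; `outside_duplex` when the SNP lies beyond the
#' duplex. When a formerly mismatched position gains pairing, the
#' `pairing_gained` flag is set.
#'
#' @param call one-row miR-SNP call from [scan_variants()].
#' @param duplex data.frame describing the duplex, one row per miRNA
#'   position: `position`, `mirna_base`, `target_base` (NA at a miRNA
#'   bulge), `state` in match/mismatch/GU/bulge_mirna.
#' @return list with `classification` and logical `pairing_gained`.
#' @export
snp_vs_duplex <- function(call, duplex) {
  pos <- call$snp_position
  row <- duplex[duplex$position == pos, , drop = FALSE]
  if (nrow(row) == 0) {
    return(list(classification = "outside_duplex", pairing_gained = FALSE))
  }
  alt_state <- if (is.na(row$target_base)) "mismatch" else
    base_pairs(call$alt_base, row$target_base)
  alt_pairs <- alt_state %in% c("match", "GU")
  if (row$state %in% c("match", "GU")) {
    cls <- if (alt_pairs) "pairing_retained" else "creates_new_mismatch"
    gained <- FALSE
  } else {
    cls <- "at_existing_mismatch"
    gained <- alt_pairs
  }
  list(classification = cls, pairing_gained = gained)
}

#' Write miR-SNP / miR-LD tables as TSV
#'
#' @param calls variant call table from [scan_variants()].
#' @param snp_path,ld_path output files (NULL to skip one).
#' @export
write_variant_tables <- function(calls, snp_path = NULL, ld_path = NULL) {
  if (!is.null(snp_path)) {
    snp <- calls[calls$kind == "miR-SNP",
                 c("wildtype_id", "wildtype_seq", "variant_seq",
                   "snp_position", "ref_base", "alt_base", "read_count")]
    snp$change <- paste0(snp$ref_base, ">", snp$alt_base)
    utils::write.table(snp[, c("wildtype_id", "wildtype_seq", "variant_seq",
                               "snp_position", "change", "read_count")],
                       snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(ld_path)) {
    ld <- calls[calls$kind == "miR-LD",
                c("wildtype_id", "wildtype_seq", "variant_seq",
                  "delta5", "delta3", "read_count")]
    utils::write.table(ld, ld_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
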