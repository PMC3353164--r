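# Base coding and penalty tables shared by the duplex routines. Penalties:
# mismatch 1.0, G:U wobble 0.5, match 0; doubling applies to miRNA positions
# 2-13 (5'-proximal region).
.DUPLEX_BASES <- c("A", "C", "G", "T", "N")

.pair_class_matrix <- local({
  m <- matrix("mismatch", 5, 5, dimnames = list(.DUPLEX_BASES, .DUPLEX_BASES))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- "match"
  m["G", "T"] <- m["T", "G"] <- "GU"
  m
})

.pair_penalty_matrix <- local({
  p <- matrix(1, 5, 5, dimnames = list(.DUPLEX_BASES, .DUPLEX_BASES))
  p[.pair_class_matrix == "match"] <- 0
  p[.pair_class_matrix == "GU"] <- 0.5
  p
})

#' Build a miRNA:target-site duplex alignment
#'
#' The miRNA (5'->3') is paired antiparallel against a candidate site
#' (5'->3' on the transcript), so miRNA position 1 faces the 3'-most site
#' base. At most one bulged nucleotide is supported: `bulge = list(side =
#' "mirna"|"target", pos = p)` leaves miRNA base `p` unpaired, or inserts an
#' unpaired target base between miRNA positions `p` and `p + 1`.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site target site sequence, 5'->3'; length must equal the miRNA
#'   length (no bulge), length - 1 (miRNA bulge) or length + 1 (target
#'   bulge).
#' @param bulge NULL or `list(side, pos)`.
#' @return data.frame in duplex order from the miRNA 5' end: `position`
#'   (miRNA position; NA on a target-bulge row), `mirna_base`, `target_base`
#'   (NA on a miRNA-bulge row), `site_index` (position within `site`),
#'   `state` in match/mismatch/GU/bulge_mirna/bulge_target.
#' @export
align_duplex <- function(mirna, site, bulge = NULL) {
  m <- strsplit(norm_seq(mirna), "")[[1]]
  s <- strsplit(norm_seq(site), "")[[1]]
  L <- length(m); Ls <- length(s)
  if (is.null(bulge)) {
    if (Ls != L) stop("site length must equal miRNA length", call. = FALSE)
    position <- seq_len(L)
    site_index <- Ls - position + 1L
    state <- .pair_class_matrix[cbind(m, s[site_index])]
    out <- data.frame(position = position, mirna_base = m,
                      target_base = s[site_index], site_index = site_index,
                      state = state, stringsAsFactors = FALSE)
  } else if (bulge$side == "mirna") {
    if (Ls != L - 1)
      stop("miRNA bulge needs a site of miRNA length - 1", call. = FALSE)
    p <- bulge$pos
    if (p < 2 || p > L - 1) stop("bulge position out of range", call. = FALSE)
    position <- seq_len(L)
    site_index <- ifelse(position < p, L - position,
                         ifelse(position > p, L - position + 1L, NA_integer_))
    tb <- ifelse(is.na(site_index), NA_character_, s[site_index])
    state <- ifelse(is.na(site_index), "bulge_mirna",
                    .pair_class_matrix[cbind(m, ifelse(is.na(tb), "A", tb))])
    out <- data.frame(position = position, mirna_base = m, target_base = tb,
                      site_index = site_index, state = state,
                      stringsAsFactors = FALSE)
  } else if (bulge$side == "target") {
    if (Ls != L + 1)
      stop("target bulge needs a site of miRNA length + 1", call. = FALSE)
    p <- bulge$pos
    if (p < 1 || p > L - 1) stop("bulge position out of range", call. = FALSE)
    position <- seq_len(L)
    site_index <- ifelse(position <= p, L + 2L - position, L + 1L - position)
    state <- .pair_class_matrix[cbind(m, s[site_index])]
    out <- data.frame(position = position, mirna_base = m,
                      target_base = s[site_index], site_index = site_index,
                      state = state, stringsAsFactors = FALSE)
    brow <- data.frame(position = NA_integer_, mirna_base = NA_character_,
                       target_base = s[L + 1L - p], site_index = L + 1L - p,
                       state = "bulge_target", stringsAsFactors = FALSE)
    out <- rbind(out[seq_len(p), ], brow, out[(p + 1):L, ])
  } else stop("bulge$side must be 'mirna' or 'target'", call. = FALSE)
  row.names(out) <- NULL
  out
}

#' Allen-style duplex penalty score
#'
#' Penalties: mismatch 1.0, G:U wobble 0.5, each bulged position 1.0;
#' penalties are doubled for miRNA positions 2-13 inclusive (the 5'-proximal
#' region; a target bulge is charged to the miRNA position it follows). A
#' perfect duplex scores 0; granularity is 0.5.
#'
#' @param alignment data.frame from [align_duplex()].
#' @return non-negative numeric penalty.
#' @export
score_duplex <- function(alignment) {
  if (!all(c("position", "state") %in% names(alignment)))
    stop("malformed duplex alignment", call. = FALSE)
  base <- c(match = 0, mismatch = 1, GU = 0.5,
            bulge_mirna = 1, bulge_target = 1)
  if (!all(alignment$state %in% names(base)))
    stop("malformed duplex state vector", call. = FALSE)
  pen <- unname(base[alignment$state])
  pos <- alignment$position
  for (i in which(is.na(pos))) pos[i] <- if (i > 1) pos[i - 1] else 1L
  dbl <- pos >= 2 & pos <= 13
  sum(pen * ifelse(dbl, 2, 1))
}

# Vectorized window scoring for one alignment variant: given the coded
# transcript, window starts and the per-miRNA-position window offsets,
# returns total penalty and raw mismatch count per start.
.score_windows <- function(tcode, starts, mcode, offsets, mult, extra_penalty) {
  pen <- rep(extra_penalty, length(starts))
  mm <- integer(length(starts))
  for (k in seq_along(mcode)) {
    if (is.na(offsets[k])) next # bulged miRNA base, charged via extra_penalty
    tb <- tcode[starts + offsets[k]]
    pen <- pen + .pair_penalty_matrix[cbind(mcode[k], tb)] * mult[k]
    mm <- mm + (.pair_class_matrix[cbind(mcode[k], tb)] == "mismatch")
  }
  list(penalty = pen, mismatches = mm)
}

#' Scan transcripts for miRNA target sites
#'
#' Every transcript window of the miRNA length (and length +/- 1 when one
#' bulge is allowed) is aligned antiparallel to the miRNA and scored with the
#' Allen penalty scheme ([score_duplex()]); windows scoring at most
#' `max_score` are reported, after reducing each cluster of overlapping
#' windows to its best-scoring site (ties: 5'-most). An optional raw
#' mismatch-count filter (`max_mismatches`, exclusive bound) mirrors
#' BLAST-style "fewer than four mismatches" candidate selection.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcripts named character vector, `DNAStringSet`, or data.frame
#'   with `id` and `sequence` columns.
#' @param max_score Allen-penalty cutoff (default 4.0).
#' @param max_bulges 0 or 1 bulged nucleotides per duplex (default 1).
#' @param max_mismatches optional exclusive raw mismatch bound (e.g. 4),
#'   NULL to disable.
#' @param mirna_id label recorded in the hit table.
#' @return data.frame of hits sorted by score then coordinate: `mirna_id`,
#'   `transcript_id`, `start`, `end`, `score`, `mismatches`, `gu_count`,
#'   `bulges`, plus a list-column `alignment` holding each hit's duplex
#'   alignment.
#' @export
scan_transcripts <- function(mirna, transcripts, max_score = 4,
                             max_bulges = 1, max_mismatches = NULL,
                             mirna_id = "miRNA") {
  if (methods::is(transcripts, "DNAStringSet"))
    transcripts <- stats::setNames(as.character(transcripts),
                                   names(transcripts))
  if (is.data.frame(transcripts))
    transcripts <- stats::setNames(transcripts$sequence, transcripts$id)
  if (length(transcripts) == 0) stop("no transcripts", call. = FALSE)
  mirna <- norm_seq(mirna)
  mch <- strsplit(mirna, "")[[1]]
  L <- length(mch)
  mult <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  variants <- list(list(width = L, bulge = NULL,
                        offsets = (L - seq_len(L) + 1L) - 1L, extra = 0))
  if (max_bulges >= 1 && L >= 3) {
    for (p in 2:(L - 1)) {
      off <- ifelse(seq_len(L) < p, L - seq_len(L),
                    ifelse(seq_len(L) > p, L - seq_len(L) + 1L, NA_integer_)) - 1L
      variants[[length(variants) + 1L]] <-
        list(width = L - 1L, bulge = list(side = "mirna", pos = p),
             offsets = off, extra = 1 * mult[p])
    }
    for (p in 1:(L - 1)) {
      off <- ifelse(seq_len(L) <= p, L + 2L - seq_len(L),
                    L + 1L - seq_len(L)) - 1L
      variants[[length(variants) + 1L]] <-
        list(width = L + 1L, bulge = list(side = "target", pos = p),
             offsets = off, extra = 1 * mult[p])
    }
  }
  rows <- list(); alns <- list()
  for (tx in names(transcripts)) {
    tch <- strsplit(norm_seq(transcripts[[tx]]), "")[[1]]
    n <- length(tch)
    for (v in variants) {
      if (n < v$width) next
      starts <- seq_len(n - v$width + 1L)
      sc <- .score_windows(tch, starts, mch, v$offsets, mult, v$extra)
      ok <- sc$penalty <= max_score
      if (!is.null(max_mismatches)) ok <- ok & sc$mismatches < max_mismatches
      for (s in starts[ok]) {
        site <- paste(tch[s:(s + v$width - 1L)], collapse = "")
        aln <- align_duplex(mirna, site, v$bulge)
        aln$transcript_pos <- ifelse(is.na(aln$site_index), NA_integer_,
                                     s + aln$site_index - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mirna_id, transcript_id = tx, start = s,
          end = s + v$width - 1L, score = score_duplex(aln),
          mismatches = sum(aln$state == "mismatch"),
          gu_count = sum(aln$state == "GU"),
          bulges = sum(grepl("^bulge", aln$state)),
          stringsAsFactors = FALSE)
        alns[[length(rows)]] <- aln
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      mismatches = integer(), gu_count = integer(),
                      bulges = integer(), stringsAsFactors = FALSE)
    out$alignment <- list()
    return(out)
  }
  tab <- do.call(rbind, rows)
  tab$alignment <- I(alns)
  keep <- logical(nrow(tab))
  for (tx in unique(tab$transcript_id)) {
    idx <- which(tab$transcript_id == tx)
    idx <- idx[order(tab$start[idx])]
    cur <- integer(0); cl_end <- -1L
    groups <- list()
    for (i in idx) {
      if (length(cur) && tab$start[i] > cl_end) {
        groups[[length(groups) + 1L]] <- cur
        cur <- integer(0); cl_end <- -1L
      }
      cur <- c(cur, i); cl_end <- max(cl_end, tab$end[i])
    }
    if (length(cur)) groups[[length(groups) + 1L]] <- cur
    for (g in groups) {
      best <- g[order(tab$score[g], tab$start[g])][1]
      keep[best] <- TRUE
    }
  }
  out <- tab[keep, , drop = FALSE]
  out <- out[order(out$score, out$transcript_id, out$start), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Predicted cleavage position for a target hit
#'
#' Guided cleavage leaves the 5' end of the 3' fragment at the transcript
#' nucleotide pairing the miRNA's 10th (or 9th) nucleotide; this returns that
#' transcript coordinate, following the alignment's pair states across
#' bulges. A mismatched anchor is allowed but flagged; a bulged (unpaired)
#' anchor yields an NA position with the flag set.
#'
#' @param hit one row of the [scan_transcripts()] hit table (with its
#'   `alignment` list-column).
#' @param anchor miRNA anchor position, 9 or 10 (default 10).
#' @return list with `position` (transcript coordinate), `anchor`, and
#'   logical `flagged`.
#' @export
predict_cleavage <- function(hit, anchor = 10) {
  if (!anchor %in% c(9, 10)) stop("anchor must be 9 or 10", call. = FALSE)
  aln <- hit$alignment[[1]]
  if (anchor > max(aln$position, na.rm = TRUE))
    stop("anchor beyond miRNA length", call. = FALSE)
  row <- aln[!is.na(aln$position) & aln$position == anchor, , drop = FALSE]
  if (row$state == "bulge_mirna") {
    return(list(position = NA_integer_, anchor = anchor, flagged = TRUE))
  }
  list(position = row$transcript_pos, anchor = anchor,
       flagged = row$state != "match")
}

#' Label the transcript region of a target hit
#'
#' Uses the site midpoint against the CDS span: `5UTR` before, `CDS` within,
#' `3UTR` after; `unknown` when no model is supplied for the transcript.
#'
#' @param hit one row of the hit table.
#' @param transcript_model data.frame with `transcript_id`, `cds_start`,
#'   `cds_end` (or NULL).
#' @return region label.
#' @export
annotate_region <- function(hit, transcript_model = NULL) {
  if (is.null(transcript_model)) return("unknown")
  m <- transcript_model[transcript_model$transcript_id == hit$transcript_id, ,
                        drop = FALSE]
  if (nrow(m) == 0) return("unknown")
  mid <- (hit$start + hit$end) / 2
  if (mid < m$cds_start[1]) "5UTR"
  else if (mid > m$cds_end[1]) "3UTR"
  else "CDS"
}

#' Pretty-print a duplex alignment
#'
#' Renders the target site (5'->3', top), pairing symbols (| Watson-Crick,
#' o G:U wobble, X mismatch, space at bulges) and the miRNA (3'->5',
#' bottom).
#'
#' @param alignment data.frame from [align_duplex()].
#' @return character vector of three display lines.
#' @export
format_duplex <- function(alignment) {
  a <- alignment[rev(seq_len(nrow(alignment))), , drop = FALSE]
  tgt <- ifelse(is.na(a$target_base), "-", a$target_base)
  mir <- ifelse(is.na(a$mirna_base), "-", a$mirna_base)
  sym <- vapply(a$state, function(st) switch(st, match = "|", GU = "o",
                                             mismatch = "X", " "),
                character(1), USE.NAMES = FALSE)
  c(paste0("5' ", paste(tgt, collapse = ""), " 3'  target"),
    paste0("   ", paste(sym, collapse = ""), ""),
    paste0("3' ", paste(mir, collapse = ""), " 5'  miRNA"))
}
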