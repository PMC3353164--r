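#' Read raw small-RNA reads from FASTA or FASTQ
#'
#' Reads are returned as a plain data.frame with one row per read so that the
#' cleaning steps ([trim_adapters()], [quality_filter()], [length_filter()],
#' [collapse_reads()]) can be composed freely. Qualities are kept as
#' Sanger/Phred+33 encoded strings and are `NA` for FASTA input.
#'
#' @param path input file.
#' @param format "auto" (by extension), "fasta" or "fastq".
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  }
  data.frame(id = names(x), seq = norm_seq(as.character(x)), qual = qual,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Trim sequencing adapters from raw reads
#'
#' The 3' adapter is located by a best-overlap semi-global search: every read
#' suffix is compared against the adapter prefix, keeping the highest-scoring
#' occurrence (score = matches - mismatches) with overlap >= `min_overlap`
#' and mismatch rate <= `max_mismatch_rate`. The insert is everything before
#' that occurrence. Reads in which no 3' adapter is found are dropped, because
#' their insert may run past the read end. If `adapter5` is non-empty, any
#' residual 5' adapter suffix at the start of the insert is removed in the
#' same way.
#'
#' @param reads data.frame from [read_reads()].
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 optional 5' adapter sequence ("" to skip).
#' @param min_overlap minimum adapter overlap in nt (default 6).
#' @param max_mismatch_rate maximum mismatches/overlap (default 0.1).
#' @return data.frame of trimmed reads, input order preserved.
#' @export
trim_adapters <- function(reads, adapter3, adapter5 = "", min_overlap = 6,
                          max_mismatch_rate = 0.1) {
  if (missing(adapter3) || is.na(adapter3) || nchar(adapter3) == 0)
    stop("adapter3 must be a non-empty sequence", call. = FALSE)
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  if (nrow(reads) == 0) return(reads)
  adapter3 <- norm_seq(adapter3)
  ins_len <- .trim3_pos_cpp(reads$seq, adapter3, as.integer(min_overlap),
                            max_mismatch_rate)
  keep <- ins_len >= 0
  out <- reads[keep, , drop = FALSE]
  ins_len <- ins_len[keep]
  out$seq <- substr(out$seq, 1L, ins_len)
  out$qual <- ifelse(is.na(out$qual), out$qual, substr(out$qual, 1L, ins_len))
  if (!is.na(adapter5) && nzchar(adapter5) && nrow(out) > 0) {
    adapter5 <- norm_seq(adapter5)
    cut5 <- .trim5_len_cpp(out$seq, adapter5, as.integer(min_overlap),
                           max_mismatch_rate)
    out$seq <- substr(out$seq, cut5 + 1L, nchar(out$seq))
    out$qual <- ifelse(is.na(out$qual), out$qual,
                       substr(out$qual, cut5 + 1L, nchar(out$qual)))
  }
  row.names(out) <- NULL
  out
}

#' Filter reads on base-call quality and N content
#'
#' Reads whose mean Phred score falls below `min_mean_quality`, or whose
#' fraction of N bases exceeds `max_n_fraction`, are removed. Reads without
#' quality strings (FASTA input) are filtered on N content only.
#'
#' @param reads data.frame of reads.
#' @param min_mean_quality minimum mean Phred score (default 20).
#' @param max_n_fraction maximum N fraction (default 0: no N allowed).
#' @return filtered data.frame.
#' @export
quality_filter <- function(reads, min_mean_quality = 20, max_n_fraction = 0) {
  if (nrow(reads) == 0) return(reads)
  n_frac <- vapply(gregexpr("N", reads$seq, fixed = TRUE), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1)) / pmax(nchar(reads$seq), 1L)
  ok_n <- n_frac <= max_n_fraction
  ok_q <- rep(TRUE, nrow(reads))
  has_q <- !is.na(reads$qual) & nchar(reads$qual) > 0
  if (any(has_q)) {
    mq <- vapply(reads$qual[has_q],
                 function(q) mean(utf8ToInt(q) - 33L), numeric(1),
                 USE.NAMES = FALSE)
    ok_q[has_q] <- mq >= min_mean_quality
  }
  out <- reads[ok_n & ok_q, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Retain sequences within a length window
#'
#' Works on raw reads (column `seq`) and on collapsed tags (column
#' `sequence`) alike. Default bounds are the informatic filter used ahead of
#' genome mapping.
#'
#' @param x data.frame of reads or tags.
#' @param min_len,max_len inclusive bounds in nt (defaults 18 and 30).
#' @return filtered data.frame of the same kind.
#' @export
length_filter <- function(x, min_len = 18, max_len = 30) {
  if (min_len > max_len)
    stop("min_len must be <= max_len", call. = FALSE)
  col <- if ("sequence" %in% names(x)) "sequence" else "seq"
  len <- nchar(x[[col]])
  out <- x[len >= min_len & len <= max_len, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Remove poly-A-tail artifacts
#'
#' Drops sequences whose A content reaches `max_a_fraction` or that end in a
#' run of at least `min_terminal_a_run` A's; these are library-preparation
#' tails, not genuine small RNAs.
#'
#' @param x data.frame of reads or tags.
#' @param max_a_fraction A-content threshold (default 0.8).
#' @param min_terminal_a_run terminal A-run threshold in nt (default 8).
#' @return filtered data.frame.
#' @export
filter_polya <- function(x, max_a_fraction = 0.8, min_terminal_a_run = 8) {
  col <- if ("sequence" %in% names(x)) "sequence" else "seq"
  s <- x[[col]]
  a_frac <- (nchar(s) - nchar(gsub("A", "", s, fixed = TRUE))) / pmax(nchar(s), 1L)
  tail_run <- grepl(paste0("A{", min_terminal_a_run, ",}$"), s)
  out <- x[a_frac < max_a_fraction & !tail_run, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Collapse cleaned reads into unique tags with redundancy counts
#'
#' One tag per distinct sequence; `read_count` is the number of input reads
#' carrying that sequence, so the sum of `read_count` equals the number of
#' input reads exactly. Output order is deterministic: descending
#' `read_count`, then lexicographic sequence.
#'
#' @param reads data.frame of cleaned reads.
#' @return data.frame with columns `sequence`, `length`, `read_count`.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0) {
    return(data.frame(sequence = character(), length = integer(),
                      read_count = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(reads$seq)
  out <- data.frame(sequence = names(tab),
                    length = nchar(names(tab)),
                    read_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$read_count, out$sequence), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Read-count-weighted length distribution of a tag library
#'
#' @param tags collapsed tags from [collapse_reads()].
#' @param min_len,max_len histogram support (defaults 15 and 30 nt).
#' @return data.frame with columns `length`, `unique_count`,
#'   `redundant_count`, `redundant_fraction`. Fractions are computed over the
#'   total redundant reads; lengths outside the support are ignored.
#' @export
length_distribution <- function(tags, min_len = 15, max_len = 30) {
  if (nrow(tags) == 0)
    stop("length_distribution: empty tag set", call. = FALSE)
  lens <- min_len:max_len
  uc <- vapply(lens, function(l) sum(tags$length == l), integer(1))
  rc <- vapply(lens, function(l) sum(tags$read_count[tags$length == l]),
               numeric(1))
  total <- sum(rc)
  data.frame(length = lens, unique_count = uc,
             redundant_count = as.integer(rc),
             redundant_fraction = if (total > 0) rc / total else rep(0, length(lens)))
}

#' Write / read collapsed-tag FASTA
#'
#' Uses the common small-RNA "collapsed" header dialect
#' `tag{serial}_x{read_count}`.
#'
#' @param tags collapsed tag data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path) {
  x <- Biostrings::DNAStringSet(tags$sequence)
  names(x) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$read_count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_collapsed_fasta
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  cnt <- suppressWarnings(as.integer(sub(".*_x([0-9]+)\\s*$", "\\1", names(x))))
  if (anyNA(cnt))
    stop("headers are not in tag{serial}_x{count} form", call. = FALSE)
  data.frame(sequence = norm_seq(as.character(x)),
             length = Biostrings::width(x),
             read_count = cnt, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a length histogram as TSV
#'
#' @param hist data.frame from [length_distribution()].
#' @param path output file.
#' @export
write_length_histogram <- function(hist, path) {
  utils::write.table(hist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-call read cleaning
#'
#' Convenience wrapper chaining adapter trimming, quality filtering, poly-A
#' removal, length filtering and collapsing, in that order.
#'
#' @param reads raw reads data.frame.
#' @param adapter3,adapter5 adapter sequences (see [trim_adapters()]).
#' @param min_len,max_len length bounds (defaults 18 and 30).
#' @param min_mean_quality,max_n_fraction see [quality_filter()].
#' @return collapsed tag data.frame.
#' @export
clean_reads <- function(reads, adapter3, adapter5 = "", min_len = 18,
                        max_len = 30, min_mean_quality = 20,
                        max_n_fraction = 0) {
  reads <- trim_adapters(reads, adapter3, adapter5)
  reads <- quality_filter(reads, min_mean_quality, max_n_fraction)
  reads <- filter_polya(reads)
  reads <- length_filter(reads, min_len, max_len)
  collapse_reads(reads)
}
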