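#' Default criteria for hairpin-based miRNA annotation
#'
#' Thresholds used by [evaluate_candidate()]: MFE at most `mfe_threshold`
#' kcal/mol, precursor length within `[min_len, max_len]` nt, at most
#' `max_mature_unpaired` unpaired mature bases, mature entirely on one arm of
#' a single stem-loop. Sequenced miRNA* support is recorded as evidence but
#' is not a gate.
#'
#' @param mfe_threshold MFE acceptance threshold (default -18 kcal/mol).
#' @param min_len,max_len precursor length bounds (defaults 60 and 320 nt).
#' @param max_mature_unpaired unpaired-mature-base budget (default 4).
#' @param max_bulge_asymmetry largest asymmetric bulge (in nt) tolerated in
#'   the mature:star duplex (default 2, per the annotation convention that
#'   duplex bulges be at most one or two bases); larger asymmetric interior
#'   loops mark pseudo-hairpins assembled from scattered complementarity.
#' @return named list of criteria settings.
#' @export
hairpin_criteria <- function(mfe_threshold = -18, min_len = 60, max_len = 320,
                             max_mature_unpaired = 4,
                             max_bulge_asymmetry = 2) {
  list(mfe_threshold = mfe_threshold, min_len = min_len, max_len = max_len,
       max_mature_unpaired = max_mature_unpaired,
       max_bulge_asymmetry = max_bulge_asymmetry)
}

#' Enumerate genomic windows around a mature-tag locus
#'
#' Windows extend the mature locus upstream-only, downstream-only and on both
#' sides, in `step`-nt increments up to `max_flank` nt per side (the zero/zero
#' window is skipped). Windows are strand-aware: minus-strand windows are
#' reverse complemented so the mature always reads 5' to 3' inside the window
#' sequence; windows are clipped at chromosome ends.
#'
#' @param locus one-row data.frame (`chrom`, `start`, `end`, `strand`).
#' @param genome `DNAStringSet`.
#' @param max_flank maximum flank per side in nt (default 280).
#' @param step flank increment in nt (default 20).
#' @return data.frame: `chrom`, `start`, `end`, `strand`, `seq`,
#'   `mature_start`, `mature_end` (mature span in window coordinates).
#' @export
excise_precursor_windows <- function(locus, genome, max_flank = 280,
                                     step = 20) {
  if (max_flank < 20) stop("max_flank must be >= 20", call. = FALSE)
  chrom <- locus$chrom
  if (!chrom %in% names(genome))
    stop("locus chromosome not in genome", call. = FALSE)
  chrlen <- Biostrings::width(genome[chrom])
  if (locus$start < 1 || locus$end > chrlen)
    stop("locus outside genome", call. = FALSE)
  flanks <- seq(0, max_flank, by = step)
  grid <- expand.grid(up = flanks, down = flanks)
  grid <- grid[grid$up + grid$down > 0, , drop = FALSE]
  # upstream is 5' of the mature in transcript orientation
  if (locus$strand == "+") {
    ws <- pmax(1L, locus$start - grid$up)
    we <- pmin(chrlen, locus$end + grid$down)
  } else {
    ws <- pmax(1L, locus$start - grid$down)
    we <- pmin(chrlen, locus$end + grid$up)
  }
  keep <- !duplicated(paste(ws, we))
  ws <- ws[keep]; we <- we[keep]
  seqs <- as.character(Biostrings::subseq(
    rep(genome[chrom], length(ws)), start = ws, end = we))
  if (locus$strand == "-") seqs <- revcomp(seqs)
  if (locus$strand == "+") {
    ms <- locus$start - ws + 1L
  } else {
    ms <- we - locus$end + 1L
  }
  me <- ms + (locus$end - locus$start)
  data.frame(chrom = chrom, start = ws, end = we, strand = locus$strand,
             seq = seqs, mature_start = ms, mature_end = me,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Locate the miRNA* of a mature sequence within a fold
#'
#' The star span follows the pair-table partners of the mature (bulges
#' skipped), shifted to give the canonical 2-nt 3' overhang on each strand of
#' the Dicer duplex: partners of mature positions 1..(len-2) are taken and
#' the star is extended by 2 nt at its own 3' end.
#'
#' @param fold a `fold_result` (see [fold()]).
#' @param mature_start,mature_end mature span in fold coordinates.
#' @return list with `start`, `end`, `sequence`, or NULL when fewer than 60%
#'   of the relevant mature bases are paired.
#' @export
star_sequence <- function(fold, mature_start, mature_end) {
  pt <- fold$pair_table
  n <- length(pt)
  core <- mature_start:max(mature_start, mature_end - 2L)
  partners <- pt[core]
  partners <- partners[partners > 0]
  if (length(partners) < 0.6 * length(core)) return(NULL)
  lo <- min(partners)
  hi <- min(n, max(partners) + 2L)
  list(start = lo, end = hi,
       sequence = substr(fold$sequence, lo, hi))
}

#' Adjudicate a precursor window against the annotation criteria
#'
#' Evaluates the named criteria on a folded window: (`mfe`) minimum free
#' energy at most the threshold; (`arm`) the mature lies entirely on one arm
#' of a single stem-loop, with no mature base inside a hairpin loop and all
#' paired mature partners on one side across exactly one terminal loop;
#' (`pairing`) at most `max_mature_unpaired` unpaired mature bases;
#' (`length`) precursor length within bounds; (`duplex`) the mature:star
#' duplex contains no asymmetric bulge larger than `max_bulge_asymmetry` nt.
#' Acceptance requires all five.
#' The miRNA* is searched in the tag library by exact sequence equality and
#' recorded as supporting evidence (`star_reads`), never as a gate — genuine
#' miRNAs frequently lack a sequenced star.
#'
#' @param window_fold `fold_result` of the window sequence.
#' @param mature_start,mature_end mature span within the window (1-based).
#' @param tag_library collapsed tag data.frame used for star lookup (NULL to
#'   skip).
#' @param criteria list from [hairpin_criteria()].
#' @return list of class `hairpin_candidate`: mature/star sequences, arm
#'   (5p/3p or NA), `criteria_flags`, `stem_loop_length`, `mfe`, `accepted`.
#' @export
evaluate_candidate <- function(window_fold, mature_start, mature_end,
                               tag_library = NULL,
                               criteria = hairpin_criteria()) {
  n <- nchar(window_fold$sequence)
  if (mature_start < 1 || mature_end > n || mature_start > mature_end)
    stop("mature span outside window", call. = FALSE)
  pt <- window_fold$pair_table
  m <- mature_start:mature_end
  flags <- c(mfe = window_fold$mfe <= criteria$mfe_threshold,
             arm = FALSE, pairing = FALSE,
             length = n >= criteria$min_len && n <= criteria$max_len,
             duplex = FALSE)
  arm <- NA_character_
  paired <- m[pt[m] > 0]
  unpaired_n <- length(m) - length(paired)
  flags["pairing"] <- unpaired_n <= criteria$max_mature_unpaired
  loops <- hairpin_loops(pt)
  in_loop <- any(vapply(loops, function(l) any(m %in% l), logical(1)))
  if (length(paired) > 0 && !in_loop) {
    partners <- pt[paired]
    if (all(partners > max(m))) arm <- "5p"
    if (all(partners < min(m))) arm <- "3p"
    if (!is.na(arm)) {
      span <- range(c(m, partners))
      n_loops_between <- sum(vapply(loops, function(l)
        length(l) > 0 && min(l) > span[1] && max(l) < span[2], logical(1)))
      flags["arm"] <- n_loops_between == 1
    }
    if (length(paired) >= 2) {
      ord <- sort(paired)
      asym <- abs(diff(ord) - abs(diff(pt[ord])))
      flags["duplex"] <- all(asym <= criteria$max_bulge_asymmetry)
    }
  }
  star <- NULL; star_reads <- 0L
  if (flags["arm"]) {
    star <- star_sequence(window_fold, mature_start, mature_end)
    if (!is.null(star) && !is.null(tag_library)) {
      hit <- tag_library$sequence == star$sequence
      if (any(hit)) star_reads <- sum(tag_library$read_count[hit])
    }
  }
  res <- list(mature_seq = substr(window_fold$sequence, mature_start,
                                  mature_end),
              mature_start = mature_start, mature_end = mature_end,
              precursor_seq = window_fold$sequence,
              fold = window_fold, arm = arm,
              star_seq = if (is.null(star)) NA_character_ else star$sequence,
              star_reads = star_reads,
              criteria_flags = flags,
              stem_loop_length = n, mfe = window_fold$mfe,
              accepted = all(flags))
  class(res) <- "hairpin_candidate"
  res
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("hairpin candidate (", if (x$accepted) "accepted" else "rejected",
      ")\n  mature: ", x$mature_seq, " [", x$arm, "]\n  precursor: ",
      x$stem_loop_length, " nt, MFE ", format(x$mfe), " kcal/mol\n",
      "  criteria: ",
      paste(names(x$criteria_flags),
            ifelse(x$criteria_flags, "pass", "FAIL"), collapse = ", "),
      "\n  star reads: ", x$star_reads, "\n", sep = "")
  invisible(x)
}

#' Choose the best accepted candidate among a tag's windows
#'
#' Lowest MFE wins; ties go to the shortest precursor, then the smallest
#' window start.
#'
#' @param candidates list of `hairpin_candidate` objects.
#' @param starts optional numeric window starts (for the final tie-break).
#' @return the chosen candidate, or NULL when none is accepted.
#' @export
select_best_candidate <- function(candidates, starts = seq_along(candidates)) {
  acc <- which(vapply(candidates, function(x) isTRUE(x$accepted), logical(1)))
  if (!length(acc)) return(NULL)
  mfe <- vapply(candidates[acc], `[[`, numeric(1), "mfe")
  len <- vapply(candidates[acc], `[[`, numeric(1), "stem_loop_length")
  ord <- order(mfe, len, starts[acc])
  candidates[[acc[ord[1]]]]
}

#' Discover novel miRNA candidates from unannotated mapped tags
#'
#' For every tag with at least `min_reads` reads, each genomic locus is
#' expanded into flanking windows ([excise_precursor_windows()]), folded, and
#' adjudicated ([evaluate_candidate()]); the best accepted window per locus
#' is kept.
#'
#' @param tags mapped tag data.frame (typically the unannotated,
#'   conserved-unassigned subset).
#' @param genome `DNAStringSet`.
#' @param tag_library full tag library for miRNA* lookup (defaults to
#'   `tags`).
#' @param criteria list from [hairpin_criteria()].
#' @param min_reads minimum read support to attempt discovery (default 5).
#' @param max_flank,step window enumeration parameters.
#' @param engine,external_cmd folding engine (see [fold()]).
#' @return list with `candidates` (list of accepted `hairpin_candidate`s)
#'   and `table` (one row per accepted locus: `sequence`, `read_count`,
#'   `stem_loop_length`, `start_in_chr`, `mfe`, `arm`, `star_found`,
#'   `star_reads`).
#' @export
discover_novel_mirnas <- function(tags, genome, tag_library = tags,
                                  criteria = hairpin_criteria(),
                                  min_reads = 5, max_flank = 280, step = 20,
                                  engine = "builtin", external_cmd = NULL) {
  cands <- list(); rows <- list()
  todo <- which(tags$read_count >= min_reads & tags$n_loci > 0)
  for (i in todo) {
    loci <- tags$loci[[i]]
    for (l in seq_len(nrow(loci))) {
      wins <- excise_precursor_windows(loci[l, ], genome, max_flank, step)
      evals <- vector("list", nrow(wins))
      for (w in seq_len(nrow(wins))) {
        if (grepl("N", wins$seq[w], fixed = TRUE)) next
        f <- fold(wins$seq[w], engine = engine, external_cmd = external_cmd)
        evals[[w]] <- evaluate_candidate(f, wins$mature_start[w],
                                         wins$mature_end[w], tag_library,
                                         criteria)
      }
      keep <- !vapply(evals, is.null, logical(1))
      best <- select_best_candidate(evals[keep], wins$start[keep])
      if (!is.null(best)) {
        cands[[length(cands) + 1L]] <- best
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = tags$sequence[i], read_count = tags$read_count[i],
          stem_loop_length = best$stem_loop_length,
          start_in_chr = paste0(loci$chrom[l], ":", loci$start[l]),
          mfe = best$mfe, arm = best$arm,
          star_found = best$star_reads > 0, star_reads = best$star_reads,
          stringsAsFactors = FALSE)
      }
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), read_count = integer(),
               stem_loop_length = integer(), start_in_chr = character(),
               mfe = numeric(), arm = character(), star_found = logical(),
               star_reads = integer(), stringsAsFactors = FALSE)
  list(candidates = cands, table = table)
}

#' 5' nucleotide composition of mature candidate sequences
#'
#' Plant miRNAs preferentially start with uridine; this tallies the mature 5'
#' base over the candidate set.
#'
#' @param sequences character vector of mature sequences.
#' @return data.frame with `base`, `count`, `fraction` over A/C/G/T.
#' @export
five_prime_composition <- function(sequences) {
  stopifnot(length(sequences) > 0)
  first <- substr(norm_seq(sequences), 1, 1)
  bases <- c("A", "C", "G", "T")
  cnt <- vapply(bases, function(b) sum(first == b), integer(1))
  data.frame(base = bases, count = cnt, fraction = cnt / sum(cnt),
             row.names = NULL)
}

#' Classify candidate novelty against known sequence sets
#'
#' A candidate is `shared` when it matches (within `max_mismatch`
#' substitutions and `terminal_slack` nt of terminal overhang) a sequence
#' known outside the Vitis genus, `vitis_specific` when it matches only the
#' supplied Vitis set, and `species_specific` otherwise.
#'
#' @param sequences character vector of candidate mature sequences.
#' @param vitis_known,other_species_known data.frames with a `sequence`
#'   column (may be empty).
#' @param max_mismatch substitution budget (default 2).
#' @param terminal_slack terminal overhang budget (default 2).
#' @return character vector of classes, one per candidate.
#' @export
classify_novelty <- function(sequences, vitis_known, other_species_known,
                             max_mismatch = 2, terminal_slack = 2) {
  hits <- function(known) {
    if (is.null(known) || nrow(known) == 0)
      return(rep(FALSE, length(sequences)))
    m <- .match_known_cpp(norm_seq(sequences), norm_seq(known$sequence),
                          as.integer(max_mismatch),
                          as.integer(terminal_slack))
    m[, 1] > 0
  }
  in_other <- hits(other_species_known)
  in_vitis <- hits(vitis_known)
  ifelse(in_other, "shared",
         ifelse(in_vitis, "vitis_specific", "species_specific"))
}
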