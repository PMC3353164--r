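#' Annotation category vocabulary
#'
#' The controlled set of small-RNA annotation categories used by
#' [classify_tags()] and [summarize_categories()], in report order.
#' @export
ANNOT_CATEGORIES <- c("exon_antisense", "exon_sense", "intron_antisense",
                      "intron_sense", "miRNA", "rRNA", "repeat", "siRNA",
                      "snRNA", "snoRNA", "tRNA", "unann")

# Classification precedence: structural RNA wins over gene-model categories;
# miRNA first because it is assigned from sequence (known-mature matching),
# not from a genomic track.
CATEGORY_PRECEDENCE <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                         "siRNA", "exon_sense", "exon_antisense",
                         "intron_sense", "intron_antisense", "unann")

TRACK_CATEGORIES <- c("exon", "intron", "rRNA", "tRNA", "snRNA", "snoRNA",
                      "repeat")

#' Load a genome FASTA
#'
#' @param path FASTA file.
#' @return named `DNAStringSet`; header descriptions after the first
#'   whitespace are stripped.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Load annotation tracks from GFF3
#'
#' Feature types are mapped to annotation categories through `type_map`;
#' the default map recognises the standard exon/intron/structural-RNA/repeat
#' types. A feature whose mapped category is not in the controlled vocabulary
#' is a configuration error.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param type_map named character vector, GFF3 `type` -> category.
#' @return `GRanges` with a `category` metadata column.
#' @export
read_tracks_gff <- function(path, type_map = NULL) {
  if (is.null(type_map)) {
    type_map <- c(exon = "exon", intron = "intron", rRNA = "rRNA",
                  tRNA = "tRNA", snRNA = "snRNA", snoRNA = "snoRNA",
                  repeat_region = "repeat", `repeat` = "repeat")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  cat <- unname(type_map[type])
  if (anyNA(cat) || !all(cat %in% TRACK_CATEGORIES))
    stop("unknown feature category in annotation track: ",
         paste(unique(type[is.na(cat) | !cat %in% TRACK_CATEGORIES]),
               collapse = ", "), call. = FALSE)
  S4Vectors::mcols(gr)$category <- cat
  gr
}

#' Map tags to the genome by exact full-length matching
#'
#' Every exact, ungapped, full-length occurrence of each tag is recorded:
#' forward-strand matches as `+`, reverse-complement matches as `-`.
#' Multi-locus tags keep all loci; tags with no occurrence get an empty locus
#' set. Coordinates are 1-based inclusive.
#'
#' @param tags collapsed tag data.frame.
#' @param genome `DNAStringSet` (or path to a FASTA file).
#' @return `tags` with added integer column `n_loci` and list-column `loci`
#'   (each element a data.frame `chrom`, `start`, `end`, `strand`).
#' @export
map_to_genome <- function(tags, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (length(genome) == 0) stop("empty genome", call. = FALSE)
  n <- nrow(tags)
  rows <- list()
  for (len in unique(tags$length)) {
    idx <- which(tags$length == len)
    fwd <- Biostrings::DNAStringSet(tags$sequence[idx])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (ch in seq_along(genome)) {
      chrom <- names(genome)[ch]
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPDict(if (strand == "+") pd_f else pd_r,
                                    genome[[ch]])
        starts <- BiocGenerics::start(m)
        hit <- which(lengths(starts) > 0)
        for (h in hit) {
          st <- starts[[h]]
          rows[[length(rows) + 1L]] <- data.frame(
            tag = idx[h], chrom = chrom, start = st,
            end = st + len - 1L, strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  all_loci <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag = integer(), chrom = character(), start = integer(),
               end = integer(), strand = character(), stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  loci <- rep(list(empty), n)
  if (nrow(all_loci)) {
    all_loci <- all_loci[order(all_loci$tag, all_loci$chrom, all_loci$start,
                               all_loci$strand), , drop = FALSE]
    sp <- split(all_loci[, -1], all_loci$tag)
    for (k in names(sp)) {
      d <- sp[[k]]
      row.names(d) <- NULL
      loci[[as.integer(k)]] <- d
    }
  }
  tags$n_loci <- vapply(loci, nrow, integer(1))
  tags$loci <- I(loci)
  tags
}

# GRanges of all loci of mapped tags, with a tag-index metadata column.
loci_granges <- function(tags) {
  keep <- which(tags$n_loci > 0)
  if (!length(keep)) {
    return(GenomicRanges::GRanges())
  }
  d <- do.call(rbind, lapply(keep, function(i) cbind(tags$loci[[i]], tag = i)))
  GenomicRanges::GRanges(d$chrom,
                         IRanges::IRanges(d$start, d$end),
                         strand = d$strand, tag = d$tag)
}

#' Assign each tag to a single annotation category
#'
#' Mapped tags are classified by precedence
#' miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > siRNA > exon > intron >
#' unann. The miRNA category is sequence-based: tags listed in
#' `known_mirna_hits` (sequences assigned to a known mature miRNA, see
#' [match_known()]) are miRNA regardless of genomic context. Sense/antisense
#' for exon and intron is decided by the tag strand versus the feature
#' strand; a multi-locus tag is classified once, by the highest-precedence
#' category over all its loci. The optional siRNA rule marks 21-24 nt tags
#' whose locus is overlapped, on the opposite strand, by the locus of another
#' mapped tag. Tags overlapping no feature (and unmapped tags) are `unann`.
#'
#' @param tags mapped tags from [map_to_genome()].
#' @param tracks `GRanges` with a `category` column ([read_tracks_gff()]),
#'   or NULL for no tracks.
#' @param known_mirna_hits character vector of tag sequences assigned to
#'   known mature miRNAs.
#' @param sirna_rule logical; apply the double-stranded siRNA signature rule.
#' @return `tags` with an added `category` column.
#' @export
classify_tags <- function(tags, tracks = NULL, known_mirna_hits = character(),
                          sirna_rule = TRUE) {
  if (!"loci" %in% names(tags))
    stop("tags must be mapped first (see map_to_genome)", call. = FALSE)
  if (!is.null(tracks)) {
    bad <- setdiff(unique(tracks$category), TRACK_CATEGORIES)
    if (length(bad))
      stop("unknown track category: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  n <- nrow(tags)
  # candidate categories per tag, filled from loci overlaps
  cand <- vector("list", n)
  gr <- loci_granges(tags)
  if (!is.null(tracks) && length(gr) && length(tracks)) {
    ov <- GenomicRanges::findOverlaps(gr, tracks, ignore.strand = TRUE)
    if (length(ov)) {
      ti <- gr$tag[S4Vectors::queryHits(ov)]
      fcat <- tracks$category[S4Vectors::subjectHits(ov)]
      same <- as.character(GenomicRanges::strand(gr))[S4Vectors::queryHits(ov)] ==
        as.character(GenomicRanges::strand(tracks))[S4Vectors::subjectHits(ov)]
      lab <- ifelse(fcat %in% c("exon", "intron"),
                    paste0(fcat, ifelse(same, "_sense", "_antisense")), fcat)
      for (k in seq_along(ti))
        cand[[ti[k]]] <- c(cand[[ti[k]]], lab[k])
    }
  }
  if (sirna_rule && length(gr) > 1) {
    ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    opp <- as.character(GenomicRanges::strand(gr))[qh] !=
      as.character(GenomicRanges::strand(gr))[sh]
    other <- gr$tag[qh] != gr$tag[sh]
    si_tags <- unique(gr$tag[qh[opp & other]])
    si_tags <- si_tags[tags$length[si_tags] >= 21 & tags$length[si_tags] <= 24]
    for (i in si_tags) cand[[i]] <- c(cand[[i]], "siRNA")
  }
  if (length(known_mirna_hits)) {
    hit <- tags$sequence %in% known_mirna_hits
    for (i in which(hit)) cand[[i]] <- c(cand[[i]], "miRNA")
  }
  tags$category <- vapply(cand, function(cc) {
    if (is.null(cc)) return("unann")
    CATEGORY_PRECEDENCE[min(match(cc, CATEGORY_PRECEDENCE))]
  }, character(1))
  tags
}

#' Per-category unique/redundant summary table
#'
#' Accepts either per-tag assignments (columns `category` and `read_count`,
#' as produced by [classify_tags()]) or a pre-tabulated count table (columns
#' `category`, `unique_count`, `redundant_count`). Percentages are
#' `100 * count / total` rounded to two decimals; a `total` row closes the
#' table. Unique counts sum to the number of tags, redundant counts to the
#' number of reads, by construction.
#'
#' @param x data.frame as described above.
#' @return data.frame with columns `category`, `unique_count`,
#'   `unique_percent`, `redundant_count`, `redundant_percent`.
#' @export
summarize_categories <- function(x) {
  if (all(c("unique_count", "redundant_count") %in% names(x))) {
    tab <- x[, c("category", "unique_count", "redundant_count")]
  } else {
    stopifnot(all(c("category", "read_count") %in% names(x)))
    tab <- data.frame(
      category = ANNOT_CATEGORIES,
      unique_count = vapply(ANNOT_CATEGORIES, function(cc)
        sum(x$category == cc), integer(1)),
      redundant_count = vapply(ANNOT_CATEGORIES, function(cc)
        sum(x$read_count[x$category == cc]), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  bad <- setdiff(tab$category, ANNOT_CATEGORIES)
  if (length(bad))
    stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  tab <- tab[match(intersect(ANNOT_CATEGORIES, tab$category), tab$category), ,
             drop = FALSE]
  ut <- sum(tab$unique_count); rt <- sum(tab$redundant_count)
  out <- data.frame(category = tab$category,
                    unique_count = tab$unique_count,
                    unique_percent = pct(tab$unique_count, ut),
                    redundant_count = tab$redundant_count,
                    redundant_percent = pct(tab$redundant_count, rt),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(category = "total", unique_count = ut,
                        unique_percent = 100,
                        redundant_count = rt, redundant_percent = 100))
}
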