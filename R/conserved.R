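#' Read a miRBase-style mature miRNA FASTA
#'
#' Headers are expected to start with the mature id (e.g. `vvi-miR156a`);
#' U is normalized to T at load time. Family and species labels are parsed
#' from the id.
#'
#' @param path FASTA of mature sequences.
#' @return data.frame with columns `id`, `family`, `species`, `sequence`.
#' @export
read_mature_fasta <- function(path) {
  # BStringSet: miRBase mature files are RNA-alphabet, normalized below
  x <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, family = mir_family(ids), species = mir_species(ids),
             sequence = norm_seq(as.character(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign tags to known mature miRNAs
#'
#' For each tag, all ungapped alignments in which the shorter of tag and
#' known mature lies within the longer are scored; substitutions are counted
#' over the overlap and the terminal overhang (the length difference) must
#' not exceed `terminal_slack`. The best assignment has the fewest
#' substitutions, then the smallest total overhang, then the
#' lexicographically smallest known id. Tags with no qualifying alignment are
#' left unassigned.
#'
#' @param tags collapsed tag data.frame.
#' @param known_set data.frame from [read_mature_fasta()] (or with columns
#'   `id`, `sequence`; `family` is derived when missing).
#' @param max_substitutions substitution budget (default 3).
#' @param terminal_slack total terminal overhang budget in nt (default 3).
#' @return data.frame with one row per assigned tag: `sequence`,
#'   `read_count`, `known_id`, `family`, `known_seq`, `substitutions`,
#'   `offset5`, `offset3` (offsets positive where the known extends beyond
#'   the tag).
#' @export
match_known <- function(tags, known_set, max_substitutions = 3,
                        terminal_slack = 3) {
  if (is.null(known_set) || nrow(known_set) == 0)
    stop("empty known mature set", call. = FALSE)
  known_set$sequence <- norm_seq(known_set$sequence)
  if (is.null(known_set$family)) known_set$family <- mir_family(known_set$id)
  known_set <- known_set[order(known_set$id), , drop = FALSE]
  m <- .match_known_cpp(tags$sequence, known_set$sequence,
                        as.integer(max_substitutions),
                        as.integer(terminal_slack))
  hit <- m[, 1] > 0
  idx <- m[hit, 1]
  data.frame(sequence = tags$sequence[hit],
             read_count = tags$read_count[hit],
             known_id = known_set$id[idx],
             family = known_set$family[idx],
             known_seq = known_set$sequence[idx],
             substitutions = m[hit, 2],
             offset5 = m[hit, 3], offset3 = m[hit, 4],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-member and per-family abundance of assigned miRNAs
#'
#' Member abundance is the summed read count of all tags assigned to that
#' known mature; family abundance sums over members.
#'
#' @param assignments data.frame from [match_known()].
#' @return list with data.frames `members` (`known_id`, `family`,
#'   `read_count`) and `families` (`family`, `read_count`), both sorted by
#'   descending abundance then label.
#' @export
family_abundance <- function(assignments) {
  mem <- stats::aggregate(read_count ~ known_id + family, data = assignments,
                          FUN = sum)
  mem <- mem[order(-mem$read_count, mem$known_id), c("known_id", "family",
                                                     "read_count")]
  fam <- stats::aggregate(read_count ~ family, data = assignments, FUN = sum)
  fam <- fam[order(-fam$read_count, fam$family), , drop = FALSE]
  row.names(mem) <- row.names(fam) <- NULL
  list(members = mem, families = fam)
}

#' Terminal divergence between two orthologous mature sequences
#'
#' Over all ungapped relative offsets, the alignment maximizing the number of
#' matched core positions is chosen (ties: fewest internal substitutions,
#' then smallest 5' divergence). `d5` and `d3` are the unmatched terminal
#' lengths summed over both sequences at the 5' and 3' ends;
#' `internal_substitutions` counts mismatches inside the aligned core.
#'
#' @param seq_a,seq_b mature sequences (RNA or DNA alphabet).
#' @return one-row data.frame: `d5`, `d3`, `internal_substitutions`,
#'   `core_length`.
#' @export
terminal_divergence <- function(seq_a, seq_b) {
  a <- norm_seq(seq_a); b <- norm_seq(seq_b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  la <- nchar(a); lb <- nchar(b)
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  best <- NULL
  # offset o: position i of a aligns position i - o of b
  for (o in (-(lb - 1)):(la - 1)) {
    i1 <- max(1, 1 + o); i2 <- min(la, lb + o)
    if (i2 < i1) next
    core <- i2 - i1 + 1
    subs <- sum(va[i1:i2] != vb[(i1 - o):(i2 - o)])
    matched <- core - subs
    d5 <- (i1 - 1) + (i1 - o - 1)
    d3 <- (la - i2) + (lb - (i2 - o))
    cand <- c(matched = matched, subs = subs, d5 = d5, d3 = d3, core = core)
    if (is.null(best) ||
        cand["matched"] > best["matched"] ||
        (cand["matched"] == best["matched"] && cand["subs"] < best["subs"]) ||
        (cand["matched"] == best["matched"] && cand["subs"] == best["subs"] &&
         cand["d5"] < best["d5"])) {
      best <- cand
    }
  }
  data.frame(d5 = unname(best["d5"]), d3 = unname(best["d3"]),
             internal_substitutions = unname(best["subs"]),
             core_length = unname(best["core"]))
}

#' Terminal divergence table for a list of ortholog pairs
#'
#' @param pairs data.frame with columns `id`, `seq_a`, `seq_b`.
#' @return data.frame with one row per pair: `id`, `seq_a`, `seq_b`, `d5`,
#'   `d3`, `internal_substitutions`, `core_length`, `total_divergence`
#'   (`d5 + d3`).
#' @export
divergence_table <- function(pairs) {
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    terminal_divergence(pairs$seq_a[i], pairs$seq_b[i])))
  out <- cbind(pairs[, c("id", "seq_a", "seq_b")], res)
  out$total_divergence <- out$d5 + out$d3
  row.names(out) <- NULL
  out
}

#' Family presence/absence matrix across species
#'
#' A family is present in a species iff the species' supplied mature set
#' contains at least one member whose id parses to that family.
#'
#' @param families character vector of family labels (e.g. "miR156").
#' @param species_mature_sets named list of data.frames (each with an `id`
#'   column, as from [read_mature_fasta()]).
#' @return logical matrix, families x species.
#' @export
family_presence_matrix <- function(families, species_mature_sets) {
  stopifnot(length(families) > 0)
  m <- matrix(FALSE, nrow = length(families),
              ncol = length(species_mature_sets),
              dimnames = list(families, names(species_mature_sets)))
  for (sp in names(species_mature_sets)) {
    fams <- unique(mir_family(species_mature_sets[[sp]]$id))
    m[, sp] <- families %in% fams
  }
  m
}

#' Write a presence matrix as a "+"/"-" TSV
#'
#' @param m logical matrix from [family_presence_matrix()].
#' @param path output file.
#' @export
write_presence_matrix <- function(m, path) {
  d <- data.frame(family = rownames(m),
                  ifelse(m, "+", "-"), check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
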