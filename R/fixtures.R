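#' Bundled Amur grape reference tables
#'
#' Small reference tables from the Amur grape (Vitis amurensis) deep-
#' sequencing small-RNA survey this package models, shipped as plain TSV
#' under `inst/extdata`:
#' `amur_category_counts()` returns the published per-category unique and
#' redundant read counts; `amur_ortholog_pairs()` the mature-sequence pairs
#' with terminal divergence between Amur grape and Vitis vinifera
#' (`"vinifera"`) or the 'Summer Black' hybrid (`"summer_black"`);
#' `amur_novel_mirnas()` the catalog of non-conserved miRNA candidates
#' (sequence, reads, stem-loop length, genomic start, MFE, star evidence).
#'
#' @return a data.frame (see above).
#' @export
amur_category_counts <- function() {
  utils::read.delim(system.file("extdata", "amur_category_counts.tsv",
                                package = "vamir"),
                    stringsAsFactors = FALSE)
}

#' @rdname amur_category_counts
#' @param set which ortholog comparison to load.
#' @export
amur_ortholog_pairs <- function(set = c("vinifera", "summer_black")) {
  set <- match.arg(set)
  f <- if (set == "vinifera") "amur_vinifera_orthologs.tsv" else
    "amur_summerblack_orthologs.tsv"
  utils::read.delim(system.file("extdata", f, package = "vamir"),
                    stringsAsFactors = FALSE)
}

#' @rdname amur_category_counts
#' @export
amur_novel_mirnas <- function() {
  d <- utils::read.delim(system.file("extdata", "amur_novel_mirnas.tsv",
                                     package = "vamir"),
                         stringsAsFactors = FALSE)
  d$star <- d$star == "Y"
  # multi-locus candidates carry -1..-n suffixes; the stem is the candidate id
  d$candidate_id <- sub("-[0-9]+$", "", d$id)
  d
}
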