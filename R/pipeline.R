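#' Pipeline configuration
#'
#' Central, validated parameter set for [run_pipeline()]. Unknown keys are
#' rejected.
#'
#' @param adapter3,adapter5 adapter sequences for read cleaning.
#' @param min_len,max_len informatic length filter (defaults 18 and 30 nt).
#' @param min_mean_quality,max_n_fraction quality filtering thresholds.
#' @param max_substitutions,terminal_slack known-mature matching budgets
#'   (defaults 3 and 3).
#' @param min_variant_reads minimum read support for a variant call.
#' @param max_shift_total miR-LD terminal-shift cap (default 4).
#' @param criteria hairpin acceptance criteria ([hairpin_criteria()]).
#' @param novel_min_reads minimum read support for hairpin discovery
#'   (default 10: candidate support down to which star evidence is
#'   realistically recoverable).
#' @param max_flank,step hairpin window enumeration (defaults 280 and 20 nt;
#'   scale `max_flank` down when the expected precursors are short).
#' @param engine,external_cmd folding engine selection (see [fold()]).
#' @param max_target_score,max_target_bulges,target_max_mismatches Allen-scan
#'   settings (see [scan_transcripts()]).
#' @param sirna_rule apply the double-stranded siRNA category rule.
#' @param seed seed recorded in the run manifest.
#' @return list of class `vamir_config`.
#' @export
pipeline_config <- function(adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                            adapter5 = "", min_len = 18, max_len = 30,
                            min_mean_quality = 20, max_n_fraction = 0,
                            max_substitutions = 3, terminal_slack = 3,
                            min_variant_reads = 1, max_shift_total = 4,
                            criteria = hairpin_criteria(),
                            novel_min_reads = 10, max_flank = 280, step = 20,
                            engine = "builtin", external_cmd = NULL,
                            max_target_score = 4, max_target_bulges = 1,
                            target_max_mismatches = NULL, sirna_rule = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "vamir_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full small-RNA analysis pipeline
#'
#' Composes the stages in order: read cleaning, genome mapping, conserved
#' miRNA matching, annotation categorisation, variant scanning, novel
#' hairpin discovery, and (optionally) ortholog divergence and target
#' scanning. Conserved matching precedes novel discovery, so tags assigned
#' to known matures - and any tag with a genomic annotation - are excluded
#' from the hairpin-candidate input.
#'
#' @param reads raw reads data.frame ([read_reads()]) or path to
#'   FASTQ/FASTA.
#' @param genome `DNAStringSet` or FASTA path.
#' @param tracks `GRanges` with a `category` column, GFF3 path, or NULL.
#' @param known_matures data.frame (see [read_mature_fasta()]) or FASTA
#'   path.
#' @param transcripts optional transcript set for target scanning.
#' @param ortholog_pairs optional data.frame (`id`, `seq_a`, `seq_b`) for
#'   terminal-divergence analysis.
#' @param vitis_known,other_species_known optional comparison sets for
#'   novelty classification.
#' @param config a [pipeline_config()].
#' @return object of class `vamir_pipeline`: list with `tags`,
#'   `length_histogram`, `assignments`, `abundance`, `category_summary`,
#'   `variant_calls`, `snp_families`, `novel` (discovery output),
#'   `five_prime`, `novelty`, `divergence`, `target_hits`, `stage_counts`
#'   and `manifest`.
#' @export
run_pipeline <- function(reads, genome, tracks = NULL, known_matures = NULL,
                         transcripts = NULL, ortholog_pairs = NULL,
                         vitis_known = NULL, other_species_known = NULL,
                         config = pipeline_config()) {
  if (is.character(reads)) reads <- .stage("input", read_reads(reads))
  if (is.character(genome)) genome <- .stage("input", read_genome(genome))
  if (is.character(tracks)) tracks <- .stage("input", read_tracks_gff(tracks))
  if (is.character(known_matures))
    known_matures <- .stage("input", read_mature_fasta(known_matures))
  counts <- list(raw_reads = nrow(reads))

  tags <- .stage("clean", {
    r <- trim_adapters(reads, config$adapter3, config$adapter5)
    counts$adapter_trimmed <- nrow(r)
    r <- quality_filter(r, config$min_mean_quality, config$max_n_fraction)
    r <- filter_polya(r)
    r <- length_filter(r, config$min_len, config$max_len)
    counts$clean_reads <- nrow(r)
    collapse_reads(r)
  })
  counts$unique_tags <- nrow(tags)
  hist <- .stage("clean", length_distribution(tags))

  tags <- .stage("map", map_to_genome(tags, genome))
  counts$mapped_tags <- sum(tags$n_loci > 0)
  counts$mapped_reads <- sum(tags$read_count[tags$n_loci > 0])

  assignments <- NULL; abundance <- NULL
  if (!is.null(known_matures)) {
    assignments <- .stage("conserved",
                          match_known(tags, known_matures,
                                      config$max_substitutions,
                                      config$terminal_slack))
    abundance <- .stage("conserved", family_abundance(assignments))
    counts$conserved_tags <- nrow(assignments)
  }

  tags <- .stage("categorize", classify_tags(
    tags, tracks,
    known_mirna_hits = if (is.null(assignments)) character() else
      assignments$sequence,
    sirna_rule = config$sirna_rule))
  summary <- .stage("categorize", summarize_categories(
    tags[, c("category", "read_count")]))

  variant_calls <- NULL; snp_families <- NULL
  if (!is.null(assignments) && nrow(assignments)) {
    vs <- .stage("variants", scan_variants(assignments,
                                           config$min_variant_reads,
                                           config$max_shift_total))
    variant_calls <- vs
    snp_families <- .stage("variants", snp_family_distribution(vs$calls))
    counts$snp_types <- sum(vs$calls$kind == "miR-SNP")
    counts$ld_types <- sum(vs$calls$kind == "miR-LD")
  }

  novel <- .stage("novel", {
    cand_tags <- tags[tags$category == "unann" & tags$n_loci > 0 &
                        tags$read_count >= config$novel_min_reads, ,
                      drop = FALSE]
    discover_novel_mirnas(cand_tags, genome, tag_library = tags,
                          criteria = config$criteria,
                          min_reads = config$novel_min_reads,
                          max_flank = config$max_flank, step = config$step,
                          engine = config$engine,
                          external_cmd = config$external_cmd)
  })
  counts$novel_candidates <- nrow(novel$table)
  five_prime <- if (nrow(novel$table))
    five_prime_composition(novel$table$sequence) else NULL
  novelty <- NULL
  if (nrow(novel$table) && (!is.null(vitis_known) ||
                            !is.null(other_species_known))) {
    novelty <- .stage("novel", classify_novelty(
      novel$table$sequence, vitis_known, other_species_known))
  }

  divergence <- NULL
  if (!is.null(ortholog_pairs))
    divergence <- .stage("divergence", divergence_table(ortholog_pairs))

  target_hits <- NULL
  if (!is.null(transcripts) && nrow(novel$table)) {
    target_hits <- .stage("targets", {
      hits <- lapply(seq_len(nrow(novel$table)), function(i)
        scan_transcripts(novel$table$sequence[i], transcripts,
                         max_score = config$max_target_score,
                         max_bulges = config$max_target_bulges,
                         max_mismatches = config$target_max_mismatches,
                         mirna_id = sprintf("novel_%d", i)))
      do.call(rbind, hits)
    })
    if (!is.null(target_hits) && nrow(target_hits)) {
      target_hits$cleavage_pos_anchor10 <- vapply(
        seq_len(nrow(target_hits)), function(i) {
          p <- predict_cleavage(target_hits[i, ], 10)$position
          if (is.na(p)) NA_integer_ else as.integer(p)
        }, integer(1))
    }
    counts$target_hits <- if (is.null(target_hits)) 0L else nrow(target_hits)
  }

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("vamir")),
                   parameters = config,
                   parameter_hash = unname(config_hash(config)),
                   timestamp = NA_character_) # kept NA for reproducible output
  out <- list(tags = tags, length_histogram = hist,
              assignments = assignments, abundance = abundance,
              category_summary = summary, variant_calls = variant_calls,
              snp_families = snp_families, novel = novel,
              five_prime = five_prime, novelty = novelty,
              divergence = divergence, target_hits = target_hits,
              stage_counts = counts, manifest = manifest)
  class(out) <- "vamir_pipeline"
  out
}

# Stable md5 of the resolved configuration.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(unclass(config)))]), f)
  unname(tools::md5sum(f))
}

#' @export
print.vamir_pipeline <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a human-readable pipeline report
#'
#' @param bundle a `vamir_pipeline` object.
#' @return character vector of report lines (markdown-ish plain text).
#' @export
render_report <- function(bundle) {
  sc <- bundle$stage_counts
  lines <- c("# small RNA analysis report", "",
             sprintf("reads in: %s | clean: %s | unique tags: %s | mapped tags: %s",
                     sc$raw_reads, sc$clean_reads, sc$unique_tags,
                     sc$mapped_tags),
             "", "## annotation categories")
  s <- bundle$category_summary
  lines <- c(lines, sprintf("%-16s %10s %8s %12s %8s", "category", "unique",
                            "uniq%", "redundant", "red%"))
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("%-16s %10d %8.2f %12.0f %8.2f",
                              s$category[i], s$unique_count[i],
                              s$unique_percent[i], s$redundant_count[i],
                              s$redundant_percent[i]))
  }
  if (!is.null(bundle$abundance)) {
    top <- utils::head(bundle$abundance$families, 5)
    lines <- c(lines, "", "## top families by abundance",
               sprintf("%s: %d reads", top$family, top$read_count))
  }
  if (!is.null(bundle$variant_calls)) {
    lines <- c(lines, "", sprintf("miR-SNP types: %d | miR-LD types: %d",
                                  sum(bundle$variant_calls$calls$kind == "miR-SNP"),
                                  sum(bundle$variant_calls$calls$kind == "miR-LD")))
  }
  nv <- bundle$novel$table
  lines <- c(lines, "", sprintf("novel hairpin candidates: %d", nrow(nv)))
  if (!is.null(bundle$novelty)) {
    tb <- table(bundle$novelty)
    lines <- c(lines, sprintf("  %s: %d", names(tb), as.integer(tb)))
  }
  if (!is.null(bundle$target_hits)) {
    lines <- c(lines, sprintf("target hits: %d", nrow(bundle$target_hits)))
  }
  cfg <- bundle$manifest$parameters
  lines <- c(lines, "",
             sprintf("MFE threshold: %s kcal/mol | target score cutoff: %s",
                     cfg$criteria$mfe_threshold, cfg$max_target_score),
             sprintf("seed: %s | parameter hash: %s", bundle$manifest$seed,
                     bundle$manifest$parameter_hash))
  lines
}

#' Write the report bundle tables to a directory
#'
#' Emits the category summary, length histogram, conserved assignment and
#' abundance tables, variant tables, novel-candidate table, divergence table
#' and target hits as TSV, plus the rendered report.
#'
#' @param bundle a `vamir_pipeline` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    if (!is.null(x) && nrow(x))
      utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  wt(bundle$category_summary, "category_summary.tsv")
  wt(bundle$length_histogram, "length_histogram.tsv")
  wt(bundle$assignments, "conserved_assignments.tsv")
  if (!is.null(bundle$abundance)) {
    wt(bundle$abundance$members, "member_abundance.tsv")
    wt(bundle$abundance$families, "family_abundance.tsv")
  }
  if (!is.null(bundle$variant_calls))
    write_variant_tables(bundle$variant_calls$calls,
                         file.path(dir, "mir_snp.tsv"),
                         file.path(dir, "mir_ld.tsv"))
  wt(bundle$novel$table, "novel_candidates.tsv")
  wt(bundle$divergence, "ortholog_divergence.tsv")
  if (!is.null(bundle$target_hits))
    wt(bundle$target_hits[, setdiff(names(bundle$target_hits), "alignment")],
       "target_hits.tsv")
  writeLines(render_report(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}
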