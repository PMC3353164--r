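# Default redundant-read category fractions: exact ratios of the bundled
# Amur grape category counts (see amur_category_counts()), so they sum to 1.
.default_category_fractions <- function() {
  counts <- c(exon_antisense = 301729, exon_sense = 616910,
              intron_antisense = 447068, intron_sense = 880478,
              miRNA = 1030053, rRNA = 1858381, `repeat` = 1094074,
              siRNA = 2927927, snRNA = 25039, snoRNA = 12647,
              tRNA = 842565, unann = 8865829)
  counts / sum(counts)
}

# Default length profile: 24 nt dominant, then 21 > 22 > 23, with 20-24 nt
# making up ~85% of reads.
.default_length_profile <- function() {
  p <- c(`15` = 0.005, `16` = 0.01, `17` = 0.01, `18` = 0.015, `19` = 0.02,
         `20` = 0.05, `21` = 0.16, `22` = 0.14, `23` = 0.13, `24` = 0.37,
         `25` = 0.03, `26` = 0.02, `27` = 0.015, `28` = 0.01, `29` = 0.01,
         `30` = 0.005)
  p / sum(p)
}

#' Configuration for the synthetic small-RNA study
#'
#' Defines the simulated study conditions: a random genome with planted
#' annotation features, conserved and novel miRNA hairpins, decoy windows,
#' and an adapter-flanked read library whose category proportions, length
#' profile, heavy-tailed expression, variant rates and miRNA* frequency
#' emulate a deeply sequenced plant small-RNA library.
#'
#' @param seed integer RNG seed; a fixed seed makes all outputs byte-identical.
#' @param total_reads number of clean-category reads to draw (default 20000).
#' @param genome_length background genome size in nt (default 60000).
#' @param n_mirnas number of planted conserved miRNAs (default 12).
#' @param n_families number of conserved families the miRNAs are grouped
#'   into (default 6).
#' @param n_novel number of planted novel (unannotated) miRNA hairpins
#'   (default 8).
#' @param n_decoys number of composition-preserving shuffled decoy windows
#'   (default 20).
#' @param expression log-normal read-count model for mature miRNAs,
#'   `c(meanlog, sdlog)` (default c(5, 1.5): a spread of roughly 2 to 1e5
#'   copies).
#' @param snp_rate fraction of conserved miRNAs carrying a planted miR-SNP
#'   (default 0.4).
#' @param ld_rate fraction carrying a planted miR-LD (default 0.3).
#' @param variant_fraction variant reads as a fraction of wild-type reads
#'   (default 0.03; variants are always rarer than their wild types).
#' @param star_fraction miRNA* reads as a fraction of mature reads
#'   (default 0.1).
#' @param novel_star_rate fraction of novel hairpins with sequenced star
#'   reads (default 0.5).
#' @param category_fractions named redundant-read fractions over the twelve
#'   annotation categories; must sum to 1 (default: the bundled Amur grape
#'   proportions).
#' @param length_profile named read-length fractions over 15-30 nt; must sum
#'   to 1.
#' @param adapter3,adapter5 adapter sequences ligated around each insert.
#' @param read_length sequencer read length (default 36).
#' @param low_quality_rate extra low-quality reads as a fraction of
#'   `total_reads` (default 0.01).
#' @param n_unann_pool number of distinct unannotated background tags the
#'   unannotated reads are drawn from (default 3000).
#' @param n_sirna_loci number of planted double-stranded siRNA loci
#'   (default 8).
#' @return validated configuration list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, total_reads = 20000, genome_length = 60000,
                       n_mirnas = 12, n_families = 6, n_novel = 8,
                       n_decoys = 20, expression = c(meanlog = 5, sdlog = 1.5),
                       snp_rate = 0.4, ld_rate = 0.3, variant_fraction = 0.03,
                       star_fraction = 0.1, novel_star_rate = 0.5,
                       category_fractions = .default_category_fractions(),
                       length_profile = .default_length_profile(),
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       read_length = 36, low_quality_rate = 0.01,
                       n_unann_pool = 3000, n_sirna_loci = 8) {
  cfg <- list(seed = as.integer(seed), total_reads = total_reads,
              genome_length = genome_length, n_mirnas = n_mirnas,
              n_families = n_families, n_novel = n_novel,
              n_decoys = n_decoys, expression = expression,
              snp_rate = snp_rate, ld_rate = ld_rate,
              variant_fraction = variant_fraction,
              star_fraction = star_fraction,
              novel_star_rate = novel_star_rate,
              category_fractions = category_fractions,
              length_profile = length_profile, adapter3 = adapter3,
              adapter5 = adapter5, read_length = read_length,
              low_quality_rate = low_quality_rate,
              n_unann_pool = n_unann_pool, n_sirna_loci = n_sirna_loci)
  rates <- c(cfg$snp_rate, cfg$ld_rate, cfg$variant_fraction,
             cfg$star_fraction, cfg$novel_star_rate, cfg$low_quality_rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$category_fractions) - 1) > 1e-9)
    stop("category_fractions must sum to 1", call. = FALSE)
  if (!setequal(names(cfg$category_fractions), ANNOT_CATEGORIES))
    stop("category_fractions must cover exactly the annotation categories",
         call. = FALSE)
  if (abs(sum(cfg$length_profile) - 1) > 1e-9)
    stop("length_profile must sum to 1", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Largest-remainder apportionment of n among fractions p (sums exactly to n).
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}

# Composition-preserving shuffle in dinucleotide blocks: destroys the planted
# helix while approximately conserving dinucleotide content.
block_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pairs <- split(ch, ceiling(seq_len(n) / 2))
  paste(unlist(pairs[sample(length(pairs))]), collapse = "")
}

# Build a hairpin precursor around a mature sequence: flanking extensions,
# an unpairable A/C loop, and a reverse-complement star arm with `n_defects`
# internal mutations that break single stem pairs. Coordinates are local to
# the precursor (5'->3').
make_precursor <- function(mature, arm = c("5p", "3p"), ext = 10,
                           loop_len = 8, n_defects = 1) {
  arm <- match.arg(arm)
  L <- nchar(mature)
  mch <- strsplit(mature, "")[[1]]
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
  star <- strsplit(revcomp(mature), "")[[1]]
  if (n_defects > 0) {
    # star index j pairs mature index L - j + 1; replace with a base that
    # neither Watson-Crick nor wobble pairs it
    cand <- 4:(L - 3)
    pos <- sample(cand, n_defects)
    for (j in pos) {
      mb <- mch[L - j + 1]
      bad <- switch(mb, A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
      star[j] <- sample(setdiff(c("A", "C", "G", "T"), bad), 1)
    }
  }
  star <- paste(star, collapse = "")
  e5 <- rand_dna(ext); e3 <- rand_dna(ext)
  if (arm == "5p") {
    seq <- paste0(e5, mature, loop, star, e3)
    ms <- ext + 1L
    arm_start <- ext + L + loop_len + 1L
  } else {
    seq <- paste0(e5, star, loop, mature, e3)
    ms <- ext + L + loop_len + 1L
    arm_start <- ext + 1L
  }
  # canonical miRNA* span: the star arm shifted for 2-nt 3' overhangs
  list(seq = seq, arm = arm, mature_start = ms, mature_end = ms + L - 1L,
       star_seq = substr(seq, arm_start + 2L, arm_start + L + 1L))
}

#' Simulate a genome with planted features and hairpins
#'
#' Generates a random background chromosome and embeds, without overlaps:
#' structural-RNA/repeat/exon/intron features (locations for the annotation
#' tracks), conserved and novel miRNA hairpin precursors built so the
#' built-in fold engine accepts them, shuffled decoy windows, and
#' double-stranded siRNA loci. All placements are recorded in the truth
#' ledger.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `tracks` (`GRanges` with a
#'   `category` column), `known_matures` (data.frame usable as a known
#'   mature set), and `truth` (planted ground truth so far).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  glen <- config$genome_length
  gseq <- strsplit(rand_dna(glen), "")[[1]]
  cursor <- 1L
  place <- function(len) {
    gap <- sample(100:300, 1)
    start <- cursor + gap
    cursor <<- start + len
    if (cursor > glen - 2000)
      stop("genome too small for the requested features", call. = FALSE)
    start
  }
  # annotation-track features (locations only; background sequence suffices)
  spec <- rbind(
    data.frame(category = "rRNA", len = 400, n = 2),
    data.frame(category = "tRNA", len = 80, n = 3),
    data.frame(category = "snRNA", len = 120, n = 2),
    data.frame(category = "snoRNA", len = 110, n = 2),
    data.frame(category = "repeat", len = 300, n = 3),
    data.frame(category = "exon", len = 300, n = 4),
    data.frame(category = "intron", len = 250, n = 4))
  feats <- list()
  for (i in seq_len(nrow(spec))) {
    for (k in seq_len(spec$n[i])) {
      st <- place(spec$len[i])
      feats[[length(feats) + 1L]] <- data.frame(
        category = spec$category[i], start = st,
        end = st + spec$len[i] - 1L,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
  }
  feats <- do.call(rbind, feats)
  # conserved miRNA hairpins, grouped into families whose members differ by
  # three substitutions (family labels parse from the ids)
  members_per_fam <- apportion(config$n_mirnas,
                               rep(1, config$n_families))
  matures <- list()
  fam_idx <- 0L
  for (f in seq_len(config$n_families)) {
    fam_idx <- fam_idx + 1L
    base <- rand_dna(21)
    for (m in seq_len(members_per_fam[f])) {
      seq <- base
      if (m > 1) {
        pos <- sample(3:19, 3)
        ch <- strsplit(seq, "")[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        seq <- paste(ch, collapse = "")
      }
      matures[[length(matures) + 1L]] <- data.frame(
        id = sprintf("vam-miR%03d%s", 100 + fam_idx, letters[m]),
        family = sprintf("miR%d", 100 + fam_idx), sequence = seq,
        conserved = TRUE, stringsAsFactors = FALSE)
    }
  }
  # novel hairpins: unannotated matures absent from the known set
  for (k in seq_len(config$n_novel)) {
    matures[[length(matures) + 1L]] <- data.frame(
      id = sprintf("novel-%02d", k), family = NA_character_,
      sequence = rand_dna(sample(20:23, 1)), conserved = FALSE,
      stringsAsFactors = FALSE)
  }
  matures <- do.call(rbind, matures)
  # build each precursor with a controlled star defect. The defect is
  # mandatory (a perfect star arm would make the mature match the opposite
  # strand of its own precursor) but must not change the minimum-energy
  # structure enough to displace the mature from its arm, so every planted
  # hairpin is verified against the adjudicator, redrawing the defect and
  # flanks until it passes.
  build_precursor <- function(mature, arm) {
    for (attempt in 1:10) {
      pre <- make_precursor(mature, arm = arm, n_defects = 1)
      ms <- regexpr(mature, pre$seq, fixed = TRUE)
      cand <- evaluate_candidate(fold(pre$seq), ms, ms + nchar(mature) - 1)
      if (cand$accepted && identical(cand$arm, arm) &&
          identical(cand$star_seq, pre$star_seq)) return(pre)
    }
    stop("could not realise a planted hairpin", call. = FALSE)
  }
  pre_rows <- list()
  for (i in seq_len(nrow(matures))) {
    arm <- sample(c("5p", "3p"), 1)
    strand <- sample(c("+", "-"), 1)
    pre <- build_precursor(matures$sequence[i], arm = arm)
    lp <- nchar(pre$seq)
    st <- place(lp)
    pseq <- if (strand == "+") pre$seq else revcomp(pre$seq)
    gseq[st:(st + lp - 1L)] <- strsplit(pseq, "")[[1]]
    if (strand == "+") {
      m_start <- st + pre$mature_start - 1L
    } else {
      m_start <- st + (lp - pre$mature_end)
    }
    pre_rows[[i]] <- data.frame(
      precursor_start = st, precursor_end = st + lp - 1L, strand = strand,
      arm = arm, mature_chr_start = m_start,
      mature_chr_end = m_start + nchar(matures$sequence[i]) - 1L,
      precursor_seq = pre$seq, star_seq = pre$star_seq,
      stringsAsFactors = FALSE)
  }
  matures <- cbind(matures, do.call(rbind, pre_rows))
  # decoys: hairpin-like neighborhoods, shuffled to destroy structure; the
  # planted decoy tag is an actual substring so it still maps. A shuffle can
  # recreate a workable stem by chance, which would contradict the decoy's
  # defining property, so each shuffle is verified non-hairpin over the
  # window grid around the tag (flanks up to 60 nt in 20-nt steps) and
  # redrawn when any window passes the annotation criteria.
  decoy_is_hairpin <- function(shuf, tag_off) {
    lp <- nchar(shuf)
    for (u in seq(0, 60, by = 20)) {
      for (d in seq(0, 60, by = 20)) {
        if (u + d == 0) next
        ws <- max(1L, tag_off - u)
        we <- min(lp, tag_off + 20L + d)
        cand <- evaluate_candidate(fold(substr(shuf, ws, we)),
                                   tag_off - ws + 1L, tag_off - ws + 21L)
        if (cand$accepted) return(TRUE)
      }
    }
    FALSE
  }
  decoys <- list()
  for (k in seq_len(config$n_decoys)) {
    proto <- make_precursor(rand_dna(21), arm = "5p", ext = 45)
    lp <- nchar(proto$seq)
    tag_off <- as.integer((lp - 21) / 2) + 1L
    for (attempt in 1:10) {
      shuf <- block_shuffle(proto$seq)
      if (!decoy_is_hairpin(shuf, tag_off)) break
    }
    st <- place(lp)
    gseq[st:(st + lp - 1L)] <- strsplit(shuf, "")[[1]]
    decoys[[k]] <- data.frame(
      id = sprintf("decoy-%02d", k), start = st, end = st + lp - 1L,
      tag_seq = substr(shuf, tag_off, tag_off + 20L),
      stringsAsFactors = FALSE)
  }
  decoys <- do.call(rbind, decoys)
  # double-stranded siRNA loci: two overlapping 24-nt tags on opposite
  # strands (the canonical plant heterochromatic siRNA length)
  sirna <- list()
  for (k in seq_len(config$n_sirna_loci)) {
    st <- place(30)
    fwd <- paste(gseq[st:(st + 23L)], collapse = "")
    rev <- revcomp(paste(gseq[(st + 5L):(st + 28L)], collapse = ""))
    sirna[[k]] <- data.frame(locus_start = st, tag_fwd = fwd, tag_rev = rev,
                             stringsAsFactors = FALSE)
  }
  sirna <- do.call(rbind, sirna)
  unann_region <- c(cursor + 200L, glen - 50L)
  genome <- Biostrings::DNAStringSet(paste(gseq, collapse = ""))
  names(genome) <- "chr1"
  tracks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(feats$start, feats$end), strand = feats$strand,
    category = feats$category)
  known <- matures[matures$conserved, c("id", "family", "sequence")]
  row.names(known) <- NULL
  list(genome = genome, tracks = tracks, known_matures = known,
       truth = list(matures = matures, decoys = decoys, sirna = sirna,
                    features = feats, unann_region = unann_region,
                    config = config))
}

# Draw insert lengths from the configured profile.
draw_lengths <- function(n, profile) {
  as.integer(sample(names(profile), n, replace = TRUE, prob = profile))
}

#' Simulate the adapter-flanked read library
#'
#' Draws reads per the configured category fractions: structural and
#' gene-model reads are substrings of their planted features (sense or
#' antisense as the category dictates), miRNA reads follow the log-normal
#' expression model with planted miR-SNP / miR-LD variant reads and miRNA*
#' reads, novel-hairpin and decoy reads land in the unannotated fraction,
#' and the remaining unannotated reads come from a background tag pool.
#' Every insert is wrapped with the 3' adapter and given synthetic qualities;
#' a small set of extra low-quality reads is added on top. Every read traces
#' to one truth record.
#'
#' @param sim output of [simulate_genome()].
#' @return `sim` extended with `reads` (data.frame `id`, `seq`, `qual`) and
#'   a completed `truth` ledger (`reads`, `expression`, `variants`,
#'   `category_counts`).
#' @export
simulate_library <- function(sim) {
  config <- sim$truth$config
  set.seed(config$seed + 1L)
  gch <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  sub_g <- function(s, e) paste(gch[s:e], collapse = "")
  profile <- config$length_profile
  budget <- apportion(config$total_reads,
                      config$category_fractions[ANNOT_CATEGORIES])
  names(budget) <- ANNOT_CATEGORIES
  inserts <- character(0); cats <- character(0); srcs <- character(0)
  add <- function(seqs, counts, category, source) {
    keep <- counts > 0
    inserts <<- c(inserts, rep(seqs[keep], counts[keep]))
    cats <<- c(cats, rep(category, sum(counts[keep])))
    srcs <<- c(srcs, rep(source[keep], counts[keep]))
  }
  feats <- sim$truth$features
  # feature-derived categories
  feature_reads <- function(category, n_reads, antisense = FALSE) {
    rows <- which(feats$category == sub("_(anti)?sense$", "", category))
    if (!length(rows) || n_reads == 0) return()
    per <- apportion(n_reads, rep(1, length(rows)))
    for (j in seq_along(rows)) {
      f <- feats[rows[j], ]
      if (per[j] == 0) next
      lens <- draw_lengths(per[j], profile)
      mid <- as.integer((f$start + f$end) / 2)
      lo <- if (antisense) mid + 1L else f$start
      hi <- if (antisense) f$end else mid
      pos <- lo + vapply(pmax(1L, hi - lo + 1L - lens), function(w)
        sample.int(w, 1), integer(1)) - 1L
      seqs <- vapply(seq_along(pos), function(r)
        sub_g(pos[r], min(pos[r] + lens[r] - 1L, f$end)), character(1))
      strand <- if (antisense) setdiff(c("+", "-"), f$strand) else f$strand
      if (strand == "-") seqs <- revcomp(seqs)
      add(seqs, rep(1L, length(seqs)), category,
          rep(sprintf("feat_%s_%d", f$category, rows[j]), length(seqs)))
    }
  }
  for (cc in c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat"))
    feature_reads(cc, budget[cc])
  feature_reads("exon_sense", budget["exon_sense"])
  feature_reads("exon_antisense", budget["exon_antisense"], antisense = TRUE)
  feature_reads("intron_sense", budget["intron_sense"])
  feature_reads("intron_antisense", budget["intron_antisense"],
                antisense = TRUE)
  # siRNA loci: split each locus budget across the two strands
  si <- sim$truth$sirna
  per <- apportion(budget["siRNA"], rep(1, nrow(si)))
  for (k in seq_len(nrow(si))) {
    nf <- as.integer(ceiling(per[k] / 2)); nr <- per[k] - nf
    add(c(si$tag_fwd[k], si$tag_rev[k]), c(nf, nr), "siRNA",
        rep(sprintf("sirna_%d", k), 2))
  }
  # conserved miRNAs: log-normal expression + variants + stars
  mat <- sim$truth$matures
  cons <- mat[mat$conserved, , drop = FALSE]
  w <- stats::rlnorm(nrow(cons), config$expression[["meanlog"]],
                     config$expression[["sdlog"]])
  wt_counts <- pmax(2L, apportion(budget["miRNA"], w))
  expression <- data.frame(id = cons$id, sequence = cons$sequence,
                           planted_count = wt_counts,
                           stringsAsFactors = FALSE)
  add(cons$sequence, wt_counts, "miRNA", cons$id)
  variants <- list()
  has_snp <- stats::runif(nrow(cons)) < config$snp_rate
  has_ld <- stats::runif(nrow(cons)) < config$ld_rate
  for (i in seq_len(nrow(cons))) {
    L <- nchar(cons$sequence[i])
    vcount <- max(1L, as.integer(round(config$variant_fraction *
                                         wt_counts[i])))
    if (has_snp[i]) {
      pos <- sample(2:(L - 1), 1)
      ch <- strsplit(cons$sequence[i], "")[[1]]
      ref <- ch[pos]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      ch[pos] <- alt
      vseq <- paste(ch, collapse = "")
      add(vseq, vcount, "miRNA", paste0(cons$id[i], "_snp"))
      variants[[length(variants) + 1L]] <- data.frame(
        wildtype_id = cons$id[i], kind = "miR-SNP", variant_seq = vseq,
        snp_position = pos, ref_base = ref, alt_base = alt,
        delta5 = NA_integer_, delta3 = NA_integer_, planted_count = vcount,
        stringsAsFactors = FALSE)
    }
    if (has_ld[i]) {
      end5 <- sample(c(TRUE, FALSE), 1)
      delta <- sample(c(-2L, -1L, 1L, 2L), 1)
      pre <- cons$precursor_seq[i]
      ms <- regexpr(cons$sequence[i], pre, fixed = TRUE)
      me <- ms + L - 1L
      ns <- if (end5) ms - delta else ms
      ne <- if (end5) me else me + delta
      vseq <- substr(pre, ns, ne)
      if (vseq != cons$sequence[i]) {
        add(vseq, vcount, "miRNA", paste0(cons$id[i], "_ld"))
        variants[[length(variants) + 1L]] <- data.frame(
          wildtype_id = cons$id[i], kind = "miR-LD", variant_seq = vseq,
          snp_position = NA_integer_, ref_base = NA_character_,
          alt_base = NA_character_,
          delta5 = if (end5) delta else 0L,
          delta3 = if (end5) 0L else delta,
          planted_count = vcount, stringsAsFactors = FALSE)
      }
    }
    star_count <- max(1L, as.integer(round(config$star_fraction *
                                             wt_counts[i])))
    add(cons$star_seq[i], star_count, "unann", paste0(cons$id[i], "_star"))
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(wildtype_id = character(), kind = character(),
               variant_seq = character(), snp_position = integer(),
               ref_base = character(), alt_base = character(),
               delta5 = integer(), delta3 = integer(),
               planted_count = integer(), stringsAsFactors = FALSE)
  # novel hairpins and decoys live in the unannotated fraction
  nov <- mat[!mat$conserved, , drop = FALSE]
  wn <- stats::rlnorm(nrow(nov), config$expression[["meanlog"]],
                      config$expression[["sdlog"]])
  # novel miRNAs are low-abundance relative to conserved ones; they take a
  # small slice of the unannotated fraction
  novel_budget <- as.integer(round(0.05 * budget["unann"]))
  nov_counts <- pmax(3L, apportion(novel_budget, wn))
  add(nov$sequence, nov_counts, "unann", nov$id)
  has_star <- stats::runif(nrow(nov)) < config$novel_star_rate
  star_counts <- ifelse(has_star,
                        pmax(1L, as.integer(round(config$star_fraction *
                                                    nov_counts))), 0L)
  add(nov$star_seq, star_counts, "unann", paste0(nov$id, "_star"))
  expression <- rbind(expression,
                      data.frame(id = nov$id, sequence = nov$sequence,
                                 planted_count = nov_counts,
                                 stringsAsFactors = FALSE))
  dec <- sim$truth$decoys
  add(dec$tag_seq, rep(12L, nrow(dec)), "unann", dec$id)
  # background unannotated pool
  used <- sum(nov_counts) + sum(star_counts) + 12L * nrow(dec)
  pool_budget <- max(0L, budget["unann"] - sum(nov_counts) - 12L * nrow(dec))
  ur <- sim$truth$unann_region
  pool_n <- config$n_unann_pool
  pool_lens <- draw_lengths(pool_n, profile)
  pool_pos <- ur[1] + vapply(ur[2] - ur[1] + 1L - pool_lens, function(w)
    sample.int(w, 1), integer(1)) - 1L
  pool_seqs <- vapply(seq_len(pool_n), function(r)
    sub_g(pool_pos[r], pool_pos[r] + pool_lens[r] - 1L), character(1))
  pool_counts <- apportion(pool_budget, rep(1, pool_n) +
                             stats::runif(pool_n))
  add(pool_seqs, pool_counts, "unann",
      sprintf("pool_%d", seq_len(pool_n)))
  # assemble reads: insert + 3' adapter, truncated to the read length
  n_reads <- length(inserts)
  perm <- sample.int(n_reads)
  inserts <- inserts[perm]; cats <- cats[perm]; srcs <- srcs[perm]
  seqs <- substr(paste0(inserts, config$adapter3), 1L, config$read_length)
  quals <- strrep("I", nchar(seqs))
  lowq <- rep(FALSE, n_reads)
  n_lq <- as.integer(round(config$low_quality_rate * config$total_reads))
  if (n_lq > 0) {
    pick <- sample.int(n_reads, n_lq, replace = TRUE)
    seqs <- c(seqs, seqs[pick]); quals <- c(quals, strrep("#", nchar(seqs[pick])))
    inserts <- c(inserts, inserts[pick])
    cats <- c(cats, cats[pick]); srcs <- c(srcs, srcs[pick])
    lowq <- c(lowq, rep(TRUE, n_lq))
  }
  ids <- sprintf("read%06d", seq_along(seqs))
  sim$reads <- data.frame(id = ids, seq = seqs, qual = quals,
                          stringsAsFactors = FALSE)
  sim$truth$reads <- data.frame(id = ids, insert = inserts, category = cats,
                                source = srcs, low_quality = lowq,
                                stringsAsFactors = FALSE)
  sim$truth$expression <- expression
  sim$truth$variants <- variants
  counts <- vapply(ANNOT_CATEGORIES, function(cc)
    sum(cats == cc & !lowq), integer(1))
  sim$truth$category_counts <- counts
  sim
}

#' One-call synthetic study
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `tracks`, `known_matures`, `reads`, `truth`.
#' @export
simulate_small_rna <- function(config = sim_config()) {
  simulate_library(simulate_genome(config))
}

#' Write a simulated study to disk
#'
#' Emits genome FASTA, tracks GFF3, reads FASTQ and the truth tables as TSV.
#'
#' @param sim output of [simulate_small_rna()] / [simulate_library()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  rtracklayer::export(
    GenomicRanges::GRanges(GenomicRanges::seqnames(sim$tracks),
                           IRanges::ranges(sim$tracks),
                           strand = GenomicRanges::strand(sim$tracks),
                           type = sim$tracks$category,
                           source = "vamir_sim"),
    file.path(dir, "tracks.gff3"), format = "gff3")
  x <- Biostrings::DNAStringSet(sim$reads$seq)
  names(x) <- sim$reads$id
  Biostrings::writeXStringSet(
    x, file.path(dir, "reads.fastq"), format = "fastq",
    qualities = Biostrings::BStringSet(sim$reads$qual))
  for (tb in c("reads", "expression", "variants")) {
    utils::write.table(sim$truth[[tb]],
                       file.path(dir, paste0("truth_", tb, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
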