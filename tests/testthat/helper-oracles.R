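# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R enumeration and naive scans.

oracle_pair_energy <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AT", "TA")) return(-2)
  if (key %in% c("GT", "TG")) return(-1)
  NA_real_
}

# Exhaustive enumeration of all nested structures (min hairpin loop 3) and
# their energies under the stacking-weighted model; returns the optimum.
oracle_fold_mfe <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  enum <- function(i, j) {
    if (j - i < 4) return(list(list()))
    out <- enum(i + 1, j) # i unpaired
    for (k in (i + 4):j) {
      if (!is.na(oracle_pair_energy(ch[i], ch[k]))) {
        inner <- enum(i + 1, k - 1)
        outer <- enum(k + 1, j)
        for (a in inner) for (b in outer)
          out <- c(out, list(c(list(c(i, k)), a, b)))
      }
    }
    out
  }
  energy <- function(ps) {
    if (!length(ps)) return(0)
    pt <- integer(n)
    for (p in ps) { pt[p[1]] <- p[2]; pt[p[2]] <- p[1] }
    e <- 0
    for (p in ps) {
      i <- p[1]; j <- p[2]
      if (j - 1 > i + 1 && pt[i + 1] == j - 1)
        e <- e + oracle_pair_energy(ch[i], ch[j]) # stacked outer pair
      inside <- (i + 1):(j - 1)
      if (!any(pt[inside] > 0)) e <- e + 4 # hairpin loop
    }
    e
  }
  sets <- enum(1, n)
  min(0, min(vapply(sets, energy, numeric(1))))
}

# Naive both-strand exact scan of a genome string for a tag; returns a
# data.frame of 1-based loci.
oracle_scan_genome <- function(tag, chrom_seq, chrom = "chr1") {
  out <- list()
  n <- nchar(chrom_seq)
  scan1 <- function(pat, strand) {
    m <- nchar(pat)
    if (m > n) return()
    starts <- which(substring(chrom_seq, 1:(n - m + 1), m:n) == pat)
    for (s in starts)
      out[[length(out) + 1L]] <<- data.frame(
        chrom = chrom, start = s, end = s + m - 1L, strand = strand,
        stringsAsFactors = FALSE)
  }
  scan1(tag, "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  scan1(rc, "-")
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer(), strand = character()))
  d <- do.call(rbind, out)
  d[order(d$chrom, d$start, d$strand), , drop = FALSE]
}

# Brute-force best containment alignment of a tag against a known set
# (fewest substitutions, then smallest overhang, then smallest id).
oracle_match_known <- function(tag, knowns, max_sub = 3, slack = 3) {
  best <- NULL
  for (r in order(knowns$id)) {
    k <- knowns$sequence[r]
    lt <- nchar(tag); lk <- nchar(k)
    ovh <- abs(lk - lt)
    if (ovh > slack) next
    shorter <- if (lt <= lk) tag else k
    longer <- if (lt <= lk) k else tag
    for (s in 0:ovh) {
      sub <- sum(strsplit(shorter, "")[[1]] !=
                   strsplit(substr(longer, s + 1, s + nchar(shorter)), "")[[1]])
      if (sub > max_sub) next
      if (is.null(best) || sub < best$sub ||
          (sub == best$sub && ovh < best$ovh)) {
        best <- list(id = knowns$id[r], sub = sub, ovh = ovh)
      }
    }
  }
  best
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

make_reads <- function(seqs, qual = NULL) {
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = if (is.null(qual)) rep(NA_character_, length(seqs)) else
               qual,
             stringsAsFactors = FALSE)
}

# One shared simulated study + full pipeline run (expensive; computed once).
.sim_cache <- new.env(parent = emptyenv())
get_sim_run <- function() {
  if (!exists("run", envir = .sim_cache)) {
    sim <- simulate_small_rna(sim_config(seed = 7))
    cfg <- pipeline_config(max_flank = 60, step = 20, seed = 7)
    res <- run_pipeline(sim$reads, sim$genome, sim$tracks,
                        sim$known_matures, config = cfg)
    assign("run", list(sim = sim, res = res), envir = .sim_cache)
  }
  get("run", envir = .sim_cache)
}
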