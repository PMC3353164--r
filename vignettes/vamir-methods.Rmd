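---
title: "Methods: small-RNA analysis and miRNA discovery with vamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA analysis and miRNA discovery with vamir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vamir` re-implements, as a tested and reusable toolkit, the analysis used to
characterise the small-RNA complement of Amur grape (*Vitis amurensis*
Rupr.): cleaning and collapsing a deeply sequenced small-RNA library,
partitioning tags into annotation categories, assigning tags to known mature
miRNAs, calling sequence variants of conserved miRNAs (miR-SNPs and
miR-LDs), discovering novel miRNAs from hairpin-forming genomic
neighbourhoods, and scanning transcripts for miRNA targets with
cleavage-site prediction. A fully seeded synthetic-data generator with
planted ground truth stands in for the original sequencing library, which is
not redistributed here.

This vignette documents the models, the parameters that matter, and the
design decisions taken where the published description leaves the method
under-determined.

## Read cleaning and tag accounting

Raw reads are adapter-flanked inserts. `trim_adapters()` locates the 3'
adapter by a best-overlap semi-global search: every read suffix is compared
with the adapter prefix, and the highest-scoring occurrence (matches minus
mismatches, overlap at least `min_overlap = 6` nt, mismatch rate at most
`max_mismatch_rate = 0.1`) marks the insert end. Reads without a detectable
3' adapter are discarded, because their insert length is not determined by
the read. Quality filtering defaults to a mean Phred score of 20 and zero N
bases; poly-A artifacts are dropped at 80% A content or a terminal run of 8
A's. None of these four thresholds is stated in the original description;
all are exposed as arguments.

Two length regimes appear in the source protocol: 15-30 nt at gel
purification and 18-30 nt at the informatic stage. The pipeline default is
the informatic filter `[18, 30]`; both bounds are configurable.

`collapse_reads()` produces the unique/redundant dichotomy used throughout:
one *tag* per distinct sequence with its read count. Collapsing conserves
the total read number exactly, and output order is deterministic
(descending count, then sequence), which every downstream table relies on.

## Genome mapping and annotation categories

Mapping is exact, ungapped and full-length (`map_to_genome()`, built on
`Biostrings::matchPDict`), recording all loci on both strands; 1-based
inclusive coordinates are used everywhere. Tags are then assigned exactly
one of twelve categories. The category precedence is a design decision:

> miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > siRNA > exon > intron >
> unann

Structural-RNA contamination must not be absorbed by gene-model categories,
and miRNA comes first because it is assigned from sequence (known-mature
matching), not from a genomic track. Sense/antisense for exon and intron is
the tag strand versus the feature strand; within one feature class, sense is
preferred over antisense when a tag overlaps features on both strands.
Multi-locus tags are classified once, by the highest-precedence category
over all loci, so unique and redundant column sums always equal the totals
row. Unmapped tags fall into `unann`, matching the totals arithmetic of the
published category table (bundled as `amur_category_counts()`).

The siRNA category has no recoverable published definition; the rule
implemented here is a documented stand-in: a 21-24 nt tag whose locus is
overlapped, on the opposite strand, by another mapped tag's locus (a
double-stranded siRNA signature). It can be switched off
(`sirna_rule = FALSE`).

## Conserved miRNA assignment

`match_known()` compares each tag with a known mature set (miRBase-style
FASTA, U normalised to T at load time). The published rule is "0-3
mismatches"; whether length differences count as mismatches is not stated.
Because the ortholog tables in the same survey treat terminal shifts as
*divergence* rather than mismatch, the implementation separates the two: an
ungapped containment alignment (the shorter sequence inside the longer) with
substitutions counted only over the overlap (`max_substitutions = 3`) and a
total terminal overhang budget (`terminal_slack = 3` nt). The best
assignment minimises substitutions, then overhang, then takes the
lexicographically smallest id — full determinism is required for testing.
Family labels parse from the id stem ("miR" + number; letter suffixes and
member dashes ignored).

`terminal_divergence()` aligns two orthologous matures over all ungapped
offsets, maximising matched core positions (ties: fewer substitutions, then
smaller 5' divergence), and reports the unmatched terminal lengths `d5`/`d3`
summed over both sequences. Values are reported raw: two bundled catalog
rows exceed the survey's own "1-3 nt" summary, and the package reports the
computed divergence rather than clamping it.

## miR-SNP and miR-LD calling

Within each conserved group, the wild type is the tag equal to the known
mature when present, else the most abundant tag. Every other tag is tested
as a miR-SNP (equal length, Hamming distance exactly 1), then as a miR-LD
(substitution-free ungapped overlap with non-zero terminal shifts, total
shift capped at `max_shift_total = 4` nt — beyond that a tag is a distinct
sequence, not a length variant). The two classes are mutually exclusive per
pair by construction; tags combining a shift *and* a substitution fit
neither class and are reported in an `other` bucket, uncounted in either
statistic. Minimum read support defaults to 1 (all sequenced variants
count), configurable to suppress sequencing noise. No sequencing-error model
is applied: the method reports counts, as the source analysis did.

`snp_vs_duplex()` classifies a SNP site against a miRNA:target duplex:
`creates_new_mismatch` when a paired (Watson-Crick or G:U) position loses
pairing, `at_existing_mismatch` when the position was already unpaired
(with a `pairing_gained` flag when the substitution restores pairing, e.g.
A:C to G:C), `pairing_retained` when pairing survives the substitution, and
`outside_duplex` beyond the site. The unit tests check the full 4x4x4 truth
table.

## Hairpin discovery

For each unannotated, conserved-unassigned tag with sufficient read support,
genomic windows extend the mature locus upstream-only, downstream-only and
both ways in `step = 20` nt increments up to `max_flank` per side
(strand-aware, clipped at chromosome ends). Each window is folded and
adjudicated.

**The built-in fold engine** finds the minimum-energy pseudoknot-free
structure under a deliberately simple stacking-weighted model: a base pair
contributes energy only when the pair immediately inside it is also formed
(GC -3, AU -2, GU -1 kcal/mol), each hairpin loop costs +4 kcal/mol, and
hairpin loops are at least 3 nt. The empty structure scores 0, so reported
MFE is never positive and is 0 exactly when no pairing is worthwhile. The
dynamic program is O(n^3) and implemented in C++; tests pin it against an
exhaustive enumeration of all nested structures for sequences up to 20 nt.
Bit-compatibility with thermodynamic folders (ViennaRNA, miRCat) is *not*
claimed; any external tool that consumes FASTA on standard input and emits
a dot-bracket plus "(mfe)" line can be plugged in (`engine = "external"`,
e.g. `RNAfold --noPS`), and published MFE values should only be compared
through such an engine.

**Acceptance criteria** (`hairpin_criteria()`), all mandatory:

* `mfe`: MFE at most `mfe_threshold = -18` kcal/mol. A strict -20 gate
  would contradict the published catalog, which retains two candidates at
  -19.7 (and prints one row at -19.4) despite citing -20 as a criterion;
  -18 brackets the catalog's observed minimum.
* `arm`: the mature lies entirely on one arm of a single stem-loop — no
  mature base inside a hairpin loop, all paired mature partners on one side,
  and exactly one terminal loop between mature and partners.
* `pairing`: at most `max_mature_unpaired = 4` unpaired mature bases.
* `length`: precursor length within `[60, 320]` nt, bracketing the
  catalog's observed 65-311 nt.
* `duplex`: no asymmetric bulge larger than `max_bulge_asymmetry = 2` nt
  between consecutive paired mature bases. This mirrors the annotation
  convention that duplex bulges be at most one or two bases; without it,
  long quasi-stems assembled from scattered complementarity (frequent in
  shuffled sequence under the simple energy model) pass as pseudo-hairpins.

The miRNA* is located from the pair table (partners of mature positions
1..len-2, shifted for the canonical 2-nt 3' overhangs, bulges skipped) and
matched in the tag library by exact sequence equality — conservative on
purpose. Star support is recorded as evidence (`star_reads`), never as a
gate: genuine miRNAs frequently lack a sequenced star because star
abundance runs an order of magnitude below the mature. Among a tag's
windows, the accepted candidate with the lowest MFE wins (ties: shortest
precursor, then smallest window start).

`classify_novelty()` tiers candidates: `shared` when matched (within 2
substitutions and 2 nt of terminal overhang) in a non-Vitis known set,
`vitis_specific` when matched only in the Vitis set, else
`species_specific`.

## Target scanning and cleavage prediction

`scan_transcripts()` replaces BLAST seeding with an exhaustive
complementarity scan, which is exact at the scale this package targets and
removes an external-binary dependency. Every window of the miRNA length
(and length +/- 1 when one bulge is allowed) is aligned antiparallel and
scored with the Allen penalty scheme: mismatch 1.0, G:U wobble 0.5, bulged
position 1.0, all doubled at miRNA positions 2-13 (an imported convention —
the 5'-proximal region — not restated in the source survey). The default
cutoff is 4.0. Because "fewer than four mismatches" (a raw count) and
"penalty at most 4" (weighted) can disagree, both filters are exposed
(`max_score`, `max_mismatches`); the scan defaults to the weighted rule.
Overlapping windows are reduced to the best-scoring site (ties: 5'-most).

`predict_cleavage()` returns the transcript coordinate pairing the miRNA's
10th (or 9th) nucleotide, following the alignment's pair states across
bulges — the position where ligase-mediated 5'-RACE fragments of a cleaved
target are expected to map. A mismatched anchor is allowed but flagged; a
bulged anchor yields NA with the flag set. Target regions (5'UTR/CDS/3'UTR)
are labelled by the site midpoint against an optional CDS model.

## The synthetic study

`sim_config()` defines the simulated conditions; `simulate_small_rna()`
emits a genome, GFF3-exportable tracks, an adapter-flanked FASTQ-ready read
set and a complete truth ledger. The defaults emulate the published
library's statistical shape:

* **Category proportions** default to the exact ratios of the published
  redundant counts (so they sum to 1), and read budgets are apportioned by
  largest remainder — sampling noise never moves a category by more than
  rounding.
* **Length profile** peaks at 24 nt (0.37) with 21 > 22 > 23 next and
  20-24 nt covering 85% of reads. Planted siRNA-locus tags are 24 nt (the
  canonical plant heterochromatic siRNA length); conserved matures are
  21 nt, novel matures 20-23 nt.
* **Expression** is log-normal (meanlog 5, sdlog 1.5), reproducing a
  heavy-tailed copy-number spread over roughly four orders of magnitude.
  Novel miRNAs draw from a small slice (5%) of the unannotated budget,
  reflecting that novel miRNAs are reported as mostly low-abundance.
* **Variants**: a configurable fraction of conserved miRNAs carries a
  planted miR-SNP (single substitution at a uniform internal position)
  and/or a miR-LD (1-2 nt terminal shift realised from the precursor
  context, so length variants still map to the genome). Variant reads
  default to 3% of wild-type reads — always rarer than the wild type.
* **miRNA*** reads run at 10% of mature reads, the frequency convention for
  star accumulation; half of novel hairpins carry sequenced stars.
* **Hairpins are verified constructions.** Each precursor is an arm, an
  unpairable A/C loop, and a reverse-complement star arm with one
  controlled defect. The defect is mandatory — a perfect star arm would
  make the mature match the opposite strand of its own precursor and
  trigger the siRNA signature — but it must not displace the
  minimum-energy structure, so each precursor is checked against
  `evaluate_candidate()` and redrawn until accepted with the designed arm
  and star. Decoys are composition-preserving shuffles (non-overlapping
  2-mer permutation) of hairpin-like neighbourhoods, and symmetrically are
  verified *non*-hairpins: the shuffle is redrawn while any window around
  the planted tag passes the criteria. Both verifications enforce the
  generator's contract; they do not touch the pipeline under test.
* Reads are insert + 3' adapter truncated to 36 nt with uniform high
  qualities; a small extra set (1%) of low-quality duplicates exercises the
  quality filter. The 5' adapter never appears inside sequenced reads, as
  in real single-end small-RNA data, but the trimmer supports it.

What the generator does **not** emulate: position-dependent quality decay,
homopolymer errors, isomiR ladders from imprecise Dicer processing,
multi-chromosome genomes, repeat-induced multi-mapping ambiguity, and
composition bias of real genomes. Passing the closed-loop tests therefore
demonstrates correctness of the pipeline's logic under clean conditions,
not robustness to every artifact of real libraries.

## Problem sizes and runtime choices

The test suite and the acceptance script run the closed loop on a 60 kb
genome, 20,000 reads, 12 conserved miRNAs in 6 families, 8 novel hairpins
and 20 decoys, with hairpin windows up to 60 nt of flank in 20 nt steps
(the planted precursors are about 70 nt, so the grid covers them with
margin). These sizes keep a full run under half a minute while leaving
every code path exercised; all of them scale up through `sim_config()` and
`pipeline_config()`. The default `max_flank = 280` nt suits real genomes
where precursors can exceed 300 nt.

## Degenerate inputs and tie-breaking, collected

* Empty read sets flow through cleaning unchanged; an empty tag set is an
  error only where a distribution is undefined (`length_distribution()`).
* `fold()` rejects non-ACGT input; sequences shorter than 2 nt return the
  empty structure with MFE 0. Traceback prefers the unpaired branch on
  ties, so MFE 0 always reports zero pairs.
* All orderings are total: collapsing (count, then sequence), assignment
  (substitutions, overhang, id), candidate selection (MFE, length, window
  start), hits (score, transcript, coordinate). Re-running any stage with
  the same configuration and seed is byte-identical, and the run manifest
  records the seed and an md5 of the resolved configuration.

## Known limitations

* The built-in energy model is a teaching-grade approximation: adequate to
  rank hairpin windows and enforce geometry, unsuitable for comparing
  kcal/mol values with thermodynamic folders — use the external engine for
  that.
* Conservation calls depend entirely on the user-supplied known sets; no
  online database is consulted.
* Genomic mapping is exact-match only; sequencing variants of a tag map
  zero loci and are handled at the sequence level (conserved matching,
  variant calling) instead.
* The siRNA category rule is a stand-in for an unrecoverable in-house
  definition and should be treated as indicative.
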