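---
title: "Methods: transcriptome QC, abundance and siRNA design in potoroo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome QC, abundance and siRNA design in potoroo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potoroo)
```

# Scope

`potoroo` re-implements, as a tested and reusable pipeline, the
computational stages behind a de novo transcriptome resource for rat
kangaroo (*Potorous tridactylus*) PtK2 kidney epithelial cells: read
trimming and base statistics, in-silico k-mer coverage normalization,
assembly statistics, ORF detection, read mapping with TPM/FPKM
estimation, library complexity, ortholog completeness classification,
annotation summaries, exon-structure inference and consensus siRNA
design with off-target screening. The assembly step itself (a de Bruijn
graph assembler) and database annotation (BLAST/Pfam/eggNOG/GO searches)
are out of scope; the package consumes assembler-style transcript sets
and annotation reports.

Every stage is exercised by a seeded synthetic generator, so the whole
pipeline is testable offline with known ground truth.

# The synthetic data generator

`sim_config()` fixes the study conditions the generator emulates:

* **Library geometry.** Paired-end 150 nt reads from ~275 bp inserts
  (`fragment_mean = 275`, `fragment_sd = 25`), non-stranded (fragment
  orientation flipped with probability 0.5). Fragments shorter than a
  read run into a 33-nt sequencing-adapter prefix, exercising adapter
  trimming.
* **Gene structure.** Loci with 3–8 exons of 100–400 nt separated by
  introns of 60–400 nt (minimum 30 nt), placed without overlap on one
  chromosome; half-open 0-based coordinates throughout; minus-strand
  genes are stored as plus-strand exon intervals with a strand flag.
  Introns carry canonical `GT..AG` termini, as real introns
  overwhelmingly do.
* **Coding content.** A configurable fraction of loci (default 0.7)
  carries a stop-free ORF of at least 100 codons spanning most of the
  mature transcript. The default of 0.7 favours coding loci because the
  downstream stages under test (ORF calling, completeness, siRNA
  design) operate on them; the genome-wide coding fraction is a free
  parameter, not a claim about any real transcriptome.
* **Isoforms.** Each locus emits `1 + Geometric` isoforms (mean 3.7,
  the per-locus isoform multiplicity the pipeline's statistics report),
  as exon-skip variants and/or alternative terminal-exon lengths.
  Variant structures are sampled without replacement so two isoforms of
  one locus never share the same structure; when a locus supports no
  variant at all (for example a single-exon gene), an identical isoform
  is emitted with a warning.
* **Abundance.** Locus abundance on the log10-TPM scale is drawn from a
  two-component mixture for coding loci (`0.5·N(0.3, 0.4) +
  0.5·N(1.5, 0.5)`) and from the low component (`N(0, 0.4)`) for
  non-coding loci, then split across isoforms and renormalized to sum
  to 1e6. This reproduces the qualitative bimodality of deeply
  sequenced poly(A) libraries; the parameters are configuration, not
  claims.
* **Quality and errors.** Mean Phred 38 at cycle 1 decaying linearly to
  30 at cycle 150, Gaussian jitter (sd 3), floored at 2; substitution
  errors injected at each base's quality-implied rate. No indels and no
  PCR-duplicate model: what passing tests show about real data is
  therefore limited to substitution-type noise and uniform fragment
  sampling; positional bias, GC bias and duplication structure are not
  emulated.

One master seed drives everything; each stage derives its own seed by a
stable hash of the stage name, so a fixed configuration yields
byte-identical FASTA/FASTQ outputs.

# Read QC

`trim_read_pairs()` merges the cascade of external trimmers the
original processing chained into one fixed-order rule set: (1) adapter
clip at the best suffix/prefix overlap (at least 5 nt, at least 90%
identity; the leftmost qualifying start, i.e. the longest overlap,
wins), (2) removal of up to two trailing Ns, (3) quality-trimming of
both ends below Phred 28, (4) rejection when mean quality falls below
28 or fewer than 20 nt remain. A pair is rejected when either mate is;
the first failing mate's reason is recorded, so reasons partition the
rejected pairs.

Q20 is reported per base (the fraction of base calls with Phred >= 20);
a per-read variant (`q20_read_pct`) is computed alongside because the
phrase "percentage of sequences with error rate below 1%" admits both
readings. The per-base figure is the community convention at the scale
of the usual published values.

`normalize_by_kmer_coverage()` is a single streaming pass with a
canonical-k-mer (lexicographic minimum of k-mer and reverse complement,
k = 25) count table: a pair is accepted iff the median multiplicity of
at least one mate is at most 30, and only accepted pairs update the
table. The pass is order-dependent by design, matching digital
normalization semantics; its output is always a subsequence of its
input.

# Assembly statistics

`n50()` returns the largest length L such that transcripts of length
>= L hold at least half the assembled bases; the result is always an
element of the input.

`find_orfs()` is a longest-ORF stand-in for dedicated ORF extractors:
all six frames are scanned (the library is non-stranded); candidates
are ATG-to-stop, transcript-edge-to-stop (5'-partial) and ATG-to-edge
(3'-partial); the longest candidate with at least `min_codons`
(default 100) wins, with ties preferring the plus strand, then the
lowest frame, then the smallest start. Two deliberate conventions:
5'-partial candidates are accepted only when translation starts at the
transcript edge itself (frame 0) — a candidate beginning mid-sequence
without an ATG is not a credible ORF — and edge-to-edge (doubly
partial) candidates are not emitted. Translation never applies
initiator-codon rules (a leading CTG is leucine, not methionine).

Unigenes are inferred from the assembler's hierarchical identifiers
(the prefix before the final `_seq<k>`), not by sequence re-clustering.
Clusters are coding Unigenes with two or more coding isoforms,
singletons have exactly one; non-coding Unigenes count in neither, so
clusters + singletons always equals Unigenes-with-ORF. Both the total
Unigene count and the coding Unigene count are reported explicitly,
because "Unigenes" is used for both in common summary tables.

# Read mapping and abundance

`map_reads()` is a deliberately small stand-in for a short-read
aligner: 31-mer seeds at up to three non-overlapping offsets per mate,
both orientations, verified by full-mate comparison with at most two
substitutions (no indels). Mates landing inward on one transcript with
a fragment of at most 800 nt are concordant; an inward pair with a
longer fragment is kept but flagged discordant. All equally-best
placements (minimal total mismatches) are reported, which is what
makes multi-mapping visible to the estimator.

`estimate_abundance()` computes `effective_length = max(length -
fragment_mean + 1, 1)` and resolves multi-mapped pairs with a
simplified EM: fractional assignment of each pair proportional to
`theta_t / el_t` over its placements, `theta` re-estimated as summed
fractions, iterated until the relative change drops below 1e-8 or 1000
iterations. It deliberately omits the fragment-length likelihood and
quality model of full estimators; TPM and FPKM use the standard
formulas and TPM always sums to 1e6. Strictly nested isoforms (an
alternative terminal-exon variant is a substring of its parent) carry
no distinguishing sequence, so transcript-level rank recovery is
evaluated on exon-skip variants, whose junctions are mutually
exclusive; with both variant kinds present, locus-level abundances
remain accurately recovered (Spearman rho ~0.997 in the test
conditions) while nested-isoform ranks are not identifiable.

`library_complexity()` samples concordant, uniquely mapped pairs with
a fixed seed and reports unique mate start sites over mapped reads
(unpaired) and unique fragment start/stop pairs over mapped pairs
(paired). At desk scale these values are dominated by birthday
collisions on a small transcriptome and are not comparable to
full-library values.

# Completeness and cross-species identity

`global_align_identity()` is Needleman–Wunsch with affine gaps (a gap
of length L costs `gap_open + L*gap_extend`; defaults 11/1, BLOSUM62)
and deterministic tie-breaking (match over gap, then gap in the second
sequence). Identity divides identical columns by the full alignment
length including gap columns; the shorter-sequence denominator is a
configuration switch because published identity tables rarely state
their convention, and neither convention is asserted against any
published table.

`search_protein()` is seed-and-extend local alignment (exact 4-mer
seeds, Smith–Waterman extension) with no low-complexity masking, so
short degenerate peptides still find their verbatim copies — the
behaviour needed to recover extreme cases like a 25-residue
arginine/lysine-rich ribosomal peptide. `classify_completeness()`
keeps the classical coverage rule: complete at >= 70% reference
coverage by a reportable hit, partial below, absent with no hit at the
score threshold. The HMM/e-value machinery of core-gene pipelines is
replaced by raw score + coverage; the classification logic is the
content, not the search engine.

`most_abundant_full_length()` walks a gene's isoforms by decreasing
TPM and accepts the first whose protein is full-length against the
reference: length ratio within [0.85, 1.20] (bracketing the
87.7%–106.3% spread seen across well-assembled ortholog sets) and a
global alignment reaching within 15 residues of both reference
termini.

# Exon inference

`infer_exons()` chains maximal exact matches (>= 20 nt, found by
k-mer anchoring and diagonal merging) between an mRNA and genomic
sequence, maximizing total transcript coverage by dynamic programming;
both the given orientation and the reverse complement are tried. Exact
matching (no mismatches) is sufficient for same-species or
close-relative alignment and keeps the chain semantics simple; a
mismatch-tolerant mode is deliberately out of scope.

A subtlety dictates the reconstruction step: a maximal exact match can
extend one or two chance bases across a splice junction, making the
blocks of adjacent exons overlap in transcript coordinates. Chaining
therefore tolerates overlaps (scoring covered bases, not block sums)
and the junction split is chosen inside the overlap, preferring a
split flanked by a canonical splice motif (`GT..AG`, or `CT..AC` for a
gene on the genomic minus strand) and falling back to the maximal
upstream block. Motifs are preferred on ties, never required.
Genomic gaps between chained blocks are putative introns, annotated
with their terminal dinucleotides.

`compare_exon_tables()` assigns exon ordinals by clustering genomic
intervals that overlap by at least 1 nt (ordered by genomic start) and
tabulates per-isoform block lengths, flagging exons that vary in
length or are absent — the standard exon × isoform comparison view.

# siRNA design

`design_sirna()` implements the published procedure: enumerate every
19-nt window of the canonical ORF that occurs verbatim in all of the
gene's isoforms; score with a panel of three scorers; keep candidates
appearing in at least two of the three top-10 lists; screen survivors
against the whole transcriptome and discard a candidate if (a) an
off-target window matches it (or, by default, its reverse complement)
in at least 18 of 19 positions — Hamming similarity, no indels — or
(b) a contiguous stretch of at least 16 of its nucleotides occurs
exactly in an off-target transcript. Hits to the target Unigene's own
isoforms are excluded. The two rules are genuinely distinct: a single
central substitution trips (a) but not (b); a verbatim 16-mer with
three scattered mismatches trips (b) but not (a).

The screen is index-based: exact postings of all 16-mers for rule (b),
and two half-length seed tables for pigeonhole Hamming search at one
allowed mismatch for rule (a) (a full scan replaces the pigeonhole
when the threshold allows more mismatches). The index-based verdicts
are tested for exact agreement with an exhaustive
every-window-both-orientations scan.

The three built-in scorers are documented rule-based stand-ins for
external design services (GC window 30–52%; thermodynamic end
asymmetry from nearest-neighbor stacking energies, favouring an
unstable 3' sense end; composition penalties for base runs and
self-complementarity). The consensus and discard rules — the procedure
itself — are exact; the scorer panel is pluggable, and any function
from sequences to scores can replace a built-in.

# Pipeline and numerical choices

`run_pipeline()` executes the enabled stages in dependency order with
one master seed, re-checks the partition identities of the assembly
statistics at report time, and fails with a named error when a stage's
dependency is disabled. Reports are written as a summary table with
the conventional row labels, a TSV, and a JSON serialization that
excludes wall-clock timings so identical configurations produce
identical files.

Numerical conventions collected in one place: all coordinates 0-based
half-open; minus-strand features stored on plus-strand intervals with
a strand flag; EM tolerance 1e-8 (relative) with a 1000-iteration cap
and uniform-split initialization; quartiles by linear interpolation
(the common statistics-package default); ties in every ranked list
broken lexicographically; empty inputs produce warnings and zero/NA
results rather than errors wherever a downstream stage can continue.

Default problem sizes used by the test-suite and the acceptance
script — 60 genes, ~200 isoforms, 100,000 read pairs for abundance
recovery; 50 genes for exon-boundary recovery; 100 randomized
transcriptomes for the off-target screen cross-check — were chosen as
the smallest sizes at which the stochastic recovery properties are
stable across seeds.

# Known limitations

* The mapper ignores indels and quality values; reads whose first
  three 31-mer seeds all contain errors go unmapped (~0.3% at the
  default quality model).
* The EM is position-agnostic; nested isoform variants are reported
  but their individual abundances are not identifiable (see above).
* Exon inference requires exact matches, so it is limited to
  same-species or very close cross-species alignment.
* The annotation module summarizes existing reports; it performs no
  database searches and no GO-graph propagation (direct annotations
  only).
* Desk-scale library-complexity values are not comparable to
  full-library sequencing runs.
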