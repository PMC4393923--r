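---
title: "Methods: quantifying what strand specificity buys you"
author: "strandcheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying what strand specificity buys you}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A non-strand-specific (NSS) RNA-seq library erases the strand of origin of
each cDNA fragment. For most transcripts this is harmless. For transcripts
that overlap another gene at the antisense strand it is not: a read mapping
inside the shared exonic region aligns equally well to both mRNAs, and the
standard remedy — assigning weight 1/k to each of the k compatible
transcripts — implicitly assumes the two transcripts are equally abundant.
For a pair with true abundances $a_1 \gg a_2$ and overlap fraction $o$, the
equal-split expectation of the estimated count for transcript 1 is roughly
$a_1(1-o') + \tfrac{o'}{2}(a_1+a_2)$ where $o'$ is the fraction of reads
falling wholly inside the shared region, so both estimates are pulled toward
the pair mean and the estimated ratio is pulled toward 1. A strand-specific
(SS) protocol preserves orientation, sense-only counting becomes
unambiguous, and the bias disappears. Everything in this package either
measures that mechanism, controls for it, or exploits strand specificity to
find transcription the NSS protocol cannot see.

The central quantities:

* **Overlap value** $O$: for each member of an antisense-overlapped pair,
  the shared exonic base count divided by that transcript's mRNA (exonic)
  length, times 100. It is asymmetric: the same shared bases are a small
  fraction of a long transcript and a large fraction of a short one. We
  compute shared bases as the exon-by-exon genomic intersection, not the
  span intersection, because read-assignment ambiguity only arises where
  exons actually share bases; intron-only antisense overlap produces no
  ambiguous reads and is excluded from the "mutually overlapped" set.
* **RPKM**: weighted count / (exonic length / 1000) / (mapped library reads
  / 1e6). Counts are fractional exactly when equal-split allocation fired.
  The mapped-library denominator is counted per strand mode (distinct reads
  with at least one surviving assignment under that mode), which is also
  the numerator convention of the mappable-rate QC.
* **Delta-Ct fold change**: $FC = 2^{Ct_{control} - Ct_{target}}$, with
  amplification efficiency fixed at 2 (no efficiency calibration is
  attempted). A panel of T targets, C internal controls and K replicates
  yields $T \times C \times K$ fold changes; RPKM fold changes have no
  replicate dimension and are expanded across replicates when the two sets
  are aligned.

## Procedures and their assumptions

**Annotation.** refFlat records (11-column UCSC dialect, 0-based half-open,
comma-terminated exon lists) become a `TranscriptSet`. Transcripts whose
accession appears on more than one line map to multiple loci and are
removed entirely before overlap analysis — multi-locus detection keys on
accession string equality alone. Overlap detection then considers every
same-chromosome, opposite-strand pair with positive exonic intersection.
Because exons within a transcript are disjoint, per-exon-pair intersection
widths sum exactly to the shared base count (verified in the tests against
a per-base boolean-mask oracle).

**Quantification.** Alignments arrive as SAM (converted internally via
Rsamtools; FLAG 0x10 gives orientation, the NM tag gives mismatches,
secondary alignments are kept because equal-split needs every placement).
Reads with more than `maxMismatches` (default 3, the conventional
three-mismatch cap for 101-base reads) are discarded before anything else,
including the library-size denominator. Counting runs in transcript space
by default; genome space projects contiguous read intervals onto exons and
assigns a read to every transcript overlapping it by at least one base. A
read assigned to several transcripts — including isoforms of one gene —
splits equally; total weight per counted read is exactly 1.

**Overlap-stratified concordance.** Overlapped transcripts are binned by
their *maximum* overlap percentage across partners, default decile edges
(0,10], ..., (90,100]; the edges are a parameter because reasonable analyses
may bin differently. Within each bin we take Pearson correlation of log2
RPKM between the SS and NSS libraries, keeping transcripts whose read count
exceeds 1e-4 in both libraries (this guards the log against zero and
near-zero fractional counts; no pseudocounts are added). The control
("mimic") redraws, for each bin size, that many transcripts *without
replacement* from the nonoverlapped O = 0 pool — a mimic set imitates set
membership, and membership does not repeat a transcript — and averages the
correlation over replicates (default 100). Flatness of the mimic curve is
judged against the empirical resampling standard error of a single
resampled correlation (the SD across replicates): if the spread of mimic
means across bin sizes stays within twice that scale, set size does not
explain differences between bins.

**qPCR concordance bootstrap.** The resampling unit is the *target gene*
(drawn with replacement, controls and replicates expanded), because the
worry being addressed is that a small gene panel over-weights particular
genes; resampling individual fold-change tuples is available via
`unit = "tuple"`. Correlations are computed on log2 fold changes — fold
changes span orders of magnitude and the log2 scale is the package's
uniform choice. The two per-replicate correlation distributions are
compared with a paired two-sided t-test plus the plain fraction of
replicates favouring SS. Replicates drawing fewer than three distinct genes
are redrawn (correlation needs three points), with a retry cap.

**Strandedness QC.** Mappable rates divide by *all* sequenced reads, mapped
or not. The sense:antisense mappable-rate ratio is the library-level
strandedness statistic: near 1 for NSS, far above 1 for SS, with the
antisense fraction of mapped reads estimating the SS leakage level.
Per-transcript sense/antisense count ratios are reported only for
transcripts reaching 10 reads on both strands — smaller counts produce
dramatic ratios that are pure sampling noise. Gene-body coverage assigns
each aligned base (CIGAR M/=/X, not the read span) at transcript position
$p$ of a length-$L$ transcript to bin $\lfloor 100p/L \rfloor$, then
divides by total mapped bases.

**Antisense discovery.** Assembled contigs come in as PSL. Identity is
matches / (matches + mismatches + query gap count), the standard mRNA
convention, with the threshold 0.95 boundary-inclusive. A contig passing at
several loci keeps only its best-identity locus; an exact tie is ambiguous
and drops the contig. Splice validation is strict GT-AG on the contig's
strand (minus-strand introns must read CT...AC on the genomic plus strand);
the minor GC-AG and AT-AC classes are deliberately rejected. A contig
qualifies as novel antisense only if it overlaps known exons exclusively on
the opposite strand — any same-strand exonic overlap marks it as a fragment
of a known gene — and by default only known genes that are not themselves
antisense-overlapped are eligible hosts (`nonoverlappedOnly = FALSE`
relaxes this). Grouping into novel genes takes the transitive closure of
same-strand exonic overlap; transcripts a few hundred bases apart but
without shared exonic bases remain separate genes, which is exactly the
situation the FCsame/FCdiff test then interrogates: if neighbouring novel
genes hosted by the same known gene have systematically more similar
expression (smaller max/min RPKM fold changes, one-sided Welch t-test on
log2) than novel genes from different hosts, they plausibly are fragments
of one transcript that assembly failed to join.

## The synthetic-data generator

The generator exists so that every claim above can be tested against known
truth. Its defaults describe the study conditions the package is validated
under: 101-base single-end reads; log-normal true abundances (sdlog 1.5, a
typical bulk RNA-seq dynamic range); fragment starts drawn Beta(1, 2) along
the transcript, giving the 5'-biased, decaying gene-body coverage seen in
oligo-dT-primed libraries; SS strand leakage 0.13 (matching the antisense
fraction observed in real SS libraries of this design); qPCR noise 0.1
cycles across three replicates. Antisense pairs are built as two
opposite-strand single-exon transcripts positioned so both sides realize a
target overlap fraction to within rounding; singleton genes carry 1–6 exons.
Reads falling wholly inside a shared exonic segment receive a secondary
alignment on the partner in flipped orientation — this, and nothing else,
is what makes equal-split allocation engage downstream, so the bias in the
simulation arises by the same mechanism as in real data rather than being
painted on. Planted novel antisense transcripts are written inside
singleton hosts with canonical splice dinucleotides edited into the genome,
and a perfect-alignment PSL writer (`transcriptsToPsl`) stands in for the
assembler/aligner when building discovery fixtures.

What the generator does **not** emulate: sequencing errors and quality-
dependent mismatches (mismatch filtering is tested with explicit counts
instead), PCR duplicates, GC bias, paired-end fragments, multi-isoform
genes sharing exons, and expression correlation between neighbouring genes.
Tests passing on this generator therefore demonstrate the *mechanisms* —
equal-split bias, leakage estimation, overlap-binned decorrelation,
GT-AG-filtered recovery — not performance on any particular real library.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open externally (refFlat, PSL, SAM POS-1)
  and 1-based closed IRanges internally; conversions happen only at I/O
  boundaries.
* Correlation requires three points; smaller sets return `r = NA` with an
  `ok = FALSE` flag rather than a value.
* A library with zero antisense-mapped reads reports an infinite
  sense:antisense ratio with an explicit flag instead of an error.
* Zero-RPKM novel genes are skipped pairwise (with a warning) in
  FCsame/FCdiff rather than producing infinite fold changes.
* Transcripts shorter than the read length are excluded from read
  simulation with a warning and recorded in the result.
* Seeds are mandatory wherever resampling occurs (`mimicResample`,
  `bootstrapCompare`); every generator is bit-reproducible given
  (seed, config).

## Problem sizes

The validation suite runs at desk scale, chosen to finish in minutes while
keeping sampling error well below every asserted effect: the equal-split
bias demonstration uses a 70%-overlap pair with a 4:1 ratio at 1e5 reads
over 100 seeds; the overlap-binned correlation uses 300 antisense pairs
spread over all ten overlap deciles plus 120 nonoverlapped genes at 3e5
reads with 100 mimic replicates; strandedness QC uses 30-gene annotations
at 1e5 reads; discovery recovery plants 10 transcripts in 5 hosts. The
packaged 12-gene qPCR table and 9-transcript novel-gene table are analysed
in full.

## Known limitations

* Multi-mapping across *nonoverlapping* loci is resolved by the same
  equal-split rule rather than an EM model; statistical read-assignment
  models are explicitly out of scope, since for antisense overlap the SS
  protocol itself is the fix.
* Host assignment picks the single largest-overlap known transcript; a
  contig genuinely antisense to two adjacent genes is attributed to one.
* The genome-space counting path requires contiguous alignment intervals,
  so spliced (junction-spanning) reads are only handled in transcript
  space; the simulator's genome-space projection drops junction reads and
  reports how many.
* Overlap-bin edges for the concordance analysis are a free parameter;
  results should be read with the binning in mind.
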