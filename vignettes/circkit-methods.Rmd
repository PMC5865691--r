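---
title: "Classifying and quantifying circular RNA back-splice junctions with circkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and quantifying circular RNA back-splice junctions with circkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circkit)
library(dplyr)
```

## The problem

A circular RNA (circRNA) arises when a downstream splice donor is joined to
an upstream splice acceptor of the same transcript. The only direct evidence
of a circRNA in RNA-seq data is a *back-splice* (BS) junction read: a read
spanning the non-colinear join between the 3' end of the downstream
circularising exon (3'CE) and the 5' end of the upstream one (5'CE). That
junction sequence does not exist in any linear transcript, which makes it
both the defining signature of a circle and an awkward target for standard
aligners.

circkit provides the desk-scale machinery around this signature:

* **classification** of BS coordinate pairs against a reference
  transcriptome into five mutually exclusive categories, with a univocal
  main-isoform resolution and a rank-based nomenclature;
* **junction reconstruction**: the 2L-nt sequence window centred on the BS
  point, built from the genome;
* **quantification** of junction-spanning reads in FASTQ samples with a
  two-stage procedure — a k-mer hash pre-selection followed by
  Smith-Waterman confirmation and best-hit counting;
* **control constructions** (half-permuted chimeras, nucleotide shuffles,
  intron-length-matched gene pairings, divergent repeat-pair calls, and an
  exon-level signal-ratio score);
* a **simulator** that generates toy genomes, annotations, planted circRNAs
  of every category and reads with known truth, so the whole pipeline is
  testable without downloads.

## Coordinates and data model

All internal coordinates are 0-based half-open; only readers and writers
convert (CIRI-style tables are 1-based inclusive, BED is 0-based, GTF goes
through rtracklayer). The BS sites are single-base positions: on `+` the 5'
BS site is `start` and the 3' site is `end - 1`; on `-` they swap ends. Exon
ranks are always strand-aware: rank 1 is the 5'-most exon in transcript
orientation, which on the minus strand is the genomically last exon. This is
the only convention under which statements like "the second and third exons
circularise most often" are meaningful.

Everything user-facing is a tibble; sequences travel in Biostrings
containers. The transcript "gene span" used for intergenic calls is the exon
hull of the transcript; annotation files carrying explicit gene features are
reduced to their exon content on reading.

## Classification

Each circRNA/transcript overlap is classified by a fixed-precedence
decision tree:

1. any BS site outside the transcript span → **intergenic**;
2. any BS site inside an intron → **intronic**;
3. both BS sites exactly on exon boundaries (5' site at an exon's 5'
   boundary, 3' site at an exon's 3' boundary, transcript orientation) →
   **monoexonic** if the same exon, otherwise **multiexonic**, with exon
   ranks attached;
4. otherwise → **putative exonic** (both sites exonic, no precise boundary
   match).

The precedence makes the five categories mutually exclusive and total: every
record gets exactly one label. Two genuinely open points were resolved as
follows. *Monoexonic* requires an exact boundary match on one exon; an exon
merely containing both sites is putative exonic — this keeps "no precise
match" and "spans the entire exon" disjoint. Boundary matching tolerance is
0 bp by default and configurable (`wobble`) for annotation-mismatch studies.

Univocal resolution across isoforms prefers the main isoform, identified by
the `001` suffix of the transcript name (after an optional `-` or `.`
separator, as in `GENE-001`); failing that, transcripts are evaluated in
annotation-file order with ties broken by transcript id, and the first
classification is kept. circRNAs overlapping no transcript are intergenic
with a null transcript.

Names follow the field convention: `Circ_<GENE>_<r>` (monoexonic),
`Circ_<GENE>_<r5>-<r3>` (multiexonic), `Circ_<GENE>_I` (intronic),
`Circ_<GENE>_PE` (putative exonic; no established rule exists for this
class, so a transparent suffix is used), and
`Circ_<chrom>:<start>-<end>(<strand>)` with 1-based inclusive display
coordinates for intergenic events.

Summary tables report counts and fractions per category, per number of
exons spanned (`rank3 - rank5 + 1`, multiexonic + monoexonic only), and per
5'/3'CE rank. Exon-span fractions are taken over *all* classified circRNAs,
so that "two-exon circles are 19% of the set" reads the same way regardless
of how many intronic or intergenic records the set contains.

```{r classify-demo}
ref <- simulate_reference(n_genes = 8, seed = 7)
circs <- plant_circrnas(ref, c(multiexonic = 3, monoexonic = 2,
                               intronic = 1), seed = 8)
classified <- classify_circs(circs, ref$exons)
classification_summary(classified)
```

## Junction reconstruction

For a circRNA spanning `[start, end)` the strand-oriented genomic sequence
`S` of the span is taken and the junction is the last `L` bases of `S`
followed by the first `L` (default `L = 35`, a 70-nt window). The flanks are
*genomic* windows abutting the BS sites: for exonic circRNAs the BS sites
sit at exon boundaries, so the flanks run into the circularised exons; when
an exon is shorter than `L` the window simply continues into the
neighbouring retained intron of the circle. Introns are never spliced out of
the flanks — the window is anchored at the BS point, not at a spliced
transcript.

Circles shorter than `2L` are split in two halves: with `h = ⌈|S|/2⌉` the
junction is the rotation `S[h+1..] + S[..h]`, so odd lengths place the extra
base 3' of the BS point and rotating back by the stored `junction_offset`
reproduces the circle sequence exactly. In all cases the pair
`(sequence[offset], sequence[offset+1])` is the last and first base of `S` —
the back-splice itself.

A spliced-flank variant (concatenating exonic sequence across the BS) was
considered and not implemented: the genomic window is the construction the
quantifier's reference set is defined on, and nothing downstream consumes a
spliced variant.

## The two-stage quantifier

The quantifier takes a reference set `s1` (the junction FASTA) and read sets
`s2` (FASTQ samples) and three parameters:

* `k` — k-mer length;
* `N` — minimum number of read k-mer positions present in the reference
  index for the read to be kept as *putative*;
* `M` — minimum Smith-Waterman score for a putative read to be counted.

**Stage 1** decomposes every reference into its `len - k + 1` overlapping
k-mers and stores the set in a hashed index (`isPresent`). Unstranded mode
(the default — read strand is generally unknown in these libraries) also
indexes the reverse-complement k-mers. K-mers containing N are never indexed
and never match.

**Stage 2** scans each read once, counts how many of its k-mer positions hit
the index, and keeps reads with at least `N` hits (a `strict_gt` flag
restores a strictly-greater reading; the at-least form is the one consistent
with the parameter arithmetic — a 50-nt junction-spanning read shares at
most 30 k-mers at `k = 21`, and `N = 17` must admit it). Shared k-mers are
counted against the union index rather than per reference; a per-reference
count would only differ when two references share k-mers, in which case
stage 3 arbitrates anyway.

**Stage 3** aligns every putative read against every reference with a
Smith-Waterman kernel (match +2, mismatch −2, affine gaps costing 3 for the
first gapped base and 1 per extension — the convention of the SIMD
alignment libraries; with match +2, `M = 30` is roughly 15 aligned bases).
Unstranded mode takes the better of the read and its reverse complement per
reference. Each read increments exactly one reference — its best-scoring one
— and only when that score reaches `M`; ties go to the lexicographically
smallest reference id, which makes the output independent of input order.

Defaults are `k = 21, N = 17, M = 30` (the short-read setting; longer reads
scale to 22/18/33 or 26/21/40). Counts are emitted raw; normalisation and
differential expression belong to dedicated count-based packages and are
out of scope.

```{r quantify-demo}
jn <- build_bs_sequences(circs, ref$genome)
sim <- simulate_reads(ref, circs, bs_depth = 5, linear_depth = 3,
                      min_side_overlap = 2, seed = 9)
fq <- file.path(tempdir(), "s1.fq.gz")
write_fastq(sim$reads, fq)
res <- hashcirc_run(c(sample1 = fq), jn)
glance(res)
```

### What the filter does and does not guarantee

Two properties matter and are worth stating precisely, because the test
suite asserts both.

*Selection soundness for junction reads.* An error-free read of length `R`
is guaranteed to pass selection exactly when its overlap with the 2L-nt
junction window is at least `k + N - 1` nt (37 nt at 21/17). A 50-nt read
crossing the BS point by a single base overlaps the window by 36 nt, shares
16 < 17 k-mers, and is dropped even though its alignment score (72) clears
`M` comfortably. The simulator exposes `min_side_overlap` so fixtures can be
built on either side of this boundary; exact-recovery tests use
`min_side_overlap = 2`, the losslessness condition for 50-nt reads.

*Noise suppression, not just speed.* Under this scoring scheme the best
local alignment score of a uniform-random 50-nt read against a set of 50
random 70-nt junctions (both strands) has median ≈ 28: `M = 30` sits at the
random-alignment noise floor, and roughly a third of background reads would
be counted by a threshold-only exhaustive aligner. Those reads share
essentially no 21-mers with the references and are rejected by stage 2. The
two-stage pipeline is therefore *not* equivalent to exhaustive
Smith-Waterman with the same `M` on realistic mixed read sets — it is
better, and the package treats the conditional equivalence (restricted to
reads that satisfy both thresholds) as the invariant worth testing.

*Substitution sensitivity.* A single substitution in the middle of a 50-nt
read invalidates up to `k = 21` of its 30 k-mer positions, leaving 9 < 17:
the read is lost at selection. At a 1% per-base substitution rate about 39%
of reads carry at least one error and roughly half of those errors fall in
the destructive centre, so expected read recovery is ≈ 70–80%, not ≥ 95%.
This is an intrinsic property of long-k exact-k-mer filtering at these
settings, not an implementation artefact; detection (at least one read per
junction at realistic depth) is unaffected, which is why detection rates
stay at ~100% while per-read recovery does not. Raising sensitivity means
lowering `k`/`N`, at the cost of admitting more noise reads into stage 3.

## Control constructions

*Half-permuted chimeras.* Each control sequence joins the left half of one
junction (up to `junction_offset`) to the right half of a different one,
with the re-pairing drawn as a uniform random derangement — so each control
set conserves the left- and right-half multisets exactly and contains no
original junction. A within-sequence half swap was rejected: it preserves
both halves of the same junction and therefore most of its local sequence,
which defeats the purpose of a junction-shaped null.

*Nucleotide shuffles* permute each sequence's bases uniformly, conserving
per-sequence length and composition while destroying all k-mer structure.

*Intron-length-matched pairing* draws, per iteration (default 1000), a
control gene uniformly among those whose first-intron length is within ±10%
relative difference of the host's; with no qualifying candidate the nearest
control is used and flagged. Controls may be reused across hosts.

*Divergent repeat pairs.* A circRNA is flagged when a repeat overlapping the
500-bp flank upstream of the 5' BS site and one overlapping the downstream
flank of the 3' BS site (transcript orientation) lie on opposite strands
oriented toward each other — upstream repeat on the circRNA's strand,
downstream on the opposite one — the inverted configuration that allows the
flanking introns to base-pair.

*Exon signal ratio.* For circRNAs whose 5'CE has rank ≥ 2, fragment counts
(e.g. H3K36me3 ChIP reads) over the 5'CE and over its upstream exon are
normalised to per-base coverage and scored as
`(ce5 + ε) / (upstream + ε)` with ε = 0.1 per-base by default. The
pseudocount guards empty exons; per-base normalisation makes exons of
different length comparable, and the flag is configurable because raw-count
ratios are also in use. Interval counting overlaps by ≥ 1 bp, the
`coverageBed` convention, and is backed by GenomicRanges.

All stochastic constructions take an explicit seed and are bit-reproducible
given (seed, inputs, number of sets).

## The simulator and its limits

`simulate_reference()` lays out non-overlapping, randomly stranded genes
left-to-right on uniform-composition random chromosomes (GC skew
configurable); each gene carries one transcript named `<SYMBOL>-001`, so
main-isoform resolution is always exercised. `plant_circrnas()` places
events that *must* classify as requested: multiexonic at exact boundaries of
two distinct exons, monoexonic on one full exon, putative exonic 3 bp inside
an exon, intronic with the 5' site mid first intron, intergenic inside a
gene-free gap. `simulate_reads()` emits BS-spanning windows of the rotated
circle at uniform offsets, linear windows of spliced transcripts, and
uniform-random background, with i.i.d. per-base substitutions; read names
carry class, origin and offset, so truth reconciliation needs no side
files.

Defaults mirror a compact version of the data the method targets: 50-nt
single-end reads (the depth-scale of poly(A)-depleted total RNA-seq runs),
exons of 120–300 bp, introns of 200–800 bp, 4–8 exons per gene. What the
simulator deliberately does not model: sequencing-quality profiles, indel
errors, coverage biases, paired-end mates, overlapping genes and alternative
isoforms, and repeat-derived sequence. Passing tests on these fixtures
therefore demonstrate algorithmic correctness (coordinate arithmetic,
filtering thresholds, counting rules), not robustness to every property of
real libraries.

## Numerical and design choices, in one place

* 0-based half-open internal coordinates; readers convert, nothing else.
* Non-ACGT bases are normalised to N, preserved in length; N never matches
  in either the k-mer index or the alignment kernel.
* Main-isoform detection: transcript-name suffix `001` after an optional
  `-`/`.` separator; annotation order = file order of first appearance.
* Short-circle split puts the extra base of odd spans 3' of the BS point
  (`h = ⌈len/2⌉`).
* Selection threshold is `≥ N`; `strict_gt` restores `> N`.
* Tie-breaks (equal best alignment scores) go to the smallest reference id.
* Derangements are drawn by rejection (expected < 3 tries; `n = 2` always
  swaps).
* Desk-scale problem sizes throughout the tests and the acceptance script
  (tens of genes, 50-nt reads, ≤ 2000 reads per sample) keep the whole
  suite in minutes on one CPU; the same code paths scale to real FASTQ
  inputs unchanged.

## Known limitations

* Per-read recovery degrades with substitution errors as analysed above;
  `k`, `N`, `M` trade sensitivity against noise admission and should be
  rescaled with read length.
* The classifier trusts the annotation: no rescue of off-by-a-few boundary
  mismatches unless `wobble` is raised explicitly.
* Genomic (unspliced) junction flanks are the modelled object; tools
  expecting spliced-exon junction sequences will disagree for circles with
  exons shorter than the flank.
* The quantifier is single-end; mate information (e.g. for intron-retention
  analysis) is out of scope.
* Linear reads crossing the splice boundary of the two circularising exons
  share most of one junction flank; when the neighbouring exon happens to
  begin with the same base(s) as the 5'CE, such a read can just clear `N`
  and be counted — a rare but nonzero linear false-positive mode, visible
  as occasional single counts in linear-only negative controls.
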