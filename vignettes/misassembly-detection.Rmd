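---
title: "Detecting and correcting misassembled contigs with contigMend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting misassembled contigs with contigMend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

De novo metagenomic assemblies contain structural errors: contigs that join
sequence from two genomes (inter-genome translocations), from distant loci of
one genome (relocations), or with an inverted segment (inversions). Such
chimeric contigs contaminate metagenome-assembled genomes and distort
downstream analyses. Reference genomes are unavailable for most environmental
organisms, so contigMend detects these errors *reference-free*, using only
the alignment of the sample's paired-end reads back to its own contigs. It
scores each contig for misassembly, localizes the breakpoint inside flagged
contigs, and corrects errors by splitting contigs at breakpoints.

## Features

All evidence comes from a coordinate-sorted BAM/SAM of read-pair alignments.
Four families of features are computed per contig and per 100-bp window
(`extractFeatures()`), under one fixed manifest (`featureManifest()`).

**Read-pair consistency.** Insert sizes are modelled as N(mu, sigma) with mu
the median insert size and sigma its median absolute deviation
(`fitInsertSizeModel()`; raw MAD, no normal-consistency scaling, floored at
1 bp so the proper window never collapses). Each primary alignment gets one
of four geometry classes — proper; mate on another contig; wrong insert size
(outside mu +/- 3 sigma); wrong orientation — plus two independent flags:
clipped (>= 20 unaligned bases at either end) and supplementary (parts of
the read aligned to different places). The six per-scope fractions are
features. A chimera junction manufactures clipped reads (reads that run off
the end of their true locus) and discordant pairs (mates whose true
continuation lies elsewhere), so these fractions rise on misassembled
contigs.

**Standardized coverage.** Per-base read coverage and fragment coverage (the
number of proper-pair sequencing fragments spanning a base) are divided by
their contig-wide mean; features are the root-mean-square deviation of the
standardized value from 1 and the fraction of bases outside the (0.5, 2)
band (strict inequalities; the band is configurable — the notion of
"unusual" coverage is a design choice). Fragment coverage collapses at a
junction because no true fragment spans it.

**Nucleotide variants.** At every position the mapped base calls are counted
as correct (equal to the contig base), discordant (different A/C/G/T), or
ambiguous (N); features are the three proportions of total mapped bases.
For example, a position whose contig base is A covered by ten reads — six A,
three T, one N — counts 3 discordant, 6 correct, 1 ambiguous.

**k-mer abundance difference (KAD).** For each canonical 25-mer of the
contig with copy number n in the contig and abundance c in the mapped reads,
at contig sequencing depth m (the median read abundance of single-copy
k-mers),

KAD = log2((c + m) / (m (n + 1))).

KAD is 0 when read support matches copy number (c = n m); k-mers with KAD
outside [-0.5, 0.5] are error k-mers, and any contig base covered by an
error k-mer is an error base. Features are the error-base fraction and the
mean |KAD|. Junction-spanning k-mers exist in no real genome, have c = 0,
and score KAD = -1. k-mers containing N are skipped. k = 25 follows the KAD
reference convention; canonical k-mers are used because reads come from both
strands.

### Feature scope

Contig-level features exclude the terminal 300 bp of the contig (when the
interior remains >= 1000 bp). Contig ends generate clipped reads and
discordant mates on *every* contig — reads there extend past the assembled
sequence — and fragment coverage ramps from zero over one insert length.
These artifacts are indistinguishable from junction signal but carry no
information about misassembly, and in testing they dominated the
pair-fraction and sigma features. The same reasoning motivates the standard
300-bp terminal exclusion during breakpoint localization, so one constant is
used for both (configurable via `trim =` / `endExclusion =`).

Window-level features standardize coverage by the *contig* mean, not the
window mean: a window at half the contig's depth is precisely the anomaly a
junction produces, and within-window standardization would erase it. Window
pair fractions weight reads by their base overlap with the window.

## Classifying misassembled contigs

A down-sampled random-forest ensemble (`trainEnsemble()`): misassembled
contigs are rare, so each of 10 sub-models is trained on all positives plus
an equal-size random subset of negatives drawn without replacement; each
sub-model is a 1000-tree probability forest (ranger, sqrt-features per
split, unrestricted depth — all overridable). The misassembly score S(c) is
the mean positive-class probability across sub-models. Only contigs strictly
longer than 5000 bp are scored; shorter contigs carry most of their length
within terminal artifact range and are excluded from assemblies'
quality-sensitive analyses anyway. Models persist with their feature
manifest and loading refuses manifest drift. Training is deterministic per
seed.

## Localizing breakpoints

Windows of 100 bp (non-overlapping tiles; a sliding step equal to the window
keeps windows independent and costs linear time) are scored by an isolation
forest fitted once per sample over all contigs' windows — windows from many
contigs form the background population against which junction windows are
isolated. The package implements the classic algorithm (no isolation-forest
package is available in this stack): 100 trees on uniform subsamples with
uniformly random axis-parallel splits, scores reported as the canonical
isolation score s = 2^(-E[h]/c(psi)) in (0, 1), higher = more anomalous.
The subsample defaults to min(n, 4096) rather than the classic 256: the
score ceiling 2^(-1/c(psi)) grows with psi, which matters when an absolute
threshold is applied in isolate mode, and a larger subsample resolves rare
single-window anomalies better.

For each contig to localize, the eligible window (outside the terminal
300 bp) with the highest anomaly score is the error region (ties leftmost).
Within it, the breakpoint is the position with the highest read-breakpoint
ratio — the fraction of reads overlapping the position whose alignment
boundary (clip or split) falls there rather than at the read's end — again
leftmost on ties; a window with no read breakpoints falls back to its centre
position. The boundary coordinate convention places both flanks of a
junction at the same base (first clipped base for right clips, first aligned
base for left clips), so clip evidence from both sides accumulates at the
true junction. One breakpoint is reported per contig in metagenome mode:
multi-error contigs are a small minority and a single split already removes
the dominant error.

**Isolate mode.** For isolate (single-genome) assemblies the classifier
stage is skipped: every window with anomaly score > 0.95 is an error region,
and every position inside with read-breakpoint count > 5 and ratio > 0.2
(all strict) is emitted. These thresholds are conservative under the
canonical score convention — 0.95 sits near the theoretical ceiling of the
isolation score — so isolate mode trades recall for precision; both
thresholds are configurable.

## Correction

`correctAssembly()` splits a contig at breakpoint p into [0, p) and [p, L)
only when S(c) >= 0.8 and both fragments are at least 1000 bp; otherwise the
contig is emitted unchanged with the skip reason. Multiple breakpoints (from
isolate mode) apply sequentially left to right, re-checking the length guard
at each cut. Fragments are named `<contig>_1`, `<contig>_2`, ... and total
bases are conserved exactly — correction can fragment but never lose or
alter sequence.

## The synthetic community

`simulateCommunity()` / `injectMisassemblies()` / `simulateReads()` build a
fully truth-labelled test bed. Genomes are i.i.d. uniform ACGT backbones
(optionally with planted repeats) with Lognormal(5, 2) relative abundances.
Contigs are faithful genome slices or two-segment chimeras (inter-genome
translocation, relocation with >= 1 kb source gap, inversion), the junction
uniform in [0.2 L, 0.8 L] so it stays detectable under the terminal
exclusion. Source intervals never overlap — they are laid out along each
genome with short random spacers — so each locus is assembled at most once,
as in a real assembly, and truth alignments are unambiguous.

Reads are drawn from the *genomes* (fragments proportional to abundance,
insert ~ N(300, 30), i.i.d. substitution errors at 0.002/base, emulating a
short-read error rate) and their contig alignments are derived analytically
through the truth coordinate maps: reads inside one segment align in full;
reads overhanging a segment boundary are soft-clipped; a second disjoint
segment overlap becomes a supplementary alignment; mates resolve wherever
their own locus lives, producing mate-other-contig and wrong-orientation
pairs exactly as geometry dictates. This is what makes misassembly signal
appear at junctions without running an aligner, and the emitted
coordinate-sorted SAM is consumed by the standard ingestion path unchanged.

What the simulator does **not** emulate: position-dependent quality and
error profiles, indels, GC-coverage bias, shared sequence between genomes
(unless repeats are planted), strain mixtures, and alignment ambiguity from
repeats — real aligners produce MAPQ-0 multi-mappers that this truth map
never creates. Passing tests on this generator therefore demonstrate the
machinery is correct and the signal model sound, not that real-data accuracy
matches any particular benchmark.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; SAM input and text outputs
  are 1-based (documented per writer).
* Ties break leftmost at both the window and position level; determinism is
  guaranteed per seed everywhere randomness enters (community, reads,
  forests, down-sampling).
* Contigs with no mapped reads, all-zero fragment coverage, or no
  single-copy k-mers are excluded with a logged reason rather than imputed;
  windows without mapped bases are marked unusable.
* The read-breakpoint ratio denominator counts reads by full extent
  (including clipped tails), bounding the ratio by 1.
* sigma uses the raw MAD, floored at 1 bp; depth m must be positive or KAD
  is undefined for the contig.

## Scale of the validation runs

The packaged tests and the acceptance script run the full pipeline on two
independent replicates of a 10-genome x 100-kb community at 30x mean depth,
100 contigs of 8 kb with 20% chimeras (~150,000 read records per replicate):
train the ensemble on one replicate, evaluate on the fresh one. On one CPU
this completes in about a minute per replicate. At this scale the held-out
AUPRC, the fraction of breakpoints within 500 bp of the planted junction,
the normalized error, chimera reduction after correction, and
fragment-to-source purity are all computed by the test suite and
`scripts/acceptance.R` — the vignette states no number the code does not
itself produce.

## Known limitations

* One breakpoint per contig in metagenome mode; contigs containing several
  misassemblies are only partially corrected.
* The classifier transfers poorly across assemblers in general (different
  assemblers make different error types); train on data from the assembler
  you evaluate.
* Isolate mode's absolute 0.95 anomaly threshold is near the canonical
  score's ceiling and rarely fires at moderate depth; lower it for recall.
* KAD depth estimation is noisy below ~5x coverage, inflating the error-base
  fraction on shallow contigs; the ensemble learns this but per-contig calls
  at very low depth are unreliable.
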