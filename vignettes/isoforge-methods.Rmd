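---
title: "Multi-evidence isoform assembly and transcriptome dynamics with isoforge"
author: "isoforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence isoform assembly and transcriptome dynamics with isoforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoforge)
```

## The problem

Long sequencing reads can span complete mRNA molecules, but individual
reads carry three characteristic artifacts: splice-boundary errors of a
few nucleotides, spurious short "bubble" introns inside exons, and 5'
truncation from RNA degradation or incomplete reverse transcription. A
read on its own therefore cannot be trusted as an isoform model.
isoforge rebuilds trustworthy isoforms by confronting every read with
three independent short-read assays: cap-tag (CAGE-style) 5' signal
defining transcription start sites (TSS), polyadenylation-tag 3' signal
defining transcription end sites (TES), and splice-junction counts from
spliced short-read alignments. On top of the validated annotation it
computes the transcriptome-dynamics statistics that alternative
promoter, polyadenylation and splicing studies report: an entropy
tissue-specificity score, dominant-site switch scores, weighted 3'UTR
lengths and alternative-polyadenylation (APA) calls, microexons,
intronic-terminus coupling events, a branching-process null model for
alternative-splicing (AS) hotspots, and polycistron detection.

## Coordinate conventions

All internal coordinates are 1-based closed intervals, the native
convention of the GenomicRanges containers the package is built on.
BED, bedGraph and junction tables are converted from their 0-based
half-open conventions at the file boundary; GFF3/GTF are already
1-based closed. A splice junction is stored as the first and last base
of its intron. Spliced (transcript) coordinates run 5' to 3' and are
1-based; a CDS is stored in spliced coordinates with the stop codon
included.

## Tag clustering

TSS and TES positions come from per-base tag counts clustered with a
density-based maximal-scoring-segment scheme. A candidate cluster is a
run of tag positions that, for some density parameter d, has every
prefix and suffix denser than d while no longer run does. Densities
follow the convention in which a prefix ending at position k is
measured against the distance to the next tag, so a single position has
infinite density and the candidate family is laminar (nested or
disjoint). Each candidate carries the largest density at which it holds
together (`max_den`) and the largest density of any enclosing candidate
(`min_den`); a cluster is retained when

* its summed tag count is at least `min_value` (default 20 tags),
* its genomic span is at most `max_length` (default 200 nt), and
* its stability `max_den / min_den` is at least `min_density_fold`
  (default 5).

Retained candidates nested inside another retained candidate are
flattened away, leaving disjoint clusters. The implementation is a
recursive weakest-boundary split; the test suite proves it equal to an
exhaustive enumeration over all O(n^2) runs on hundreds of random
inputs.

Per-sample clusters are merged across samples (1 bp of overlap
suffices; mere adjacency does not), and a merged cluster is *reliable*
when its tags-per-million reaches 0.5 in at least one sample **and**
its per-base maximum signal reaches 10 in at least 3 samples. The
summit is the position of maximum pooled signal, ties resolved to the
leftmost position, deterministically.

Two further distance rules serve different consumers. For assembly,
clusters of one kind separated by less than 400 nt merge by single
linkage, because sites below that resolution cannot anchor distinct
isoform termini in the segment graph. For dynamics, clusters whose
summits lie within 50 nt keep only the stronger cluster (greedy by
descending total, leftmost on ties) — summit distance, not interval
gap, because the summit is what usage statistics are computed on.

## The assembler

The genome is scanned in 100 bp windows; windows touched by any
coverage merge into **linkage groups**, and a long read spanning two
groups (its introns bridging the signal gap) forces them to merge.
Within a group, the boundaries of credible junctions (at least 3
supporting reads in at least 1 sample by default), TSS summits and TES
summits divide the region into **indivisible segments**; a segment
containing a summit is a TSS or TES segment. Summits are placed so that
a transcript 5' start opens its segment and a 3' end closes it, on
either strand.

Every read becomes a binary path over the segments: a bit is set when
the read's exonic overlap covers at least half the segment. The
half-length rule is what makes the machinery robust to boundary jitter:
a few displaced nucleotides cannot flip a bit. The junctions implied by
the path's absent-segment runs are checked two ways — the implied
intron must be a credible junction *and* the read itself must carry an
intron with exactly those boundaries. A path is then

* **isoF** (full-length) when it starts at a TSS segment, ends at a TES
  segment and every junction is supported;
* a **completion candidate** when junctions are supported but a
  terminal anchor is missing (typically 5' truncation). It is completed
  to **isoC** with the terminal structure of isoF paths matching it
  over the shared covered range at the incomplete end; if different
  isoF paths offer different extensions the completion is ambiguous and
  refused. Pairs of uncompleted candidates anchored at opposite ends
  that agree on their overlap merge into **isoM**.
* **conflicted** when a junction fails. The failing junction's window
  (its absent-segment run plus flanking covered segments) is replaced
  with the structure of isoF paths agreeing everywhere else; a unique
  replacement yields **isoR**. Otherwise the wrong junctions are
  dropped and the gaps re-filled with the segment pattern whose implied
  junctions are all credible, choosing on ties the pattern that best
  matches short-read exonic coverage, giving **isoP**.

Ambiguity always demotes: a read that cannot be uniquely completed or
corrected falls through to the weaker class or is dropped. The package
deliberately favours reliability over sensitivity. Identical exon
chains collapse to one record keeping the best class (isoF > isoR >
isoC > isoM > isoP); terminal exon coordinates of anchored records snap
to their cluster summits. isoF and isoR form the core annotation; at
loci without long-read coverage, externally assembled short-read
transfrags — filtered at 0.5 FPKM (single-exon) or 0.2 FPKM
(multi-exon), termini moved to a reliable summit within 500 nt when one
exists and the move does not cross the terminal junction — enter as
**isoN**. No locus mixes isoN with long-read classes.

Gene loci are connected components of same-strand exonic overlap
(transitive closure); purely intronic containment does not join genes.
This grouping rule is a package design decision, as is the half-length
projection rule, the 3-read junction default and the unique-completion
requirement; the surrounding thresholds (20/200/5 clustering, 0.5 TPM
and 10-in-3 reliability, 400 nt and 50 nt distances, 0.5/0.2 FPKM,
500 nt boundary fixing) are the published operating point of the method
and are all exposed in `isoforgeConfig()`.

## Dynamics statistics

With N tissues and row-normalised expression `P_i`, the tissue
specificity score is `S = log2(N) + sum_i P_i log2 P_i` (zero terms
contribute nothing): 0 for uniform expression, `log2 N` for single-
tissue expression. Normalisation runs over all N tissues; the separate
"expressed in tissue i" predicate (level strictly above 20% of the row
maximum) is kept independent of S. A gene's dominant site in a tissue
is the one with strictly more than half the signal; for two tissues
with dominant sites `d(i) != d(j)` the switch score is
`W = P_{i,d(i)} + P_{j,d(j)} - 1`, else 0. A gene is a switch gene when
its dominant sites across tissues take at least two values and the
maximum pairwise W is strictly above 0.3, computed on clusters that
survived the TPM prefilter (above 0.5 TPM in at least two tissues and
on average) and 50 nt summit pruning. The weighted 3'UTR length is
`L_w = sum_s P_s * length_s`; an APA switch between two samples
requires `|delta L_w| > 100` nt and total termination-site signal above
5 TPM in both samples (all strict inequalities, matching the method's
published thresholds).

## Sequence features

CDSs are longest ATG-to-stop ORFs over the three forward frames of the
spliced sense sequence, ties to the 5'-most start. Microexons are
internal exons of at most 51 nt. Distal/proximal/coding site roles are
assigned against a representative CDS — the longest ORF of the longest
isoform: summits not 5' of the start codon (for TSS; mirrored around
the stop codon for TES) are coding (CT), the farthest remaining summit
is distal (DT), the rest proximal (PT). Intronic-terminus coupling is
evaluated pairwise: an isoform whose terminus falls inside another's
intron creates an Is event when its terminal exon stays inside the
intron and splices out through its own junction, and an Ic event when
the terminal exon runs continuously into the neighbouring exon.

The G-quadruplex scanner requires four G-tracts of at least 4 G (at
least four stacked tetrads) with loops of 2–7 nt; maximal G-runs serve
as tracts and overlapping hits resolve to the highest-scoring (longest
tracts, then 5'-most). The U-rich scanner has no published operational
definition, so the package defines one and exposes it: sliding windows
of 10 nt with U fraction at least 0.8, overlapping qualifying windows
merged, regions of at least 6 nt reported. uORFs are ATG-initiated
ORFs whose stop lies inside the 5'UTR with at least 2 codons before the
stop. All scanners are tested against independent brute-force oracles
on random sequences.

## The AS-hotspot null model

A gene is segmented at the union of its isoforms' exon boundaries and
each isoform becomes a 0/1 string over the segments. For a window of k
segments, the observed statistic is the number of distinct k-substrings
across the gene's isoforms. Under the null hypothesis that splicing
decisions are independent, this count follows a branching process:
each of the current distinct paths duplicates independently with
probability p per segment,

    P(xi = 2 | K = 1) = p,   P(xi = 1 | K = 1) = 1 - p
    P(xi = n | K = k+1) = sum_{i = ceil(n/2)}^{n}
        C(i, n-i) p^(n-i) (1-p)^(2i-n) P(xi = i | K = k)

with expectation `E(X) = (1+p)^K`, which inverts to the estimator
`p = mean(count)^(1/K) - 1` from genome-wide window counts. Binomial
terms are computed in log space so that large-K coefficients cannot
overflow. The genome is scanned at k = 3..10 with p estimated per k
independently; the hotspot cutoff at each k is the smallest count whose
observed frequency is at least three-fold the null probability
(pointwise on the probability mass, the most literal reading of the
minimum-count rule). Windows at or above the cutoff are evidence;
evidence windows of a gene sharing segments merge into regions, and a
gene is reported when it holds strictly more than 3 (gene, k, window)
evidence triples. Genes with fewer segments than k are skipped.

Calibration uses a string-level genome of 1000 genes with 12 segments
and a branching rate of 0.1 — a diversity level (about three isoforms
per gene) typical of compact plant genomes. Under this null the scan
flags well under 1% of genes, and 20 planted hotspot genes (8 distinct
local patterns inside a 4-segment window) are recovered at over 90%
recall. With a much more diverse background the planted signal drowns
in the genuine tail of the estimated null — a property of the method,
not of the implementation: the three-fold rule is self-calibrating
because p is re-estimated from the data being scanned.

## Polycistrons

A transcript is polycistronic when its spliced sequence contains two or
more non-overlapping ATG-to-stop ORFs of at least 100 codons ("major";
the threshold is a package default, exposed in the configuration, since
no published value exists). ORFs are chosen greedily by descending
length. Inter-CDS distances are spliced stop-to-start gaps.
Co-expression of member genes is contrasted against random
same-chromosome gene pairs with a one-sided rank-sum test, and a member
pair is co-linear in another species when both orthologs share a
chromosome and strand with a gap below 20 kb.

## The synthetic-data generator

`simulateTruth()` lays out non-overlapping genes on one synthetic
chromosome (3–8 exons of 100–300 nt, introns of 80–250 nt, intergenic
gaps of 1.5–2.5 kb, 16 tissues — mirroring a compact plant genome and a
multi-tissue atlas design), generates isoforms by internal-exon
skipping, writes coding sequence into the genome, and draws per-tissue
abundances (lognormal gene levels, gamma isoform usage floored at a
detectable share). Feature genes are planted on request: promoter
switches (two TSS more than 500 nt apart, usage 0.9/0.1 flipped between
tissue halves), APA genes (two TES on the last exon; a 250 nt site
separation under the 0.9/0.1 flip yields the 200 nt weighted-3'UTR
change used in the recovery checks, a 100 nt separation the 80 nt
negative control), microexons, 8-isoform hotspot windows, two-ORF
polycistrons, and single-tissue genes whose specificity score is
exactly log2 N.

`simulateLongReads()` corrupts reads with the three artifact classes at
controllable per-read rates: boundary jitter of 1–10 nt on one junction
edge, spurious 20–60 nt introns, and 5' truncation ending inside an
exon — magnitudes chosen to mimic the published long-read error
taxonomy. `simulateTagsAndJunctions()` emits 5'/3' tags at the true
sites (optionally with geometric positional noise) and junction counts
proportional to abundance. With all rates at zero the pipeline must —
and in the test suite does — reconstruct every expressed isoform
exactly, chain-identical and anchored on the true summits, with no
false isoforms. What the generator does *not* emulate: base-level
sequencing errors, internal priming artifacts, antisense noise,
overlapping gene structures, and expression-dependent truncation bias.
Passing its tests therefore demonstrates correctness of the assembly
logic under the stated error model, not performance on any particular
real data set.

Default problem sizes in the tests and the acceptance study — 50 genes,
up to 10 isoforms per gene, read depth 8, a 1000-gene string genome for
the hotspot calibration, 10,000 draws for the estimator check — are
chosen so a full run completes in minutes on one core while leaving the
statistics well away from their decision boundaries.

## Numerical and degeneracy choices

Summit ties break leftmost. Cluster pruning is greedy by descending
total signal, leftmost on ties. Unspliced (monoexonic) reads classify
purely on their terminal anchors. Reads overlapping no segment at the
half-length rule are dropped with the locus left intact. Empty inputs
(no tags, no junctions, no transcripts) yield empty, valid objects
rather than errors; genuinely invalid inputs (negative tag values,
donor not before acceptor, overlapping bedGraph intervals, all-zero
expression rows) raise errors at the boundary. All randomness flows
through explicit seeds; assembly itself is deterministic and seed-free.

## Limitations

The assembler resolves terminal sites only to the 400 nt merge
resolution; genuinely distinct TSS/TES closer than that collapse to one
anchor. Junction validation is exact-match: a true junction absent from
the short-read table demotes its read, which is intentional but costs
sensitivity at very low expression. The hotspot null treats windows as
independent and p as shared across genes at a given k; both are
approximations the three-fold excess rule is designed to absorb. Is/Ic
coupling is evaluated pairwise, not against a collapsed gene model, so
event counts scale with isoform number.
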