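---
title: "Methods: post-assembly processing of a pyrosequenced transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-assembly processing of a pyrosequenced transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postasm)
```

## Scope and model of the data

`postasm` implements the computations that sit between a de novo assembly
of a pyrosequenced (454-style) transcriptome and its biological read-out.
The assembler itself, the homology search engines and the microarray
normalization are upstream and out of scope: the package consumes their
standard outputs (FASTA, 12-column tabular alignment hits, normalized
probe-intensity tables) and owns everything after that.

The central data model is the **contig graph**. Assemblers of this era
split transcripts at points of internal variability — alternative splice
forms, diverged alleles or recent paralogs — leaving contigs connected by
*broken reads*: reads whose alignment spans two contigs that were kept
separate. `postasm` treats the contigs as vertices and each broken read as
an edge. Connected components of this graph are **isogroups** (putative
genes); maximal simple paths in which every consecutive contig pair shares
at least one broken read are **isotigs** (putative transcripts).

## Isogroup clustering and isotig enumeration

Clustering is plain connected components (via igraph) and is always
undirected: a broken read is evidence of co-transcription regardless of
orientation. Path enumeration is where the open design choices live:

* **Orientation.** When every link carries an orientation
  (`forward` = contig A precedes contig B in the transcript), enumeration
  is directed and isotigs are maximal directed simple paths — for the
  canonical diamond (shared 5' contig, two alternatives, shared 3' contig)
  this yields exactly the two isoform chains. Without orientation the
  graph is treated as undirected and each path is canonicalized to start
  at its lexicographically smaller endpoint so no path is reported twice.
* **Support.** A path is supported if every consecutive pair shares at
  least one broken read. Support is pairwise: read-level phasing across
  three or more contigs is not required, because the link table only
  records pairs.
* **Cycles.** Isotigs are simple paths, so a cycle cannot be traversed
  twice; enumeration terminates and a warning names the isogroup. This is
  the only decidable reading of "all potential paths" on a cyclic graph.
* **Combinatorics.** A dense isogroup can have exponentially many maximal
  paths; enumeration stops at `max_isotigs` (default 100) and flags the
  truncation rather than failing.

The test suite checks both modes against a brute-force oracle
(exhaustive path enumeration with an independent maximality check) on
random graphs of up to 10 contigs.

## Annotation consolidation

Per-isotig annotations are top hits by bit score among alignments with
e-value strictly below 1e-5 (ties: smaller e-value, then lexicographically
smaller subject, so results are independent of input row order). Isotigs
of one isogroup are then reduced to a single gene label by a cascade:

1. all (normalized) labels agree — `single`;
2. labels differ but map to one canonical label under a user-supplied
   synonym table — `collapsed_synonym`;
3. otherwise each isotig's top-five secondary alignments (pre-filtered at
   e < 1e-10) are intersected; a gene present in every isotig's top five
   and among the original labels wins, with ties broken by the highest
   cumulative bit score across isotigs — `resolved_top5`;
4. otherwise `unresolved` (no label), while isogroups whose isotigs had no
   passing hits at all are `none`.

Label normalization (case-folding, stripping punctuation and the tokens
"predicted", "hypothetical", "-like") stands in for the manual curation a
human annotator would do; the synonym table turns the remaining curation
into data. Unresolved isogroups still count as *annotated* in the census —
they returned alignments — but carry no label, mirroring how such studies
bookkeep their totals. Term assignment (GO, pathway, orthology) is a join
of lookup tables onto each unit's top subject under per-source cutoffs
(1e-15, 1e-5, 1e-10); isogroups whose isotigs map to different subjects
are excluded as multi-annotation rather than arbitrated.

All e-value thresholds in the package are strict inequalities.

## Completeness by reciprocal best hit

A transcript and a core single-copy gene are paired iff each is the
other's best passing alignment (bit score, then e-value, then subject id).
Coverage statistics use the aligned span on the core protein divided by
the protein length, and each recovered gene contributes its single
best-bit alignment. The tie-break order is a package choice; it only
matters on exactly tied tables and makes the result deterministic under
row shuffling.

## Expression calling against a random-probe null

Each array individual gets its own threshold: the 97.5% empirical
quantile of that individual's random-probe scores, computed with linear
interpolation between order statistics (quantile "type 7") — the
estimator choice is a documented convention, and calls use a strict `>`.
A unit's statistic is the median of its probe scores (a single score for
one-probe units; the mean of the two for two-probe units, the standard
median). A tissue-sex group is called when at least 3 of its 6
individuals exceed their thresholds; under independence the group-level
false-call rate is the exact binomial tail
`P(X >= 3 | n = 6, p = 0.025)` = `r signif(replication_pvalue(6, 3, 0.025), 4)`.
The commonly quoted rounded figure 6e-4 is an upper bound on this exact
value. Dye/channel structure is collapsed to one normalized score per
probe per individual, because the calling rule operates on normalized
per-individual scores; normalization itself is upstream.

Probe design allocates up to three non-overlapping 60-mers per contig,
evenly spaced, sliding windows off runs of `N`; short contigs get two or
one, and sequences shorter than a probe are skipped with a warning.
Random probes are sampled from an order-k Markov chain (k = 0–2, default
1) fitted to the supplied sequence composition, so they match background
hybridization statistics while targeting nothing.

## Variant calling

Read-to-isotig alignments pass four filters: e-value < 1e-5, identity
>= 95%, at most 5 unaligned bases at each read end, and removal of every
alignment of any read whose hits touch more than one isogroup. Five bases
are then trimmed from each aligned read end (alignment edges are
error-prone) before pileup. A site is called when the second most frequent
non-gap base has at least 3 supporting reads and a frequency strictly
above 20% of the non-gap depth. Gap "alleles" are excluded from both the
candidate alleles and the depth denominator: indels are the dominant
error mode of this platform and are deliberately not called. Columns with
more than two non-gap alleles are tested as major versus top minor only.

Because isotigs of an isogroup share contigs, the same polymorphism is
typically called once per isotig. Within an isogroup, calls sharing
(major, minor, position key) form one redundancy class and exactly one —
the call with the greatest minor-allele support, ties to the smallest
isotig id — is flagged unique. The position key is the underlying contig
position when an isotig-to-contig offset map is available and the
isotig-local position otherwise; with only local positions, identical
variants at different offsets in different isotigs remain distinct, which
over-counts slightly and is therefore the conservative direction for the
unique-call total's use as a marker list.

The expected number of false calls from sequencing error is modelled as
`n_sites * P(X >= 3 | depth, p)` with the platform substitution rate
p = 2.2e-4 — an exact binomial tail. At depth 8 this is 5.96e-10 per
site; the package reports the exact tail and takes any larger published
per-site figure as a conservative upper bound rather than attempting to
reproduce its intermediate arithmetic.

All internal coordinates in the package are 1-based inclusive (the
R/Bioconductor convention); file output (tabular hits, VCF) is 1-based as
those formats require, so a call at position 551 appears at `POS=551`.

## The synthetic-data generator

Every stage can be exercised on generated data with known truth:

* **Transcriptome** — single-isoform genes become lone contigs;
  multi-isoform genes become shared flank contigs plus one alternative
  contig per isoform, with `forward` links across each true junction. By
  default 19% of genes are multi-isoform and contig lengths are
  log-normal with mean 884 bp (typical for this platform); singletons are
  emitted at mean 344 bp.
* **Reads** — log-normal lengths with mean 372 bp and CV 0.3 (the
  platform reports only the mean; the CV is a package choice),
  substitutions at 2.2e-4 per base, optional homopolymer indels (a run of
  length L >= 3 gains or loses one base with probability `rate * L`, a
  minimal parametric form of the platform's dominant error mode), and
  planted biallelic SNPs whose minor allele is carried by each
  overlapping read with probability equal to the site MAF. Reads carry
  their true gapped alignments, so the variant caller runs without an
  external aligner.
* **Hit tables** — every isotig hits its gene's true protein with the top
  bit score plus a weaker decoy; a chosen fraction of labels are
  synonymous aliases (with the alias table supplied alongside); core
  genes are present as reciprocal-best pairs for a chosen fraction.
* **Expression** — null probes and unexpressed units share one Gaussian
  background; expressed units are shifted by a chosen number of
  background SDs in designated tissue-sex groups.

What the generator does *not* emulate is worth stating: assembler
consensus errors, chimeric contigs, read-mapping ambiguity between
paralogs, dye bias and spatial array artefacts, and diploid linkage
between nearby planted sites (alleles are drawn independently per read).
Passing tests therefore demonstrate that the rules are implemented
correctly and calibrated as designed, not that they are robust to every
pathology of real data.

## Calibration and problem sizes used by the checks

The null calibration of the expression caller uses 100,000 simulated
null probes and 2,604 random probes across 6 individuals: the measured
per-individual rate sits at 2.5% and the group-level rate at the exact
binomial tail, within sampling error of those sizes.

For planted-SNP recovery the package simulates 1,000 sites at MAF
0.3–0.5 over 40 transcripts of 2 kb at 60-fold coverage. The coverage is
a deliberate calibration: with the support filter (>= 3 reads) and the
strict 20% frequency filter, per-read binomial sampling of alleles at
MAF 0.3 needs on the order of 50–60 observations for the minor allele to
clear both filters in more than 95% of sites — at 10–12x, recovery of a
MAF-0.3 site is mathematically capped near 75% however good the caller.
Sixty-fold is the regime in which the *caller* (rather than coverage) is
being measured, and the analytic binomial computation above, not a test
outcome, fixed the value. False calls on the co-simulated monomorphic
sites are compared against the binomial error bound.

The brute-force path/component oracles run on random graphs of up to 10
contigs; larger graphs add nothing to the equivalence argument while
growing factorially.

## Known limitations

* Orientation bookkeeping of the original assembler is proprietary; the
  pair-level support rule and the undirected fallback are documented
  approximations.
* The adaptor/polyA cleaning rule (terminal run of >= 8 A/T with at most
  one interruption, iterated to a fixpoint so cleaning is idempotent,
  then dropping reads <= 30 bp) stands in for an unpublished in-house
  cleaner.
* Quality scores are ignored throughout: the pipeline operates on cleaned
  bases only, as its filters were designed to.
* Open-reading-frame prediction ahead of the completeness search is
  upstream; the module consumes protein-space hit tables directly.
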