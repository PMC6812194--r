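---
title: "Scatter-gather variant calling: model, guarantees and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scatter-gather variant calling: model, guarantees and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scattervc)
```

## The problem

Small-variant calling on a whole genome is embarrassingly parallel in
principle — a variant at one locus depends only on the reads covering that
locus — but the common tools operate on whole alignment files, so a single
deep sample can take days on one machine. `scattervc` implements the
scatter-gather architecture that makes the parallelism explicit: cut the
reference into pieces, cut the alignment files to match, call variants on
every piece concurrently, then lift the per-piece calls back to absolute
coordinates and merge them into one sorted VCF.

The danger in any such scheme is the piece boundary: a read stack straddling
a cut sees only part of its evidence in each piece, and naive splitting
produces boundary artifacts (missed or doubled calls, shifted qualities).
The whole design of this package is organized around eliminating that
artifact class *exactly*, not approximately.

## The partition model

Each chromosome of length $L$ is tiled by **core** intervals
$[i\,c,\ \min((i+1)\,c, L))$ for core size $c$: disjoint, gapless, in
order. Around each core a **pad** of $p$ bases is kept on both sides
(clamped at the chromosome ends), giving the **padded** interval whose
sequence is what a piece actually carries. Coordinates are 0-based
half-open everywhere inside the package; 1-based coordinates appear only
at the SAM/VCF boundary. The piece-map TSV (piece id, chromosome, core and
padded intervals) is the single source of truth for the bidirectional
coordinate map; piece FASTA headers carry only the piece id, because
headers tend to be mangled by downstream tools.

A mapped read is assigned to every piece whose **padded interval fully
contains its reference span** (the span counts CIGAR M/D/N/=/X). Full
containment, rather than mere overlap, is the load-bearing choice:

* every emitted record is a legal alignment to the piece sequence — no
  clipping logic, no negative positions;
* if $p \ge$ the maximum read reference-span, then for **every core
  position of every piece** the multiset of aligned bases in the piece
  pileup equals the multiset in the unsplit pileup. Reads in an overlap
  zone are duplicated into both neighbouring pieces; reads spanning wider
  than every padded window (e.g. spliced alignments with long N) are
  counted and skipped rather than truncated.

Pileup equality at core positions is proved by the test suite
position-by-position, and it is what turns the boundary question from
"how much noise?" into an identity.

At merge time the converse rule resolves the duplicates that padding
necessarily creates: a lifted variant is kept only by the piece whose core
contains its (0-based) start position — each position has exactly one
owner because cores tile the chromosome. Qualities are never recomputed or
averaged at merge; the owner piece saw the complete pileup, so its call is
authoritative verbatim. Together the two rules give the pipeline's central
theorem, asserted record-for-record by the acceptance tests:

> With the built-in caller and pad ≥ max read span, the merged VCF of the
> split pipeline is identical — (chrom, pos, ref, alt, qual, genotypes) —
> to calling on the unsplit inputs.

## The built-in caller

External callers (samtools, GATK, freebayes) are supported through command
templates with `{ref}`, `{bams}`, `{out}` placeholders, but the test
surface needs a caller that is deterministic, dependency-free and exactly
reproducible, so the package ships a minimal pileup SNV genotyper:

* the pileup counts raw aligned bases (CIGAR M/=/X) per position and
  sample; no base-quality weighting, deliberately, so that split-vs-unsplit
  equivalence is a statement about integer multisets rather than floats;
* per sample, the candidate allele is the non-reference base with the
  highest count (ties to the lexicographically smallest base) and
  $f = k/d$ its fraction of the counted depth $d$; the genotype is `1/1`
  when $f \ge$ `hom_min` (default 0.8), `0/1` when `het_min` $\le f <$
  `hom_min` (default 0.2), `0/0` otherwise, and `./.` below `min_depth`
  (default 4 reads);
* site QUAL is the Phred-scaled binomial tail
  $-10\log_{10} P(X \ge k),\ X \sim \mathrm{Bin}(d, \varepsilon)$ under
  the error-only null ($\varepsilon$ = `err`, default 0.01), computed on
  the log scale so deep pileups cannot underflow, rounded and capped at
  255; the emitted ALT and QUAL come from the highest-quality variant
  sample, ties again lexicographic.

Every tie-break is deterministic precisely so that output is byte-stable
under any worker count, completion order or piece layout. The caller is
SNV-only; indels and MNVs are the domain of external callers run through
the template mechanism. The defaults (`het_min` 0.2, `hom_min` 0.8,
`min_depth` 4) are conventional fraction thresholds for ~30x short-read
data: at depth 30 a balanced heterozygote leaves the 0.2–0.8 band with
probability below $10^{-3}$.

## Jobs and concurrency

One job per piece (not per chromosome — pieces are what balance a long
chromosome across workers), ordered by (chromosome rank, core start), with
a JSON-serializable manifest built before anything runs. Jobs communicate
only through the filesystem: each reads its piece FASTA and per-sample
piece SAMs and writes one piece VCF. That makes the final output a pure
function of the manifest, makes order-independence trivially testable, and
is what would let a cluster backend place jobs on different nodes — the
mandatory backend here is local forked processes; anything else need only
implement submit/poll/collect. Failure policy is fail-fast: a failed job
marks the report and the merge refuses to run (a keep-going mode collects
all failures first). Resume skips jobs whose output is newer than all
inputs, which is also why the scatter stages leave existing artifacts
untouched when resuming.

## Concordance metrics

For two callsets the package matches variants exactly on
(chrom, pos, ref, alt) — multi-allelic rows are expanded first — and
computes, over callset A (size $|m|$), callset B (size $|n|$) and their
intersection $l$:

* **missing rate** = (number of different variants) / $|m|$, where
  "different" defaults to the symmetric difference $|m \,\Delta\, n|$; a
  `missed_by_A` reading ($|n \setminus m|$) and an $|n|$ denominator are
  exposed as configuration because the printed definition admits both
  readings — the default follows it literally;
* **difference rate** = fraction of $l$ whose relative score difference
  $|s_a - s_b| / \max(s_a, s_b)$ is ≥ 5% (0 when both scores are 0; the
  larger-score base makes the measure scale-free across callers with
  different QUAL conventions — an interpretation, since no base is stated);
* **score correlation** = Pearson correlation of the paired QUALs over the
  concordant part of $l$ (relative difference ≤ 5%). With fewer than two
  concordant pairs or zero variance the function returns an explicit
  undefined-result object rather than a number.

A split-vs-unsplit transparency run must and does score missing rate 0,
difference rate 0, correlation 1.

## The synthetic-data generator

The generator emulates exactly what the pipeline consumes: a uniform
random multi-chromosome reference; planted diploid SNVs (alt uniform over
the three non-reference bases; heterozygous with configurable probability,
the alt on one random haplotype; positions a minimum distance apart);
uniform-coverage fixed-length reads copied from one haplotype per read
with i.i.d. base errors flipped to a uniformly different base; and a truth
VCF. Reads are emitted pre-aligned (the generator knows their origin), so
no aligner enters the test loop — alignment is out of scope. All
randomness flows from one seed per stage, derived from a single master
seed.

What it does **not** emulate — indels and structural variants, quality
score profiles, paired-end inserts, GC or mappability bias, repeat-induced
mismapping — bounds what green tests mean: they certify the scatter-gather
machinery (partitioning, remapping, concurrency, lift, dedup, merge) and
the caller's arithmetic, not robustness of genotyping on real libraries.
The default study conditions used by the reproduction script are one
200 kb chromosome, 200 SNVs at 50% heterozygosity, 30x coverage of 100 bp
reads at 1% base error, cores of 20 kb and a 300 bp pad; the companion
checks use 10–50 kb chromosomes. These sizes exercise every code path —
dozens of pieces, overlap zones at every boundary, ~60k reads — while
keeping the whole suite a desk-scale computation.

## Numerical and degenerate-input choices

* Binomial tails via `pbinom(..., log.p = TRUE)`; the tests verify
  agreement with direct term-by-term summation for all $d \le 30$ within
  one Phred unit after rounding, and monotonicity in $k$.
* Pad defaults to twice the declared read length; a pipeline run refuses
  `pad < read_len` outright (the overlap kept around a piece must be
  longer than the reads, or transparency is lost), while the lower-level
  table builder merely warns, since library-level users may want
  degenerate layouts on purpose.
* A final core shorter than the pad can optionally be merged into its
  neighbour (off by default): it avoids pieces smaller than their own
  overlap.
* Empty inputs degrade gracefully end-to-end: zero reads give empty piece
  files and an all-zero report; zero pieces merge into a header-only VCF.
* The reference parser refuses non-IUPAC characters (naming character and
  line), duplicate names and empty sequences rather than silently
  dropping letters.

## Known limitations

The built-in caller has no genotype likelihoods, no indels, and no
base-quality model. Mate fields are reset on remapped records (mates may
land in different pieces; pairing flags are preserved) — external callers
that *require* consistent mate information should be run with pads large
enough that proper pairs co-locate, which is not validated. Multi-allelic
normalization, left-alignment and CRAM are out of scope. The cluster
backend is a contract, not an implementation.
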