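---
title: "Closing assembly gaps with flank-anchored alignment: methods and design"
author: "gapweld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing assembly gaps with flank-anchored alignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Draft genome assemblies represent unresolved sequence between contigs as
runs of `N` inside scaffolds. Data that could resolve those regions often
already exists: an assembly of the same reads with a different assembler or
k-mer, contigs from another sequencing platform, or long reads. gapweld
closes gaps by searching such alternative datasets for sequences that span
a gap: the known sequence on each side of the N-run (the *flanks*, or
contig ends) is aligned against every dataset sequence with nucleotide
BLAST, hits for the two flanks landing on the same dataset sequence in a
consistent geometry define a candidate fill, and the highest-scoring
candidate is spliced into the scaffold. Because contig ends frequently
overlap instead of being separated (*negative gaps*), the same geometry
also supports closures that remove bases rather than insert them.

## The closure model

For a gap `[start, end)` on a scaffold (all internal coordinates are
0-based and half-open; the human-readable logs use 1-based inclusive
coordinates, matching BLAST convention), the two flank windows of up to
`end_length` bases are extracted, shifted away from the gap by `trim`
bases when the contig edges are to be distrusted. A flank never crosses
into a neighbouring gap: it is truncated at any interior `N`, because the
alignment query must be real sequence.

Both flanks are aligned separately against every dataset sequence. For a
pair of hits (one per flank) on the same subject and strand, with the
left-flank hit preceding the right-flank hit in flank order, define on the
subject as the flanks see it (reverse-complemented for minus-strand
pairs):

* `insert_len` = (right hit start) − (left hit end). Positive values are
  inserted sequence; negative values mean the true flanks overlap by that
  many bases; zero means the contigs abut exactly.
* `removed_left` = unaligned gap-adjacent left-flank tail + `trim`, and
  symmetrically `removed_right` (plus the overlap for negative gaps).
  Unaligned tails are treated as removable low-quality edge sequence and
  are replaced by the dataset's version of the same region, which lies
  inside the subject interval between the two hits.

A candidate is admissible when `insert_len` lies in
`[-max_remove, max_insert]`, each side's removal is at most `max_remove`,
each hit covers at least `min_query_cov` of its flank (default 40%,
mirroring the validation coverage rule), negative/zero inserts are
permitted by their switches, and the fill does not reintroduce `N`s
(configurable cap, default 0). Among admissible candidates the one with
the highest combined score — the sum of the two hits' bit scores — wins.
The tie-break is deterministic: greater minimum single-hit score, then
smaller `|insert_len|`, then lexicographically smallest subject id, then
smallest subject start. Summing the two bit scores is a design choice: it
is symmetric in the two anchors and monotone in each, so a candidate can
never improve by weakening one anchor.

The applied edit replaces
`[start - removed_left, end + removed_right)` with the fill sequence.
For negative gaps the replacement is empty and the overlap is removed from
the right side using subject-coordinate arithmetic, under the assumption
that the alignment is locally collinear near the junction (the tabular
engine contract does not expose per-base traceback; the log records this
assumption on every negative closure).

## Multi-round execution and conflict safety

Closing one gap edits exactly the region a close neighbour would use as
its alignment query. Each round therefore processes gaps per scaffold in
ascending coordinate order, and a gap is eligible only if neither of its
flank windows (`end_length` per side) intersects an interval already
edited in the same round; otherwise it is logged `deferred_conflict` and
retried next round, when its neighbourhood is stable. Downstream gap
coordinates are shifted after every edit, and the shifted coordinates are
provably identical to re-scanning the edited sequence (a tested
invariant). Rounds repeat until one closes nothing or `max_rounds`
(default 3) is reached; round *k*'s FASTA is the input of round *k*+1, so
changes are incremental and every round's output is inspectable.

The pipeline has no random component: identical inputs and configuration
produce byte-identical FASTA, logs and statistics. The engine is run
single-threaded by default for this reason; `threads` only parallelizes
the engine's internal search.

## Alignment engine and its parameters

The external engine is BLAST+ (`makeblastdb`/`blastn`, `-task blastn`),
invoked with dust masking disabled so that hit sets are reproducible and
threshold-driven rather than composition-driven. Tabular output with an
explicit column list is parsed into forward-strand, half-open coordinates
plus an orientation flag; minus-strand hits are recognized by the
reported strand and normalized, so all downstream geometry lives in one
coordinate system.

Hits are filtered by three thresholds, applied both in the engine call
and again defensively in R: minimum bit score (`min_score`, default 25 —
"score" is interpreted as bit score, the engine's primary ranking
statistic; raw scores are not exposed), maximum e-value (`max_evalue`,
default 1e-7) and minimum percent identity (`min_identity`, default 70).
Scoring defaults are the conventional blastn set: match +1, mismatch −3,
gap open 5, gap extend 2, word size 11, and at most `max_alignments`
(default 50) hits per query are kept by descending score. All are
user-overridable; the defaults are deliberately conservative so that a
fill must be anchored by two confident alignments.

The package also contains an exact affine-gap local aligner
(`oracle_align`, in C++), used two ways: as an engine-independent oracle
in the test suite (checked against a second, independently written
dynamic-programming implementation), and to measure the identity of
inserts too short for blastn's word size during validation. A gap of
length L costs `open_gap + L * extend_gap`; among equal-scoring optima the
alignment with the smallest query start, then smallest subject start, is
returned, which makes every downstream consumer deterministic. It is
guarded to problems of at most 10^6 cells — it is an exact oracle, not a
production aligner.

## Validation against a reference

A closed gap is accepted when three criteria hold against a reference
genome: (1) both flanks align over at least `min_flank_coverage` of
their length (default 40%); (2) the flank and insert identities reach
`min_identity`; (3) the closed region agrees with the reference more than
the two flanks joined without the insertion did.

Two measurement choices matter here. First, "identity" of a region is
defined as identical bases divided by alignment columns plus unaligned
query bases. A plain per-alignment percent identity cannot express
criterion 3: joining two flanks across a small deletion still yields a
single near-perfect local alignment, and an alignment covering only one
flank of a scrambled closure reports 100% identity over half the region.
Normalizing by the full region penalizes both gap columns and unaligned
tails, and restores the intended ordering (verified on constructed
closures with exact, noisy and scrambled fills). Second, for closures
that insert nothing (zero and negative gaps) the before and after regions
coincide, so criterion 3 uses greater-or-equal there and strictly-greater
otherwise; the original criteria were formulated for inserted sequence
only.

Inserts are aligned inside the reference window bracketed by the two
flank hits using the exact aligner (falling back to the engine when the
window exceeds the exact aligner's guard), so 10 bp fills are validated
as reliably as 400 bp ones. Validation uses the same engine contract as
closing rather than a separate whole-genome aligner, keeping the
dependency set minimal; the criteria are engine-agnostic statements about
coverage and identity.

## The synthetic fixture generator

`fixture_spec()` describes a reference/draft/dataset triple with known
ground truth; generation is fully deterministic given the seed. The
defaults are the package's standard study conditions, used by the test
suite and the acceptance script: a 100 kb random genome at 50% GC, 20
evenly spaced gaps cycling through positive (fills 10–400 bp), zero and
negative (8–60 bp overlap) kinds with N-runs of 1–80 bp, two error-free
fragments (~4 kb) spanning each gap region plus its flanks, and ten
decoy fragments drawn from an unrelated random sequence, length- and
GC-matched so the threshold filters are genuinely exercised. Options add
substitution errors (the noisy scenario uses 1%) and reverse-complement
fragments (strand-invariance checks flip all of them). These sizes keep a
full multi-round run plus validation in the order of seconds while still
covering every gap kind and both strands; they were chosen once as
realistic desk-scale conditions and the tests state their expectations
against them.

What the generator emulates: gap-spanning sequence from alternative
assemblies or long reads, overlap-induced negative gaps, substitution
noise, strand ambiguity, and unrelated sequence that must be rejected.
What it does not: indels and chimerism in the datasets, repeat-induced
ambiguous anchoring, quality values, and real genomic composition
(repeats, low-complexity tracts). Passing the perfect-recovery suite
therefore demonstrates the geometry, bookkeeping and selection logic are
exact, not that closure accuracy on a repeat-rich real genome will be
100%; on real data the conservative thresholds, the coverage minimum and
reference validation carry that burden.

## Degenerate inputs and edge behaviour

Boundary N-runs (a scaffold starting or ending in `N`) are reported but
never filled: they have no flank pair. Flanks shorter than `min_flank`
(default 20 bp — below any sensible score threshold) make a gap
unalignable for the round. Gaps with no admissible candidate are logged
`no_candidate` with the hit/pair counts that led there. Lowercase input
and IUPAC ambiguity codes are uppercased and preserved; only `N` defines
gaps. Datasets may contain `N`s; a fill overlapping them is rejected by
the default N-cap.

## Known limitations

* One subject per fill: a gap is never closed by stitching two dataset
  sequences (no chimeric fills, no iterative flank extension).
* Negative-gap resolution assumes local collinearity at the junction;
  a subject with an indel inside the overlap region would shift the
  junction by that indel's length.
* `min_score` is a bit-score threshold; tools whose "score" is the raw
  alignment score will need a converted value.
* Validation requires a reference; there is no reference-free QC beyond
  the closure log itself.
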