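---
title: "Inside pgarc: splitter segmentation, grouped LZSS and the archive format"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside pgarc: splitter segmentation, grouped LZSS and the archive format}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pgarc stores collections of assembled genomes of one species in a single
compressed file that still answers random-access queries — a contig, a base
range, a sample — without decompressing anything else, and that can be
extended in place with new samples.  This vignette explains the method, the
parameters that matter, the numerical choices behind the implementation, and
what the synthetic benchmarks used by the test suite do and do not show.

## The model: why splitters?

Assemblies of conspecific individuals are overwhelmingly similar, but they
arrive as contigs of arbitrary length and unknown origin, so chromosome-wise
differential coding is not available.  pgarc instead anchors homology with
**splitters**: k-mers (default k = 31) that occur exactly once in a
designated reference genome, selected during a spaced walk so that
consecutive splitters lie approximately `segment_size` bases apart (default
60 000).  Because each splitter is effectively unique in the species, its
occurrences in *any* contig of *any* sample mark homologous positions.

Compression is three-staged:

1. **Candidate k-mers.** All canonical k-mers of the reference are counted
   (a k-mer and its reverse complement count as one entity); those occurring
   exactly once form the candidate pool.  Windows containing non-ACGT
   symbols are skipped.
2. **Splitter selection.** Each reference contig is walked left to right:
   the first candidate occurrence becomes a splitter, scanning resumes
   `segment_size` bases later, and the last candidate occurrence of each
   contig is also kept.  Insertion order fixes the splitter ids for the life
   of the archive.
3. **Per-genome compression.** Every contig of every sample (the reference
   itself is added first) is cut at splitter occurrences into **segments**;
   the terminating splitter's k bases belong to both neighbours, so
   reconstruction drops each segment's overlap prefix.  Segments fall into
   three classes: **spt-2** (two terminating splitters, the common case),
   **spt-1** (one, at contig boundaries), and **spt-0** (none — short,
   repetitive, or reference-alien contigs, always whole contigs).

Segments sharing terminating splitters are collected into **groups**.  The
first segment of a group is kept verbatim (packed and compressed) as the
group reference; every later member is LZSS-parsed against it and stored as
a short description of literals and matches.  Descriptions are concatenated
into **blocks** of `block_size` members (default 50) and each block is
xz-compressed as one frame — the unit of random access.  Compressing many
homologous descriptions together is where the collection-level redundancy is
harvested; `block_size` therefore trades archive size against extraction
granularity.

### Orientation normalization

Group identity must be strand-free: an inverted contig should reuse the same
groups.  An spt-2 segment is reverse-complemented when the canonical form of
its right splitter is lexicographically smaller than that of its left one,
so the smaller splitter always leads; when the two canonical forms are equal
the orientation with the lexicographically smaller whole sequence is kept
(a deterministic tie-break).  An spt-1 segment is flipped when its splitter
sits at the end.  The flip is recorded per segment and undone at
decompression.

One alphabet subtlety: the IUPAC complement maps U to A while A maps to T,
so complementation is not invertible on U.  pgarc therefore never flips a
segment containing U — it joins its group in contig orientation, possibly
parsing poorly against the group reference, but round-tripping exactly.
This is a correctness/ratio trade that only affects RNA-style inputs.

### Placement rules

* **spt-2** with pair (s1, s2): join the existing (s1, s2) group; otherwise,
  if some third splitter s3 bridges existing groups (s1, s3) and (s3, s2),
  the segment straddles a **missing splitter** (a mutation destroyed the
  splitter's occurrence) and is cut at a cost-optimal division point into
  two parts appended to those groups, with overlap 0 at the junction;
  otherwise the segment founds a new group.  When several s3 qualify the one
  with the smallest two-part cost wins (ties to the smaller id); the search
  does not recurse — each part is placed directly.  Segments shorter than 2k
  cannot host a division point and simply found a new group.
* **spt-1** with splitter s: every group whose key contains s is tried, in
  both orientations of the segment, and the cheapest description wins —
  provided it costs less than half the radix-packed segment
  (`new_group_threshold` = 0.5); otherwise the segment founds a new
  single-keyed group.
* **spt-0**: a stable 64-bit FNV-1a hash of the lexicographically smaller
  orientation of the sequence, mod 16, assigns one of 16 buckets —
  deterministic across platforms and insertion orders, and identical for a
  segment and its reverse complement.  Buckets behave like ordinary groups
  (first member is the bucket reference).

## The LZSS codec

Members are parsed greedily left to right against the group reference: at
each position the longest reference match of at least `min_match` = 20 bases
is taken (anchored by 16-base seeds; among equally long matches the leftmost
reference occurrence wins, examining at most 128 candidate anchor positions
so that degenerate references such as N runs stay linear-time), otherwise a
literal is emitted.  The serialized stream is:

| token | encoding |
|---|---|
| terminator | `0x00` |
| literal run | `0x01`, varint run length, raw symbols |
| match | `0x02`, varint zigzag(offset − cursor), varint(length − min_match) |

All varints are LEB128.  The *cursor* is an implicit reference position: 0
initially, offset+length after each match, advanced by the run length after
each literal run.  A substitution therefore costs a three-byte literal run
plus a match whose offset delta is zero — descriptions of SNP-divergent
segments become near-constant byte patterns, which both shortens them and
makes blocks of them highly compressible.  Decoding is exact by
construction and validated against the reference bounds.

The division point for a missing-splitter segment minimizes
`cost(parse(prefix, refA)) + cost(parse(suffix, refB))` over all cuts, with
prefix costs from one forward pass (only the token crossing the cut needs
rework, including re-finding the leftmost occurrence of a truncated match)
and suffix costs from one backward dynamic program.  Because greedy token
*choices* are independent of the cursor, suffix parses share all token costs
once their boundaries merge except the first match after the merge, whose
delta depends on the incoming cursor; the DP carries that first-match
correction explicitly, so the result equals exhaustive re-parsing of every
cut, with ties broken toward the smallest cut.  The tests verify this
equality directly on short strings.

`min_match` = 20 also guarantees the greedy parse never beats itself with
literals: the worst-case match token (11 bytes) plus the cost of restarting
an interrupted literal run is still below 20 literal bytes.

## Archive format

A little-endian single file:

```
magic "PGARC001"
sealed frames      group reference segments (radix-packed, xz) and
                   full blocks (concatenated descriptions, xz) — append-only
tail frames        one xz frame per group with a partially filled block
metadata frame     xz-compressed: format version; parameters (k,
                   segment_size, block_size, adaptive, min_match, anchor
                   length, hash and codec ids); splitters as packed 2-bit
                   k-mers in id order; per group: key, reference geometry
                   and packing descriptor, block directory with per-segment
                   byte offsets; per sample: contigs with segment records
                   (group id, in-group id, orientation, length, overlap);
                   end of the sealed region
footer             u64 metadata offset, u64 metadata size, magic
```

Segment-record columns are delta-coded against cheap predictors (previous
group id + 1, previous in-group id, `segment_size` + k) before the varint
stage, leaving mostly zero bytes for xz.  Reference segments are packed 4,
3, 2 or 1 symbols per byte depending on each segment's own alphabet size
(≤4, ≤6, ≤16, larger).

Appending reopens the file, truncates after the sealed region, and rewrites
only tails, metadata and footer; sealed frames never move, which bounds
write amplification and keeps batch-created and incrementally-extended
archives content-equivalent (the tests compare them byte-range by
byte-range).  Untouched tail frames are carried over verbatim; touched ones
are decompressed lazily on first use.  Archive bytes are a pure function of
inputs, parameters and format version — creation is bit-for-bit
deterministic.

Queries read the metadata, locate the records overlapping the requested
range, and decompress only the touched groups' reference frames and block
frames; an instrumentation counter (`io_stats`) exposes exactly how many
frames a query cost, which the tests use to verify that access locality is
independent of collection size.

## Adaptive mode

For collections too divergent for the reference's splitters (bacteria,
two-clade collections), whole contigs fall through as spt-0 and compress
poorly.  With `adaptive = TRUE`, each incoming sample's splitter-free
contigs are buffered; canonical k-mers unique within the buffer, minus
*every* k-mer present in the reference (any count) and minus all existing
splitters, become sample-candidates, from which the same spaced walk selects
new splitters that extend the global set (ids never reused, collisions
impossible by construction).  The buffer is then re-segmented once — no
recursion — and handled normally.  The first divergent sample founds the new
groups; later samples of its clade land in them as cheap spt-2/spt-1
members.  At append time the reference k-mer set is recomputed by
decompressing sample 0, so no original FASTA is needed.  Earlier samples are
never re-encoded, so adding divergent samples helps future samples, not past
ones.

## Parameters

| parameter | default | meaning / guidance |
|---|---|---|
| `k` | 31 | splitter length (odd, 11–32); smaller k for smaller genomes |
| `segment_size` | 60 000 | splitter spacing in bases; 1500 suits bacterial-scale genomes |
| `block_size` | 50 | descriptions per frame; larger = smaller archive, coarser access (500 for bacteria/viruses) |
| `adaptive` | off | extend splitters from divergent samples |
| `min_match` | 20 | minimum LZSS match; recorded in the header |
| `mmer` | 16 | LZSS anchor seed length; recorded in the header |

The frame codec is xz (base R's `memCompress`), pinned as codec id 2 in the
header, chosen for ratio at these frame sizes; the 16-byte anchor makes
chance seed collisions negligible at desk-scale reference sizes while SNP-
interrupted matches (≥ 20 bases) are still found.

## The synthetic generator, and what the tests show

`simulate_collection()` emulates a pangenome collection: a uniform random
ACGT reference and per-sample independent mutations — SNPs (default rate
10⁻³, typical of within-species divergence), short geometric indels,
occasional block inversions and translocations — followed by fragmentation
into contigs, soft-masked runs, N runs and sparse IUPAC ambiguity codes.
Event order is pinned and one global RNG stream makes output a pure function
of the spec.  `two_clade_collection()` adds a second reference at ~30%
divergence (essentially no shared 31-mers) to exercise adaptive mode.

Problem sizes used by the test suite — a 1 Mb reference with 10 samples for
the round-trip grid (k ∈ {17, 31} × segment_size ∈ {1500, 10 000, 60 000} ×
block_size ∈ {1, 50, 500}), 20 samples at bacterial-scale settings
(segment_size 1500) for the marginal-cost experiment, 50 samples for the
access-locality comparison, and 2 × 500 kb clades for adaptive mode — are
chosen as the smallest collections on which every code path (missing
splitters, inversions, fragmentation, bucket storage, splitter extension)
triggers reliably.

Two caveats about inference to real data.  First, the generator mutates
samples independently, so there is no shared population structure of
variants; real haplotype collections share most variants across samples,
which blocked compression exploits heavily — compression ratios measured
here are therefore conservative relative to real pangenomes.  Second,
synthetic contigs have uniform composition; real assemblies contain
satellite repeats and segmental duplications that stress the unique-k-mer
assumption harder than any test here.  What the passing tests do establish
is exactness: lossless round trips, slice-consistency of random access,
append/batch equivalence and bit-level determinism hold for every parameter
combination exercised, independently of how favourable the data is.

## Known limitations

* Archives are not interchange-compatible with other tools' formats; the
  token layout and frame codec are this package's own, documented above.
* The spt-1 group search examines every group containing the splitter; on
  collections with extreme splitter reuse this is linear per segment.
* One writer at a time; no crash-recovery journal (a failed seal leaves the
  previous footer unreachable).
* U survives ingestion and round-trips, but U-bearing segments forgo
  orientation normalization (see above).
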