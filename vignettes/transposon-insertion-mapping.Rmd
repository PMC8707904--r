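---
title: "Mapping transposon insertion sites from resequencing reads: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transposon insertion sites from resequencing reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The procedure and its assumptions

`tnscout` localizes a Tn5 cassette insertion in a sequenced bacterial
mutant by the classical resequencing argument: every read that lies
entirely in unmodified genome maps to the wild-type reference; every read
that spans a genome–cassette junction does not. The unmapped,
cassette-containing fraction of the library therefore concentrates all
the information about the insertion, and assembling it reconstructs the
junctions directly.

The decisive classification step is the **double-hit criterion**: an
assembled contig evidences an insertion if and only if it carries local
alignments to the reference genome *and* to the cassette that are
adjacent on the contig. A contig reconstructing
genome–cassette–genome carries two such adjacencies (both flanks); a
partially assembled junction carries one. Contigs lying wholly in the
genome or wholly in the cassette carry none and are ignored.

Assumptions worth stating explicitly:

* a single reference replicon; multi-replicon genomes must be analysed
  per replicon;
* the cassette sequence is known and essentially absent from the
  wild-type genome (shared k-mers would contaminate the screen);
* insertions are clonal in the colony (no mixture estimation is
  attempted);
* substitutions dominate the sequencing error process. Indel errors are
  not modelled by the simulator and are only tolerated by the aligners'
  banded gapped extension.

# Coordinates and the target-site duplication

All coordinates are 1-based inclusive on the forward strand of the
reference, the convention of GFF3 and of public genome records. Tn5
duplicates a short target site (canonically 9 bp) on insertion, so the
left and right junctions of one insertion touch *different* reference
coordinates: if the duplication starts at position $p$ and has length
$t$, the left genomic flank ends at $e = p + t - 1$ and the right flank
starts at $s = p$. The caller normalizes both to $p$ (left: $e - t + 1$;
right: $s$) and reports **the first base of the duplication** as the
insertion position. This convention is used consistently by the
simulator and the caller, which is what makes exact recovery a
meaningful test. `tsd_len` is configurable (0 disables the duplication,
and the left/right normalization then degenerates to the shared junction
base).

One subtlety makes naive coordinate extraction inexact: when the first
cassette base happens to equal the next genomic base (probability ~1/4),
the reference-side alignment extends into the cassette by the length of
that chance match (microhomology), inflating its endpoint. The cassette-
side alignment cannot over-extend in the same way — it abuts a *subject
boundary* of the cassette sequence. The caller therefore takes the
junction column on the contig from the cassette-side HSP and projects it
through the reference HSP's diagonal, which cancels the microhomology
shift and keeps recovery exact on error-free contigs. Residual off-by-one
calls can still arise when a microhomology shift is simultaneously
consistent on both flanks; this is rare (about 1 in 16 insertions shows
a 1-bp ambiguity) and bounded by the microhomology length.

# Parameters

| parameter | default | role |
|---|---|---|
| `k_map` | 21 | mapping seed k-mer; unique in multi-Mb genomes, tolerant of 1% errors in 150 bp reads |
| `map_min_identity`, `map_min_cov` | 0.90, 0.90 | a read maps when its best banded local alignment reaches this identity over this fraction of the read |
| `map_band` | 8 | half-width of the verification band |
| `k_scr`, `min_hits` | 21, 2 | cassette screen; two shared 21-mers require ≥ 22 genuine cassette bases, so one chance k-mer in an error read is not retained |
| `k_grid` | 21, 25, 31 | candidate assembly k (odd, ≤ 31 — k-mers are packed 2 bits/base into one 64-bit word) |
| `min_abund` | 3 (pipeline) | k-mer solidity cutoff for assembly |
| `hsp` scoring | +1/−2/−2, seed 11, X-drop 20, band 8 | blastn-like; plain score/length/identity thresholds replace E-values because there are exactly two subjects |
| `min_len` / `tn_min_len` | 30 / 16 | minimum HSP length against reference / cassette |
| `max_gap`, `max_overlap` | 10, 5 | junction adjacency: untemplated bases / microhomology between the two HSPs |
| `tsd_len`, `slack` | 9, 2 | duplication length; merge slack absorbing end-trimming |

Two of these deserve their rationale spelled out.

**`min_abund = 3`.** The abundance filter is what separates genomic
k-mers from error k-mers. At the ~50× coverage this pipeline is tuned
for, two of the ~50 reads covering a position carry the *same*
substitution often enough (≈ 0.04 expected events per covered position)
that an abundance-2 cutoff leaves hundreds of error k-mers solid across
a few kilobases, and each one fragments a unitig. Abundance 3 requires
three identical independent errors, which is negligible at 1% error,
while genuine junction-flank k-mers comfortably exceed it. The
`build_unitigs()` function itself defaults to 2 — the permissive choice
appropriate for low-coverage or error-free input — and the pipeline
overrides it.

**`tn_min_len = 16`.** When a mutant carries several insertions, the
cassette's two ends are shared between all junction paths in the De
Bruijn graph, so each genomic arm's unitig stops one node before the
first all-cassette k-mer: it penetrates the cassette by only $k - 1$
bases (20 at $k = 21$). Requiring 30 aligned cassette bases (the
reference-side default) would discard precisely the multi-insertion
evidence. 16 is low enough to accept these stubs and high enough that a
chance cassette hit of that length almost always *overlaps* the
reference HSP by far more than `max_overlap` and is rejected by the
adjacency test, not promoted to a junction.

# What the simulator emulates — and what it does not

`simulate_dataset()` draws an i.i.d. random genome (default 64% GC,
typical of the high-GC soil bacteria this procedure targets), a random
3 kb cassette, insertion positions separated by more than
`cassette_len + 2·frag_mean` (so no fragment touches two insertions),
orientations at random, and a paired-end library: fragment lengths
Normal(350, 50) truncated to the representable range, uniform start
positions, mate 1 the first 150 bases of the fragment, mate 2 the
reverse complement of the last 150. Substitution errors are applied per
base; qualities are constant Q40. The pair count is
`round(coverage·L/(2·read_len))`. When an adapter is configured,
fragments may be shorter than the read and their 3′ ends read through
into adapter sequence; without one, fragment lengths are truncated at
`read_len` and read-through never occurs.

The simulator deliberately omits: indel sequencing errors, PCR
duplicates and chimeras, quality-score profiles, coverage bias, and
repetitive genome structure. Consequently, passing the recovery tests
demonstrates the correctness of the *logic* (classification, assembly,
junction arithmetic) under realistic coverage fluctuation and
substitution noise — it does not certify performance on repeat-rich
genomes or indel-heavy platforms. On real data the insertion position
may also be reported under a different convention than a published
coordinate (TSD start vs junction base), i.e. offsets up to `tsd_len`
against external tables are expected.

All randomness is seeded; each simulator operation derives its stream
from `cfg$seed` plus a fixed offset, so a configuration reproduces its
dataset byte for byte, including gzip output.

# Numerical and degenerate-input choices

* Mapping verifies the single best-voted (diagonal, strand); ties break
  to the leftmost diagonal, forward strand first. A gapless scan of the
  voted diagonal short-circuits the banded alignment when it already
  clears the identity threshold (the alignment could only raise it).
* A read whose best local alignment sits exactly at the coverage
  threshold can legitimately flip mapped/unmapped through chance 1–2
  base extensions; the contracts are therefore stated in terms of the
  alignment, not of cassette-overlap length.
* Unitigs are emitted in canonical orientation (lexicographic minimum of
  sequence and reverse complement) and sorted by sequence, making
  assembly output independent of hash iteration order. Odd $k$ excludes
  palindromic k-mers.
* `choose_k` maximizes the count of distinct abundance-≥2 canonical
  k-mers over the grid (ties to the smallest k). This deliberately
  simple surrogate for a histogram-model fit tends toward larger k on
  error-bearing data; junction detection is insensitive to the choice
  within the grid because `tn_min_len` accepts stubs from the smallest
  grid k.
* HSPs are deduplicated on (query interval, subject interval, strand)
  and sorted by descending score with (subject start, query start) tie
  breaks; all downstream steps are order-stable.
* Empty inputs degrade gracefully: an insertion-free library produces an
  empty call set and a dash report row; a contig with hits to only one
  subject produces no evidence; an empty annotation leaves gene columns
  as dashes.

# Problem sizes used in validation

The packaged validation runs 20 simulations at 100 kb / 50× / 1–3
insertions (the regime the defaults are tuned for), oracle suites of 200
alignment and 200 mapping cases against independent dynamic-programming
implementations (Biostrings), 100 random annotation fixtures against a
brute-force interval scan, plus hand-computed assembly graphs. These
sizes keep the full suite in the low minutes on one CPU while exercising
every decision path; the pipeline itself scales linearly in read count
and genome length.

# Known limitations

* Reports one replicon at a time; no multi-contig references.
* No mate-pair rescue in mapping: mates are classified independently
  (pairing is only used optionally to enrich the assembly input).
* Insertions closer together than a fragment length violate the
  simulator's spacing precondition and would merge evidence in real
  data.
* The assembler does no bubble popping or tip clipping beyond the
  abundance filter — by design, so its output remains checkable against
  a hand-drawn graph.
* No zygosity/mixture modelling; a sub-clonal insertion with low
  junction coverage may surface as a single-sided call (`sides = left`
  or `right`), which is reported rather than discarded.
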