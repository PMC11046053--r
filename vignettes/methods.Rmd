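---
title: "Locating a randomly integrated transgene from paired-end WGS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating a randomly integrated transgene from paired-end WGS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitewalkr)
```

## The problem

Recombinant production cell lines (typically CHO) are often made by random
integration of an expression construct — promoter, antibody heavy-chain (HC)
and light-chain (LC) cassettes, and a glutamine synthetase (GS) selection
marker — into the host genome. Where the construct lands, how many copies of
each cassette survive, and what rearrangements accompany integration all
shape productivity and stability, so characterizing the integrant locus at
base resolution from whole-genome sequencing is a routine need in cell-line
development. Real integrants are rarely clean single insertions: truncated
and inverted construct copies, captured fragments of unrelated contigs,
contig–contig fusions and regional amplification are all common.

`sitewalkr` implements that characterization pipeline end to end, and — since
the class of datasets it targets is rarely public — pairs it with a
synthetic-data module that builds integrant genomes with exactly these
complications and a machine-checkable truth set.

## Informative-read classification

Both mates of every pair are aligned against the joint reference set (host
contigs plus the construct). Pairs are then classified:

* **isolateral** — both mates on the construct only; these pile up on the
  construct body and carry no junction position.
* **flanking** — one mate uniquely on the construct, the other uniquely on a
  host contig; evidence that the fragment straddles a junction.
* **chimeric** — a single read is split by the aligner: the matched block is
  on one reference and the soft-clipped remainder re-aligns to another.
  These resolve junctions to the base.
* **homologous** — a mate is ambiguous between construct and host because of
  shared sequence. The GS marker is the canonical case: the host genome has
  its own GS locus, so GS-derived reads cannot be assigned an origin.
* **non-informative** — everything else.

Precedence when several criteria fire is chimeric > flanking > homologous >
isolateral > non-informative, so base-resolution evidence is never absorbed
into a coarser class. Host contigs are nominated as integration candidates
by their combined flanking+chimeric support above a floor (`min_support`,
default 5 pairs).

Isolateral R1 and R2 counts are equal by construction (both mates of a
classified pair exist), which is the quick sanity check that construct-body
pairs are properly paired; unbalanced mate counts in the junction-bearing
classes are expected, since those reads sit on two different references.

## The built-in mapper and its soft-clip behaviour

The mapper is seed-and-extend: 21-mers (k configurable, ≥ 11) are looked up
in a hash index of the references, hits are voted per (reference, strand,
diagonal), and each candidate diagonal is scored gaplessly — +1 per matching
base, −8 per mismatch — taking the maximal-scoring contiguous segment
(Kadane's algorithm) as the aligned block and the remainders as terminal
soft clips. Two choices matter downstream:

* **Gapless extension.** The read simulator's error model is
  substitutions-only (the dominant short-read error mode), so indel-capable
  banded extension would add complexity without changing any result; with a
  gapless model the clip boundary of a fusion-spanning read falls exactly at
  the fusion point.
* **The heavy mismatch penalty.** At a fusion point the read continues into
  the partner reference, whose bases match the anchor reference's
  continuation only by chance. With penalty −8 the aligned block absorbs a
  chance run beyond the junction only if 9 surplus matches accumulate
  (probability ≈ 4 × 10⁻⁶ per read), so breakpoint evidence stays exact.
  The cost is that a genuine sequencing error within 8 bp of a read end gets
  clipped rather than aligned, which is harmless here: clips below 20 bp are
  ignored by every consumer.

All co-optimal placements are reported and flagged ambiguous — never broken
randomly — because the homologous class *is* the detection of that
ambiguity. Alignments read and write SAM (1-based positions, S ops in
CIGARs, secondary placements as 0x100), so an external mapper can be
substituted for any downstream stage.

## Junction resolution

Terminal soft clips ≥ 20 bp of primary alignments are re-aligned against
all references on both strands (seeded with 15-mers so the shortest
admissible clip is recoverable). A clip qualifies if it aligns with ≥ 95%
identity over ≥ 20 bases and the placement is unambiguous; ambiguous clips
are discarded rather than guessed, mirroring the exclusion of homologous
evidence. Each qualifying clip pairs its anchor coordinate (the matched
base adjacent to the clip) with the re-alignment's entry point (the
reference position of the anchor-adjacent clip base); reverse-strand hits
are marked inverted. Candidates are clustered per reference pair and
orientation within a positional tolerance (default 2 bp; 0 in the
error-free validation), the modal coordinate pair becomes the call, support
counts distinct reads, and same-reference calls closer than a read length
are suppressed as internal soft-clip noise.

Junction endpoints are stored canonically — the two (reference, position)
pairs sorted — so calls made from either side of the fusion, and truth
junctions derived from the integration plan, compare directly.

**Micro-homology caveat.** A fusion is single-base identifiable only if the
joined references do not share the bases flanking the fusion point; under
h bases of shared sequence any caller (and any truth derivation) is
ambiguous within h. The scenario builders therefore adjust the flanking
reference base at each planned junction so every truth breakpoint has zero
flanking homology, and the exactness property (precision = recall = 1 at
tolerance 0 over a 50-scenario sweep) is claimed under that condition. Real
junctions with micro-homology are still called, just with the usual
within-homology positional ambiguity — hence the default 2 bp tolerance.

## Genome walking

Short reads cannot see far past a junction when the flanking region is
rearranged, so the pipeline extends the construct-anchored sequence by
iterative assembly and re-mapping. Each cycle: map all reads to the current
contig; recruit the reads whose alignments overlap the terminal 200 bp
window on the growing end, **plus their mates even when unmapped** (mate
rescue — the mates reach up to one insert length into unknown sequence,
and are what actually extends the walk); assemble the recruited set; splice
the assembled contig onto the growing end by its exact overlap. Upstream
walks grow at the 5' end seeded with the whole construct; downstream walks
seed with the construct's terminal 1 kb window.

The assembler is a greedy overlap–layout–consensus: repeatedly merge the
pair with the longest exact suffix–prefix overlap ≥ `min_overlap` (default
40 bp), in both orientations, absorbing contained sequences, with a fixed
total order for ties — so assembly, and the whole walk, is deterministic
given reads and configuration. A de Bruijn assembler would tolerate higher
error rates, but on near-error-free desk-scale data the contract is on the
reconstructed sequence, not the assembler, and exact overlaps keep the
consensus trivially correct.

Walk geometry: a read whose alignment starts inside the 200 bp end window
has a mate reaching roughly `insert − read_len` beyond it, so per-cycle
extension concentrates around `insert_mean − read_len` up to
`insert_mean + end_window`; at the default 500 ± 50 bp inserts and 150 bp
reads we observe ≈ 500–550 bp per cycle, and 12 cycles comfortably exceed
5 kb of upstream reconstruction at ≥ 99.9% identity on 40× error-free
data. The walk stops early as `stalled` (nothing extends the end) or
`circular` (> 90% of a new extension's 31-mers already occur in the contig
— the signature of walking into repeated construct copies, which is exactly
how the downstream walk behaves on the default scenario: it extends into
truncated-construct sequence and then stops, and `place_contig()` places
the extension on the construct, not the host).

`place_contig()` maps an assembled contig back onto the references by exact
21-mer anchors clustered per (reference, strand, diagonal) with identity
verification — a contig spanning a fusion yields two placements
partitioning it.

## Read-depth copy number

Depth is averaged in 500 bp tiling windows from primary, unambiguous
alignments. The normalization constant is twice the genome-wide modal
window depth, inferred from the observed peak structure of such data: a
mostly-two-copy (diploid-like) background then sits at 0.5 and a region at
copy count c at c/4 — one-copy 0.25, three-copy 0.75, four-copy 1.0.
Integer copies are `round(4 × mean normalized depth)`.

Two numerical choices:

* **Modes are kernel-density peaks** (Silverman bandwidth, floored at
  pilot/50 where the pilot is the median positive depth), not fixed-bin
  histogram maxima: a histogram mode is biased by up to half a bin and
  flips between adjacent bins under resampling, which alone would consume
  most of a ±0.02 tolerance on the 0.25 peak.
* **Feature means are per-base, not per-window.** A 1 kb cassette at four
  copies flanked by three-copy sequence would have its windowed mean
  diluted by every straddling window; `estimate_feature_copies()` therefore
  averages per-base coverage over the exact feature interval, divided by
  the same normalization constant.

Reads whose origin is ambiguous between references (the GS cassette versus
the host GS locus) are excluded from depth, so the GS cassette's depth-based
copy estimate is structurally undefined in the default scenario — the same
ambiguity the homologous read class exists to flag. Copy-recovery claims are
therefore made for the mappable features (HC, LC, promoter, amplified
region).

qPCR relative quantification is the standard ΔΔCt: per sample,
ΔCt = mean Ct(target) − mean Ct(reference gene); fold = 2^−ΔΔCt, assuming
100% amplification efficiency (one doubling per cycle; the simulator makes
the same assumption, so the noiseless round trip is exact).

## Sliding-window scoring

`score_track()` bins a sequence into 249 bp windows at stride 1, applies a
pluggable scorer to every window, and aggregates scores per base: each
window's score is assigned to all bases it covers, and per-base mean,
minimum and maximum are reported. Assigning to the whole window (rather
than its center) is what makes per-base min/max bands possible; edge bases
keep their partial coverage rather than being trimmed. The aggregation is
O(L): coverage counts and score sums via difference arrays, min/max via a
rolling window over the score vector with brute-forced edges. The shipped
scorer is GC content — a stand-in exercising the adapter contract
(`function(character vector of window sequences) -> numeric`); an external
enhancer-activity model plugs in behind the same interface, and any claim
about the biology of the scored sequence belongs to the scorer, not this
package.

## Bioprocess quantitation

Units are fixed: VCD in cells/mL, titer in µg/mL, specific productivity
q_p in pg/cell/day (1 µg/mL = 10⁶ pg/mL), IVCD in cell·day/mL. IVCD is the
trapezoidal integral of VCD; q_p is the titer increment over an interval
divided by that interval's IVCD; P_max is the series maximum. The interval
is always caller-supplied and always reported back; an exponential-phase
detector (longest window with log-linear VCD fit R² ≥ 0.98) is provided but
never applied silently, because phase-boundary choices change q_p and must
be visible. Fold changes round half-to-even at presentation only.

The culture simulator is logistic growth with titer accumulating as
q_p × trapezoidal viable-cell integral per step, so noiseless quantitation
recovers the generator's q_p to machine precision — the round trip that
pins the unit conventions.

## The synthetic study conditions

The default scenario is one deterministic function of a seed:

* two host contigs (60 kb, 12 kb) with uniform base composition and a
  two-copy background — sized so the genome-wide modal depth is estimated
  from a few hundred background windows, since every copy call scales with
  that one constant;
* a 9.3 kb construct: backbone, promoter (800 bp), LC cassette (2.4 kb),
  spacer, HC cassette (2.4 kb), spacer, GS (1.5 kb), backbone — cassette
  sizes chosen as realistic full expression cassettes, which also sets the
  fragment-count noise of a cassette's depth estimate (~4% at 30×) safely
  inside the ±12.5% an integer call at four copies tolerates;
* a host GS locus identical to the construct's GS cassette (the homologous
  ambiguity);
* the integrant haplotype at the insertion point: a 7× tandem-amplified
  3 kb upstream region (8 copies total against 2 in a control — 4-fold by
  qPCR), a 240 bp captured fragment of the second contig, the intact
  construct, two tandem truncated copies (promoter+LC, lacking GS and HC),
  and one inverted LC cassette — LC ×4, HC ×1, GS ×1 in truth;
* the unmodified homolog kept at copy 1, all other contigs at copy 2.

Reads are TruSeq-like 150 bp pairs, insert 500 ± 50 bp, fragments drawn
proportional to local copy count, substitution errors only (default
10⁻³; error-free in the validation suites). Read length and insert
geometry are asserted defaults, not published values. Pair count is
`round(coverage × Σ lengthᵢ·copiesᵢ/2 ÷ (2·read_len))`, so `coverage` means
depth over two-copy background.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: indels and quality-correlated errors, GC and
mappability bias, PCR duplicates, repeat families beyond the planted
cassette repeats, and real CHO sequence composition. The pipeline's
contracts (classification partition, breakpoint exactness under zero
micro-homology, copy-number normalization, walk reconstruction) are
validated against truth; its robustness to those real-data artifacts is
not claimed.

Problem sizes in the validation suite are desk-scale by design — a few
hundred kb of genome, tens of thousands of read pairs, 12 walk cycles on a
20 kb integrant — chosen so the complete suite runs in minutes on one core
while every structural feature of the target datasets is represented.

## Command line and configuration

`run_discovery()` drives the full chain from a single YAML/list
configuration (per-stage sections, one global seed) and writes every
intermediate in plain-text formats (FASTA/FASTQ/SAM/TSV/JSON), so runs are
resumable and any stage replaceable. A thin wrapper at
`inst/cli/sitewalkr` exposes `simulate` and `run-all` subcommands; it
contains no logic of its own. The implementation is single-threaded and
deterministic under the configured seeds.

## Known limitations

* Junction positions inside micro-homology tracts are reported at the
  aligner's maximal-extension boundary, not a canonical shifted position.
* The mapper is gapless: indel-bearing reads near a junction would be
  soft-clipped early rather than split precisely.
* The greedy assembler assumes near-exact reads; it will fragment rather
  than error-correct.
* Depth normalization presumes a dominant two-copy background; a heavily
  aneuploid genome would shift the modal anchor.
* The walk's circularity guard stops at repeat entry; it does not attempt
  repeat resolution or scaffolding.
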