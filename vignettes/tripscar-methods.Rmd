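---
title: "Methods: barcoded DSB-repair reporter analysis with tripscar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded DSB-repair reporter analysis with tripscar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripscar)
```

## The assay and its data model

A barcoded reporter pool integrates many copies of one DSB-repair reporter
across the genome. Each copy ("reporter" below) carries a random 16 bp
barcode inside a constant cassette, a Cas9 target site, and — downstream of
the cut — seven 6 bp marker *spacers* whose wild-type positions are known.
Two libraries are sequenced per experiment: single-end indel-PCR reads
(internal sample index + barcode cassette + scar region) and paired-end
inverse-PCR reads that capture the genomic sequence flanking each
integration via circularized DpnII fragments.

`tripscar` models the reporter as a `reporter_spec`: the wild-type amplicon
as read by the indel PCR, the two adapter arms that flank the barcode, the
blunt-cut offset, the spacer set, and one or more named *recognition
sequences* — exact windows whose presence names a read's call ("wt" is
mandatory and must span the cut; designed repair products such as a
templated insertion can be added under their own names).

**Coordinate convention.** All amplicon offsets (cut, spacers, deletion
intervals) are 0-based, with position 0 the first base after the 3′ adapter
arm. The spacer offsets 83–124 are expressed in this frame; the origin is a
documented package choice, shared by the simulator and the caller, so all
internal arithmetic is self-consistent. Genomic coordinates are 1-based
closed internally (the R/Bioconductor convention used by Rsamtools) and
exported 1-based, labelled as such in the column headers.

## Barcode retrieval

Retrieval tries three steps in order: (1) *full* — the 5′ arm is found and
the 3′ arm lies exactly 16 (then 15, then 17) bases downstream, recovering
the tolerated barcode-length range; (2) *five_prime* — only the 5′ arm is
found and the next 16 bases are taken; (3) *three_prime* — only the 3′ arm
is found with at least 16 bases before it. Failures are recorded, never
raised. Matching tolerates `adapter_max_mismatches` substitutions
(default 1) per arm; arms of 5 bp or less are always matched exactly,
because indel or mismatch tolerance in a 5 bp arm would produce spurious
matches. When an arm matches several positions the leftmost is used — the
cassette sits at a fixed 5′ position by design. The mismatch tolerance is a
package decision exposed as a parameter; the adapter-trimming tool the
protocol is built on does not pin one value.

Read-through trimming removes the reverse complement of the constant
patterns from the 3′ end of the remainder (leftmost occurrence, same
mismatch tolerance): when a large deletion shortens the amplicon, the
sequencer continues into the plasmid backbone and these patterns appear.

Internal indices demultiplex at the read's 5′ end; a read is assigned only
when exactly one index matches within `max_mismatch` (default 1), and index
tables whose pairwise Hamming distance does not exceed twice that tolerance
are rejected up front as a configuration error.

## Barcode clustering

Sequencing and PCR errors scatter each true barcode into satellites.
Barcodes are clustered greedily: candidate centres in order of decreasing
count (ties broken lexicographically, so runs are deterministic); every
unassigned barcode within Levenshtein distance `max_barcode_dist` of the
centre joins it; centres are the *genuine* barcodes. The protocol's
criterion "distance < 2" is implemented as `max_barcode_dist = 1`, reading
the strict inequality as printed. Greedy sphere clustering was chosen over
message-passing variants because only the distance criterion and the
most-abundant rule are specified, and the sphere mode is deterministic and
directly testable against an all-pairs single-linkage oracle (the suite
runs exactly that comparison; on chained instances where a radius-1 path
connects two high-abundance centres the two algorithms can legitimately
differ, which the property test would surface). Length-15/17 barcodes
cluster with 16-mers naturally since edit distance absorbs length.

Cluster application is a filtering step by default (drop reads whose
barcode is not genuine); rescue mode instead rewrites members to their
genuine barcode and merges.

## Integration mapping

Alignment itself is delegated — the module consumes SAM, with the barcode
in a tag or in the read name — because the assay-specific content is the
pre- and post-processing, not the aligner. Circularized fragments can
ligate two distant genomic pieces; such chimeras align at the distant locus
with the true junction piece soft-clipped at the read's 5′ end. Triage of
the transposon-edge mate: no leading clip — keep; clip of 1–16 bp —
discard; clip > 16 bp — realign the clipped sequence and let it re-enter
aggregation at its new coordinates, so the genomic sequence actually next
to the reporter is counted. Realignment uses the package's exact-match
aligner against the supplied genome; it reports only unique exact hits,
which is sufficient for clipped junction pieces and keeps the pipeline free
of external aligner dependencies in testing.

Reads aggregate per barcode into location groups keyed by chromosome,
strand and junction position (strand-aware: leftmost aligned base on `+`,
rightmost on `-`), collapsing positions within ±2 bp to absorb end jitter
(the window is a package choice; no coordinate tolerance is prescribed).
The two best-supported locations are reported with read counts and MAPQ
sums; ties break deterministically by count, MAPQ sum, chromosome,
position.

A barcode passes as a trustworthy integration iff `reads1 >= 5`,
`mapq_sum1/reads1 > 10`, `reads1/total >= 0.95` and `reads2/total <=
0.025`. The denominators are the barcode's total reads across all location
groups — the source phrasing ("of the reads") does not qualify the
denominator, so the more conservative total was chosen and the thresholds
are parameters. Failing barcodes carry every violated reason code.

## Scar calling

Two independent signals are computed per read.

*Recognition match* — exact substring search of each named recognition
sequence; the longest match wins. Exactness is deliberate: these windows
define calls, and tolerance would blur `wt` against point mutants; reads
that fail all windows are routed to size-based calls anyway.

*Spacer size* — spacers are scanned in order; for the first spacer found,
the occurrence nearest its expected offset is used and the size is
observed − expected offset. Any intact spacer suffices, which makes the
size robust to errors or mutations downstream of the first intact spacer,
and captures deletions up to one base short of the first spacer offset.
One concordant spacer is required (the minimum is not prescribed
anywhere); choosing the occurrence nearest the expected offset guards
against marker sequences recreated by chance after mutation.

The taxonomy is total: recognition name if found (size still attached, so
`wt` with size −1 is representable and flagged in QC); otherwise `del` /
`ins` / `wt_point_mut` for sizes < 0 / > 0 / = 0; otherwise `not_clear`.

### Alignment mode

The finer mode aligns each remainder to the wild-type amplicon
(`pairwiseAlignment`, pattern-global / subject-local so sequencer
truncation is free). Two numerical choices matter:

- **Anchoring.** Both sequences are prefixed with a fixed 20 bp anchor.
  Without it, the free subject window can absorb a large deletion by
  sliding past it instead of opening a gap whenever the bases upstream of
  the deletion are few enough to mismatch cheaply; the anchor pins the
  alignment at the amplicon start and removes that failure mode.
- **Scoring** (+1 match, −4 mismatch, 3 gap opening, 0.25 gap extension):
  long deletion gaps must stay cheaper than the mismatch runs they could
  be traded for, while a single substitution error must still be absorbed
  as one mismatch (cost 4) rather than an indel pair (cost 6.5). An
  earlier, more conventional −1 mismatch setting failed the first
  requirement for deletions around 20 bp and was replaced; the
  spacer/alignment concordance test in the suite pins the behaviour.

Deletions are left-aligned (shift left while the base before the interval
equals the base at its end) before the microhomology is computed as the
longest run by which the deletion could slide — exactly the flanking-repeat
length under which MMEJ deletions are coordinate-ambiguous. Alignments
below 50 % identity yield no detail and the read falls back to
`not_clear`.

## Pathway quantification

`not_clear` reads are filtered with their fraction logged (historically
around a sixth of reads in real data; the simulator produces whatever its
spectrum programs). Cell representation per barcode is read share ×
100,000 assumed cells × 6 barcodes per cell (= share × 600,000); barcodes
under 50 estimated cells are flagged out. The estimator conserves its
total by construction.

Replicates are scaled to counts per million, averaged per (barcode, call,
size) with absent combinations contributing zero, and proportions computed
on the average — so depth differences cancel exactly.

Classification (count mode) routes indel reads by size: −7 → MMEJ, +1 →
NHEJ, everything else `other`; wild-type, named, `wt_point_mut` and
`not_clear` reads are excluded from all indel denominators. Detail mode
additionally requires the signature microhomology (3 bp for −7, and for
the further known products −14/3 bp and −22/6 bp) from the alignment
output. The balance is `MMEJ/(MMEJ+NHEJ)`, undefined when both are zero,
and invariant to depth scaling. Wild-type reads are reported but never
enter denominators; note that apparent wild-type can have several origins
(uncut, faithfully repaired, or cut after sampling), which is why the
package reports the balance rather than an absolute editing rate.

NHEJ discovery from inhibitor data: indel types with a vehicle (DMSO)
ratio of at least 0.01 — the pooled mean across units; a per-barcode
variant is a flag away — are tested for a decrease under inhibition with a
one-sided Wilcoxon rank-sum test across per-barcode (or per-replicate)
values, Benjamini–Hochberg adjusted across tested types, labelled NHEJ at
adjusted p < 0.05. The adjustment method and test flavour (rank-sum
across units rather than paired signed-rank) are package choices where the
protocol says only "adjusted p-value" and "one-sided Wilcoxon"; BH is the
field default and rank-sum matches the per-barcode data layout. Types with
fewer than three values per condition are reported untested, never
guessed.

## The simulator: what it emulates, and what it does not

`make_reporter()` draws a random amplicon with the designed structure: the
adapter arms, a blunt cut, an engineered 3 bp direct repeat separated by
4 bp around the cut — so the repeat-collapsing deletion is −7 bp with a
3 bp microhomology *by construction*, verified by enumeration in the tests
— and seven unique 6-mers at offsets 83–124. `simulate_indel_reads()`
emits full-structure reads (index, cassette, edited amplicon, backbone
read-through) with per-reporter outcome spectra, barcode substitutions and
uniform per-base substitution errors; `simulate_ipcr()` builds a
two-chromosome mini-genome, places integrations, and emits read pairs plus
truth-consistent SAM, including circular-ligation chimeras whose clipped
true-junction piece is recoverable; `simulate_drift()` models clonal
takeover with log-normal growth-rate spread.

Default study conditions: 150 bp reads, 2,000 indel reads per reporter
(the recommended sequencing depth), 0.1 % per-base substitution error
(Illumina-like), 1 % of reads with a one-base barcode error, 5 % chimeric
fragments, and an outcome spectrum of 50 % wild-type, 15 % MMEJ deletion,
35 % NHEJ insertion; programmed per-reporter MMEJ fractions for recovery
studies are drawn uniformly from [0.05, 0.95]. Where no value is
prescribed these are one-time choices of plausible magnitudes, not fitted
quantities.

The error model is substitution-only: sequencing indel errors, PCR
jackpotting/duplicates, quality-score structure and genomic repeats are
not modelled. Passing tests therefore demonstrate the correctness of the
algorithms under realistic substitution noise and chimera rates — not
robustness to every artefact of real libraries; on real data the
`not_clear` fraction and the soft-clip discard rate should be watched as
the primary QC dials. Simulated SAM records are emitted error-free (the
simulator stands in for the aligner, whose output would already
incorporate errors as mismatches); FASTQ reads do carry errors.

## Degenerate inputs and determinism

Empty or too-short reads are counted as failures, never errors; empty
count tables error only where a denominator would be undefined
(`estimate_cells`). Zero-total replicates are excluded with a warning.
All randomness flows from explicit integer seeds; simulator functions
restore the caller's RNG state. Ties anywhere (cluster centres, location
ranking, count-table ordering) break deterministically, so fixed seeds
give byte-identical outputs, which the pipeline manifest's checksums make
verifiable.

## Problem sizes used in the shipped checks

The suite exercises the stated guarantees at: 500 barcodes against the
single-linkage clustering oracle; 1,000 random mapping-table rows against
the filter-predicate oracle; exact rank-sum enumeration up to group size
8; a noiseless end-to-end run of 100 reporters × 2,000 reads; 10,000
single-indel reads for spacer/alignment concordance; 200 reporters ×
2,000 reads for MMEJ-fraction recovery (root-mean-square error below
0.02, absolute bias below 0.005); and 1,000 null indel types for the
false-label bound. These sizes are the package's chosen test scale; the
functions themselves stream over vectors and handle larger inputs.

## Known limitations

- Homologous recombination leaves no indel at this reporter and is
  therefore invisible to the assay and to this package.
- The exact-match realigner is intentionally naive; for real genomes,
  realignment of clipped fragments should go through a full aligner and
  re-enter `aggregate_locations()` unchanged.
- Recognition matching is exact; heavily error-laden recognition windows
  route reads to size-based calls, slightly inflating `wt_point_mut` at
  high error rates.
- Chromatin-feature correlation, predictive scar models and qPCR-based
  copy-number estimation are out of scope.
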