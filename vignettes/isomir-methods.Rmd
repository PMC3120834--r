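---
title: "Calling isomiRs and 3' non-template additions from SOLiD colorspace reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling isomiRs and 3' non-template additions from SOLiD colorspace reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solmir)
```

## The problem

A mature miRNA is rarely a single sequence. Imprecise and alternative
Drosha/Dicer cleavage of the ~70-nt precursor hairpin releases a family of
length and end variants (isomiRs), and nucleotidyl transferases append
non-template nucleotides -- most often adenosine or uridine -- to the 3'
end after Dicer processing. On a SOLiD instrument the reads arrive in
two-base *colorspace*: each color encodes an adjacent base pair, so a
single mis-called color corrupts every downstream base once decoded, while
a genuine sequence difference changes two adjacent colors. This package
implements the complete analysis for such data: reference handling,
colorspace decoding and alignment, isomiR/addition calling, per-locus
spectrum statistics, dual-scheme expression profiling, fold-change
differential expression without replicates, and cleavage-site inference --
plus a synthetic-data generator with planted ground truth, since the kind
of placental study this pipeline addresses typically leaves no deposited
raw data to test against.

## The colorspace codec and the boundary rule

Bases map to the 2-bit codes A=0, C=1, G=2, T=3 and the color of a base
pair is the XOR of the two codes, which reproduces the standard SOLiD
di-base matrix (0 on the diagonal, symmetric, every row a permutation of
0-3). `cs_encode()` pairs the library primer (default T) with the first
insert base; `cs_decode()` inverts by a running XOR.

Alignment happens in color space, never on decoded bases. Against a
candidate precursor offset, at most **one** internal color mismatch is
tolerated and corrected to the reference -- an isolated single color
change cannot be a real sequence variant. The 3' boundary is where the
biology lives:

* a mismatch at the final aligned color **whose following color (the
  first color of the insert/adaptor junction) also mismatches** marks a 3'
  non-template addition; the added base is decoded from the terminal
  color and checked against the precursor at its notional position (it
  must differ -- otherwise the read is a templated extension and is
  classified as such);
* a terminal mismatch whose junction color matches the templated
  expectation is a sequencing error in the last color and is corrected;
* two trailing mismatches with a consistent junction decode to a double
  addition (at most 2 nt; longer tails go unaligned).

`classify_boundary()` implements exactly this single-junction-color
contract. The aligner itself verifies **two** junction colors: the first
pairs the last insert base with the adaptor's first base, the second is
the adaptor-internal color of its first two bases. One junction color is
not identifiable: if the adaptor's leading dinucleotide (or merely the
color of its leading pair) recurs near its start, a templated read
followed by the adaptor can be reinterpreted as a fake 1-2-nt addition
with a frame-shifted junction that still "matches". The packaged default
adaptor is therefore constructed with no self-similar junction structure
(first two bases differ; the leading dinucleotide and the leading pair
color never recur), and `build_align_index()` warns when a user-supplied
adaptor violates this. With that structure, the two-color junction check
pins the insert length exactly on error-free reads.

Reads whose only inconsistency sits in the junction or adaptor colors are
not discarded: they keep their best templated alignment (a "weak" hit,
preferred by fewest mismatches then longest span). A single sequencing
error can therefore cost a read its addition call, but never the read --
only reads with two or more errors can be lost.

## Alignment strategy

The contract is an exhaustive scan of every precursor offset on the sense
strand. At desk scale (tens of precursors, at most a few hundred nt each)
the implementation uses two exact seed lookups (colors 2-9 and 10-16,
which always lie inside the >= 16-nt template) to enumerate candidate
offsets; because at most one internal mismatch is allowed, at least one
seed is uncorrupted, so the seeded scan finds every qualifying hit and is
tested for exact agreement with a brute-force enumeration over all
(precursor, offset, length) triples. Multi-mapping reads are counted
once: ties resolve to the lexicographically first precursor (the same
"first copy" rule used to report multicopy loci), then the smallest
start, then the longest insert. A hit is assigned to the mature
annotation it overlaps by at least half the annotated mature length;
fragments overlapping no annotation (loop or unannotated star arm) are
logged as unassigned rather than guessed.

Base-space mode applies the same span/addition semantics by trailing-tail
analysis (longest templated prefix, 1-2 trailing non-template bases, no
mismatch allowed at the template's last position) and is tested to
produce identical observations on error-free data. It exists for
portability; colorspace mode is the reference implementation.

## Thresholds

All constants live in `pipeline_config()` and carry the conventional
values for this analysis family:

| parameter | default | meaning |
|---|---|---|
| `report_min` | 10 | a species enters a spectrum at >= 10 counts |
| `abundant_species_min` | 99 | an isomiR "type" counts when > 99 reads |
| `abundant_locus_min` | 999 | a locus is profiled/tested when > 999 reads |
| `modified_de_min` | 300 | modified-isomiR DE floor (> 300 in one sample) |
| `impute_floor` / `impute_value` | 100 / 10 | counts < 100 become 10 before fold change |
| `lfc_threshold` | 4 | significance at abs(log2 fold change) > 4 |
| `dominance_fold` | 5 | dominant cleavage at most/secondary fold >= 5 |

The +/-4 threshold is interpreted on the log2 scale (16-fold raw): the
worked DE examples (e.g. log2(5000/10) ~ 8.97) only make sense there. No
library-size normalisation is applied by default -- single libraries, raw
counts, no replicates, hence also no p-values: DE is a thresholded fold
change, and imputation guarantees it is finite and antisymmetric.
Whether the > 999 floor applies before or after imputation is genuinely
open; it is applied before, on raw counts, so imputation can never
qualify a locus for testing.

Spectrum percentages sum to 100 within 1e-9; raising the report floor can
only shrink a spectrum (tested as a monotonicity property). Species are
keyed by (mature id, template span, addition), so identical molecules
from different samples are the same species. Addition shares are keyed by
the printed addition string (U for T), which makes the per-addition
fractions sum exactly to the totals under both the all-species and
modified-only denominators -- the two denominators a percentage panel can
reasonably use are both emitted, labelled.

For the expression-versus-type relationship the package reports a
Spearman rank correlation: the scientific claim at stake is about
ordering ("more expression, more isomiR types"), not linearity.

## Cleavage inference

End positions are aggregated by template span with additions stripped --
a 3' addition is post-transcriptional and must never move an inferred
Dicer/Drosha cut (tested by toggling addition injection). The most
abundant span's ends are the dominant sites; when the most/secondary fold
is below 5 the secondary span's ends are flagged as non-dominant
alternative cuts, and an exact tie (fold 1) flags both. On a 5p-arm locus
the 5' end is the Drosha cut and the 3' end the Dicer cut; the mapping
reverses on a 3p arm; without an arm the sites are reported unlabelled.
Inference runs on the report-thresholded spectrum (not raw observations):
sub-threshold species are indistinguishable from noise at these depths.

## What the generator emulates

`sim_config()` fixes the study conditions; all randomness is seeded and
the within-locus species structure is drawn once from the configuration
seed and shared across samples, so spectra are conserved across samples
by construction unless explicitly shifted.

* **Loci**: 30 precursors of 70-90 nt, one mature annotation each,
  canonical lengths 20-23 nt peaked at 22 (the dominant small-RNA
  length), arms random, margins left for end shifts.
* **Spectra**: each locus draws up to two extra template species; a slot
  becomes a 3'-shifted species with probability 0.8 and a 5'-shifted one
  with probability 0.1 (offsets 1-2 nt, geometrically decaying), giving
  1-3 abundant isomiRs per locus with the canonical species leading
  (50-80% of the locus before normalisation).
* **Additions**: planted at species level so the configured type share
  (default 0.31) is directly recoverable: `round(share/(1-share) * n)`
  modified siblings are spawned from abundant template species, at 3-12%
  of their parent's abundance (with an expected-count floor of 20 so
  planted species survive the report threshold), base drawn from the
  adenosine-biased weights A 0.60 / U 0.25 / C 0.12 / G 0.03, redrawn
  when it equals the template base at its notional position (keeping
  planted additions unambiguous), 10% of modified species carrying a
  double addition.
* **Reads**: insert plus adaptor, encoded with primer T, truncated to 35
  colors (so every read carries at least two junction colors), each color
  flipped independently at rate 0.001 -- a realistic raw SOLiD color
  error rate. Reads with at least one error are emitted individually;
  clean reads stay collapsed.
* **Effects**: per-locus log2 fold changes (default six effects of
  +/-6 in the severe sample) applied as a symmetric split between
  baseline and target so library composition stays balanced; a
  `spectrum_shift` list can additionally swap the dominant and secondary
  species of chosen loci in the diseased samples.

What the generator does **not** emulate: quality values and
quality-dependent error profiles, ligation and amplification bias,
background degradation fragments (blacklist behaviour is exercised with
explicit fixtures instead), genuine biological correlation between
expression level and isomiR diversity, and moRNAs. Passing recovery tests
therefore demonstrates that the *rules* are implemented exactly and are
statistically recoverable under the stated noise model -- not that the
pipeline is robust to every artefact of a real library.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive everywhere, converted only at I/O
edges. U and T are interchangeable on input; T is canonical internally; U
is printed for additions. Ties break deterministically and documentedly:
collapsing orders by count then key; spectra by count then sequence;
top-N by value then mature id; "first precursor" is byte-wise
lexicographic. An empty spectrum is valid (not an error); a correlation
over fewer than three loci is `NA` with the paired table still emitted;
the Jaccard of two empty DE sets is 1 by convention. All randomness
passes through explicit integer seeds.

## Problem sizes used by the checks

The bundled tests and the acceptance script run entirely on generated
data at deliberately desk-sized scales: exhaustive codec round trips to
length 8; aligner-versus-brute-force agreement on 500 reads against 10
toy precursors; exact truth recovery on an error-free 1e4-read library;
statistical recovery (addition share within 0.03, heterogeneity within
0.05, all planted effects recovered with no false positives among
conserved loci) on 30 loci at 1e5 reads per sample with the default
0.001 color error rate. These sizes were chosen as the smallest at which
the statistical recovery claims are comfortably identifiable.

## Known limitations

* Additions longer than 2 nt are unaligned by design; real tails of 3+
  nt exist but cannot be separated from adaptor under a 1-mismatch rule.
* An addition whose base equals the next template base is reported as a
  templated extension -- the conservative reading; colorspace cannot
  distinguish the two.
* A single color error at the junction silently demotes an addition to
  its template species; at the default error rate this biases addition
  counts down by ~0.1% relative.
* Blacklist filtering of colorspace reads decodes before matching, so a
  read with an early color error may escape the blacklist; the
  downstream one-mismatch alignment cannot rescue such a read into an
  isomiR call unless it resembles a precursor, so the practical effect
  is confined to the removal log.
* With multiple planted effects targeting different samples at the same
  locus the realised pairwise fold changes compound; the default design
  plants at most one effect per locus.
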