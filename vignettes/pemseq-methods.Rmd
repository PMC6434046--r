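---
title: "Quantifying CRISPR editing outcomes from PEM-seq libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing outcomes from PEM-seq libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemseq)
```

## The measurement problem

Primer-extension-mediated sequencing (PEM-seq) reads out what happened to a
genomic locus after a programmable nuclease cut it. A biotinylated primer
placed within 200 bp of the cleavage site copies each template exactly once;
a bridge adapter carrying a 14-nt random molecular barcode (RMB) labels each
original molecule, so PCR amplification can later be undone by barcode
clustering. Read 1 is anchored at the primer and runs across the cut into
whatever sequence the repair machinery joined there; read 2 starts in the
bridge adapter and carries the barcode.

Every deduplicated molecule is assigned to one of three outcomes:

* **germline (G)** — no detectable mutation around the cut: the allele was
  either never cleaved or repaired perfectly;
* **indels (I)** — insertions or deletions at the cut, including large
  resection-driven deletions and inversions rejoined within ±250 kb of the
  cut;
* **translocation (T)** — the bait end joined a double-strand break
  elsewhere: beyond the proximal span or on another chromosome.

Editing efficiency is computed against a matched uncut control library and a
transfection efficiency TE:

$$\text{efficiency} \;=\; \frac{\dfrac{I_S+T_S}{G_S+I_S+T_S} -
  \dfrac{I_C+T_C}{G_C+I_C+T_C}}{\text{TE}}$$

with S the nuclease-treated and C the control library. A negative numerator
(sampling noise near zero) is clamped to 0 with a warning. We report the raw
sample fraction alongside the corrected efficiency, because the two coincide
only when the control is clean and TE = 1.

Off-target activity is read out from genome-wide translocations: junction
clusters far from the bait are tested for enrichment, screened for a cryptic
target-like sequence with a PAM, required to recur in at least two replicate
libraries, and scored as junctions per 100,000 editing events,

$$\text{intensity} \;=\;
  \frac{\text{hotspot junctions}}{(I_S-I_C)+(T_S-T_C)} \times 10^5 .$$

The intensity denominator uses the control-corrected editing events of the
treated library. (One symbol in the original formula reads "T_N" where every
other symbol pairs S with C; we treat it as T_S.)

## Classification rules and their boundaries

The classifier inspects a window of ±5 bp around the presumed cut. A
molecule without a prey segment is an indel iff an insertion or deletion
operation overlaps that window (subcategory `small_insertion`,
`small_deletion` or `insertion_plus_deletion`), otherwise germline.
Substitutions never disqualify a molecule from germline: at realistic
sequencing error rates a substitution at the cut is indistinguishable from
an error, and counting them would inflate the indel fraction by the error
rate times the window width.

A molecule whose prey lies on the bait chromosome within ±250 kb of the cut
is an indel: subcategory `large_deletion` when the prey strand matches the
bait strand (a resection-and-rejoin product), `inversion` when the strand is
flipped. Both windows are inclusive at their boundaries (an edit at exactly
cut±5, a prey at exactly ±250,000 are inside). Everything else with a prey
is a translocation. Whether proximal strand-flipped joinings belong in I or
T is not fixed by the method description; we count them in I because they
are rejoining events at the bait rather than captures of an independent
genome-wide break, which keeps the G/I/T arithmetic of the efficiency
formula consistent. Same-strand proximal preys upstream of the cut
(excision-like joinings) are counted as `large_deletion` as well.

The junction coordinate used for deduplication and hotspot counting is the
prey-proximal coordinate when a prey exists, and the end of the bait
alignment otherwise — hotspot counting must see prey positions, while
preyless molecules only need a stable signature.

## Deduplication model

Two calls are PCR copies of one molecule iff they share chromosome and
strand, their junction coordinates differ by at most 2 bp (alignment
jitter), and their barcodes are within edit distance 2 (Levenshtein by
default; Hamming available as a configuration switch since the barcodes are
fixed-length). Duplicate clusters are connected components of that link
graph; each cluster keeps the call carrying its most frequent barcode, ties
broken lexicographically. `N` in a barcode matches nothing, including
another `N` — an unread base carries no evidence of identity — but reads
with `N` in the barcode are kept, because discarding them would bias
molecule counts.

The positional condition is applied pairwise, not by chaining: germline and
small-indel molecules tile a contiguous range of junction coordinates, and
single-linkage chaining would put thousands of distinct molecules in one
comparison group, where 14-nt barcodes collide by the birthday effect
(about 860 of 4^14 barcode pairs are within Hamming distance 2). Known
limitation: molecules that genuinely share a junction signature and sit
within barcode distance 2 are merged regardless; at 10^4 molecules this
removes roughly 1% of germline molecules and is the dominant residual bias
of the pipeline — visible in the acceptance run, but inside the 99%
binomial band the acceptance criterion prescribes.

## The enrichment scan

The hotspot caller is a from-scratch local-Poisson scan that mirrors the
behaviour of a fragment-pile-up peak caller at the stated settings
(extension 50 bp, q ≤ 0.05, 10-Mb local background, bait ±250 kb excluded):

1. junctions within the exclusion zone are removed;
2. each junction is extended to 50 bp and overlapping extensions are merged
   into candidate regions;
3. a candidate with $k$ junctions and width $w$ is tested against
   $\lambda = \max(\text{genome-wide rate}, \text{local rate}) \cdot (w +
   \text{extsize})$, the local rate measured in a 10-Mb window centred on
   the candidate, clipped at chromosome ends, with the candidate's own
   junctions included — the conservative treatment-as-its-own-background
   convention;
4. $p = P(\text{Pois}(\lambda) \ge k)$, Benjamini–Hochberg across all
   candidates, keep $q \le 0.05$;
5. a candidate must contain at least 2 junctions: a single extended
   fragment never constitutes a pile-up, whatever its nominal p-value.
   Without this rule, any isolated junction on a sparse background would be
   "significant", which is a statement about the emptiness of the genome,
   not about enrichment.

Candidates are then screened for a cryptic target site: both strands of the
candidate ±500 bp are scanned for the 20-mer closest to the guide followed
by a 3-nt PAM. A site is accepted when mismatches ≤ 6 and either the PAM
matches NGG/NAG or the match is very close (mismatches ≤ 4) — the "highly
similar sequence and/or definite PAM" rule made concrete; both knobs are
exposed in `peak_params()`. The presumed cut sits between protospacer
positions 17 and 18 (3 bp 5′ of the PAM). Sites are merged across
replicates by overlap of their ±500 bp counting windows, and kept iff
supported by ≥ 2 replicates with ≥ 3 pooled junctions within ±500 bp of the
presumed cut. A two-sided exact binomial test on junction orientations is
reported as an annotation (`balance_p`), not enforced as a filter: genuine
cuts accumulate junctions in both orientations, but the method description
treats this as a characterisation, not a hard rule.

## What the simulator emulates — and what it does not

`sim_spec()` states the world the tests live in: 2 × 150 bp reads from
0.3–2 kb fragments, the primer 60–80 bp upstream of the cut (within the
200 bp the method requires — and close enough that the junction always
falls inside read 1, which is what makes the bundled single-end split
aligner sufficient), mean PCR duplication 3, per-base substitution error
0.002 applied independently per copy including inside the barcode, and an
outcome mixture with 60% germline and indels:translocations in the ratio
35.7 : 2.7 rescaled to fill the remainder. Small insertions are 1–10 bp and
deletions 1–15 bp (the ±20 bp scale of near-cut indel spectra); large
deletions decay exponentially (scale 1.2 kb, capped at 5 kb) with a
configurable resection tail placing a stated fraction (default 0.05%) of
editing events 5–50 kb downstream; inversions land within ±5 kb; background
translocation partners are uniform outside the exclusion zone. Off-target
junctions scatter around their cut with sd 15 bp — translocation junctions
concentrate tightly at the break — with balanced orientations.

Not emulated: quality-score structure (all bases Q40, so quality trimming
is exercised only by unit fixtures), GC and coverage bias, chimeric PCR
artifacts, microhomology-directed junction structure, and
chromatin-proximity weighting of translocation partners. A green end-to-end
test therefore establishes that the pipeline inverts its own generative
model at realistic noise levels — not that it is robust to every artifact
of real libraries. Real-data alignment is expected to come from an external
mapper via BAM import; the bundled aligner exists so the test suite never
shells out.

## Numerical and implementation choices

* Coordinates are 1-based inclusive internally — the R/Bioconductor
  convention used by every container this package touches; BED/BEDPE
  exports convert to the 0-based half-open convention of those formats.
* The toy aligner anchors read 1 at the primer, walks the bait reference
  until a window of 10 bases accumulates ≥ 5 mismatches, re-checks that the
  divergence is not alignment noise (in-frame continuation), then tries
  indel resynchronisation with the smallest shift first (deletions before
  insertions on ties, deletions to 18 bp, insertions to 12 bp); anything
  larger surfaces as a split alignment whose tail is seed-mapped
  genome-wide (20-mer exact seeds at offsets 0/20/40, unique placement
  required, ≤ 10% mismatches on verification). Deletions between the
  in-read limit and the proximal span therefore appear as `large_deletion`
  via the prey route — the subcategory boundary is the representation
  boundary.
* Barcode clustering is exact connected-components over bounded
  Levenshtein distances (banded DP with early exit, bit-packed Hamming and
  character-count prescreens in C++); no count-directional heuristics.
* Efficiency is clamped to [0, 1] with a warning rather than erroring when
  the control exceeds the sample — expected behaviour near zero editing.
* Reported frequencies follow the figure axes: raw fractions and
  per-100,000-editing-events values, with "editing events" = I + T.
* All randomness flows from a single integer seed per simulated library
  (sub-streams for genome, molecules, amplification), so identical specs
  give byte-identical FASTQ, and `run_pipeline()` writes its outputs with
  stable ordering and no timestamps, making reruns byte-identical.

## Known limitations

Barcode-collision merging (above) is the main residual bias. The aligner is
deliberately not a general mapper: it assumes a primer-anchored read 1 with
at most one structural event, and it will drop reads whose junction falls
within 20 bp of the read end. Hotspot recurrence requires per-replicate
junction tables; a single-library run relaxes the recurrence filter and
says so in its output. The T7EI inversion formula assumes completely random
re-annealing, and the clonal RFLP score assumes partially digested clones
have one or more edited alleles with equal chance; both are stated modelling
assumptions, not measurements.
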