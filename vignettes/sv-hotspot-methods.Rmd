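---
title: "Methods: simulating and calling rearrangements at an intronic hotspot"
author: "svhotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calling rearrangements at an intronic hotspot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the choices
behind them. The setting is a rearrangement hotspot in the first intron of a
tumor-suppressor gene: a few-kilobase region recurrently broken by somatic
deletions, inversions, reciprocal translocations and inverted insertions in
bone tumors, and by a germline inversion in a cancer-predisposition family.
Because the real specimens are not distributable, the package reconstructs
every analysis on seeded synthetic genomes with planted ground truth; all
quantitative statements below are the ones its test suite and
`scripts/acceptance.R` actually compute.

## Coordinates

All internal coordinates are 0-based half-open. The only conversions happen
at format boundaries: SAM positions (1-based) at ingest/emit, and the
junction-adjacent base convention described under *Pairwise event overlap*.

## The mate-pair library model

`library_model()` describes a long-fragment mate-pair (DNA paired-end tag)
library: genomic fragments of 1–4 kb (`frag_min`/`frag_max`), a tag
sequenced inward from each fragment end (`read_len`, 35 or 50 bp in the
emulated chemistries; default 50), and a per-base substitution error rate
(default 0; the reference simulations use 0.001). The fragment-size law is a
truncated normal (default mean 3000 bp, sd 300 bp) — the real protocol
specifies only the 1–4 kb range, so the law is a configurable modelling
choice, not a measured one. Same-strand mate-pair chemistry is supported as
an ingest flag that normalizes strands to the internal inward (FR)
convention, keeping the caller free of platform specifics.

`simulate_mate_pairs()` emits `ceiling(coverage * total_length / frag_mean)`
pairs — *physical* coverage, the number of fragments spanning a typical
base. The published protocol does not state per-tumor physical coverage;
the reference simulations use 15×, a value at which a junction is typically
supported by 10–20 pairs, comfortably above the calling threshold, while a
whole simulated tumor stays in the tens of thousands of pairs. True
alignments are reported in reference coordinates through each derivative's
block map; a tag that would cross a planted junction is reported unmapped,
as a short read failing end-to-end alignment would be. Consequently the
mapping region of a junction-flanking cluster ends strictly before the
junction, which the breakpoint estimator relies on.

## Planting junction mechanics exactly

`plant_sv()` realizes four event types with a `junction_policy()`:
micro-homology (a few bases identical between the joined flanks),
untemplated insertion, junctional duplication (the same reference segment
retained on *both* derivatives of a balanced event, as produced by fill-in
of long single-stranded overhangs — implemented by starting the second
derivative's segment `d` bases before the break), and net loss (bases
removed across a balanced junction). For reciprocal translocations
`duplication_len` may be a pair `c(dA, dB)`, since the two sides of a
balanced translocation can carry different duplication lengths (the
reference configuration uses 555 and 293 bp).

The junction analyzer is exact, so planting must be exact too: in random
sequence, a nominally blunt junction has probability ~1/4 per side of
extending a match by chance. `plant_sv()` therefore minimally edits the
reference bases immediately *beyond* each junction (never the junction
bases themselves) so that no accidental extension exists, and returns the
adjusted genome, which all downstream steps use. Micro-homology is planted
by copying the homologous stretch into the partner flank. This is what
makes the zero-tolerance policy-recovery property testable at all.

## The discordant-pair caller

*Insert model.* `estimate_library_stats()` takes the median and the raw
(unscaled) median absolute deviation of apparent inserts over
intra-chromosomal inward pairs; a pair is concordant within
`median ± k·MAD` (default `k = 5`; with MAD 0 the window is ±1 % of the
median). The raw MAD is used rather than R's 1.4826-scaled version so that
the concordance window is expressed directly in observed spread units.

*Clustering.* Discordant pairs sharing a chromosome pair and strand pattern
cluster by single linkage when both end regions are within `max_gap`
(default one fragment length, `median + k·MAD`): two pairs from one
junction can never be farther apart than one fragment. Single linkage by
transitive closure has a unique partition, so the result is deterministic
given sorted input; the suite checks it against an O(n²) brute-force
closure on random instances.

*Breakpoints.* For a cluster side whose tags point `+`, the junction lies
right of the mapping-region union; the predicted interval runs from that
proximal edge to `min(start) + insert_max − read_len`, the farthest a
junction can sit given that no concordant fragment exceeds `insert_max`. A
single-pair cluster therefore has interval width `insert_max − 2·read_len`,
and width shrinks monotonically with support. The *point* estimate is the
proximal edge plus a uniform-maximum correction, `range of member edges /
(n − 1)` — the standard correction for estimating the endpoint of a uniform
sample — pushed junction-ward. At 15× coverage this leaves a residual error
of roughly 100–250 bp per breakpoint (so ~0.2–0.4 kb on a span or donor
length built from two estimates), which is why span-level checks in the
suite use few-hundred-bp tolerances while junction-sequence checks are
exact.

*Typing.* A lone oversized-insert cluster is a DEL; `++`/`--` cluster pairs
flanking the same segment (breakpoints within `pairing_window`, default
5 kb) merge into a balanced INV whose span is the outer breakpoint
distance; reciprocal inter-chromosomal cluster pairs merge into a balanced
TRA; two inter-chromosomal clusters joining both ends of a donor segment
(B-side breakpoints more than `pairing_window` but at most `donor_ceiling`,
default 100 kb, apart) into one acceptor locus become an INS with the donor
length reported. Everything else is emitted UNCLASSIFIED rather than
dropped — the complex three-partner tumor in the reference set is exactly
the case where unmatched clusters carry the signal. `min_support` defaults
to 3: no published threshold is available, so it is explicit and logged in
the cluster census. Germline subtraction removes a tumor call when a normal
call of the same type has both breakpoints within `window` (default 2 kb).

## Targeted capture

`filter_target_pairs()` retains pairs with *exactly one* end overlapping
the target by ≥ 1 base (half-open, so an abutting end does not overlap).
One base is the simplest defensible anchoring rule given that the emulated
protocol states only that one read maps inside the region; the partition
counts (retained / both-in / both-out) are returned so the filter is
auditable. No repeat masking is applied at filter time — the real capture
deliberately included the repeat-rich intron — and low-quality mappings are
handled upstream by the ingest `mapq_floor` (default 10). Candidates are
ranked by cluster size, mirroring prioritization for PCR validation; no
hard size cutoff is imposed because none is published. Concordant pairs
straddling the target boundary are dropped before clustering when library
statistics are supplied, since they would otherwise pile up at the target
edges.

## Junction analysis

`analyze_junction()` finds the maximal prefix of the junction sequence
occurring in the locus-A flank and the maximal suffix occurring in the
locus-B flank (binary search over exact substring containment — equivalent
to, and tested against, the exhaustive split-point scan). Overlap of the
matched spans is micro-homology; a gap is untemplated insertion. Matching
is mismatch-free: junction sequence is assumed Sanger-grade, and sequencing
error is an upstream concern. Anchors shorter than `min_anchor` (default
20 bp) or anchoring ambiguously (the maximal match occurring more than once
in the locus, either orientation) abort the analysis explicitly — in a
repeat-rich intron a guessed anchor is worse than a refusal.

`analyze_balanced_pair()` anchors the two derivative junction windows in
each reference locus and intersects the covered intervals. The signed
shared length encodes the mechanism in one number: positive means the same
segment is on both derivatives (junctional duplication), negative is the
gap between the covered intervals (net loss), zero is blunt. Values within
`mh_scale` (default 10 bp) are classified micro-homology-scale rather than
duplication/net-loss, reflecting the qualitative gap between few-base
homology and the 46–555 bp fill-in signature; the threshold is a
configurable classification boundary, not a measurement tolerance — the
shared length itself is always exact. The analysis is symmetric in the two
derivatives.

*Pairwise event overlap.* When two events break in one locus, each event is
summarized by the coverage of the derivative retaining that locus, with the
breakpoint reported as the junction-adjacent retained base. Two blunt
junctions retaining `[.., E)` and `[S, ..)` with `E − S = 46` then have
spacing `(E−1) − S = 45` and shared length 46 — the only convention under
which a 45 bp breakpoint separation and a 46 bp shared stretch are
simultaneously coherent, and the one the reference configuration plants.

## Copy number and LOH

`segment_profile()` uses penalized least-squares binary segmentation with
an exhaustive single-split scan per recursion: a split is accepted when it
reduces the residual sum of squares by more than `penalty` (default 10× a
robust noise-variance estimate from first differences — scaled-MAD based,
so a clean two-level track still segments because the estimate is floored
rather than zero). The proprietary segmentation used on the real arrays is
not reproduced; the contract is boundary recovery, which the suite checks
against an independent recursive exhaustive oracle and a ±2-probe bound at
noise 0.1 on 1.0-log2 steps. `min_probes` defaults to 10; states use
±0.2 log2 thresholds, a conventional compromise robust to moderate tumor
content, declared rather than inferred from any publication. Boundaries
between same-state segments are emitted with class `none` so the tiling
stays complete.

Transitions inside the half-open gene window are classified by flanking
states only: neutral↔loss is *into-loss*, neutral↔gain *into-gain*, and a
direct loss↔gain *loss-to-gain*. The synthetic cohort
(`simulate_transition_cohort()`) plants one boundary per profile inside the
window with the observed 17/3/3 class mix, uniform boundary placement, 600
probes per profile at 1 kb spacing and noise 0.1 — enough probes that
boundary recovery is far inside the window margins.

`detect_loh()` calls LOH when the mean |BAF − 0.5| over ≥ 20 informative
SNPs exceeds 0.3, and copy-neutral LOH when the overlapping copy-number
state is neutral. Under the linear purity mixture of `simulate_baf()` the
deviation of an LOH region is `purity/2`, so 0.3 corresponds to calling LOH
down to 60 % tumor content; the 70 %-purity case (deviation 0.35) sits
deliberately just above the threshold.

## Reporting

`recurrence()` counts call junction ends (per contributing cluster side)
inside the window, so a balanced event whose two junctions both fall in the
window contributes two, and the three-tumor reference configuration yields
its seven window breakpoints. `breakapart_in_silico()` emulates the
two-color assay with BAC-sized default probe footprints (169/159 kb): a
translocation junction between the probes separates them, an inversion
separates them when exactly one junction lies between, a deletion only when
it removes a whole probe — and insertions or deletions confined to the gap
score negative, encoding the assay's limited resolution for small events.
Positivity additionally requires the carrying cell fraction to reach 10 %.
`cohort_frequency()` rounds to integer percent as screening frequencies are
conventionally reported, keeps raw fractions alongside, and reports
per-platform and pooled values separately — pooling across platforms with
different sensitivities is presented, not endorsed. `foldchange_ddcq()` is
the closed form `2^−((ΔCq_sample) − (ΔCq_control))`.

## Problem sizes and runtime

The reference simulations use 2–5 Mb genomes at 15× physical coverage
(roughly 10,000–25,000 pairs per tumor), 600-probe copy-number tracks and
500-SNP BAF tracks; junction analyses run on ~3 kb windows against ~6 kb
loci. These sizes keep every planted quantity comfortably recoverable —
junction support well above `min_support`, segmentation boundaries well
inside window margins — while a full test run and the acceptance script
each finish in a few minutes on one core.

## What passing tests do and do not show

The generator emulates fragment-size dispersion, substitution error,
multi-haplotype mixtures (clonal heterogeneity), junction micro-mechanics
and array noise. It does not emulate repeat-driven multi-mapping, coverage
bias, chimeric library artifacts, indel sequencing error, or capture
efficiency gradients; alignment itself is bypassed (true placements are
emitted directly). Recovery results therefore validate the *logic* of the
pipeline — clustering, geometry, typing, exact junction arithmetic,
segmentation — not robustness to alignment artifacts in real libraries.
Real-data use would additionally need the upstream filtering a production
aligner pipeline provides; the explicit `mapq_floor` marks where that
responsibility is handed over.
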