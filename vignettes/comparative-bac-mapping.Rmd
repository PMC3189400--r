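---
title: "Comparative BAC mapping with bacmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative BAC mapping with bacmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bacmap)
```

# Scope

`bacmap` implements the two classic routes to a whole-genome BAC map and
their use for comparative rearrangement analysis:

1. a *fingerprint-first* route — restriction fingerprints of clones are
   compared by a coincidence score and assembled into contigs, to which
   hybridization markers and BAC-end sequences (BES) are then attached;
2. a *reference-first* route — paired BES are aligned to a related,
   sequenced genome; clones placed by two consistent alignments are
   chained into comparative contigs, merged with independent fingerprint
   and hybridization evidence, and mined for discordance patterns that
   reveal inversions and fissions.

Everything is exercised against a built-in simulator, which is part of
the package's contract: the simulator plants rearrangements with a
base-exact lift-over, so every downstream call can be scored against
known truth.

# The coincidence score and its band model

Two clones that overlap share restriction fragments, which appear as
matching band sizes in their fingerprints.  `sulston_score()` quantifies
the evidence: given band counts $n_L \le n_H$ and $m$ bands matched
one-to-one within a tolerance $t$ over $G$ distinguishable band values,
the probability that at least $m$ matches arise by coincidence is modelled
as a binomial tail with per-band coincidence probability
$p = 1 - (1 - (2t+1)/G)^{n_H}$.  Lower scores mean stronger overlap
evidence; clones join a contig when their score is at or below the
cutoff.

**Band units.** Band sizes are stored as integers in *tenths of a base
pair* (`digest_params(size_scale = 10)`), the convention of
high-information-content capillary fingerprinting, where fragment sizing
is reported with sub-base-pair resolution.  The default tolerance of 7
therefore means 0.7 bp — of the same order as the 95% confidence interval
of capillary sizing error — and the default
$G = (500-35)\times 10 + 1 = 4651$ counts the distinguishable values in
the detectable 35–500 bp window.  This choice matters: with integer-bp
bands ($G = 466$) the per-band coincidence mass $(2t+1)/G$ is so large
that even identical 54-band fingerprints would score only about $10^{-4}$
and no contig could ever form at the conventional $10^{-8}$ cutoff.  At
tenth-of-a-bp resolution, identical fingerprints score below $10^{-20}$
and random pairs essentially never reach the cutoff, which is the regime
the field's assemblies actually operate in.

**The score is an approximation.**  The binomial model treats per-band
matches as independent and ignores both the one-to-one matching
constraint and window-edge effects.  A Monte-Carlo simulation of the real
matching process (`simulate_coincidence()`, used in the test suite)
shows systematic deviations of a few percent at small band counts.  This
is a known property of Sulston-type scores; the score is used as a
ranking/thresholding statistic, not as a calibrated p-value, and the
package keeps the field's standard form.

**Matching.**  `count_shared_bands()` pairs bands greedily over the two
sorted lists (advance the pointer at the smaller value, pair when within
$t$; ties resolved smallest-size-first).  On random 20-band lists the
greedy count equals the optimal bipartite matching in well over 99% of
instances and never exceeds it (property-tested against an independent
maximum-matching oracle).

# Fingerprint simulation

`digest_clone()` models end-labeled digestion: the sequence is cut at the
centre of every recognition-site occurrence of two labeled six-cutters
(defaults stand for BamHI and EcoRI) and a frequent four-cutter (standing
for HaeIII); a fragment becomes a detectable band iff at least one of its
ends is a labeled cut, and only sizes within 35–500 bp are kept.  Cutting
at the site centre makes digestion commute with reverse complementation
for palindromic motifs, a property the tests assert.  Sizing noise
(`add_sizing_noise()`) adds Normal error with `sizing_sd` (bp; default
0.2, a realistic capillary figure), rounds to integer sizing units and
re-filters the window.

**Base-composition calibration.**  Simulated genomes default to GC = 0.36.
With independent bases this reproduces the empirically observed density
of detectable bands for this enzyme combination (roughly 54 bands per
160-kb clone, squarely inside the 35–70 band design window); truly avian
GC (~0.42) over-produces frequent-cutter sites under an iid model because
real genomes cluster their motifs.  The calibration is a property of the
simulator, chosen once, not a tuning knob.

# Assembly passes

`build_contigs()` forms single-linkage components at the cutoff and
orders each component greedily: the best-scoring pair seeds the contig,
and each remaining clone is attached at the offset (in band units) that
best reproduces its observed shared-band counts with all placed clones.
This replaces the full FPC consensus-band optimizer; ordering quality is
asserted statistically (Spearman rank correlation with true clone
positions ≥ 0.95 at 10× coverage) rather than bit-for-bit.

The consensus is positional: walking members by offset, each clone's
bands are matched against the classes contributed by clones it overlaps;
unmatched bands open new classes.  The class count approximates the
number of distinct restriction fragments in the spanned region and drives
`estimate_physical_length()` (default 2.9 kb per consensus band;
`calibrate_kb_per_band()` recomputes mean-insert/mean-bands from the data
at hand).  Same-size fragment collisions make the estimate biased
slightly low — the calibration test allows 15%.  A member is flagged
questionable (Q) when fewer than `min_fit = 0.5` of its bands match
classes confirmed by at least two clones at its placement; the 0.5
threshold and the 10% Q-fraction trigger for DQ re-assembly are
configuration keys, as no published convention fixes them.

The remaining passes mirror standard practice: `dq_reassemble()`
re-clusters questionable contigs at stepped stringencies (1e−11…1e−09)
and keeps the smallest clean split; `end_merge()` joins contigs whose
terminal clones score within 1e−20…1e−07 *and* share at least 10 bands
(the conjunction stands in for the human "overall pattern supports the
merge" judgment); `incorporate_markers()` merges marker-linked contigs at
the relaxed 1e−08…1e−04 range, excluding probes that hit more than five
contigs as promiscuous; `add_singletons()` attaches singletons
(1e−20…1e−05) without ever merging contigs.  Clone conservation — every
validated clone in exactly one contig or the singleton pool — is asserted
across all passes.

# BES mapping and mate-pair consistency

`align_bes_reads()` is a deliberately simple seed-and-extend aligner for
synthetic-scale data: exact 16-mer seeds (five per read, both strands)
located by a dictionary match, ungapped full-read extension, acceptance
at ≥ 90% identity over ≥ 50 bp, hits on configured unplaced reference
names discarded as failed matches.  Uniqueness requires a single hit or a
best hit outscoring the runner-up by 1.2× (the margin is a configuration
default; published uniqueness rules do not state one).  An import path
for standard 12-column tabular alignments lets real aligner output
substitute seamlessly; the e-value threshold key is retained for that
mode.

`classify_mate_pair()` applies the consistency rule: both ends unique, one
chromosome, opposite strands, 10–400 kb apart, *facing inward*.  The
inward-facing requirement is implied by clone geometry rather than stated
in published rules and can be viewed as this package's assumption; it is
what makes same-strand and outward-facing patterns informative
signatures.  Single-end clones get library-default spans (200 kb for the
190-kb-insert library analog, 150 kb for the 160-kb one), clipped and
flagged at chromosome bounds.  Repetitive sides are resolved by exhaustive
combination search; exactly one consistent combination is adopted
(tan category), zero or several leave the clone unresolved.

# Comparative contigs and inversion calling

`anchor_bacs()` admits clones with two consistent placements (mate pair,
or unique BES plus an overgo hit inside the single-end span);
`build_comparative_contigs()` chains placements that overlap by ≥ 1 bp
(stricter chaining available via `min_overlap`); `merge_contigs()` bridges
gaps up to 2 Mb when terminal clones co-occur in a fingerprint contig or
share an overgo probe — the 2 Mb bound is a configurable stand-in for
merges that were judged manually in real projects.

Rearrangement detection uses two cooperating evidence channels:

* **Orientation segments** (`orientation_segments()`): anchored clones are
  scanned in test-genome order; segments break at reference-chromosome
  changes, orientation flips persisting for ≥ 2 clones, or reference gaps
  > 1 Mb; segments spanning < 50 kb are merged into neighbours and
  flagged.  A minus-orientation segment is the footprint of an inversion.
  The test-genome ordering comes from the simulator's clone truth table,
  standing in for the independent karyotype/genetic-map assignment a real
  project would have; it is never derived from the alignments under test.
* **Discordant clusters** (`cluster_discordant()`): inconsistent mate
  pairs grouped by signature (same-strand, distance violation,
  inter-chromosomal) and anchor proximity (50 kb single linkage, ≥ 3
  supporting clones).  An inversion produces a `++` cluster at its left
  breakpoint and a `--` cluster at its right one; pairing them localizes
  both breakpoints to within the clone spacing, which is why median
  breakpoint error lands far below one insert length at 10× coverage.

`call_inversions()` unifies overlapping candidates from both channels,
prefers cluster-pair breakpoints, sums cluster support, counts
dual-hybridizing probe BACs when hybridization data are supplied, and
flags single-channel calls low-confidence instead of dropping them.
Major events are those ≥ 100 kb (`count_major()`), and
`score_recovery()` declares a planted inversion recovered when both
called breakpoints fall within a tolerance of the truth (default: the
mean insert length, the natural localization scale of clone-based
evidence).

# The simulator: what it does and does not emulate

`simulate_reference()` draws iid bases (optionally with planted exact
repeat copies, logged in metadata, to exercise repetitive-hit handling);
`apply_rearrangements()` supports inversions, centric fissions, segmental
duplications and transpositions, maintaining a piecewise lift-over in
which every derived base maps to its reference origin and orientation
(duplicated copies carry a flag).  `sample_bac_library()` implements a
partial-digest model: clone ends sit on restriction-site occurrences and
insert lengths follow a Normal distribution truncated at mean ± 3 sd (the
truncation bounds are a package choice; real libraries' bounds are not
published).  `extract_bes()` yields inward-facing end reads with
independent substitution errors; `design_overgos()` places ~40 bp probes
at even spacing, enforcing genome-wide uniqueness on both strands;
`hybridize()` computes exact-containment hits with optional grade
downgrades and false positives.

Not emulated: chimeric clones, vector/background bands and off-scale
peaks (upstream wet-lab QC), quality-score chemistry, gapped alignment,
unassemblable heterochromatic repeats, and the redundant pooling
deconvolution of real overgo screens (probe-to-clone assignment is
direct).  Passing tests therefore certify the algorithms under clean,
known-truth conditions — motif statistics, repeat structure and artifact
modes of real genomes remain outside what the suite can show.

Planted inversions in the bundled scenarios are placed before any
length-changing event, so event intervals are already reference
coordinates; `score_recovery()` relies on this convention.

# Problem sizes and determinism

The default desk scenario (`desk_scenario()`) uses a two-chromosome
~10 Mb reference with inversions of 0.2, 0.5 and 2 Mb, two libraries
(190 ± 25 kb EcoRI-type at 340 clones; 160 ± 20 kb MboI-type at 390
clones, 3% empty) for ~12.7× clone coverage, 600 bp reads at 0.5% error
and 120 probes — sized so the full pipeline completes in minutes on one
CPU while every stage has enough signal to be meaningfully tested.
Simulation suites in the tests run 6–20 seeded replicates per property.

All randomness flows from a single configuration seed through fixed
per-stage derivations; `run_pipeline()` writes a manifest of stage hashes
and skips up-to-date stages on rerun, and repeated runs are byte-identical
(asserted in the tests).  Report tables are written 1-based inclusive
with a header note; BED files keep their native 0-based half-open
convention; rounding of report statistics is half-up at the printed
precision of conventional summary tables.

# Known limitations

* The coincidence score is an uncalibrated approximation (see above);
  cutoffs are operating points, not error rates.
* Consensus-band length estimation is biased a few percent low by
  same-size fragment collisions; recalibrate `kb_per_band` when absolute
  lengths matter.
* The aligner is ungapped and substitution-only; indel-rich data should
  use the external-alignment import path.
* Distinguishing two sequential inversions from centromere repositioning
  is out of scope; ambiguous cases should be reported as ranges.
* Centromere annotation is declarative: calls are marked
  centromere-adjacent only relative to positions supplied in the
  scenario configuration.
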