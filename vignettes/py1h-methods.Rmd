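---
title: "Methods: quantification and event calling for paired yeast one-hybrid screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification and event calling for paired yeast one-hybrid screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(py1h)
```

## The assay and what the package computes

A paired yeast one-hybrid (pY1H) screen asks whether two transcription
factors (TFs) influence one another's binding to a DNA-bait (typically a
promoter integrated upstream of *HIS3* and *lacZ* reporters). Each DNA-bait
is mated against a TF-pair strain and the two corresponding single-TF
strains; strains are pinned as 2 x 2 quadruplicates in a 1536-colony (32 x
48) array and photographed after X-gal readout. Cooperative binding shows up
as reporter activity in the pair strain that neither single shows;
antagonism as activity in a single-TF strain that the pair strain loses.

`py1h` implements the full computational chain around that comparison:
colony-array image quantification, reporter-signal scoring against
empty-empty controls, QC and event calling under the 1-AD and 2-AD designs,
plus the downstream statistics used to interpret a screen (PWM scanning with
exact p-values and core-motif merging, degree-preserving network
randomization, expression-specificity and co-expression scores, paralog
partner similarity, homology-based pair expansion, and sequencing-based
strain confirmation). A seeded synthetic-data module generates every input
with ground truth, so the whole chain is testable without external data.

## Image stage

`preprocess()` collapses the photograph to one channel and rescales to
[0, 1]; for real photographs of blue colonies on a light plate the
`invert` flag maps signal = 1 − luminance (the channel arithmetic is
configurable because cameras differ). `crop_plate()` thresholds at a fixed
value (default 0.1 of the rescaled range) and keeps the bounding box of the
foreground mask.

`detect_grid()` builds a binary colony mask — smoothing-based background
subtraction (Gaussian, sigma = 4 x expected colony radius), light smoothing
(sigma 1.5 px), then a threshold taken as the *smaller* of the Otsu cut and
a robust noise-scale cut (4 x the median absolute deviation of the
background). The two-cut rule matters: on dense bright plates Otsu is
correct and the MAD is inflated by colony signal, while on sparse plates
with mostly-weak colonies Otsu locks onto the few strong colonies and the
noise-scale cut keeps the weak ones. The mask is projected onto each axis,
peaks are found by zero-crossing analysis of the smoothed projection
gradient (moving-average window = half the expected spacing), and a strictly
equidistant 32 x 48 grid is fitted by least squares on integer-indexed
peaks, which extrapolates missing rows/columns. Fewer than `min_peaks`
(default 10) detected peaks per axis raises `no_grid_detected`.

`segment_colonies()` replaces the trained segmentation network of the
original pipeline with a classical, deterministic segmenter: per grid cell,
an Otsu threshold on a lightly smoothed copy, refined to the half-amplitude
midpoint between foreground and background means (this refinement makes
flat-top disk areas unbiased), largest connected component, hole filling,
and two guards (minimum area 9 px; minimum foreground-background contrast
0.02) that reject noise-only cells. Colonies touching across a cell border
are split at the boundary by construction. Equivalence with the original
tool's exact pixel output is not claimable — its fixed threshold value,
edge kernels and network weights are unpublished — so the contract here is
recovery of ground truth on rendered plates: grid centers within 1 px
(noise-free) or 2 px (default noise), areas within 10%, intensity rank
order preserved.

`measure_colonies()` returns, per grid position, the area `A` (label pixel
count) and intensity `I` = mean foreground pixel value minus the mean
cell-local background pixel value. Subtracting the local background mean is
our reading of "background-removed" intensity; it also cancels the smooth
plate-wide gradient locally, which otherwise biases strain comparisons by
plate position. Exactly 1536 measurements are always returned; absent
colonies are flagged `missing`.

## Reporter signal and indices

Per colony the score is `(I - I_min) * A`, where `I_min` is the minimum
intensity over all measurable colonies *on that plate* (the plate is the
imaging unit, so plate scope is the natural choice for both `I_min` and the
baseline). A strain's reporter signal is

    RS = aggregate[(I - I_min) * A over the quadruplicate]
         - mean[(I - I_min) * A over all empty-empty colonies]

The quadruplicate aggregate is the median by default (robust to one bad
colony, consistent with the 3-of-4 uniformity rule below); mean aggregation
is available and makes the empty-empty RS average exactly zero by
construction. The three indices are exact differences:
cooperativity = RS_pair − RS_TF1 − RS_TF2; antagonism 1 = RS_TF1 − RS_pair;
antagonism 2 = RS_TF2 − RS_pair.

## QC and event calling

The original screens sorted strains by index and called events by manual
curation. `py1h` replaces curation with explicit, configurable cutoffs: a
robust z-score of RS against the plate's empty-empty distribution
(`z = (RS - median) / MAD`), binned at z = 2 / 4 / 8 into very weak / weak /
moderate / strong. A series is `inconclusive` unless all its strains grew on
the mating-selection plate, have at least 3 of 4 uniform colonies
(uniformity = detected and per-colony value CV <= 0.5, with the CV
denominator floored at the plate's empty-colony scale so that near-zero
baseline strains are not spuriously flagged), are sequence-confirmed (when
that information is supplied), and are uncontaminated.

Event calling follows the assay logic exactly: cooperative = pair strain
moderate/strong with both singles at most weak; antagonistic = a single
moderate/strong with the pair at most weak (mutual if both singles active);
independent = pair and a single both active; none = nothing active. The
mapping is total over activity triples.

Under the 1-AD design with both reciprocal orientations tested, the
activity pattern (TF1-AD alone, TF1-AD + TF2, TF2-AD alone, TF2-AD + TF1)
is looked up in a mechanism-derived truth table distinguishing mutual
cooperativity, recruitment (either direction), sequestration (either TF),
competition, and independent binding. The competition rows deserve a note:
when both TFs bind alone and the pair strain retains activity in only one
orientation, the TF whose AD-tagged pair strain stays active is called the
competitor (winner), and the event maps to antagonism of the other TF. The
2-AD design can only distinguish mutual cooperativity (cooperative call)
and sequestration (antagonistic call); everything else is
indistinguishable. Patterns outside the table are `unclassified` and the
event is reported `inconclusive`.

## Motif analysis

PWMs with uniform 0.25 background are scanned by per-window sums of log2
odds on both strands; every window is evaluated (|s| − k + 1 per strand),
windows containing non-ACGT letters are skipped, and reverse-strand hits
are reported in forward coordinates (0-based, half-open). Log base 2 is
used throughout; since the p-value threshold is applied in probability
space the base cannot change hit sets. Zero probabilities are floored at
−20 bits of log-odds; scanner and p-value machinery share the floored
matrix.

P-values are exact: the null score distribution over all 4^k words is
computed by dynamic programming on a score grid discretized at 1e-4 bits
(configurable), and `P(Score >= s)` is read off the survival function. The
DP is validated against exhaustive enumeration for k <= 8. Float window
scores can drift from the integer grid by up to half a unit per position,
so queries within k grid units above the maximum attainable score are
treated as the maximum — without this, the consensus score of an
information-rich PWM can round to "unattainable".

PWMs whose maximum base probability is below 0.8 at *every* position are
dropped as low-specificity. The source rule ("all sites probabilities
< 0.8") is ambiguous between every-position and any-position readings; the
every-position reading is implemented as the less destructive one, and the
cutoff is a parameter.

Core-motif merging groups consecutive hits of one TF sharing at least 80%
of the shorter hit's nucleotides, takes the n-way intersection if it is
at least 4 nt, and otherwise falls back to (n−1)-member contiguous subsets
(longest intersection wins, leftmost on ties; excluded members re-enter as
their own groups). Because hits in *different* groups can still overlap by
less than 80%, a final left-to-right pass trims residual overlaps and drops
trimmed cores shorter than 4 nt — the original workflow resolved these by
manual review; the trim makes the non-overlap guarantee algorithmic.
TF-pair co-binding on a promoter is a pair of cores with edge-to-edge gap
<= 10 nt (overlap counts as gap 0).

## Network randomization and proportion tests

The screen network is bipartite: TF-pair nodes point at promoter nodes.
Randomization performs double-edge swaps that exchange the promoter
endpoints of two random edges; proposals that would duplicate an edge or
involve edges sharing an endpoint are rejected and retried. The stated
switch count (default 20,000) counts *successful* swaps — the source
leaves attempt-vs-success unstated — with a retry budget of 100 x the
target; degree sequences are preserved exactly by construction and verified
per network. The null is 10,000 such networks, each restarted from the
observed network; significance is the normal-theory Z of the observed
evidence overlap against the null sample, with a two-tailed p.

An edge counts as evidence-supported only when *both* member TFs have
evidence at that promoter under the chosen mode: ChIP peaks in any cell
line, in a shared cell line, with summits within 50 bp, or core motifs
anywhere / within 10 nt. The overlap of a randomized network depends only
on which (pair, promoter) cells are supported, so the evidence matrix is
precomputed once and each null network costs one indexed sum.

On a small network whose degree-preserving configuration space is
enumerable, the sampled null matches the exhaustive distribution. The test
fixture is a perfect matching (all degrees one) deliberately: there every
swap proposal between distinct edges is valid, the chain is symmetric, and
its stationary distribution is exactly uniform over the matchings. For
general degree sequences, counting successes (rather than attempts) weights
states slightly by their acceptance probability, so exact uniformity is not
guaranteed in theory — a known property of this randomization family, and
the reason the enumeration check uses the matching fixture.

The two-proportion comparison uses SE = sqrt(p(1−p)/n) per group and a
pooled-variance normal z by default (the source names no variant; unpooled
is a flag).

## Expression specificity and co-expression

Cluster-level expression is the sum of per-cell normalized expression over
a cluster's cells plus a pseudocount of 1 (empty clusters get the
pseudocount alone). The specificity score of a gene with cluster fractions
`f_c` is `sum_c f_c log2(C f_c)` = log2(C) − H(f) bits: 0 for identical
expression across all C clusters, log2(C) for expression confined to one
cluster (about 7.54 for C = 187). The implementation snaps exactly-uniform
rows to 0 and clamps to [0, log2 C] so the range invariant is exact in
floating point.

For co-expression, a gene is "expressed" in a cluster when its cpm there is
strictly above 10% of its maximum cpm across clusters — cpm computed from
the pseudocount-free sums; the pseudocount exists only to keep the entropy
well-defined. The Simpson index divides the co-expressed cluster count by
the expressed-cluster count of the more tissue-specific gene (the smaller
set; ties give the same value either way).

## Paralogs and homology expansion

Percent amino-acid identity comes from a global Needleman-Wunsch alignment
(BLOSUM62, affine gaps, gap open 10 / extend 0.5) as identical positions
over the alignment length including gap columns (denominator configurable
to the shorter sequence). The original analyses used a Clustal multiple
alignment for the homology step and pairwise BLOSUM62 for paralogs; both
are served by the same pairwise engine here — a documented divergence,
since multiple-alignment identities are not in general equal to pairwise
ones.

Homology expansion takes each known interacting pair (X, Y) and adds
(A, Y), (X, B), (A, B) for every A at or above the identity cutoff to X
and B to Y; in percentile mode the cutoff is the requested quantile of the
off-diagonal identity distribution. Only pairs tagged `known` act as seeds:
homology-derived pairs do not re-seed, which makes the expansion idempotent
(repeatedly expanding the output adds nothing). Partner-relationship
similarity builds, over the ordered shared partners of two paralogs, the
binary vector (per partner: any cooperative event, any antagonistic event)
and reports the Jaccard index; identity bins are <30% low, 30-50% (closed)
medium, >50% high.

## Strain confirmation from well sequencing

Alignment records survive filtering when they are primary, mapped, have an
alignment score at least 90% of the trimmed read length, and fewer than 5%
mismatches (strict). A well confirms an expected target when that target
has at least one surviving read and strictly more than every non-expected
target — a tie fails, reading "the gene with the most aligned reads"
(singular) as a strict maximum. Wells expecting two targets (a TF plus an
empty vector) evaluate each expected target against the non-expected ones
over the same surviving reads. A TF-pair series is sequence-confirmed when
all six checks hold: both TFs in the pair well, TF1 + the AD2u vector in
the TF1-empty well, TF2 + the pGADT7 vector in the TF2-empty well. The
observation that most wells have >90% on-target reads is not used as a
criterion.

## The synthetic-data module

The generators are first-class, tested code, and their defaults define the
study conditions for every end-to-end check.

Plates: colonies are flat-top disks (full amplitude to radius r, linear
1-px anti-aliased rim) on an equidistant grid — the flat-top model keeps
the true area well-defined as the half-amplitude pixel count. The default
radius is 4.7 px on a 14-px pitch; 4.7 rather than a half-integer because
a half-max contour at an exact lattice radius (e.g. 5.0) makes the area
ground truth depend on float tie-breaking. Background is a pedestal (0.1)
plus a low-order polynomial gradient (5% of the maximum amplitude) and
i.i.d. Gaussian pixel noise (sd 0.02) — enough structure to exercise
background handling without drowning the weakest colonies.

Screens: planted events draw amplitudes baseline 0.05, strong 0.85, and —
for the singles of "enhanced" cooperative events — 0.056, with lognormal
per-colony jitter (sdlog 0.05). The enhanced value is chosen so those
singles sit near robust-z 3, the middle of the weak band: that *is* the
semantics of enhanced binding (detectable activity alone, far stronger
with the partner). Each plate carries 84 empty-empty control strains spread
across the array; with a 100-event screen this fills the 384 blocks
exactly, and the control count matters because the empty median/MAD
estimate sets the z scale for every call. Strain blocks are spread evenly
across the plate, as pinned arrays are.

What the fixtures do not emulate: real agar texture, condensation and
reflections, camera color response, plate-edge growth effects, uneven
pinning volumes, or biological correlation structure between neighbouring
strains. Passing the end-to-end checks therefore demonstrates that the
algorithms recover a known signal model through the whole chain — not that
they match the original tool pixel-for-pixel on photographs.

Under these conditions the expected called-obligate fraction in a planted
90/10 obligate/enhanced cooperative screen is slightly below 0.9 (about
0.87-0.88): roughly 2-3% of baseline singles cross the z = 2 cutoff by
chance (counting an obligate event as enhanced-like) and a similar share of
enhanced singles falls outside the weak band. This is the honest behaviour
of hard thresholds replacing the original manual curation.

Problem sizes used by the test suite and the acceptance script: 1536-colony
plates (one to two per screen check), 100-event screens, 1,000-row entropy
checks over 187 clusters, k <= 8 exhaustive PWM enumerations, 10,000
randomizations of ~300-edge networks at 20,000 switches each, and 50-run
calibration sweeps at reduced null sizes. These are the package's chosen
benchmark sizes; all complete on a single CPU in minutes.

## Known limitations

* The image stage is a classical substitute for a trained segmenter;
  heavily touching or highly irregular colonies will be split at cell
  boundaries rather than by shape.
* Activity quantization depends on the plate's empty-empty sample; plates
  with few controls give noisy z-scales (the generator default of 84
  controls reflects this).
* Cross-plate normalization beyond the per-plate empty baseline is out of
  scope, as is absolute calibration of RS to enzyme units.
* The (n−1) fallback in core-motif merging explores contiguous subsets
  only; pathological nested hit sets could in principle admit a wider
  non-contiguous intersection.
* Reconciliation of conflicting reciprocal-orientation calls beyond the
  truth table (e.g. noisy patterns) is reported as `unclassified` /
  `inconclusive` rather than resolved.
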