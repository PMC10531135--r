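---
title: "Simulating nanopore metabarcoding long reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nanopore metabarcoding long reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoampsim)
```

This vignette is the package's own account of its models: what is simulated,
which knobs exist and why their defaults are what they are, the numerical
choices that make results reproducible, and what the simulation does *not*
capture.

## What is being modelled

Nanopore sequencing of a full-length marker gene (16S rRNA and relatives)
produces reads with three salient properties that a useful simulator must
reproduce:

* a broad **per-read error rate** distribution — reads from one run vary
  from a few percent to over 20% error;
* an error composition dominated by **indels inside homopolymer runs**,
  with a reproducible insertion/deletion/substitution balance;
* a **multi-modal read-length distribution**: a tight Gaussian peak near the
  amplicon length, a shoulder of reads carrying one long internal deletion,
  a tail of short fragments, and rare over-long reads.

`simulate_reads()` composes three independent stages (error rate → edit
injection → length reshaping) over error-free community amplicons, and the
trainer estimates each stage's parameters from a SAM alignment of real
reads.

## The per-read error-rate law

The error rate $r$ (percent of read length) follows the exponentiated
Weibull distribution
$$F(x) = \left[1 - e^{-((x-\mathrm{loc})/\mathrm{scale})^{\kappa}}\right]^{\alpha},
\qquad x \ge \mathrm{loc},$$
with two shape parameters ($\alpha$, $\kappa$), a location and a scale,
all rate-type quantities in percent. The two shapes make the law flexible
enough to capture both the sharp lower edge (few nearly error-free reads)
and the long upper tail seen in real identity histograms. Draws are made by
inverse-CDF transformation of uniform variates and **clipped to
[0, 100]**: a fitted distribution can place small mass at unphysical rates,
and clipping (rather than rejection) keeps the draw count exact and the
stream deterministic.

`default_error_model()` is `exp_weibull_params(a = 1.3, c = 2.2, loc = 5,
scale = 9.7)`, chosen once to give a mean per-read error rate of ≈14.5%
with bulk mass between 8% and 20% — typical of an R9.4.1 flowcell 16S run.
Anyone simulating a specific instrument configuration should train instead
(`train_model()`).

Each drawn rate is split deterministically into the three error types as
$(r\,p_{ins},\, r\,p_{del},\, r\,p_{sub})$; the default split is
$(0.28, 0.42, 0.30)$, representative of current-chemistry nanopore 16S
runs. Keeping the split deterministic at the profile level (randomness
enters only through $r$ and through placement) means a profile file fully
determines the expected composition; the integer edit counts are realized
later as $k = \mathrm{round}(L \cdot \mathrm{pct}/100)$ per type, so
sub-0.5 remainders are dropped rather than dithered — reproducible at the
cost of a negligible downward bias for very short reads.

## Error injection

Indels are placed first, one event at a time. Each event selects a
homopolymer run with probability proportional to
$\mathrm{length}^{w}$ (default $w = 1$), recomputing weights as runs grow
and shrink. A deletion removes one base of the chosen run; an insertion
duplicates the run's base inside it — the classic homopolymer-miscount
signature, rather than a uniform random base. Linear weighting is the
mildest bias consistent with indels concentrating in longer homopolymers;
the exponent is exposed (`run_weight_exponent`) so stronger bias (or none,
$w = 0$) can be explored. Substitutions are drawn after the indels, at
distinct uniform positions of the current sequence, each base replaced by
one of the other three; they may hit inserted bases (the simplest position
model). The substitution count is capped at the current read length; a
deletion count reaching the read length is an error (the read would
vanish).

Every edit is recorded in an ordered log whose sequential replay reproduces
the output exactly (`replay_edits()`, `verify_edit_counts()`); positions
are 1-based in the sequence as it stands when the edit applies. The log is
what allows the training loop to be tested without an external aligner.

The injection inner loop is implemented in C++ (a run-length encoded
sequence; deletions and insertions only change run lengths, with merging
when a run empties), drawing from R's RNG so that `set.seed()` governs the
whole pipeline.

## Read-length categories

Six categories, with the mixture given as six integer percentages in the
order (gauss, longDel, longRead, short, veryShort, secondGauss), default
$(67, 21, 1, 9, 2, 0)$:

| category | law | notes |
|---|---|---|
| gauss | $T \sim N(1500, 30)$, rounded | the main amplicon peak |
| secondGauss | $T \sim N(1100, 30)$ | secondary peak seen in some runs |
| longDel | delete $D \sim 50 + \mathrm{Exp}(150)$ contiguous internal bases | final length constrained to (1000, 1450) |
| longRead | $T \sim 1601 + \mathrm{Exp}(200)$ | rare over-long reads |
| short | $T \sim U\{200, \dots, 999\}$ | fragments |
| veryShort | $T \sim U\{20, \dots, 199\}$ | lower bound 20 avoids zero-length reads that break SAM tooling |

Two deliberate choices:

* **The Gaussians are not truncated** to the 1450–1600 (or second-peak)
  range. The ranges describe where such reads fall and drive
  classification during training; truncating the sampling law would bias
  the realized mean and SD away from their nominal (1500, 30). The
  consequence — a known ≈4.6% of Gauss-category reads falling below
  1450 bp — is handled on the training side (below).
* When the drawn target exceeds the current read length the read is
  **padded** (default: uniform random bases; `duplicate-tail` repeats the
  read's own tail), and when shorter it is **truncated at the 3' end**,
  the sequencing-order interpretation of an early pore exit. How real
  over-length reads arise is not observable from length data alone, so the
  strategy is a flag rather than a claim.

The longDel deletion-size law is exponential with offset 50 and scale
150 bases: the offset encodes that the phenomenon is a *long* deletion
(dozens of bases minimum) and the scale puts typical final lengths
mid-range (~1300 bp). $D$ is resampled (up to 100 tries, then forced) until
the final length lands in (1000, 1450); inputs of ≤1001 bp cannot host such
a deletion and are relabelled veryShort/short by their current length, with
a warning, rather than silently reshaped.

Random reads (`-r` percent, `generate_random_reads()`) are uniform ACGT
with lengths drawn through the same category mixture (the longDel law
acting on a nominal 1500-base template); they model library noise that maps
nowhere.

## Training

Given alignment summaries (from `parse_sam()` or, aligner-free, from the
simulator's own annotations via `alignments_from_annotations()`):

* the **split** pools insertion, deletion and mismatch base counts over
  mapped reads and normalizes;
* the **identity histogram** (default 1000 bins over [0, 100]) feeds the
  exponentiated Weibull fit: the error sample is reconstructed as
  100 − bin centre, weighted by count, a deliberate bias of at most half a
  bin width (0.05 points at 1000 bins);
* the four parameters are estimated by **maximum likelihood** (L-BFGS-B on
  log-transformed shapes and scale, location box-constrained to
  [0, min(sample)], a small multi-start grid). A fit whose mean deviates
  from the sample mean by more than 5% is rejected with an error rather
  than returned silently; a degenerate sample (all mass in one bin) yields
  a near-degenerate law that preserves the mean;
* **length percentages** classify read lengths by the category boundaries
  and convert to integers summing to exactly 100 by largest-remainder
  rounding. The secondGauss share cannot be identified from lengths alone
  (its range lies inside the longDel range) and is supplied by the user,
  carved out of longDel.

Two corrections make the train→simulate loop a fixed point, and both are
exposed as arguments:

* **Insertion inflation** (`correct_ins_inflation`, default on in
  `train_model()`): identity-derived error rates have alignment columns
  (read length + insertions) in the denominator, while the injector
  consumes rates as percent of read length. Fitting the raw values would
  compress the mean by ≈0.3–0.6 points at nanopore-typical rates; the
  trainer converts via $r = e / (1 - p_{ins}\, e / 100)$ before fitting,
  so a model trained on real data reproduces that data's alignment error
  rate when simulated.
* **Gaussian spill-over deconvolution** (`deconvolve_gauss`, default on in
  `train_model()`, off in the raw classifier): since the Gauss law is
  untruncated, a fixed fraction ($\Phi((1449.5-1500)/30) \approx 4.6\%$)
  of Gauss reads is classified longDel by length. The trainer inverts this
  known mixing so that simulating with the trained percentages reproduces
  the observed length-class composition; without it the round trip loses
  ~3 points from the Gauss share at the default mixture.

## The fixture generator

`generate_references()` mutates one random ancestor independently per taxon
at a per-site substitution fraction (default 5%, kept below a 97% pairwise
identity ceiling so species remain distinguishable), and
`generate_amplicons()` draws taxa i.i.d. from the abundance profile,
emitting each read as the full, unmutated reference — community amplicon
sequencing with length bias, copy bias and truncation all disabled.
`mock_community_profile()` provides eight-species abundance sets matching
the composition of a standard bacterial mock community as measured in real
runs.

What the fixtures deliberately do **not** emulate: PCR chimeras, primer
mismatch and amplification bias, rRNA copy-number variation, real 16S
conserved/variable architecture, or quality-score structure (the simulator
writes one fixed phred value, default 8, as real downstream tools expect
for nanopore amplicon data). Tests passing on these fixtures therefore
validate the simulator's own laws and the training loop's consistency — not
classifier accuracy on real biology.

## Numerical and reproducibility choices

* Every stochastic function takes a `seed`; `simulate_reads()` derives
  deterministic per-stage sub-seeds from it, so a stage rerun in isolation
  with the same sub-seed agrees with the end-to-end run. Seeds are kept in
  32-bit range.
* Profile files are comma-separated, 4 decimal places, one read per line in
  input order; round-trips are exact to the written precision.
* Title-line annotations use space-separated `key=value` tokens
  (`nbIns`, `nbDel`, `nbSub`, `cat`, optional `taxon`) — greppable and
  unambiguous to parse.
* Mismatch counts from SAM prefer `NM − I − D`; when an `MD` tag disagrees,
  MD wins and one warning reports the conflict count. Clipped bases are not
  aligned columns and never enter error accounting.
* Read-stat SDs are population SDs by default (a flag switches to sample
  SD); species assignment takes the primary alignment's target, first
  occurrence on ties.
* Test and validation problem sizes are chosen so that multinomial/moment
  checks run at three-standard-error tolerances: $10^5$ reads for mixture
  fractions and error-type shares, $5\times 10^4$ for length moments and
  the training round trip, $10^3$–$10^4$ randomized cases for replay,
  edit-distance and uniformity properties.

## Known limitations

* Errors are context-independent beyond the homopolymer-length bias: no
  k-mer model, no strand asymmetry, no quality-aware placement.
* The exponentiated Weibull is fitted to binned identities; distributions
  with structure finer than 0.1 identity points are smoothed over.
* The secondGauss category is not identifiable from lengths and relies on
  user input during training.
* Random-read lengths reuse the main category mixture; truly noisy runs may
  have a different junk-length law.
* The package never runs an aligner; evaluation against real references
  consumes externally produced SAM/BAM.
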