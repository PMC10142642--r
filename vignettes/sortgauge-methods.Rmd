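---
title: "Quantifying particle-sorter performance by flow cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying particle-sorter performance by flow cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortgauge)
```

## The problem

Continuous-flow microfluidic sorters (inertial spirals, zigzag channels and
similar devices) split a particle or cell suspension into an inner (target)
outlet and an outer (waste) outlet, typically to enrich rare large cells
such as circulating tumour cells (CTCs) and CTC clusters out of blood.
Validating such a device requires knowing, for every particle type and for
single particles versus clusters, what fraction ended up in the target
outlet (Separation Efficiency, SE) and how contaminated the target fraction
is (Purity, P). Flow cytometry answers both at once when three pieces of
protocol are in place:

1. every population of interest can be gated cleanly in some channel
   combination,
2. pulse processing (area vs height of the scatter pulse) splits each
   gated population into singlets and doublets/clusters, and
3. counting beads spiked in equal quantity into equal-volume collection
   tubes convert per-file event counts into volume-comparable counts, even
   on cytometers without volumetric acquisition.

`sortgauge` implements the full analysis chain and, because no public
event files accompany the protocol, a synthetic-data generator that
emulates the validation samples with known ground truth, so that every
stage of the pipeline is testable end to end.

## The data model

Events are rows of an eight-channel table: FSC-A/H and SSC-A/H (scatter
pulse area and height), and the fluorescence channels B530, YG610, B610
and R670. Each population is a log-normal model per channel, parameterised
by median and CV. Two structural choices matter:

* **Scatter scales with size.** FSC and SSC medians are proportional to
  diameter², with population CVs (default 0.35) wide enough that adjacent
  bead sizes overlap in scatter alone. This mirrors the practical
  observation that forward scatter orders the bead sizes but cannot
  separate them, which is why the shipped gating strategies resolve size
  through fluorescence.
* **Pulse heights ride on areas.** FSC-H is drawn as FSC-A times a tight
  log-normal pulse-shape factor (CV 0.05), so the per-event area/height
  ratio is sharply concentrated near 1 for single particles. A
  two-particle cluster reuses a singlet draw with all pulse-area channels
  scaled ×2 (twice the integrated signal) and pulse-height channels ×1.2
  (the pulse elongates more than it grows in amplitude). Both scales are
  per-population parameters; the defaults make the cluster ratio
  2/1.2 ≈ 1.67, well separated from 1 at CV 0.05. Only the separation of
  the two ratio modes — not the particular constants — is load-bearing for
  doublet discrimination.

Cluster prevalence is not reported for any of the validation samples; the
generator defaults to `doublet_fraction = 0.05` per population, exposed as
configuration. Clusters larger than two particles are not simulated, and
the classifier deliberately folds anything above the ratio threshold into
one "doublet" class, matching how doublets/clusters are treated as a
single category downstream.

The virtual sorter is purely probabilistic: a `device_scenario` maps each
(population, cluster class) to a probability `p_inner` of exiting through
the inner outlet, and splits the collected volume as
(`f_inner`, `1 − f_inner`) with `f_inner = 1/3` by default, matching the
~33% central collection of the characterised devices. No fluid dynamics is
modeled; the scenario probabilities *are* the ground truth that the
pipeline must recover. The shipped flow-rate fixtures (0.6–1.0 mL/min)
anchor the probabilities that were measured on the characterised zigzag
device — 50.7%/24.7% for 15 µm singlets/doublets at 0.7 mL/min,
46.3%/54.5% for 10 µm singlets/doublets at 0.9 mL/min, near-100% capture
of 20 µm beads from 0.7 mL/min upward, >98% capture of 15 µm singlets at
0.8 mL/min and above — and fill the unmeasured entries with constants
chosen once to follow the titration's shape (small particles increasingly
co-captured as flow rate rises; nothing large focused at 0.6 mL/min).

Counting-bead spike-ins are Poisson-distributed around
`accudrop_per_tube` (default 50,000, a typical counting-bead spike
density), appended after sorting, and each tube is then thinned
independently at its `acquired_fraction` to emulate recording only part
of a tube. All randomness derives from one run seed through fixed
per-stage tags (`derive_seed`), so stages are reproducible in isolation
and a manifest re-run is byte-identical.

## Gating

Gates are rectangles or simple polygons on a channel pair, with linear or
log10 axes; region coordinates are stored in raw units. Three numerical
conventions are fixed and tested:

* boundary points are members (deterministic tie-break; point-in-polygon
  uses the even-odd rule with an explicit on-edge test),
* on a log axis, events with values ≤ 0 fall outside every gate on that
  axis and are counted rather than dropped,
* events reaching no leaf, or more than one leaf, are reported
  (`validate_tree`), never silently discarded.

The shipped bead strategy follows the hierarchy used for the five-bead
validation mixture: counting beads split off first on high B610; among
sizing beads, the low-B530 pair (3 µm, 7 µm) is resolved on YG610 —
needed precisely because 3 µm doublets overlap 7 µm singlets in B530 —
and the high-B530 sizes 10/15/20 µm are resolved on B530 vs FSC. The
blood strategy splits counting beads on B610, WBCs on R670 (CD45-APC),
then unstained blood cells (RBC leaf) from fluorescent sizing beads on
B530. Gate coordinates are fixture constants tuned once against the
default simulator signal models and versioned together with them; the
recovery/contamination thresholds asserted in the tests (≥95% recovery,
≤2% contamination per leaf) are properties of this simulator + strategy
pair, not claims about any physical instrument.

Within each labeled leaf, singlet/doublet classification thresholds the
FSC area/height ratio. By default the threshold is placed per population
at the density valley between the two dominant modes of the log-ratio
distribution; when no credible second mode exists (fewer than 50 events,
secondary peak under 1% of the main peak, or no valley below half the
smaller peak) it falls back to the geometric midpoint of the singlet and
default doublet ratios, √(2/1.2) ≈ 1.29. Events with non-positive pulse
height are "unclassifiable" and appear in `total` counts only.

## Quantification

With equal spikes into equal-volume tubes, recorded counting-bead numbers
are proportional to the acquired volume of each file. Two correction
conventions are implemented because the protocol's worked example and its
stated goal pull in opposite directions. In the worked example, 10,000
beads recorded in the inner tube against 5,000 in the outer (reference)
tube leads to *doubling* the inner counts — that is `paper_literal` mode,
factor `A_j / A_ref`. Scaling counts to a common acquired volume actually
requires the reciprocal, factor `A_ref / A_j`, which is the
`volume_consistent` default: the tube that recorded twice the counting
beads had twice the volume acquired, so its counts are halved relative to
the reference. Both modes are tested; with equal recorded counts they
coincide (all factors 1). Which of the two the protocol intended cannot be
resolved from its text, so neither is guessed away; the choice is a flag.

Separation Efficiency for population *i* and cluster class *c*, with
corrected counts *n*:

SE = 100 · n(target) / (n(target) + n(other)),

computed with corrected counts in both terms (the reference outlet's
factor is 1, so this is identical to correcting only the non-reference
term). Purity defaults to the percent-of-total convention — the
population's share of all gated sample events in the target outlet, which
sums to 100 across populations — with the literal target/non-target count
ratio available as `definition = "ratio"`. Counting beads are excluded
from the purity denominator by default: they are an added reagent, not
sample. Undefined metrics (population absent from both outlets, empty
target outlet) propagate as `NA`, never 0, so the absence of a rare
population is distinguishable from its perfect depletion.

The collection-ratio QC flags runs whose inner volume fraction deviates
from the expected 1/3 by more than 0.05 (both configurable); replicate
aggregation excludes QC-failed runs, lists them, and reports per-metric
mean and sample SD.

## What the simulations show — and what they cannot

Problem sizes were chosen so the default suite runs comfortably on a
laptop core: the parameter-recovery experiments simulate ~26,000 objects
of one bead size (≈20,800 singlets and ≈5,200 doublets at
`doublet_fraction = 0.2`) plus 2 × 50,000 counting beads, the mixture
fixtures run at 2–10 µL of the recipe (≈10⁴–5×10⁴ events), the blood
fixture at ~10⁵ events, and the unbiasedness property runs 50 seeds of a
small two-population scenario. At these sizes the pipeline estimates of
SE land within three binomial standard errors of the configured capture
probabilities, and the 50-seed mean error is within three standard errors
of zero.

Passing these tests shows that gating, pulse-processing classification,
spike-in normalization and the metric algebra are mutually consistent and
unbiased *under the generator's assumptions*: log-normal, spillover-free
channels; independent per-event routing; exactly two-particle clusters;
counting beads that gate perfectly. Real instruments add spectral
spillover and compensation, debris and platelets, cluster-size mixtures,
drift, and carryover — none of which are modeled, which is why gate
coordinates shipped here should be re-tuned on single-stain controls
before the strategies are applied to real FCS exports.

## File formats

The FCS writer emits the minimal dialect the protocol requires: one FCS
3.0 dataset, list mode, 32-bit little-endian floats, with `$PnN` channel
names and 0-based segment offsets; the reader accepts FCS 3.x float files
and rejects integer/double dialects, `$TOT` mismatches and corrupt
headers with distinct diagnostics. Round trips are exact at 32-bit
precision. A TSV dialect (header row of channel names) round-trips at
full double precision and yields SE values identical to the FCS path to
at least six significant figures on a fixed-seed simulation. Ground-truth
labels travel only in row-aligned sidecar TSVs, never inside the FCS
payload. Gating strategies, population sets and device scenarios use this
package's own documented YAML schemas (a gating interchange standard
would add weight without value here), with fixtures shipped under
`inst/extdata/`.
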