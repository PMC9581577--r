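---
title: "Methods: MEA spheroid-network analysis in spheromea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA spheroid-network analysis in spheromea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spheromea` quantifies the development of electrical activity in human
iPSC-derived neuron/astrocyte co-cultures on 60-channel microelectrode
arrays, and the cell-cluster ("spheroid network") morphology those cultures
develop. This vignette documents the models and procedures, every tunable
that matters, the numerical choices made where the method leaves room, what
the synthetic-data generators do and do not emulate, and the known
limitations. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## Data model and conventions

A recording is 59 voltage traces (µV) on the standard 8 × 8-minus-corners
grid (30 µm electrode radius, 200 µm pitch, one internal reference), sampled
at 32 kHz for 10 min by default. One convention is used everywhere: voltage
in µV, time in seconds, 0-based from recording start. The HDF5 container
stores one dataset per channel with `sample_rate` and `conversion_uV`
attributes and an embedded JSON document for layout and culture metadata;
the amplifier's conversion to physical units is not part of the method, so
µV-by-convention is fixed at read time and converters are applied there,
never downstream.

## Spike detection

Traces are band-pass filtered with a second-order Butterworth (250–3000 Hz)
to remove slow field potentials, mains noise and high-frequency noise. The
filter is applied forward–backward (zero phase), so detected peak times are
not phase-shifted; the squared magnitude response doubles the effective
roll-off, which is documented rather than compensated.

Background noise is estimated per electrode as σ = median(|x|)/0.6745, the
Gaussian-consistent robust scale. The choice matters: spikes riding on the
noise inflate a plain SD but barely move the median of absolute amplitude,
so thresholds stay stable as activity grows. The detection threshold is
double-sided at ±kσ with k = 5; either polarity triggers, and each
supra-threshold excursion is aligned to its absolute-amplitude extremum.
Two constants the detection step needs but the method itself does not pin
down are set to bracket extracellular spike widths at 32 kHz: a 1 ms dead
time between events, and a −1/+2 ms waveform window around the extremum.
Events whose window would leave the trace are dropped. A zero σ (constant
trace) makes the threshold undefined, so detection refuses it explicitly
rather than returning an empty result. The threshold is applied per whole
trace, not per sliding window.

## Spike sorting and unit-count selection

Waveforms are mean-centred and projected onto their top two principal
components; two suffice because units that are separable at all on one
electrode differ grossly in shape (dominant polarity, width). For
k = 1…k\_max (default 6) k-means is run with k-means++ seeding and 10
restarts under a fixed seed, recording the mean within-cluster radius
r(k) — the membership-weighted mean distance of points to their centroid,
equivalently the grand mean over events.

Splitting one homogeneous cloud makes log r(k) decrease roughly linearly in
log k; genuine multi-unit structure pulls r(k) *below* that line at the true
count. The knee rule therefore fits log r(k) on log k by least squares and
chooses the k with the most negative residual, subject to two guards:

- the k−1 → k relative radius drop must exceed 20 % (`min_drop`), and
- the residual must be at least 0.15 log units below the fit (`min_resid`).

The second guard is this package's addition, and it is load-bearing. A
single *realistic* waveform cluster is not isotropic — per-spike amplitude
jitter stretches it along the template direction — and splitting such a
cloud already drops the radius by ~30 %, so the drop criterion alone
over-splits. The residual of that split stays an order of magnitude smaller
(≲0.06 log units in our synthetic checks) than the residual at the true k
of a genuinely multi-unit electrode (≈0.4–0.6), so a 0.15 margin separates
the two regimes with headroom on both sides. Fewer than two events skip
sorting (all events become unit 1); duplicated points give r(1) = 0 and one
unit. Units are renumbered by time of first spike so labels are
deterministic; tests additionally match labels up to permutation.

## Burst detection (adaptive log-ISI)

Interspike intervals are binned in base-10 log histograms — 10 bins per
decade over [1 ms, 100 s], ISIs outside clipped into the end bins, values
landing numerically on a bin edge snapped at 1e−9 so binning is
deterministic. Units with fewer than three spikes have no usable histogram
and are treated as non-bursting.

Bimodality is certified on the lightly smoothed histogram (3-bin moving
average): for a peak pair whose first peak lies below 100 ms (the
intra-burst regime), the valley between them qualifies when its void
parameter, 1 − h_valley/√(h₁h₂), is at least 0.7. Among qualifying pairs the
one with the largest void wins and the threshold is the ISI at the deepest
bin between them (first bin on ties). Without a qualifying pair the
threshold falls back to 0.1 s. Both constants (void ≥ 0.7, intra-burst peak
< 100 ms) are surfaced in the configuration.

Candidate bursts are maximal runs of consecutive spikes with ISI ≤
threshold. Two exclusions apply: bursts with fewer than max(3, ⌈N/3000⌉)
spikes are dropped (N = the unit's total spikes; ⌈·⌉ because the rule is a
floor and fractional spikes do not exist), and when the threshold came from
a valley above 0.1 s, only candidates that fully enclose at least one burst
*accepted* by the 0.1 s detector survive. The enclosure reference could
alternatively be read as the 0.1 s detector's raw runs before the size
floor; we apply the floor, i.e. the reference must itself be a detectable
burst, and use the same definition in the brute-force oracle the tests
compare against. Burst intervals are closed [first spike, last spike].
Burstiness is the unit's in-burst spike fraction; a unit with no spikes has
no defined burstiness and is excluded from aggregates.

## Network bursts

A uniform series counts, at each sample, the units whose burst interval
covers it. The construction nominally has one element per raw sample; we
build it at Δt = 1 ms instead, which carries identical intervals — burst
edges are spike times, orders of magnitude coarser than 1 ms — at 1/32000th
of the memory. The detection threshold is one-third of the mean of all
samples at or above the 90th percentile of this series. Candidate network
bursts are maximal runs with counts ≥ max(threshold, 1); the floor of 1
keeps a zero threshold (silent array) from labelling silence. A candidate's
spike count totals *all* units' spikes inside the interval (the exclusion
rule does not restrict to bursting spikes), and candidates with fewer than
max(10, ⌈N_bursting/300⌉) spikes are dropped, N_bursting being the array's
total bursting spikes. NB duration is the span of the supra-threshold run,
not of the enclosed bursts; whether member bursts' tails outside the run
should extend the boundary is left as-is since the method's description
does not say so. Network burstiness is a unit's spike fraction inside any
NB interval.

## Activity metrics

An active unit fires strictly more than 10 spikes/min; the mean firing rate
averages spikes/s over active units only. Entropy is Shannon's
−Σ pᵢ ln pᵢ over the occupied bins of the normalized log-ISI histogram
(0·ln 0 ≡ 0). The natural logarithm is used — the method's statement of the
formula does not fix a base, and the base only rescales — so values are in
nats, bounded by ln N for an N-bin histogram.

For correlation, each active unit with ≥2 spikes becomes a piecewise-
constant instantaneous-rate signal: 1/ISI filled across each interspike
span, the first/last interval's value extended to the recording edges (any
constant fill would inject spurious correlation at the edges), log₁₀, then
evaluated directly on a 320 Hz grid. Building directly on the grid is
mathematically identical to constructing at 32 kHz and decimating, for a
piecewise-constant signal, and far cheaper. Pairwise zero-lag Pearson
coefficients are computed for all included pairs; pairs on the same
electrode are excluded (sorting artifacts induce spurious negative
correlation there), as are zero-variance vectors, and the array mean is
taken over included pairs only.

## Imaging

Electrode disks are near-black in phase contrast: pixels at grayscale 0 or
below mean − 1 SD, dilated by 2 px, are inpainted per channel by iterative
neighborhood averaging with the unmasked boundary held fixed (a harmonic
fill, so filled values respect the range of their boundary; convergence at
1/512 ≈ half an 8-bit unit, capped at 2000 iterations).

Dense cell aggregates absorb light with a red (brownish) shift. The hue map
is the per-pixel red/blue ratio (denominator floored at one 8-bit unit),
band-passed with a difference of Gaussians at σ = 15 µm (rejects single
cells and speckle) and 300 µm (rejects illumination gradients); the method
names no cutoffs, so these are chosen against the relevant feature scales —
single cells ~10–20 µm, clusters up to ~200 µm, illumination drift at the
montage scale. The source material states the ratio in both orientations in
different places; only red/blue is self-consistent with *above*-mean
thresholding of red-shifted clusters, so red/blue is the default and an
`invert` flag preserves the alternative rather than silently resolving the
discrepancy. Segmentation takes pixels above mean + 1.4 SD of the hue map,
then one 3 × 3 binary erosion; a zero-variance map yields an empty mask.
The cluster ratio is the masked-pixel fraction; day series are normalized
to the first day (zero first-day values are refused, not patched).

Per-electrode clusterness is the Gaussian-weighted mean of the hue map in a
31 × 31 µm window centred on the electrode, the weight's 1 SD contour
touching the window edge (σ = 15.5 µm; the window is read as micrometres,
not pixels). Content outside the window never affects the score; electrodes
whose window leaves the image score `NA`. The pixel scale is required
metadata — the package refuses to guess it.

## Group statistics

Bootstrap CIs resample with replacement 6000 times and take the 5th/95th
percentiles of the resampled means; degenerate (constant) data collapse to
a point interval. Percentiles everywhere — bootstrap, burstiness groups,
stratification — use linear interpolation between order statistics (R type
7), a single documented definition. Burstiness groups: `nonbursting` =
electrodes with no detected bursts; among the rest, `top5` = at or above
the 95th percentile (boundary ties all included), `p1_3` = between the 1st
and 3rd percentiles inclusive. Per-date stratification into tertiles or a
median split assigns equal-size groups with the remainder going to the
first (lowest) groups — 7 MEAs in tertiles split 3/2/2 — with ties broken
by MEA id so the partition is deterministic. Dates with fewer MEAs than
groups are skipped and logged. Percentile groups are computed pooled per
recording date, not per MEA.

## Synthetic data: what it emulates, and what it does not

The recording generator draws each unit's spikes as an inhomogeneous
Poisson process with piecewise-constant rate — a tonic baseline outside the
unit's burst epochs, a high in-burst rate inside — and a 2 ms absolute
refractory period, then renders a 1.5 ms biphasic difference-of-Gaussians
template per spike (10 % amplitude jitter) onto Gaussian background noise.
Defaults represent the recorded regime the package targets: 10 min at
32 kHz, noise SD 3 µV, spike amplitude 10× the noise SD (a clearly
detectable sorted unit), baseline rates of ~1–2 spikes/s, in-burst rates of
~150 spikes/s, and a shared schedule of synchronized burst epochs for the
network-burst stages. Two units placed on one electrode get opposite
dominant polarity so the PCA separation the sorter assumes is well-posed.
The generator reproduces the statistical structure each pipeline stage
consumes — it is not a biophysical model. It has no conductance-based
dynamics, no astrocyte biology, no electrode drift, no correlated or
non-Gaussian noise, and no spike-shape variation beyond amplitude jitter;
passing tests therefore validate the *algorithms* under their stated
assumptions, not performance on any particular real culture.

The image generator renders a pale textured background, red-shifted
soft-edged disks at chosen positions (optionally joined by faint strands),
and black electrode disks on the standard grid, returning the true cluster
mask. It emulates hue contrast and feature scales, not phase-contrast
optics: no halos, no stitching seams, no focus gradients.

Both generators are deterministic under a fixed seed.

## Problem sizes and tolerances in the shipped checks

The test suite validates each operation against independent oracles
(brute-force scanners, closed forms, eigendecompositions, Monte-Carlo) at
sizes chosen to make the checks sharp: the burst detector is compared with
a spike-by-spike reference scanner over 10⁴ random trains of ≤50 spikes
(exact agreement required); the network-burst threshold against a
sort-based percentile oracle over 10³ vectors (1e−12); entropy against
direct summation (1e−12); end-to-end recovery on a seeded 600 s, 32 kHz
scenario with five units on four electrodes and eight scheduled synchronous
epochs (spike recall ≥ 0.95, mean burstiness within ±0.05 of the realized
in-burst fraction, network-burst count exact, same-electrode pairs
excluded); bootstrap coverage over 500 simulated normal datasets at
B = 6000 (86–94 % for the nominal 90 %); and imaging recovery on seeded
scenes (cluster ratio within 20 % of designed area, pre-erosion noise
segmentation at Φ(−1.4) ± 0.01, electrodes under clusters outscoring
electrodes ≥200 µm away in every scene). `scripts/acceptance.R` recomputes
the same quantities from scratch under a caller-supplied seed.

## Known limitations

- Sorting is per-electrode; no cross-electrode (spatial) sorting, drift
  correction or manual curation, so units are "putative neurons" and
  same-electrode splits can be imperfect — which is exactly why
  same-electrode pairs are excluded from correlation.
- The burst machinery assumes the adaptive log-ISI model; pathological
  trains (e.g. slowly drifting rates) can land in the fallback branch.
- No lagged correlation, no spectral coherence, no sub-250 Hz field
  potential analysis, no burst-propagation analysis.
- Imaging assumes stitched, roughly evenly illuminated RGB input with a
  known µm/px scale; there is no tile stitching, 3-D/confocal analysis or
  cell counting.
- The 0.1 s fallback, the void ≥ 0.7 criterion and the knee margins are
  heuristics inherited from, or made concrete for, the adaptive method;
  they are all surfaced in `run_config()` so a study can tighten them.
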