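---
title: "Models and methods behind kymotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kymotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymotrace)
```

kymotrace quantifies single-particle motility in live-cell TIRFM
time-lapses the way it is done at the bench: trace a path along a
microtubule, build a kymograph at a finite line width, read velocity off
the slope of each run, take run time from the first and last frame of
evident movement, compute run length as their product, score directional
switches, and calibrate fluorophore counts of moving puncta against a
dimer standard. Because the raw observations in such studies are live-cell
movies that cannot be re-measured from a deposited table, the package
pairs every analysis stage with a synthetic movie generator whose ground
truth is known exactly, so that the whole chain is testable by parameter
recovery. This vignette documents the models, the defaults and why they
were chosen, the numerical choices, and what the recovery tests do and do
not demonstrate.

## The scene model

A simulated acquisition is a 12 s stream at 5 frames per second (60
frames at 0.2 s), matching streaming TIRFM with a 200 ms exposure and
2x2 camera binning. Three particle populations can share a field:

* **Runners** — the processive motor pool. Each runner draws a speed
  from a normal distribution truncated at zero, a run extent, a random
  track orientation, and a start time uniform over the stream. The
  trajectory is a straight segment traversed at constant speed; after the
  run ends the particle detaches and disappears.
* **Comets** — tip-tracking puncta: the same mechanics at the plus-end
  polymerization speed (~0.17 µm/s, one seventh of the motile pool), with
  long persistence.
* **Stationary puncta** — the immobile cortical pool. They exist so that
  the analysis has to *exclude* something, as it must on real data.

**Run extents.** Two parameterizations are offered. `run_length_mean`
draws the extent Exp(mean) in micrometers, independent of speed.
`run_time_mean` draws the *duration* Exp(mean) in seconds — a constant
detachment rate, the standard single-molecule kinetic picture — and sets
length = speed x duration. The packaged scenarios use the duration form,
for a reason worth stating precisely: with speed-independent exponential
lengths, mean duration is E(L)·E(1/v), which for the dynactin scenario
(L̄ = 2.6 µm, v ~ N(1.2, 0.46) truncated) is ≈ 2.6 s, well above the 2.2 s
that scenario is meant to reproduce; Jensen's inequality makes this
unavoidable. The duration model instead implies mean length v̄·T̄, which
matches both scenarios' length/velocity/time triplets to within the
censoring correction. It also removes an artifact in which slow particles,
which persist longer, are over-represented among scoreable runs and drag
the recovered mean velocity down.

**Directional switches.** A run reverses at most once, with probability
`reversal_prob` (0.03 in the motile scenarios). A reversal is modeled as
an *observable* event: the run extent of a switching run is drawn
conditional on having two arms of at least `min_reversal_arm` (0.5 µm,
the same threshold the scorer uses), and the switch point is uniform over
the resolvable interior. Placing the switch uniformly over the whole run
would make ~40% of switches geometrically unscoreable (one arm shorter
than the threshold) and the simulated switch fraction could then never
recover the configured rate through the scoring definition; a switch with
an invisible arm is not a switch that an observer — human or automated —
would ever have reported. The memoryless shift perturbs the extent
distribution of only the ~3% of runs that switch.

**Labeling.** Initial fluorophore counts per punctum come from a copy
model: `copy_fixed(k)` (the kinesin-1 dimer standard is `copy_fixed(2)` by
construction) or `copy_binomial(n, p)` — n taggable subunits, each tagged
with probability p. A heterozygously tagged dimer of dimers (the DHC
scenario) is Binomial(4, 0.5); dynactin with four p50 copies of which the
tagged allele contributes 1/6.5 of protein (a 5.5-fold untagged excess) is
Binomial(4, 0.154). Note a consequence used repeatedly below: a punctum
with zero tagged copies is invisible, so *visible* puncta follow the
zero-truncated binomial, whose mean (1.26 for the p50 model, 2.13 for the
DHC model) is what any intensity measurement can at best recover.

**Optics and camera.** Each fluorophore contributes an isotropic 2-D
Gaussian PSF (sigma 1.3 px) integrated exactly over pixel areas (erf
differences), rendered on a window of half-width ceil(3·sigma) so that
under 1% of photons are truncated, independent of subpixel position.
Photobleaching is per-fluorophore exponential from illumination start;
the default rate 0.02 /s (mean lifetime 50 s) makes a single fluorophore
bleach within a 12 s stream about 20% of the time — "sometimes", which is
how the imaging it emulates behaves — and a four-fluorophore punctum
almost never goes fully dark. The camera applies
Poisson(photons)·gain + offset + Gaussian read noise, clipped at zero; no
EM excess noise (sCMOS-style). The default 600 detected
photons/fluorophore/frame makes a single EGFP a clearly resolvable spot
(peak SNR ≈ 6) — a deliberate choice, because the experiments this
emulates measured motile puncta carrying on average a *single* EGFP, which
is only possible if single fluorophores are trackable.

Ground truth records every latent variable, per-frame subpixel positions
and surviving-fluorophore counts, and the observed (censored) run time;
the invariant observed ≤ true is tested.

## Kymographs

`extract_kymograph()` samples the movie along an arc-length
parameterization of the traced polyline (step 1 px, both endpoints
included so that reversing the path flips the distance axis *exactly* — a
tested identity) and at `line_width` perpendicular offsets (default 5, as
in the bench protocol), reducing across the width with a maximum by
default. The maximum is robust to a path drawn slightly off the particle
centerline; a mean reducer is available. Off-grid samples are bilinear
interpolated; samples falling outside the image clamp to the edge value
and raise a warning. Max-reduction makes kymograph values monotone
non-decreasing in line width, which is tested as a property.

## Run detection and measurement

Per frame, ridge candidates are local maxima above median + 4·MAD of the
kymograph — a robust noise floor. The threshold default of 4 (rather
than 3) keeps isolated noise excursions, of which a 60x40-sample
kymograph contains a few at 3 sigma, from attaching to the ends of real
traces, where the endpoint-slope velocity is maximally sensitive; a
single-fluorophore punctum still sits ≈ 6 sigma above the floor.
Candidates get parabolic subpixel refinement (clamped to ±0.5 sample) and
are linked greedily frame to frame within a 4-sample gate, with one
missed frame bridged (shot noise occasionally drops a dim punctum below
threshold for a single frame).

Linked traces are then reduced to *evident movement*: endpoint points
whose step is grossly inconsistent with the trace's median step are
dropped, and the trace is restricted to its longest stretch of sustained
motion (instantaneous slope at or above half the minimum speed, allowing
pauses of up to three points so the apex of a directional switch
survives). This is the automated counterpart of a human defining "the
start and end frame of evident movement" — and it is what detaches a
trace that has drifted onto a stationary cortical punctum. Traces
spanning fewer than 3 frame intervals (0.6 s) or slower than 0.2 µm/s are
discarded; the thresholds are exposed because the by-eye inclusion
criterion they stand in for is not recoverable from any protocol.

**Velocity** is the endpoint slope — |net displacement| / elapsed time —
matching the single-line measurement on a kymograph; a least-squares
option exists and agrees exactly on linear traces (tested). For a trace
containing a direction change the start-to-end net slope is not the speed
of either arm, so velocity is measured on the dominant monotone arm,
with turning points found at half the scoring threshold so that a switch
whose second arm was censored just below 0.5 µm still cannot corrupt the
speed. **Run time** spans the whole trace; **run length** is velocity x
run time, exactly as defined at the bench. **Switches** are counted by a
hysteresis walk: a reversal is scored each time the position retreats
from its running extreme by at least 0.5 µm, which guarantees both
flanking arms meet the minimum length.

Reported velocities are unsigned; the sign of net displacement is kept as
metadata, since a kymograph does not orient microtubule polarity.

## Intensities and copy numbers

`region_in_region()` implements inner-sum minus inner-area x outer-frame
mean. Defaults are a 7x7 px inner window (>99% of a sigma ≈ 1.3 px spot)
inside 13x13 px, both configurable because the original protocol does not
state its sizes. The measurement is exactly invariant to any constant
offset (tested). Each run is measured at its frame of maximum
inner-window SNR — the automated proxy for "the single time point at
which the spot was most clearly resolved" — skipping frames where another
punctum's inner region overlaps the outer window, and skipping the run
entirely if no clean frame exists.

`estimate_copy_number()` divides the mean corrected intensity of test
puncta by that of the dimer standard and doubles the ratio; a percentile
bootstrap (B = 10,000) gives the CI. The estimate is invariant to a
common gain (tested) and converges to 2 for unconditional Binomial(4,
0.5) puncta against an exact dimer (tested).

Two biases deserve explicit statement, because they are properties of the
*measurement*, not bugs, and the recovery tests are written around them.
First, visibility truncation: visible p50-like puncta average 1.26 tagged
copies, not 1.0, so "a single tagged copy" is an integer-resolution
conclusion (the estimate rounds to 1), not a point value. Second,
survivor asymmetry under bleaching: a one-fluorophore punctum that
bleaches before its run is never measured, while the two-fluorophore
standard can lose one fluorophore and still be measured, so the
standard's observed mean sits slightly below two fluorophores' worth and
the test/standard ratio inflates by roughly the pre-run survival deficit
(~10% at the default bleach rate). No bleach correction is applied,
because the protocol this reproduces applies none; the simulator surfaces
the effect instead. The stoichiometry recovery tests therefore assert the
integer readout — DHC rounds to two tagged chains, p50 to one, and p50 is
dimmer than DHC — rather than an exact 2.0 and 1.0.

`cytoplasmic_level()` is the fixed-protocol 25x25 px cytoplasm-minus-
nucleus measurement and deliberately errors on any other ROI size.

## Randomization statistics

`permutation_test()` permutes group labels for a two-sided difference of
means (median optional). When choose(n_a + n_b, n_a) ≤ 20,000 all
assignments are enumerated and p is exact; the worked small case —
a = (1, 2), b = (3, 4) — gives p = 1/3 by enumeration of the six
assignments. Otherwise Monte-Carlo sampling uses the add-one estimator
(#{perm ≥ obs} + 1)/(B + 1), which cannot return zero and attains its
floor 1/(B + 1) under a huge location shift (tested). Monte-Carlo p
converges to the exhaustive oracle on enumerable instances, the test is
exchangeable in its arguments, and its type-I error over 1,000 replicate
null pairs is calibrated at 5% (all tested). Ties are compared with a
relative tolerance of 1e-12 so that exchangeable floating-point
statistics count as ties rather than near-misses. Label permutation
without replacement is used; the statistic-monotonicity of the group-a
sum is exploited so only subset sums are drawn for the mean statistic.

## Reference scenarios and the recovery harness

`reference_scenario()` packages four study conditions (DHC motile pool,
p50 motile pool, kinesin-1 dimer standard, tip-tracking comets), with
every numeric field carrying a provenance note — reported value, derived
value (SD = SEM·sqrt(n), tagged fraction 1/6.5, comet speed 1.2/7), or
documented choice. Movie counts are sized so the *expected number of
scored runs* matches the reported sample sizes (100, 44, 90), accounting
for unlabeled puncta, late starts, short runs and bleaching; with ~8
runners per 128x128 field roughly two thirds of simulated runs are
scoreable.

`run_pipeline()` simulates the scenario's movies, extracts a 5-px
kymograph along each motile particle's ground-truth track (automatic
track-finding is out of scope by design), detects traces blind, and
attributes to each particle the trace that covers at least half of its
visible frames and lies within 3 samples of its projected position —
ground truth is used for *attribution*, never for measurement. The
recovery table joins measured and true values per particle; summaries
report mean ± SEM of velocity, run time, run length, the switch
percentage, and the detection rate.

Problem sizes in the shipped tests and acceptance script were chosen as
the scenarios' own sample sizes: two (DHC) or three (p50) replicate
scenario executions for the motility recoveries, ~1,000 scored runs for
the switch-rate check (matching the n at which its binomial tolerance is
computed), and 1,000 replicate null pairs for the type-I calibration.

## What recovery does and does not show

The generator reproduces the *reported summary statistics* under an
explicit mechanistic model — it does not reproduce real cytoplasm.
Microtubule curvature and intersections, track switching between
microtubules, motor pausing, cargo heterogeneity, comet shape (real
comets have an intensity tail), spatially varying background, uneven TIRF
illumination and sCMOS fixed-pattern noise are all absent. Recovery
passing therefore demonstrates that the measurement chain is unbiased and
correctly calibrated *for diffraction-limited puncta moving linearly at
constant speed under Poisson + Gaussian noise with exponential
bleaching*, with censoring by field exit, stream end and bleaching — the
dominant effects the protocol itself names. It does not validate path
tracing by humans, nor behavior at microtubule intersections, which the
measured studies handled by eye and report only qualitatively.

Two quantitative caveats recur in the tests. Scored runs are a
duration-thresholded sample, so recovered run times sit slightly above
and run lengths slightly below their configured scales after censoring —
both within the 2-SEM recovery bands at the scenarios' sample sizes. And
the scored switch fraction runs a few tenths of a percentage point above
the configured 3%, because observable switches are conditioned on two
resolvable arms and such runs are slightly longer, hence slightly more
scoreable, than average.

## Numerical choices

Coordinates are 0-based with pixel centers at integers; the kymograph
distance axis is kept in samples internally and converted to micrometers
only at measurement. Arc sampling uses `ceiling(L/step) + 1` evenly
spaced points so both endpoints are exact. Bilinear interpolation clamps
to the image edge (with a warning) rather than extrapolating. Parabolic
peak refinement is clamped to ±0.5 sample and skipped at flat or boundary
maxima. Degenerate inputs error early: fewer than two path vertices,
repeated consecutive vertices, even line widths, zero elapsed time,
non-positive frame intervals, ROIs touching the frame border, empty
groups in the permutation test. Zero-particle scenarios return empty
tables cleanly. All randomness flows from explicit integer seeds;
identical seeds give bit-identical movies, ground truth and pipeline
outputs (tested), and the acceptance script derives all stage seeds from
its single `--seed`.
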