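---
title: "neuroassay: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroassay: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the science behind each stage of the pipeline: the
model or procedure implemented, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the underlying methods
left genuine freedom. It states no empirical result that the test suite does
not itself compute.

## MEA spike detection

**Filtering.** Raw extracellular traces (12.5 kHz) are band-pass filtered at
200–2500 Hz with a *first-order Butterworth* filter. The digital filter is
the bilinear transform of the analog prototype
$H(s) = Bs/(s^2 + Bs + \omega_0^2)$ with both cutoffs prewarped, so the
−3 dB points land exactly at 200 and 2500 Hz and DC is rejected completely.
Zero initial conditions are used; the start-up transient decays within a few
milliseconds and is irrelevant at 10-minute recording lengths. Only order 1
is supported — higher orders would be a different filter, not a
configuration of this one.

**Adaptive threshold.** The spike threshold is $k \cdot \hat\sigma_t$ where
$\hat\sigma_t$ is the centred rolling sample standard deviation of the
filtered trace and $k = 5.25$. Parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 5.25 | – | the detection rule's stated multiplier |
| `window_s` | 0.1 | s | 1250 samples: ≈2 % relative SD of the noise estimate, short against slow drift; the vendor's window is unpublished, so this is configurable |
| `dead_time_s` | 0.001 | s | refractory-period scale; suppresses double counts of one biphasic waveform |
| `polarity` | both | – | extracellular spikes are predominantly negative, but bipolar detection matches common vendor behaviour; configurable |

A spike is one contiguous supra-threshold excursion; its timestamp is the
extremum sample (not the first crossing). The rolling SD is used exactly as
computed — detected spikes are *not* excised and the threshold re-estimated.
This matches the simple rule as stated, and has a measurable consequence the
acceptance suite quantifies: on pure Gaussian noise, the ≈2 % estimation
noise of a 1250-sample window slightly inflates the $5.25\sigma$ tail
crossing rate above the ideal $2\Phi(-5.25)n$, which is why the calibration
criterion uses a 3-σ Poisson band on the 100-seed mean rather than an exact
equality.

**Well summary.** Per-electrode rate is count/duration. Whether the "well
average" divides by all electrodes or only active ones is a vendor
convention we cannot pin down, so both are reported: the mean over all 64
electrodes (default) and the mean over electrodes firing ≥ 5 spikes/min.

## Calcium transient calling

Traces are 1 Hz fluorescence series over 10 min, background subtracted
upstream of peak calling. Candidate transients are strict local maxima;
plateaus of equal samples collapse to their midpoint (left of centre when
even) so one physiological transient yields one candidate. From each peak
the flanks are walked outward while each next sample is *strictly* lower —
an equal-value step terminates the descent, making the delimitation
well-defined on integer-valued data. Peaks lacking a flank (at trace
boundaries) are discarded.

The **relevance area** is the shoelace area of the triangle whose vertices
are the peak and the two flank minima (time in seconds × fluorescence in
trace units). "Vertices" names a polygon's corners, which is why the
triangle reading is the default; an under-the-curve functional (trace
integrated above the chord between the minima) ships as an alternative.

The keep rule compares that area with one standard deviation above the mean
*of the signal itself*: `area > mean(F) + 1·sd_pop(F)`. Three readings of
this rule are genuinely possible and all are implemented:

* `literal` (default): threshold = mean(F) + m·SD(F) over the trace samples;
* `peak_population`: threshold = mean(areas) + m·SD(areas) over the trace's
  candidate areas;
* `sd_only`: threshold = m·SD(F), no mean term.

The original routine is unavailable, so none can be *verified* correct; the
literal reading follows the rule's wording most directly. Note two of its
properties. First, it compares an area (a.u.·s) with an amplitude statistic
(a.u.); at 1 s sampling the numbers coincide and the package warns when
`dt ≠ 1`. Second, the threshold contains the trace mean, i.e. the resting
fluorescence F₀ — the rule only separates event triangles from noise
triangles because F₀ is substantial relative to noise. On a trace whose
baseline has been shifted to zero the literal rule degenerates (noise-peak
triangles beat a near-zero threshold), which is worth knowing before feeding
it ΔF/F-normalised data; the `sd_only` rule with a multiplier is the better
choice there. SD is population (÷n) throughout this module: the trace is the
entire observed population of samples, and the choice must be fixed for
exactness even though it is immaterial at n = 600.

A cell is **active** when it has ≥ 1 relevant event in the recording (the
source protocol selects "active cells" without defining the term; this is
the weakest sensible reading and is applied before any averaging).

## Scratch assay

Counts of reinvading objects (cell bodies and processes together, as
counted upstream) inside the standardized 1.3 × 0.35 mm rectangle, daily
over days 0–10. The ROI is half-open on both axes so tiled ROIs never
double-count. Outputs are raw counts, densities per mm², and counts
normalized to a reference day — by default the final day (the only
reference guaranteed non-degenerate); setting `ref_day = 4` expresses
later counts as fold change over the end of the common pre-divergence
window. Whether the original analysis normalized per area or per starting
density is unstated, so raw and density curves are always emitted together.
The recovery rate is the least-squares slope of count vs day with its
standard error — a deliberately simple summary, since the inferential work
is done by the repeated-measures ANOVA.

## Group statistics

* One-way ANOVA with Tukey HSD (studentized range; Tukey–Kramer for
  unbalanced groups). With two groups the Tukey p collapses to the pooled
  two-sample t-test p through $q = |t|\sqrt2$, which the tests verify.
* Mixed repeated-measures ANOVA: between-subject factor group, within
  factor day, subjects (wells) nested in groups, complete designs only
  (incomplete designs are rejected listing the missing cells, not silently
  dropped). Sphericity is assumed for the headline p values, and the
  Greenhouse–Geisser ε with corrected p values is always reported
  alongside. This matters for count-valued time courses: Poisson counts
  have variance growing with the mean across days, which violates
  sphericity *by construction*, and the uncorrected interaction test is
  then anti-conservative. For that reason the package's own calibration and
  power claims about the scratch assay are asserted on the GG-corrected
  interaction p; the uncorrected p is still what the tables print first,
  matching what a standard package default would have produced.
* SEM uses the sample SD (n−1) — deliberately different from the calcium
  module's population SD; the two contexts are independent and each is
  fixed explicitly. Single-observation groups get SEM 0 and a flag rather
  than NA, so downstream tables stay numeric.
* The ANOVA unit for the calcium endpoint is the well mean over active
  cells (default), avoiding pseudo-replication of cells within wells; a
  cell-level option exists for exploratory use.

## Synthetic data: what it emulates, and what a green test establishes

The generator encodes the cohort design the pipeline targets — six case and
five control lines, 16 wells per group with triplicate labels — and the
stated effect directions: case firing rates multiplied by 0.5, case calcium
event rates multiplied by 0.5, and scratch mean curves identical through
day 4 with case growth halved afterwards.

Free parameters the source material never quantifies were fixed once, at
field-typical values, and are configurable:

| parameter | default | rationale |
|---|---|---|
| control firing rate | 1 spike/s per active electrode | typical spontaneous rate of young iPSC-neuron cultures on MEA |
| silent electrode fraction | 0.5 | MEA wells are never uniformly active |
| spike waveform | biphasic, trough:rebound 2:1, 1.6 ms | canonical extracellular shape |
| spike amplitude | 8 × noise SD | "clean" SNR regime the recall criterion assumes |
| MEA noise SD | 3 µV | typical MEA noise floor |
| calcium event rate | 2 events/min (control) | typical spontaneous transient frequency |
| resting fluorescence F₀ | 50 a.u.; amplitude 100 a.u. (ΔF/F₀ = 2) | Fluo-4 spontaneous network transients commonly reach ΔF/F₀ ≈ 1–3; a nonzero F₀ is also what makes the literal relevance rule operate, as explained above |
| calcium noise SD | 5 a.u. (amplitude/20) | the "high SNR" regime of the effect-recovery property; the SNR = 10 regime is exercised separately at the control rate |
| decay τ | 2 s | single-exponential decay; rise is sub-sample at 1 Hz |
| scratch growth | 12 objects/day (control) | reaches ≈ 120 objects in the 0.455 mm² ROI by day 10, a plausible confluency |
| line-to-line CV | 0 | the stated design has no line-heterogeneity parameter; wells are exchangeable within groups, which also makes well-level null calibration well-posed. Set `line_cv > 0` to add log-normal per-line rate multipliers |

Spikes and calcium events are *independent homogeneous Poisson processes* —
deliberately so: network bursting, oscillations, photobleaching drift and
line-level heterogeneity are not modelled by default. A green recovery test
therefore establishes that the chain detects a 0.5× rate suppression in an
idealised, well-behaved cohort of the stated size; it does not establish
robustness to bursty firing, correlated noise or drifting baselines.

Determinism: every generator draws from R's RNG seeded by the parameter
object; identical parameters give identical outputs. Cohort simulation has
two fidelity levels — `counts` (ground-truth event times only; exactly the
distribution perfect detection would return) and `traces` (full waveforms).
A full-size cohort at trace fidelity is ≈ 1.2 × 10¹⁰ samples and cannot be
re-simulated hundreds of times on one CPU, so repeated power simulations run
at count fidelity while detection fidelity is established separately by the
oracle-equivalence, tail-calibration and recall criteria at trace level.

## Numerical and degenerate-input conventions

* Rolling SD windows shrink symmetrically at trace edges; the two boundary
  samples use the minimal two-sample window so the estimate exists
  everywhere. A window of at least the trace length returns the global SD.
* Collinear peak triangles have area 0 — a valid value, not an error.
* Zero rates are valid empty Poisson processes (the generator accepts them;
  detectors return empty results rather than failing).
* RM-ANOVA terms whose sum of squares is numerically zero report F = 0,
  p = 1 rather than a 0/0 ratio.
* Timestamps are seconds from recording start; sample *i* is at
  (i−1)/fs, so an extremum at sample 1 is time 0.

## Known limitations

* The spike detector does not sort spikes, de-duplicate across electrodes,
  or model the hardware's 200–5000 Hz acquisition band; only the stated
  software filter is applied.
* The calcium module consumes traces, not images: ROI segmentation,
  background estimation and ΔF/F₀ correction are upstream concerns.
* The scratch module consumes coordinates or counts; segmentation and
  wound-edge detection are out of scope.
* The statistics layer offers fixed-effects ANOVA only; nested
  line-within-group random effects would need a mixed-model extension.
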