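---
title: "Models and methods behind the MMN pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the MMN pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnpipe)
```

This vignette is the package's account of its science: the measurement
model, the synthetic-data generator and what it does and does not emulate,
the statistical machinery, and the numerical decisions taken where the
design was genuinely open.

## The measurement model

The mismatch negativity (MMN) is derived from a deviant-minus-standard
difference wave. The pipeline fixes the following conventions:

* **Epochs** are half-open windows `[-100, 400)` ms around stimulus onset
  (500 ms total, 100 ms pre-stimulus baseline), at a default sampling rate
  of 512 Hz: `round(0.5 * 512) = 256` samples, 51 of them pre-stimulus.
  Samples are 0-based; sample `n_pre` sits at time 0.
* **Peak latency** is the time of the single most negative sample of the
  difference wave at one electrode (default Fz) within the closed window
  100--250 ms. Ties resolve to the earliest sample. A flat segment returns
  the window start with a `no_unique_peak` flag rather than failing. A
  global-minimum search was preferred over local-minimum detection because
  it is deterministic, parameter-free, and identical to what a human
  reading "the most negative peak" off a plot would select on a unimodal
  deflection.
* **Mean amplitude** is the mean of the difference wave over the 50-ms
  window centred on the individual peak (`peak +/- 25` ms, inclusive at
  sample resolution), reported in the *negativity-positive* convention:
  the negated signed mean, so an MMN-like negativity is a positive number,
  as group tables print it. Negation rather than an absolute value keeps
  the measure linear — group means of individual measures equal the
  measure of the group mean — and lets individuals with little or no
  negativity take values near or below zero, which is what makes reported
  cell SDs close to the cell mean representable at all. Windows that would
  leave the epoch are clamped and flagged. The raw signed mean is always
  retained.
* **Pattern condition**: epochs are time-locked to triplet-first tones
  only, and the pattern MMN subtracts the standard-triplet first-tone
  response from the deviant-triplet first-tone response. The overlapping
  responses to tones 2 and 3 (at +180 and +360 ms) are identical in both
  averages by linear superposition and cancel in the difference.

## Preprocessing chain

The offline chain runs in a fixed, provenance-recorded order:
band-pass filter, re-reference, epoch, baseline-correct, reject.

* **Filter**: 4th-order Butterworth, 1--30 Hz, applied forward and
  backward (`signal::filtfilt`) for zero phase. Only the band is a
  scientific commitment; the realization is our choice, and the order is
  configurable. Note one numerical property: the 1-Hz poles sit close to
  the unit circle, so different evaluation orders of the same linear
  operation can differ by ~1e-6 on unit-scale data. Tests assert linearity
  at that scale, not at machine precision.
* **Re-reference**: linked mastoids subtracts `mean(A1, A2)` per sample
  from every channel. The operation is idempotent and preserves all
  pairwise channel differences exactly. An average reference is available;
  topographic statistics average-reference their maps internally either
  way.
* **Baseline**: per trial and channel, the mean over `[-100, 0)` ms is
  subtracted; a window with no pre-stimulus samples is an error.
* **Rejection**: a trial is rejected iff any scalp channel (mastoids
  excluded) has a sample with absolute amplitude *strictly* above 70 uV,
  after baseline correction. "Amplitude variations exceeding +/-70 uV" has
  a second reading — peak-to-peak range — which is available as
  `rejection_mode = "peak_to_peak"`; absolute post-baseline amplitude is
  the default because it composes cleanly with baseline correction and a
  strict `>` makes the boundary case (exactly 70 uV) retained,
  deterministically. Whether rejection preceded re-referencing in the
  original procedure is unknowable from the text; the chain applies it
  after, and the order is recorded in provenance.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground truth.
It emulates a 32-channel, nose-referenced recording of the two oddball
conditions under the reference study design: 14 females and 15 males, 200
deviants per condition at deviant probability .16, SOA 180 ms, 50-ms tone
bursts.

**Stimulus sequences.** `round(n_deviants / p_deviant)` units per block
(1250 for the reference values), deviants placed uniformly at random
subject to *no two adjacent deviant units*, and (by default) not in first
position, so the regularity is established before its first violation.
The emulated design fixes no spacing constraint; non-adjacency is
standard oddball practice and keeps the regularity interpretable. Onsets
are spaced a constant integer number of samples apart (92 at 512 Hz, i.e.
a realized SOA of 179.69 ms, recorded in the event-table metadata):
quantizing each onset separately would make inter-tone gaps jitter by one
sample, and the jitter breaks the exact cancellation of neighbouring-tone
responses between deviant and standard averages that the recovery
guarantees below rely on.

**Signal model.** Every tone evokes the same P1--N1--P2 template (three
Gaussian kernels at 55, 105, 180 ms; amplitudes +1.2, -2.5, +1.8 uV) with
a broad central scalp profile. Because the template is identical for
standards and deviants, it cancels exactly in the difference wave. Each
*deviant epoch* additionally contains a negative Gaussian MMN kernel,
default FWHM 60 ms, peaking at the subject's configured latency, with a
fronto-central scalp profile (cosine-squared taper from a point between
Fz and Cz; exactly zero beyond its radius, hence zero at occipital sites
and at the mastoids, and normalized to 1 at Fz). A Gaussian kernel makes
peak and window-mean relationships analytic. Three unanalyzed standard
tones flank the stream on each side so edge epochs have the same
neighbour-tone context as interior ones.

Two details are deliberately trial-locked rather than written into the
continuous trace: the MMN kernel and artifact bursts are injected into
their epochs at extraction time. With a 180-ms SOA and 500-ms epochs,
every continuous-time event would bleed into the two or three
neighbouring trials' windows — including their baselines — which would
make the generated effect structure impossible to state exactly and would
break the one-to-one correspondence between injected and rejected
artifact trials. The cost is that these components bypass the band-pass
stage; both are smooth and essentially in-band (the kernel's spectral
mass lies well under 30 Hz; the burst is a 10-Hz packet), so this is a
modelling simplification, not a loophole.

**Amplitude calibration.** The kernel scale is calibrated *on the
discrete sample grid*, replicating the measurement stage's baseline
subtraction and window selection, under one of two conventions:
`amplitude_mode = "window_mean"` (default; the recovered 50-ms window
mean equals the configured amplitude exactly) or `"peak"` (the most
negative sample equals minus the configured amplitude exactly). The
reference preset uses `window_mean` because published cell values are
mean amplitudes. Noiseless recovery is therefore exact to machine
precision — *provided the band-pass is off*, which is how
parameter-recovery runs are configured: a 1-Hz high-pass unavoidably
removes a few percent of a 60-ms Gaussian's area, and testing recovery
through a filter would conflate the generator's fidelity with the
filter's transfer function.

**Noise.** Zero-mean Gaussian, AR(1) in time (coefficient 0.95 at 512
Hz), spatially correlated across channels through a squared-exponential
kernel over planar montage distance (length scale 0.6 head-radius units),
scaled to a marginal SD of `noise_sd_uv` (default 10 uV, a realistic
single-trial EEG level in the 1--30 Hz band). This gives EEG-like
low-frequency-dominated spectra and spatially smooth noise topographies.
It does not model eye blinks, line noise, drifts, alpha bursts, or
non-stationarity — artifact trials are represented only as
threshold-exceeding 10-Hz packets (150 uV, 80 ms, one random scalp
channel) injected at a configurable trial fraction. Consequently, passing
tests demonstrate correctness of the *analysis*, not robustness to every
real-world contaminant.

**Between-subject structure.** Cell means and SDs of latency and
amplitude are configurable per gender and condition; the reference preset
uses the published cell means with SDs reconstructed as `SEM * sqrt(n)`.
Latencies are drawn from truncated normal distributions on [100, 250] ms
whose parent parameters are solved numerically so the *truncated*
distribution has exactly the configured mean and SD (naive truncation
would bias the male simple-condition mean by about +3 ms and distort the
configured 30.97-ms gender difference). Amplitudes are drawn from
moment-matched gamma distributions: amplitudes of a measurable negativity
are positive, and one reference cell (male, pattern: mean 0.79, SD 0.85)
has a coefficient of variation above 1, which no normal truncated at zero
can attain but a gamma represents naturally. A subject's two condition
values are coupled by a Gaussian copula with correlation 0.5 — a typical
ERP test--retest reliability, chosen once; the emulated design fixes no
within-subject covariance — which preserves the configured marginals
(hence all between-gender summary statistics) while giving the
within-subject contrasts realistic power.

`simulate_measures()` is the generative model of the measurement stage:
it writes down, in closed form, the exact Fz difference trace a noiseless
unfiltered pipeline produces for each drawn subject and applies the
package's own `peak_latency()` and `mean_amplitude()` to it. Its
equivalence with the full epoch-level pipeline is asserted in the test
suite; replicate-level recovery and power studies use it so that hundreds
of replicates stay affordable.

## Topographic statistics

Scalp maps are per-electrode means of the difference wave over the
subject's individual 50-ms MMN window (the same window as the amplitude
measure; a peak-sample alternative is available). The map uses the 30
scalp electrodes; A1/A2 are excluded. The analysis window for DISS maps
is not fixed by the emulated design; tying it to the amplitude window is this
package's decision, flagged as such.

GFP is computed on average-referenced values — the convention that makes
the DISS bounds exact: after average-referencing and GFP-normalization
each map is a unit vector in the hyperplane orthogonal to the constant
vector, so `DISS = |u* - v*|_rms` lies in [0, 2] with 0 iff the maps are
identical up to positive scaling and 2 iff polarity-reversed, and
`DISS^2 = 2 (1 - r)` with `r` the spatial Pearson correlation. Uniform
maps have zero GFP and cannot be normalized; they raise an error rather
than returning NaN.

The randomization test reassigns the pooled individual maps to two groups
of the original sizes uniformly at random (default 10,000 permutations),
averages within groups, and recomputes DISS. The p-value is the plain
proportion of permuted values greater than or equal to the observed one
— ties count as exceeding, the conservative direction — matching the
granularity of p-values reported from ten thousand permutations; the
`(b+1)/(m+1)` variant is available via `add_one = TRUE`.

## Group statistics

The 2x2 mixed ANOVA is computed from subject sum and difference scores.
For a two-level within factor this reproduces the classical (SPSS-style,
Type III) mixed-model decomposition also under unequal group sizes: the
between-subjects effect is tested against subjects-within-groups, the
within effect and the interaction against the subject-by-within residual,
all with numerator df 1 and denominator df `N - 2`, and
`eta_p^2 = SS_effect / (SS_effect + SS_error)` per effect. `aov()` with
an `Error()` stratum serves as an independent cross-check on balanced
designs in the test suite (where Type I and Type III coincide); the
additivity of the sums of squares is likewise asserted on balanced
designs, since Type III components need not sum to the total under
unbalance. A table with zero total variance returns zero effects with a
`degenerate` flag instead of 0/0.

t tests are pooled-variance Student tests throughout — this, not Welch,
is what reproduces `df = 27` and the printed t values from cell means and
SEMs of groups of 14 and 15. Cohen's d uses the pooled SD for independent
contrasts and the SD of the differences for paired contrasts; the paired
convention cannot be verified against reference values without raw data and is
documented as a choice. Degenerate inputs follow fixed rules: identical
paired vectors give `t = 0, p = 1`; constant non-zero differences
(infinite t) are an error; both-zero SEMs are an error. Sphericity
corrections are unnecessary — every within factor has exactly two levels
— and this is asserted by construction rather than assumed.

## Numerical and interface decisions

* Units are uV and ms everywhere; sample indices are 0-based; windows at
  sample resolution are closed and use a 1e-9-ms tolerance against
  floating-point grid error — the same helper selects windows in the
  generator's calibration and in the measurement stage, so the two cannot
  disagree.
* Epoch files are plain TSV matrices (trial-major, one row per
  trial-channel pair) with JSON sidecars; doubles are written with 17
  significant digits and re-read with a correctly-rounded parser, making
  the round trip bit-exact.
* All stochastic stages take explicit integer seeds; study-level seeds
  deterministically derive per-subject sub-seeds. Derived tables carry a
  configuration hash and the seed as attributes.
* Whether block-initial stimuli should be excluded from averaging is left
  configurable (`first_unit_standard`), as the emulated design leaves it open.

## Problem sizes

The test suite and acceptance script scale the design down where full
size adds nothing: parameter-recovery runs use 6--8 deviants per block
(recovery is exact, so n is irrelevant); type-I calibration uses 500--2000
null simulations at the measures level and 199-permutation DISS tests
(the rate estimate, not the per-test resolution, is what matters);
effect-structure checks use 200 full measure-level replicates plus 2000
draw-level replicates; the end-to-end study run uses 29 subjects with 30
deviants per condition and 1000 permutations. These sizes are the
package's choices for a desk-scale demonstration; the defaults
(`n_deviants = 200`, `n_perm = 10000`) remain the reference conditions.

## Known limitations

* The generator's MMN is a single Gaussian kernel at one latency; real
  MMNs ride on overlapping obligatory components, vary in width, and can
  be bimodal. Latency/amplitude recovery results transfer to real data
  only to the extent the unimodal model holds in the search window.
* No polarity inversion at the mastoids is modelled (under a nose
  reference the MMN typically inverts below the Sylvian fissure); the
  mastoid signal is noise plus the obligatory template only, which makes
  linked-mastoid re-referencing slightly *less* consequential here than
  in real data.
* Trial-locked kernel injection bypasses the filter (see above).
* ICA-based ocular correction is out of scope; the only artifact handling
  is the amplitude-threshold rejection.
* The mixed ANOVA is exactly the 2x2 design — it is not a general k-way
  repeated-measures engine, by intent.
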