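---
title: "Methods: escape decisions and looming-sensitive neurons under paired threats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: escape decisions and looming-sensitive neurons under paired threats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`loomattend` analyses how an animal — and its looming-sensitive neurons —
resolve two simultaneously approaching threats. It asks two questions. From
escape directions: does the animal *selectively attend* to one of two
looming stimuli (bimodal escapes, one mode directly away from each
stimulus) or *divide attention* between them (unimodal escapes at the
direction maximising distance from both)? From spike trains: does a
looming-sensitive neuron driven by two stimuli respond like the *stronger*
single input (select-stronger), like their *sum*, or like their *average*?

Because the behavioural and electrophysiological recordings this kind of
study produces are small, bespoke tables, the package ships seeded
generators that emulate both data types. Every analysis stage is therefore
testable end to end without external data, and the generators double as the
ground truth for parameter-recovery checks.

## Stimulus model

A looming stimulus is a disk of physical diameter $D$ approaching at
constant speed $v$ from starting distance $d_0$ on a collision course. At
time to collision $\tau$ the distance is $d = v\tau$ and the full angular
subtense is

$$\theta(\tau) = 2\arctan\!\frac{D/2}{v\tau},$$

capped at 180° once $d \le D/2$ (the rendered stimulus has filled the
display by then, and downstream code needs a defined value at $\tau = 0$).
The exact arctangent form is used rather than the small-angle
approximation; both round to the same value at the experimental geometries
(0.34° for a 30 mm disk at 5000 mm; 1.7° at 1000 mm). The expansion rate is
the analytic derivative
$\dot\theta = 2Rv/(d^2+R^2)$ rad/s with $R = D/2$, zero after saturation.
Stimulus strength on the display is summarised by Weber contrast
$(L_\text{stim}-L_\text{bg})/L_\text{bg}$, −100% for a black disk on the
grey background and −40% for the low-contrast variant.
`linearization_lut()` reproduces the standard monitor-calibration step:
given measured radiance per digital level it returns the table that makes
emitted radiance linear in the requested level, by numerically inverting
the measured curve and rounding to the nearest level.

Angles are degrees in `[0, 360)` throughout the public interface and
radians internally. All on-screen rendering is out of scope: the tabulated
trace (`stimulus_trace()`) is the authoritative stimulus description.

## Behavioural generator

`gen_escape_trials()` simulates tethered-treadmill trials. Treatment order
follows a randomised Latin square (every crab sees every treatment once per
block; every treatment occupies every serial position equally often). Per
trial:

* body orientation is uniform on the circle;
* the crab responds with probability `response_prob` (default 0.754, the
  overall response rate such treadmill preparations yield);
* on responding trials, under **selective** attention one stimulus is
  chosen with probability proportional to
  $\exp(b_\text{lat}\,|\sin\Delta|)\,\exp(b_\text{con}\,|c|)$, where
  $\Delta$ is the angle between the stimulus azimuth and the body's long
  axis ($|\sin\Delta| = 1$ when the stimulus lies on the lateral axis) and
  $c$ its Weber contrast. The escape direction is von Mises around the
  direction directly away from the chosen stimulus, concentration `kappa`
  (default 8, a realistic concentration for directed escape runs). Under
  **divided** attention the direction is von Mises around the circular
  mean of the away-directions; for antipodal stimuli that mean is
  undefined and one of the two orthogonal solutions is picked at random.
* response timing is drawn on the square-root time-to-collision scale
  (where such timing distributions are approximately normal):
  $\sqrt{\tau} \sim \mathcal N(\mu + u_\text{crab} + s(|c|-1),\ \sigma)$,
  squared back, with a per-crab intercept $u_\text{crab}$ and a contrast
  slope $s$ (default 0.5 sqrt-s per unit contrast, i.e. a −40% stimulus
  responds 0.3 sqrt-s later than a −100% one). No printed timing means
  exist to calibrate against, so the absolute defaults
  (`timing_mean_sqrt = 1.6`, `timing_sd_sqrt = 0.25`, `crab_sd = 0.15`)
  are the package's own choice of a plausible scale (responses a few
  seconds before collision).

Non-responding trials carry missing timing and direction, never sentinels.
The functional forms of the two choice biases are generator choices — the
phenomena (lateral-axis preference, higher-contrast preference) are what is
being emulated, not any published equation.

What the generator does **not** emulate: habituation or sensitisation
across presentations, errors in digitising running direction, burrow-
directed escapes, or any coupling between response probability and body
orientation. Passing recovery tests on these synthetic data therefore shows
that the *decision machinery* is sound at realistic signal-to-noise, not
that real crabs obey von Mises mixtures.

## Circular statistics

All primitives are implemented from their defining formulas
(`circ_summary()`, `rayleigh_test()`, `rao_dispersion_test()`,
`transform_multimodal()`, `bootstrap_direction_ci()`, `sector_*()`,
`bin_orientation()`).

**Multimodal transform.** Multiplying angles by 4 (stimuli 90° apart) or 2
(180° apart) and reducing modulo 360 maps both selective modes onto one
common direction and the divided mode 180° away from it. This is the pivot
of the behavioural decision: after transforming, a single mean direction
separates the hypotheses, and the transformed single-stimulus distribution
is directly comparable.

**Rayleigh test.** $Z = n\rho^2$ with the standard series approximation for
the p-value, clipped to $[0,1]$. Monte-Carlo checks in the test suite hold
its type-I error to 4–6% at $n = 30$ and its null p-values uniform.

**Dispersion homogeneity.** The package needs a chi-square test that $k$
circular samples share a dispersion. It uses Rao's delta-method
construction: each group's dispersion is $1-r$; its sampling variance
follows from the covariance of the mean cosine and sine; the weighted
between-group sum of squares is $\chi^2_{k-1}$ under the null. The exact
variant behind published "Rao test" chi-squares is ambiguous, so the
implementation is validated against an independently written reference
implementation of the same construction (50 frozen datasets, relative
tolerance $10^{-6}$) and by simulation of its type-I error, not against any
printed statistic.

**Sector scheme.** For stimuli at 0°/270° the divided prediction is 135°.
The scheme labels the central 45° around 135° *green*, the central 45°
around each away-direction (180°, 90°) *white* (excluded from analysis),
and the two outer flanks ([202.5°, 247.5°) and [22.5°, 67.5°)) *red*. Green
vs combined red is then a symmetric inner-tail vs outer-tail comparison:
under selective attention escapes fall into green and red equally often;
under divided attention green is enriched. `sector_proportion_test()`
compares $P(\text{green}\mid\text{green}\cup\text{red})$ between the
combined-rotated single distribution and the paired distribution by
permuting group membership — exactly (enumeration) when
$\binom{n}{n_1}\le 20000$, otherwise by Monte Carlo with an add-one
correction. All angular intervals are half-open $[lo, hi)$ and angles are
normalised to $[0,360)$; ties at a boundary therefore classify into the
sector whose lower edge they sit on.

**Orientation bins.** Body orientation enters as the angle between a
stimulus azimuth and the crab's transverse (lateral) axis, binned into four
90° sectors centred on 0°, 90°, 180°, 270° (half-open). With this
convention 0° means "stimulus on the lateral axis", and the bins centred on
0°/180° vs 90°/270° separate lateral from anterior–posterior alignment.
Whether the original analysis centred or bounded its bins on the body axes
is not stated; centring is adopted because it makes the bin label agree
with the nearest axis.

**Degenerate inputs.** A resultant length below $10^{-12}$ flags the mean
direction as undefined rather than returning an arbitrary angle; bootstrap
intervals then warn and return the full circle.

## Spike-train analysis

`estimate_rate()` convolves a spike train with a Gaussian kernel of full
width at half maximum 200 ms ($\sigma = \text{FWHM}/(2\sqrt{2\ln 2})
\approx 84.9$ ms) and rescales the waveform so its integral over the whole
recording equals the spike count. Kernels are truncated at the span edges
and at $\pm 6\sigma$ for speed; the global rescaling happens after
truncation, so conservation holds exactly (the test suite asserts a
relative error below $10^{-6}$ on every train, and the single-spike peak
equals the closed form $1/(\sigma\sqrt{2\pi}) \approx 4.698$ Hz). The
default grid step is 1 ms; population analyses use 10 ms, which still
oversamples the kernel ten-fold.

The spontaneous baseline is the mean and SD of the smoothed rate over the
unstimulated span, trimmed by $3\sigma$ at the edges. Response onset is the
earliest time the rate exceeds `mean + 2 * SD` and stays above threshold
for at least `min_duration`. Two readings of the published "2 standard
deviations of the spontaneous activity" criterion exist (2 SD above the
mean vs an absolute 2 SD); the mean + 2 SD reading is adopted because a
pure 2-SD level can sit below the mean for regular firing. The minimum-
duration criterion (one FWHM for single trains) is an addition: smoothed
low-rate Poisson baselines occasionally clear the threshold for a kernel
width on the strength of a few coincident spikes. For population work two
further, documented hardenings are available and used by the pipeline:

* `anchor_peak`: take the qualifying supra-threshold run that contains the
  rate maximum (a looming response rises through threshold and stays up
  through its peak), rather than the earliest run;
* `analyze_spike_trains(pool_reps = TRUE)`: pool repeat presentations into
  a trial-averaged PSTH before extracting metrics, the standard treatment
  of repeated trials;
* `window_per = "neuron"`: measure peak and average rate over a window
  common to a neuron's treatments (starting at its earliest onset).
  Per-treatment windows are correct for like-for-like comparisons, but
  rates measured over different windows do not compose additively, which
  confounds the integration-rule test below.

Peak and average rate are taken from onset to the end of stimulation;
"during response" has no published endpoints, and end-of-stimulation is the
natural right edge because these neurons peak there.

## Spike-train generator

`gen_spike_train()` draws an inhomogeneous Poisson process by thinning,
with intensity

$$\lambda(t) = r_\text{spont} + g\cdot
\mathrm{combine}_i\{w_i\,|c_i|\,\dot\theta_i(t)\},$$

where `combine` is max, sum or average, $w_i$ a receptive-field weight and
$\dot\theta_i$ the expansion rate of stimulus $i$. Driving the rate with
the expansion rate (not angular size) makes the firing rate climb to a peak
just before the predicted collision and makes lower contrast cross the
onset threshold later — the two qualitative signatures the generator must
reproduce. A homogeneous spontaneous segment precedes the trial. Defaults:
spontaneous rate 2 Hz (looming-sensitive lobula giants fire sparsely when
unstimulated), gain 0.5 Hz per deg/s (peak rates around 100 Hz at the
electrophysiology geometry), primary/secondary receptive weights 1.0/0.6
with 10% log-normal per-neuron jitter for MLG1-like cells and equal weights
for MLG2-like cells, six repeat presentations per treatment (within the
usual range for such protocols). The generator does not model biophysics,
adaptation, saturation or habituation.

## Decision procedures

**Behavioural.** For each paired treatment against the single reference:
transform both samples (×4 or ×2); Rayleigh-test the transformed paired
sample at `alpha` (no directionality → inconclusive); compare the
transformed mean against the transformed selective target and the
transformed divided target (180° apart) and let the closer target decide;
corroborating statistics (bootstrap CIs of both transformed means and
their overlap, dispersion comparison, sector test for 90° pairs, raw-data
Rayleigh) are reported alongside. Groups with fewer than 10 responding
trials are inconclusive with a warning. The original argument proceeds from
converging evidence without a formal rule; the decision tree here is the
package's own, with every threshold configurable.

**Neural.** For each neuron with complete Primary/Secondary/Paired
metrics, the spontaneous rate is subtracted (driven components compose;
baselines do not double), the paired response is predicted under the three
rules from the single responses, and each rule is scored within each metric
(peak, average) by rank of its absolute prediction error. The two metric
ranks are combined by their mean, the verdict is the rule with the lowest
mean rank, and it is declared only when the bootstrap 95% CI (resampling
neurons) of the per-neuron rank gap to the runner-up excludes zero.
Because both rules are scored against the same observed response, this
paired gap cancels shared measurement noise. One further gate: when no
stimulus is consistently the stronger single input (sign test on the
primary-minus-secondary peak across neurons), select-stronger and average
predict the same response and that pair of rules is declared
non-identifiable (inconclusive) — exactly the situation of a uniform
receptive field.

**Timing.** Group comparisons of response timing use a permutation null
stratified by subject: labels are permuted only within crab (or neuron),
preserving the repeated-measures structure the original mixed models
accounted for. Behavioural timing is compared on the square-root scale.
When every subject contributes one observation per group and there are at
most 14 such subjects, the sign-flip null is enumerated exactly; pairwise
contrasts are Holm-adjusted.

## Problem sizes and numerical choices in the tests

The test suite regenerates everything it needs: 100-seed recovery sweeps
for the behavioural verdict (53 crabs × 3 treatments, so ~40 responding
trials per treatment at the default response probability) and for the
neural verdict (20 neurons × 3 treatments × 6 repeats); 20 000 uniform
samples for the Rayleigh type-I sweep; 10 000 replicates for the
dispersion-test calibration; 1000 random trains for conservation; 500 step
trains for onset localisation; 50 trains per contrast level for the
direction-of-effect check. Rate grids use 10 ms steps in the sweeps and
1–5 ms elsewhere; the spontaneous span is shortened to 5 s in the sweeps
(it only needs to be long enough for a stable baseline, ≥ 10 FWHM).
These sizes are the package's chosen balance between statistical
resolution and runtime.

## Known limitations

* The generators are the only data source; no reader for proprietary
  acquisition formats is provided (plain CSV only).
* The dispersion test is asymptotic; for very small groups (n < 10 or so)
  its chi-square calibration degrades, which is why the implementation
  refuses groups below n = 5.
* The behavioural verdict assumes the stimulus frame has been established
  (first stimulus at 0°); data recorded in other frames must be rotated
  first, as the original analyses did.
* Under a genuinely mixed strategy (`attention_mode = "mixed"`), the
  transformed-mean rule returns whichever mechanism dominates; it does not
  estimate the mixing fraction.
* The neural decision requires receptive-field asymmetry to separate
  select-stronger from average; with uniform fields it reports
  inconclusive by design, mirroring the fact that single-unit data cannot
  distinguish those rules there.
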