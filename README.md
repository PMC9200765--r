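# loomattend

Escape decisions and looming-sensitive neuronal responses under single and
paired threats.

When two predators approach an animal at once, it can *selectively attend*
to one (escape directly away from it, suppressing the other) or *divide
attention* (escape in the direction that maximises the distance from
both). `loomattend` implements the full computational chain used to
separate these mechanisms in fiddler-crab-style experiments, for
researchers in neuroethology and sensory neuroscience:

* **Stimulus kinematics** — a disk of diameter *D* approaching at speed
  *v* subtends `θ(τ) = 2·atan((D/2)/(v·τ))` at time-to-collision *τ*
  (capped at 180° once the object reaches the eye), with the analytic
  expansion rate `θ′ = 2Rv/(d² + R²)`, Weber contrast
  `(L_stim − L_bg)/L_bg`, and a display-linearisation look-up table.
* **Circular statistics from first principles** — mean direction and
  resultant length ρ, Rayleigh test (`Z = nρ²` with the standard series
  p-value), a Rao-type chi-square test of dispersion homogeneity, the
  multimodal transform (angles ×4 or ×2 mod 360, which maps the two
  selective escape modes onto one direction and the divided mode 180°
  away), bootstrap CIs for circular means, a green/white/red 45° sector
  scheme with an exact/permutation proportion test, and 90°
  body-orientation bins.
* **Spike-train quantification** — instantaneous firing rate by Gaussian
  kernel (FWHM 200 ms) rescaled so its integral equals the spike count,
  spontaneous mean and SD, onset at the first sustained crossing of
  mean + 2 SD, peak and average rate over the response window.
* **Decision procedures** — `behavioral_decision()` (selective vs divided
  from a trial table), `neural_decision()` (select-stronger vs sum vs
  average integration from per-neuron metrics), `orientation_effect()`
  (per-bin circular summaries) and `timing_comparison()`
  (subject-stratified permutation tests on square-root-scale timing).
* **Seeded synthetic data** — von Mises mixture escape tables with
  body-axis and contrast choice biases, and inhomogeneous-Poisson spike
  trains driven by the looming expansion rate under a configurable
  integration rule, so the whole pipeline is testable without external
  recordings.

Everything is tidyverse-native: functions take a data frame first, return
tibbles, and results support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(loomattend)

# the behavioural stimulus: 30 mm disk, 200 mm/s, from 5000 mm
s <- looming_stimulus()
collision_time(s)
#> [1] 25
head(stimulus_trace(s, dt = 5), 3)
#>   time_to_collision_s angular_diameter_deg expansion_rate_deg_s
#> 1                  25                0.344               0.0138
#> 2                  20                0.430               0.0215
#> 3                  15                0.573               0.0382

# a synthetic behavioural experiment: 50 crabs, Single / Paired90 / Paired180
trials <- gen_escape_trials(default_treatments(1), n_crabs = 50, seed = 2026)
rep <- behavioral_decision(trials, seed = 1)
rep
#> <attention_report>
#>   behavioural verdict: selective
#>   per-treatment:
#>   treatment verdict   rayleigh_p_trans dist_selective dist_divided
#> 1 Paired180 selective         3.59e-11           6.49         174.
#> 2 Paired90  selective         5.84e- 3           9.68         170.

# a synthetic 17-neuron population generated under the max rule
pop <- gen_spike_population(17, spike_params(integration_rule = "max"),
                            seed = 2026)
metrics <- analyze_spike_trains(pop, dt = 0.01, pool_reps = TRUE,
                                window_per = "neuron")
neural_decision(metrics, seed = 2)
#> <neural_report>
#>   verdict: select_stronger (best select_stronger vs runner-up average,
#>            gap CI [0.265, 0.971])
#>   rule            median_error mean_rank
#> 1 select_stronger        0.102      1.21
#> 2 average                0.191      1.85
#> 3 sum                    0.618      2.94
```

The first table says the initial subtense of the simulated predator is
0.34° and its expansion accelerates toward collision. The behavioural
verdict is `selective`: after the ×4/×2 transform both paired distributions
are significantly directional (Rayleigh p ≪ 0.05) with mean directions
within ~10° of the transformed selective target and ~170° from the divided
target. The neural verdict is `select_stronger`: across neurons the
max-of-singles prediction has the smallest error (median 10%) and its rank
advantage over the runner-up excludes a tie.

`run_attention_pipeline(run_config(seed = 7))` runs the whole chain —
generate, analyse, decide — and writes the trial table, spike files and a
JSON report with a provenance block; the same config and seed give a
byte-identical report.

## Package layout

* `R/stimulus.R` — looming geometry and photometry
* `R/circstats.R` — circular statistics primitives
* `R/synthetic-behavior.R`, `R/synthetic-spikes.R` — seeded generators
* `R/spike-analysis.R` — kernel rates, baselines, onsets, metrics
* `R/attention-behavior.R`, `R/attention-neural.R` — decision procedures
* `R/io.R`, `R/pipeline.R` — CSV/YAML/JSON formats and the end-to-end run
* `vignettes/loomattend-methods.Rmd` — the model, its assumptions, and
  every tunable parameter with units and defaults
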