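# synapseflux

Quantification pipelines for the assays used in adult-onset *Drosophila*
models of amyloid-beta (Aβ42) neurotoxicity:

* **Glutamate imaging** — iGluSnFR fluorescence traces from the larval
  ventral nerve cord are normalized to ΔF/F = (F~t~ − F₀)/F₀ (F₀ = minimal
  recorded fluorescence), and glutamate release events are detected as
  supra-threshold transients (ΔF/F > 0.1). A continuous transient with ≥ 2
  peaks is a *burst*, terminated at the first frame back within 0.2 ΔF/F of
  its rising onset and scored by its highest peak. Per-animal mean
  amplitudes and event rates feed a one-way ANOVA with Tukey HSD.
* **NMJ immunofluorescence** — confocal Z-stacks are rigidly registered,
  maximum-intensity projected, background-harmonized to a common zero level,
  and quantified as per-slice mean ROI intensity averaged per NMJ.
* **Behaviour** — the negative-geotaxis performance index
  PI = ½·[N(top) + N(middle) + N(bottom) + N(top) − N(bottom)] / N(total)
  after a 20-s climb with 5/15/5-cm zones.
* **Lifespan** — Kaplan–Meier curves, two-group log-rank tests, and a
  stratified permutation test for genotype × induction interaction in the
  2×2 (e.g. RU0/RU200) design.
* **Synthetic data** — seeded generators for fluorescence traces (with
  ground-truth events), jittered image stacks (with ground-truth shifts),
  Weibull survival cohorts with known hazard ratios, and trinomial climbing
  counts, so every stage is testable without external data. Experiment
  runners (`run_glutamate_experiment()`, `run_survival_experiment()`)
  orchestrate simulate → detect → summarize → test end to end with
  bit-reproducible run directories.

Intended users: fly labs quantifying synaptic and organismal Aβ phenotypes,
and method developers who need a fully seeded, ground-truthed reference
implementation of these assay statistics.

## Worked example

Simulate one iGluSnFR trace (0.92 frames/s, events of ~0.5 ΔF/F), detect and
summarize its glutamate transients:

```r
library(synapseflux)

sim <- simulate_trace(trace_sim_params(seed = 42),
                      animal_id = "a1", condition = "ab42")
dff <- compute_dff(sim$trace)
dff
#> <dff_trace> 300 frames @ 0.92 Hz, F0 = 95.17, max dF/F = 1.03

tr <- detect_transients(dff)   # threshold 0.1, offset band 0.2
tr
#> <glut_transients> 20 transient(s) (2 burst(s)) over 300 frames
#>  onset_frame scored_peak_frame offset_frame scored_amplitude n_peaks is_burst
#>           19                21           24        0.5527941       1    FALSE
#>           48                50           54        0.6985076       1    FALSE
#>           88                96          100        0.8289257       3     TRUE
#>          112               117          119        1.0274986       2     TRUE
#>  ...

summarize_trace(tr, dff, animal_id = "a1", condition = "ab42")
#>   roi_id animal_id condition n_transients n_bursts mean_amplitude events_per_min
#> 1   roi1        a1      ab42           20        2      0.4215552           3.68
```

The trace holds 20 supra-threshold transients (two of them multi-peak
bursts, e.g. 3 peaks around frames 88–100 scored by their highest peak,
0.83 ΔF/F); at 0.92 frames/s the 300-frame recording spans 5.4 min, giving
3.68 events/min. Several of the low-amplitude detections (~0.11–0.14) are
noise excursions past the 0.1 threshold — see the methods vignette for the
signal-to-noise regime in which such false events vanish.

Survival and climbing statistics work from plain data frames:

```r
a <- data.frame(day = c(2, 4, 6), censored = c(FALSE, FALSE, TRUE))
b <- data.frame(day = c(4, 5, 9), censored = c(FALSE, FALSE, FALSE))
logrank_test(a, b)
#> Log-rank test: chi-square = 0.1615 on 1 df, p = 0.6877

performance_index(32, 11, 7)   # 32 top, 11 middle, 7 bottom
#> [1] 0.75
```

With 50 flies scored as 32/11/7 in the top/middle/bottom zones the
performance index is 0.75 — halfway between a balanced population (0.5) and
perfect climbing (1.0).

## Package layout

* `R/simulate.R`, `R/evaluate.R` — synthetic-data generators and recovery
  scoring
* `R/trace-events.R` — ΔF/F, event/burst detection, per-animal summaries
* `R/image-quant.R` — registration, projection, background harmonization,
  ROI means, TIFF I/O
* `R/survival-stats.R` — PI, Kaplan–Meier, log-rank, permutation tests,
  ANOVA + Tukey
* `R/pipeline.R` — experiment configs and end-to-end runners
* `vignettes/synapseflux-methods.Rmd` — models, rules, design decisions and
  limitations
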