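# fatiguelab

Physiology-driven labeling of mental fatigue for driver monitoring.

When a driver performs a long, monotonous task, fatigue is conventionally
labeled by **time-on-task (ToT)**: the beginning of the task is "low
fatigue", the end is "high fatigue" — the same windows for everyone. But
fatigue progresses differently across individuals, and when a driver's
drowsiest period falls mid-task, ToT labeling washes out the physiological
contrast between conditions. `fatiguelab` implements the individualized
alternative: label each subject's low/high-fatigue periods from their own
EEG via the **MDrow** drowsiness index, then measure how much larger the
low-vs-high contrasts become in independent channels — eyeblinks and heart
activity. It is aimed at researchers analyzing multimodal driver-physiology
recordings (EEG + PPG) or prototyping fatigue-detection pipelines against
synthetic ground truth.

## The index at the core

Parietal alpha power rises as vigilance falls and peaks during eyes-closed
rest. MDrow normalizes task alpha to that individual ceiling:

```
MDrow = alpha GFP task / max(alpha GFP rest)
```

where the alpha band is the individual alpha frequency ± 1 Hz (estimated
from a 1-min eyes-closed recording), GFP is the per-epoch mean of
Hanning-tapered band power over the parietal channels Pz/P3/P4, and the
per-second series is stabilized over 60-s windows every 15 s. Values near
or above 1 mean "as drowsy as eyes-closed rest".

Around the index, the package provides the full pipeline:

* EEG cleaning: zero-phase 50 Hz notch + 2–40 Hz band-pass, 1-s epochs,
  ±200 µV rejection, blink-epoch exclusion;
* eyeblink detection on AFz (rate / duration / amplitude per window);
* PPG processing: 0.4–4 Hz band-pass, AMPD beat detection, ±2 SD inter-beat
  interval correction, heart rate and Lomb–Scargle LF/HF/HRV;
* EEG-driven vs ToT labeling on the straight-road repetitions of the task,
  baseline normalization, and a paired comparison harness (Shapiro–Wilk
  gate, t/Wilcoxon, Cohen's d, Holm–Bonferroni);
* a synthetic-data generator (`simulate_session()`, `simulate_cohort()`)
  with known fatigue trajectory, blink events and inter-beat intervals, so
  every stage is testable against ground truth.

Signal I/O supports CSV (lossless, canonical) and EDF recordings, TSV event
schedules, and JSON result records.

## Worked example

Simulate one 45-min session whose alpha surge (ground truth: segment 3 of 8)
is coupled to a +4 bpm heart-rate rise, then run the EEG-driven pipeline:

```r
library(fatiguelab)

cfg <- sim_config(seed = 7, hr_surge_bpm = 4)
session <- simulate_session(cfg, seed = 7)
session$truth$trajectory$peak_segment
#> [1] 3

result <- run_pipeline(session, approach = "EEG")
result$iaf
#> [1] 10
result$labels
#> # A tibble: 2 x 4
#>   condition segment t_start_s t_end_s
#>   <chr>       <int>     <dbl>   <dbl>
#> 1 Low             5      1380    1440
#> 2 High            3       720     780
```

The EEG-driven labeling finds the planted surge: segment 3 is labeled high
fatigue (a ToT labeling would have picked segments 7–8). The feature panel
shows why that matters — heart rate (baseline-normalized, bpm) and MDrow in
the two conditions:

```r
subset(as.data.frame(result$features), feature %in% c("HR", "MDrow"))
#>    feature condition      value   raw_value baseline
#> 4       HR       Low 0.02808043 70.17543860 70.14736
#> 8    MDrow       Low 0.04109479  0.04109479       NA
#> 12      HR      High 2.95598366 73.10334182 70.14736
#> 16   MDrow      High 0.39264228  0.39264228       NA
```

In the high-fatigue window the heart rate is ~3 bpm above baseline and MDrow
is ~10× its low-fatigue value; under ToT labels the HR contrast would be
near zero because segments 7–8 miss the surge. Across a cohort,
`result_panel()` + `compare_conditions()` turn these panels into paired
effect sizes per feature (with `tidy()`, `glance()` and `autoplot()`
methods), and `plot_labels(result$mdrow, result$labels)` shows the labeled
windows over the MDrow trace.

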