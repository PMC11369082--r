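# vasodyn

Timing analysis of neurovascular and hypercapnic vascular responses.

A brief, strong CO2 challenge (10 s at 20%) and whisker stimulation probe
different cerebrovascular reflexes, and telling them apart is a question of
*when* things happen: after CO2 onset, hyperventilation (~1.8 s), an
intravascular pH drop (~2.0 s) and an arteriolar velocity dip (~2.9 s) all
precede arteriole dilation (~5.8 s) and the late rise of blood flow
(π R² v). Neurovascular coupling (NVC) dilates the same vessels within a
second of whisker stimulation, and if it depended on CO2, a CO2 load should
occlude it — whereas linear addition of the two responses argues it does
not.

`vasodyn` is an R package for scientists analysing this kind of
experiment. It implements the full measurement chain on synthetic data with
known ground truth, so every estimator is testable end to end:

- **Synthetic generators** (`gen_response_trace`, `gen_kymograph`,
  `gen_dual_channel_ph`, `gen_thermocouple`, `gen_bp_waveform`,
  `gen_fus_ensemble`, `gen_paired_trialset`) — seeded, bit-reproducible,
  each returning its ground truth alongside the data.
- **Kymograph velocimetry and diametry** — line-scanning PIV
  (`lspiv_velocity`), streak-angle search (`streak_angle_velocity`),
  FWHM diameter (`diameter_fwhm`, `diameter_timeseries`), lumen area from
  movies (`lumen_area_timeseries`), frame realignment, ΔF/F.
- **Trace statistics** — baseline z-score `z = (x − μ)/σ` over a 9 s
  baseline, 0.1 s trial averaging, trapezoidal AUC, blood flow
  `π (D/2)² v`, respiratory rate from inhalation deflections,
  beat-wise blood-pressure features.
- **Onset timing** — nonlinear least-squares response fits
  (`fit_response`) and the 10%-of-peak rule (`onset_from_fit`), plus a
  sustained 10%-over-baseline rule (`onset_above_baseline`).
- **Ratiometric pH** — background-subtracted channel ratio
  (`fluorescence_ratio`), sigmoid calibration
  `FR = α_sys (R_Range/(1+e^{α_pH (pH − pKa)}) + R_Cte)`
  (`fit_ph_calibration`), per-recording range anchored to blood pH 7.4
  (`r_range_from_baseline`), and closed-form inversion (`ph_from_ratio`).
- **Functional ultrasound** — SVD clutter filtering with exact energy
  accounting (`svd_clutter_filter`), power Doppler (`power_doppler`),
  slow/fast axial-velocity band separation via `f = 2 v f0 / c`
  (`velocity_band_filter`), ΔPD/PD responses and activation maps.
- **Additivity (occlusion) testing** — calculated summation of component
  responses, AUC-window comparison, exact small-sample Wilcoxon tests
  (`calculated_summation`, `compare_summation`, `wilcoxon_test`).

## Worked example

```r
library(vasodyn)
res <- run_demo(list(seed = 1, out_dir = "demo_out"))
res$onsets
#>     parameter onset_true onset_fit      peak converged
#> 1 respiration        1.8  1.845621  4.819944      TRUE
#> 2          ph        2.0  2.046442 -4.738873      TRUE
#> 3    velocity        2.9  2.916919 -5.035930      TRUE
#> 4    dilation        5.8  5.914445  4.912729      TRUE
res$ph$delta_ph
#> [1] -0.1577193
res$verdict
#> [1] "additive"
```

The demo generates one synthetic experiment (stimulus at 10 s), fits each
modality's response and reports the 10%-of-peak onsets next to the
latencies that generated the data: respiration and pH respond first,
velocity next, dilation last — the timing signature at the heart of the
analysis. The pH chain recovers the programmed ~0.15-unit acidification,
and the paired-stimulation comparison (experimental trials vs calculated
summation, Wilcoxon signed-rank over AUCs at 10–17 s) finds no departure
from additivity, as constructed. Reports (`onsets.csv`, `additivity.csv`,
`summary.json`, stamped with seed and config hash) are written to
`out_dir` and are bit-identical across reruns with the same seed.

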