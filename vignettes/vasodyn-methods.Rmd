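---
title: "Methods: timing analysis of neurovascular and hypercapnic responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing analysis of neurovascular and hypercapnic responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasodyn)
```

## Scientific setting

Brief, strong hypercapnia (10 s of 20% CO2 at the nostril, "briefCO2") and
whisker stimulation (5 Hz, 5 s) probe two different cerebrovascular reflexes.
Distinguishing them hinges on *timing*: after CO2 onset, hyperventilation
starts at ~1.8 s, intravascular pH drops at ~2.0 s, arteriolar red-blood-cell
velocity dips at ~2.9 s, and arteriole dilation follows only at ~5.8 s, with
blood flow (\(\pi R^2 v\)) exceeding baseline around 7.5 s. Neurovascular
coupling (NVC), by contrast, dilates vessels within a second of whisker
stimulation. If NVC depended on CO2, a CO2 load should saturate ("occlude")
it; if not, CO2 and whisker responses should add linearly.

`vasodyn` implements the full quantitative chain needed to make these
measurements reproducible on synthetic data with known ground truth: signal
generators, kymograph velocimetry and diametry, trace normalisation, fit-based
onset timing, the ratiometric pH chain, functional-ultrasound (fUS)
slow-time processing, and the additivity (occlusion) test.

## The response model

All stimulus-locked responses share one parametric family, a gated
double-exponential

\[
r(t) = A \,\frac{(1 - e^{-(t-t_0)/\tau_r})\, e^{-(t-t_0)/\tau_d}}{h^\ast},
\qquad t \ge t_0; \qquad r(t) = 0,\; t < t_0,
\]

with onset \(t_0\), signed amplitude \(A\) (negative for velocity dips and
GCaMP/pH decreases), rise and decay constants \(\tau_r, \tau_d\), and
\(h^\ast\) the peak height so \(A\) is the baseline-to-peak deviation. The
peak lag has the closed form \(\tau_r \log(1 + \tau_d/\tau_r)\). We chose
this family over logistic-difference shapes because it is *exactly zero
before onset* — the property the generators guarantee and the onset
estimators are validated against — while keeping few parameters and
representing monophasic dilations, dips, and fluorescence drops equally well.
The in-vivo model functions underlying the original analyses are not
publicly specified, so this family is a documented stand-in: recovery tests
against it validate the fitting/thresholding machinery, not the true shape
of cortical hemodynamic responses.

`fit_response()` fits \(b_0 + r(t)\) by Levenberg–Marquardt over a
deterministic multi-start grid (latency 1/3/5/8 s after the stimulus,
\(\tau_r\) 0.5/1/2 s, amplitude initialised at the post-stimulus extremum);
ties resolve by lower residual, then earlier latency. Fits with
\(|A| < 2\) z are flagged `no_response`. `onset_from_fit()` applies the
10%-of-peak rule: the earliest time the fitted deviation from its baseline
reaches 10% of the peak deviation. We measure the 10% threshold from the
*fitted baseline*, not from zero — the only reading invariant to baseline
offsets — and treat decreasing responses by sign, never by flipping data.
`onset_above_baseline()` implements the alternative raw-trace rule
(crossing of baseline ±10%, or 10% of peak deviation for z-traces) with a
0.5 s sustained-crossing requirement that rejects transient vasomotion
excursions.

## Normalisation conventions

Vessel diameter fluctuates spontaneously at ~0.1 Hz (vasomotion), so traces
are z-scored against a 9 s baseline (the [1, 10) s window of a recording
with the stimulus at 10 s): \(z = (x - \mu_{base})/\sigma_{base}\), with the
sample (n−1) SD — the convention is documented here because it is not
otherwise fixed. Trials are averaged after linear interpolation onto a 0.1 s
grid. AUC is a trapezoidal integral; blood flow is \(\pi (D/2)^2 v\) in
µm²·mm/s. Windows are half-open \([t_1, t_2)\); times are seconds from
recording start.

## Ratiometric pH chain

The pH-sensitive red dye brightens with acidity; the green reference does
not. The chain is: (1) background-subtracted channel ratio
\(FR = (F_{red}-F_{red,bg})/(F_{green}-F_{green,bg})\); (2) calibration
sigmoid \(FR = \alpha_{sys}(R_{Range}/(1+e^{\alpha_{pH}(pH-pKa)}) +
R_{Cte})\) fitted to a plasma lookup table with \(\alpha_{sys}\) fixed (an
instrument constant, never re-fit per recording); (3) per-recording dynamic
range \(R_{Range}\) anchored to an assumed baseline blood pH of 7.4; (4)
closed-form inversion to pH. Samples whose ratio leaves the sigmoid gamut
(clipped transients) are masked NA and counted, not clipped or fatal. The
default coefficients (\(\alpha_{pH} = 2.64\), \(pKa = 7.47\),
\(R_{Cte} = 0.32\)) are the plasma-calibration values used throughout the
examples; the calibration table's own \(R_{Range}\) is not published, so
synthetic tables default to 1.0 (it cancels from the per-recording chain,
which always recomputes \(R_{Range}\) from the baseline ratio).
`delta_ph_summary()` smooths with a 1 s running mean before taking the
extremum, since a pointwise minimum of a noisy trace is biased low by
extreme-value statistics.

## Kymograph velocimetry and diametry

Line scans along a vessel render moving red blood cells as oblique streaks
(dark Gaussian shadows, ~2 px wide, on bright plasma in the generator);
the streak slope encodes velocity, positive towards increasing column
index. Two estimators are implemented and cross-validated against each
other (they agree within 10% across 0.2–10 mm/s on synthetic data):

- **LSPIV** (`lspiv_velocity`): normalised cross-correlation of 25-line
  blocks at 50% overlap, with the correlated groups separated by 4 scan
  lines and the peak refined by 3-point *Gaussian* interpolation. The
  separation and the Gaussian (rather than parabolic) peak fit are what
  keep slow flows (≤0.5 mm/s, sub-pixel per-line displacement) within 5% of
  truth; peaks on the search boundary are flagged unreliable, never
  silently clipped.
- **Streak angle** (`streak_angle_velocity`): shear-projection search
  (Radon-style) maximising the variance of column sums, coarse grid then
  golden-section refinement, with linear-interpolated fractional shears. An
  anisotropy score (max/mean variance contrast) below 2 raises a no-flow
  error: white noise scores below ~1, genuine streaks above 10.

Diameter comes from full-width-at-half-maximum of transverse profiles with
sub-pixel linear interpolation at the two crossings; the background level is
the mean of the outer 10% of the profile and the plateau is the 95th
percentile of the lumen core (the band above 80% of the background-to-peak
range) — robust to streak-induced dips without widening sharp profiles.
Penetrating-vessel lumen area uses Otsu thresholding computed once on the
baseline mean image and held fixed (so threshold drift cannot masquerade as
dilation), largest connected component, hole filling, and equivalent
diameter \(2\sqrt{A/\pi}\). Frame realignment is integer-pixel
cross-correlation against the first frame's ROI; sub-pixel registration is
deliberately out of scope.

## Functional ultrasound

Slow-time ensembles (default 500 Hz frame rate, 15 MHz centre frequency)
are clutter-filtered by removing the leading singular components of the
Casorati matrix — 40 components at the acquisition scale of ≥400 frames,
scaled proportionally for the shorter ensembles used in tests. The filter
is an orthogonal projection, so the energy split input = kept + removed is
exact (Parseval), and reapplying the *same* projection (via the returned
`clutter_basis`) is exactly idempotent; re-estimating the basis on filtered
data would remove fresh blood components instead, which is why the basis is
exposed. The filter operates on the raw Casorati matrix by default: per-voxel
mean removal would break the stated energy identity, and the DC/tissue mean
is captured by the leading singular components in any case (`center = TRUE`
is available, with the mean counted as removed energy).

Power Doppler is the per-voxel slow-time mean square; its time series uses
0.4 s windows at 50% overlap (the original windowing is unstated; this is
our documented default), optionally smoothed by a zero-phase fifth-order
Butterworth low-pass. Zero-phase (forward–backward) filtering is used
everywhere because the study's conclusions rest on onset timing, which
causal filtering would delay; filters are applied to mean-removed series so
edge transients act on fluctuations, not on the DC power level. Axial
velocity bands map to Doppler frequency via \(f = 2 v f_0 / c\) with
\(c = 1540\) m/s (19.5 Hz per mm/s at 15 MHz, within 3% of the 20 Hz per
mm/s implied by the 0.5–1.5 mm/s ↔ 10–30 Hz band pairing): "slow" CBV is
the 10–30 Hz band-pass, "fast" the >60 Hz high-pass. ΔPD/PD uses the same
9 s baseline convention.

## Additivity (occlusion) analysis

`calculated_summation()` forms \(a(t) + b(t - lag)\) on a 0.1 s grid with
zero-padding outside \(b\)'s support; `compare_summation()` integrates both
the experimental paired-stimulus trials and the calculated reference over
the analysis window (10–17 s for simultaneous stimuli; 12–19 s when the
whisker train is delayed 2 s) and applies a Wilcoxon test to the per-trial
differences. Both signed-rank (paired, the default) and rank-sum modes
exist: the original analysis names a rank-sum test for paired data, and the
discrepancy is surfaced here rather than hidden. Exact permutation nulls
are used for n ≤ 25 without ties, the continuity-corrected normal
approximation otherwise.

Two comparison designs are supported, mirroring the open question of
whether AUC should be taken per trial or on averages:

- **Averaged reference** (a single calculated trace from trial-averaged
  components): matches the figure-level analysis, but the reference's own
  Monte-Carlo error is a *common offset* across trials, which inflates the
  signed-rank type-I rate above nominal.
- **Trial-wise pairing** (each experimental trial against a calculated
  trace built from held-out single component trials): under additive ground
  truth the paired differences are exactly symmetric about zero, so the
  test holds its nominal level — this is the design used for the detector
  calibration checks.

`gen_paired_trialset()` generates complete synthetic occlusion
experiments: a fast whisker-like component (peak 8 z, \(\tau_d\) 4 s, onset
0.8 s after its stimulus) and a slow hypercapnic component (peak 5 z,
\(\tau_d\) 10 s, onset 5.8 s), 8 experimental trials (matching the study's
n = 8 vessels), and 24 component trials for the averaged reference
(approximately 8 vessels × 3 stimulations). Occlusive ground truth is the
pointwise maximum. Detection power depends on where the two responses
overlap: in the simultaneous (lag 0) design the hypercapnic dilation barely
enters the 10–17 s window, so occlusion there is weakly identifiable; the
delayed (lag 2) design, whose 12–19 s window covers the overlap, is the
condition under which the detector is required to reach ≥90% power.

## Synthetic data: what it does and does not emulate

Generators produce every input the pipeline consumes, with ground truth
(and the seed) recorded alongside, and are bit-reproducible under a fixed
seed. They emulate: 0.1 Hz vasomotion on baseline diameter; stimulus-locked
responses with known onset, exactly zero before it; RBC streak kymographs
of known velocity (circular streak recycling keeps density stationary);
two-channel pH recordings through the forward sigmoid; thermocouple
inhalation deflections by phase accumulation (intervals follow the
instantaneous rate); arterial pulse waveforms with exact per-beat
systolic/diastolic extrema; and tissue+blood fUS ensembles in which tissue
has exactly the requested rank (singular values scaled so `tissue_amp` is a
per-sample RMS amplitude) and each blood component oscillates at its
Doppler frequency with random per-voxel phase.

Noise is additive Gaussian throughout (no noise model is specified for the
original data). Not emulated: optical point-spread functions, RBC rheology,
acoustic propagation/beamforming, motion artefacts, and real response-shape
families — so green tests demonstrate the correctness of the estimators
against their own forward models, not performance on in-vivo data.

## Numerical choices

- Nonlinear least squares: Levenberg–Marquardt (`minpack.lm`), time
  constants fitted in log space with bounds \(\tau_r \in [0.05, 20]\),
  \(\tau_d \in [0.5, 120]\) s; tight tolerances (1e-14) so noiseless
  self-consistency recoveries are exact to ~1e-6 relative.
- Calibration starts: pKa at the median calibration pH, slope 2, offset
  min(FR)/\(\alpha_{sys}\); at least 5 points required, spanning the
  inflection.
- The 10%-crossing is located by `uniroot` on the fitted curve between the
  stimulus and the peak (tolerance 1e-9); fraction 1 returns the closed-form
  peak time.
- Peak/valley detection uses a hand-rolled prominence rule (no installed
  package provides one): default prominence 20% of signal range, minimum
  separation 100 ms for blood pressure and 80 ms for respiration, with a
  ~30 ms running mean before valley detection on thermocouple traces.
- Degenerate inputs raise classed errors (`vasodyn_aliasing`,
  `vasodyn_no_vessel`, `vasodyn_degenerate_baseline`, ...) rather than
  returning silent NAs; the single exception is pH gamut clipping, which
  masks per-sample because transients legitimately clip.

Problem sizes in the test suite are scaled to desk conditions and stated
as such: 256–512-frame fUS ensembles on 8×8 grids (with the 40-component
rule scaled proportionally), 0.1–1 s kymographs, 100 replicate onset
recoveries per condition, 500 additive and 100 occlusive replicate
experiments for the detector calibration.

## Known limitations

On-disk ensembles use multi-page float TIFF (+ JSON metadata sidecars)
rather than HDF5. The response family is a stand-in (above). Anatomical
ROIs, beamforming, microbubble localisation, calcium hot-spot detection and
3-D reconstruction are out of scope. The Wilcoxon naming discrepancy for
paired data is resolved in favour of the signed-rank test by default.

## A worked example

```{r, eval = FALSE}
res <- run_demo(list(seed = 1, out_dir = "demo_out"))
res$onsets          # per-modality fitted onsets vs generating latencies
res$verdict         # additivity verdict for the paired experiment
```
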