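---
title: "BulbFeedback: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BulbFeedback: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(BulbFeedback)
```

This vignette documents the science implemented by the package: the
circuit model and its assumptions, the imaging and photometry statistics,
the synthetic-data generator that stands in for raw recordings, and the
numerical and design decisions taken where more than one reasonable choice
existed.

# The two-population circuit model

The olfactory bulb's output neurons (mitral and tufted cells, treated as
one excitatory population MC) and its dominant inhibitory interneurons
(granule cells, GC) are modeled as reciprocally coupled rate units with
unit time constants:

$$\dot{MC} = -MC + I - w\,GC - w_{fb}\,FB$$
$$\dot{GC} = -GC + w\,MC - w_{sac}\,SAC - 2\,w_{fb}\,FB, \qquad GC \ge 0$$

* `I` — odor drive onto MC/TC (default 10). Together with `wSacGc` it
  shifts basal rates but not the nullcline slopes, so results are
  qualitatively insensitive to both; defaults were chosen once to put the
  baseline MC/TC rate in the physiological range (~10–15 Hz equivalent)
  and are exposed as arguments.
* `w` (`wMcGc`) — reciprocal MC/TC–GC coupling (default 0.3, the
  illustrated regime in which both baseline rates are physiological).
* `w_sac` (`wSacGc`) — dSAC inhibition of GCs (default 1).
* `w_fb` (`wFbMc`) — feedback strength onto MC/TC. The feedback synapses
  are about twice as strong on GCs, so the GC term is fixed at `2*wFbMc`
  and never an independent parameter.
* `FB` — 0/1 stimulation indicator. With feedback on, the dSAC drive is
  `SAC = 0.1 / wFbMc` (stronger feedback shunts more of the dSAC input to
  GCs); without, `SAC = 1`. The constant 0.1 is treated as a fixed model
  constant. Because of it, `feedbackDelta()` at `wFbMc = 0` is defined as
  `(0, 0)` by convention — the limit for vanishing positive strength does
  not exist, since the shunting term diverges.

**Sign of the GC nullcline.** Setting the GC equation to zero gives
`GC = w*MC - w_sac*SAC - 2*w_fb*FB`, i.e. the GC nullcline *rises* with
MC; the package implements this sign (a minus sign on the MC term would
make the nullcline fall and contradict the phase-plane geometry in which
the two curves cross at a stable equilibrium).

**Rectification.** Only the GC rate is clamped at zero; MC is left
unconstrained (a warning is emitted if it goes negative, which only
happens far from the regimes of interest). On the rectified branch the
fixed point is `GC = 0`, `MC = I - w_fb*FB`, and it still satisfies both
rectified nullclines exactly.

**Numerics.** The linear branch has Jacobian `[[-1, -w], [w, -1]]` with
eigenvalues `-1 ± i w`: every parameter set is a stable focus, so no
stability search is needed. Integration uses forward Euler with default
`dt = 0.01` (stable for `dt < 2/(1 + w^2)`, i.e. any coupling below ~14 at
the default step); a divergence guard at 1e6 rate units catches
pathological use. `solveFixedPoint()` is closed-form; the test suite
verifies integration against it at 1e-6 relative tolerance over hundreds
of random parameter sets.

**Joint inhibition and its saturation.** At the reference regime
(`I = 10, w = 0.3, w_sac = 1, w_fb = 1`) feedback lowers both rates
(ΔMC ≈ −0.615, ΔGC ≈ −1.284). |ΔMC| grows strictly with `w_fb`. |ΔGC|
grows strictly only while the stimulated GC fixed point remains positive;
at this coupling the GC rate rectifies to zero near `w_fb ≈ 1.3`, beyond
which the GC population is fully silenced and ΔGC saturates at minus the
baseline GC rate. The tests assert exactly this behavior rather than
unconditional strict growth, which the rectified model cannot produce.

# Two-photon pipeline

The processing order is: out-of-plane frame QC on the raw stack, then
lateral registration, then PCA reconstruction (used to identify and refine
ROIs), with trace quantification on the raw registered data — PCA never
modifies fluorescence inside ROIs.

* **Out-of-plane detection.** Each frame is correlated (Pearson, zero
  spatial lag) with the average projection of the entire stack, computed
  once from all frames; frames at or below `r = 0.65` are flagged. The
  comparison is evaluated at zero lag because lateral motion is handled by
  the registration step; low correlation then specifically indicates a
  change of imaging plane. Constant frames (undefined correlation) are
  flagged with a message.
* **Registration.** Translational only, estimated by FFT
  cross-correlation in two passes: first against the plain kept-frame
  average, then against a reference rebuilt from the frames sharing the
  modal first-pass shift. The second pass matters when a large fraction of
  frames drifted: the plain average then contains several displaced copies
  of the anatomy and per-frame estimates become ambiguous at the 1-px
  level, whereas the modal subset is mutually aligned and yields a single
  sharp reference. Estimates are refined to subpixel precision by a
  3-point parabolic fit of the correlation peak; applied shifts are
  integer (no interpolation of pixel data), reported shifts keep the
  fraction. Frames whose shift exceeds 10% of the frame size are flagged
  not-kept instead of shifted.
* **PCA reconstruction.** Frames (kept only) are reshaped to time ×
  pixels, centered per pixel, and projected onto the leading 10 left
  singular vectors via the time × time Gram matrix; the pixel means are
  added back. Centering per pixel is the standard choice and makes the
  projection idempotent (the top-k subspace of a projected stack is
  itself). Movies of rank ≤ k are reconstructed exactly.
* **ROI refinement.** A second PCA inside each ROI; pixels whose
  amplitude-weighted loading magnitude on the first 3 components falls
  below 25% of the ROI's maximum are removed. The 25% threshold is a
  package default (exposed as `coefficientThreshold`); it cleanly
  separates cell pixels from signal-free rim pixels in the synthetic
  benchmark. Two guards keep refinement conservative: if the leading
  components explain < 20% of the within-ROI temporal variance (no
  coherent signal — pure neuropil or noise) or the refined mask would drop
  below 3 pixels, the original mask is kept with a warning.
* **Traces and windows.** Traces are mask means per frame; not-kept
  frames are filled by linear interpolation between kept neighbors so
  every trial window keeps its sample count (dropping them would make
  trial averages ragged). Smoothing is a centered 5-frame box with
  shrinking edges. Window means use half-open 1-s intervals
  `[start, start + 1)`, with frame i centered at `(i - 0.5)/rate`;
  baselines end at shutter close and responses start at shutter reopen
  (the shutter times already include the 50-ms pad around the light
  pulse), falling back to stimulus onset/offset for shutterless trials.
* **z statistic.** Implemented exactly as
  `(µ_resp − µ_base)/sqrt(σ²_resp/n − σ²_base/n)` with sample (n−1)
  standard deviations. The minus sign in the radicand makes the statistic
  undefined whenever the baseline window is more variable than the
  response window; in that case `z` is NaN and the conventional pooled
  form with a plus sign is reported as `zFallback`. Classification never
  uses z: it is a two-sided paired t-test on per-trial
  (response − baseline) differences, so labels are unaffected by the
  radicand. Degenerate zero-variance differences map to p = 1 (identical
  windows) or p = 0 (constant nonzero difference, logged).

# Photometry pipeline

Signals are smoothed with a 0.02-s boxcar and decimated to 500 Hz by bin
averaging; the boxcar is the anti-aliasing filter (at 2 Hz its attenuation
is sinc(π·f·0.02) ≈ 0.3%), and no further filter is applied. Per-trial
ΔF/F uses the mean fluorescence over the 2 s before onset as F0 (trials
with non-positive F0 are dropped with a message), which makes the result
invariant to any positive gain of the raw signal. The net light impact is
the mean ΔF/F during the 1-s light window minus the adjacent 1-s window
immediately before; the same operation with a shifted window quantifies
post-light sustained effects, and no-light trials are evaluated at the
same latencies for comparison. Reflected-light QC discards a session when
the mean absolute ΔF/F change of the reflection channel during stimulation
windows exceeds 1% — strictly, so exactly 1% keeps the session (the
comparison includes a 1e-9 relative guard so that a constructed exact-1%
artifact is not discarded through floating-point representation). The
absolute value is used because the artifact's polarity is not constrained.
No statistical test accompanies the threshold.

# Population-vector statistics

Response vectors are averaged z-score responses per cell for one odor
condition. In the *between-odors* design the pair is (odor A vector,
odor B vector) over the cells responsive to both odors; in the
*within-odor* design the same odor's trials are split into two halves
averaged separately, over the cells responsive to that odor. The split is
odd/even trial indices by default — deterministic and exchangeable, since
under the null the two halves are identically distributed — with a seeded
random split as an option. Sessions with fewer than 5 qualifying cells are
excluded (the rule is applied per odor in the within design and on the
dual-responsive set in the between design). Distances are raw Euclidean
norms, not normalized by cell count: the comparison of interest is always
paired across conditions within a session, where the cell set is identical
by construction, so a normalization would cancel. Translation invariance
of the Euclidean distance is the geometric content of the subtractive
prediction: a light effect that subtracts the same amount from every
cell's response moves both odors' vectors by a common offset and leaves
their distance unchanged, whereas a decorrelating effect increases it.
`linearSubtractionFit()` separates the two regimes at the single-cell
level: OLS of odor+light against odor responses (slope 1 and negative
intercept = subtractive; slope < 1 through the origin = divisive), plus
the correlation between the light effect and the odor response magnitude.
Downstream across-session comparisons use a two-sided paired t-test.

# Synthetic data

The generator emulates the statistical structure the analyses assume, with
every injected feature recorded as ground truth and full determinism under
a seed.

* **Protocols.** The two-photon preset is 8 s baseline, 2 s stimulation,
  10 s inter-trial interval in blocks of 20 trials (10 per odorant,
  randomized within block) at 15 Hz over 512 × 512 px; the photometry
  preset is 5-s odors every 60 s with a 1-s light pulse 3.5 s after onset
  (plus a spontaneous-activity pulse at +30 s), 10 repetitions per
  condition at 5 kHz. These presets are the documented defaults; tests and
  the acceptance script use compact variants (2/2/2-s trials, 6 per block,
  128 × 128 px; 20-s photometry periods at 1 kHz) so the suites run in
  minutes — a desk-scale choice of the package, with the timing structure
  (baseline/stim/ITI, light latency inside the odor) preserved.
* **Movies.** Gaussian-disc cells (σ 2.5–4 px) with a static resting
  brightness (so the anatomy is visible in every in-plane frame, as with a
  real indicator), Poisson events whose rates are modulated by each
  cell's condition label (excited: 0.05 → 1.5 Hz during stimulation;
  inhibited: tonic 0.4 Hz suppressed ~50-fold; null: unmodulated tonic),
  convolved with a slow-indicator kernel (0.2 s rise, 1 s decay —
  literature-informed values for a slow GCaMP, not measurements), additive
  background and Gaussian noise, and optional injected lateral drift and
  out-of-plane (noise-only) frames.
* **Window-mean trace sets.** The direct fixture for classification
  calibration: baseline and response window means drawn i.i.d. normal
  (σ = 1) with per-cell response shifts. The documented responsive effect
  size is ±1.5 with 20 trials per condition; since the two windows are
  independent, paired differences have σ√2 and noncentrality
  1.5·√(20/2) ≈ 4.74, giving a noncentral-t power of ≈ 0.96 at α = 0.01 —
  the oracle against which the Monte-Carlo power is checked (the ≥ 0.8
  requirement holds with a wide margin).
* **Photometry sessions.** Odor-evoked ΔF/F transients (exponential rise
  to a 0.2 plateau during the odor, 1-s decay after) with multiplicative
  suppression of the evoked component during in-trial light windows, at
  levels assigned to the odor+light trials in order and recorded; the
  reflection channel is flat except for an optional injected artifact of a
  stated percentage, for QC tests.

**What passing tests do and do not show.** The generator deliberately
omits neuropil contamination, bleaching, non-rigid deformation, correlated
(shot + motion) noise, spike-to-fluorescence nonlinearity and overlapping
cells. Green tests therefore demonstrate that the implementations recover
what they claim under the assumed statistical structure — calibrated false
positives, stated power, exact low-rank recovery, sub-pixel drift
recovery — not that the pipeline is robust to every artifact of real
recordings. Conversely, the model-side checks (closed form vs integration,
nullcline residuals) are exact statements about the implemented equations.

# Known limitations

* The model has no spiking dynamics, no MC-vs-TC split and no explicit
  dSAC population; dSACs enter only as a drive term with the 0.1/w_fb
  shunting rule.
* Registration is translational with integer pixel application; rotation
  and non-rigid motion are out of scope.
* ROI refinement assumes one dominant coherent source per ROI; two
  strongly correlated overlapping cells inside one ROI will not be split.
* The within-ROI PCA threshold (25%) and the 20% variance-explained guard
  are benchmark-validated defaults, not universal constants; both are
  exposed as arguments.
* `netLightImpact()` assumes the evoked response is near a plateau during
  the comparison windows; very fast transients would bias the impact
  toward zero.
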