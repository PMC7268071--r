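---
title: "Methods: arterial stiffness and resting-state fMRI fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arterial stiffness and resting-state fMRI fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwvfmri)
```

## Scientific problem

Arterial stiffening raises aortic pulse-wave velocity (PWV), the speed at
which the systolic pressure wave travels down the aorta. Stiff vessels
transmit pulsatile energy into the cerebral microcirculation and blunt
cerebrovascular reactivity, and both mechanisms are expected to damp the
spontaneous low-frequency fluctuations that resting-state BOLD fMRI measures.
`pwvfmri` implements a complete, testable analysis chain linking the two
measurements:

1. **PWV estimation** from aortic flow waveforms (arch and abdominal planes)
   by the time-to-foot method: PWV = x / t, with aortic path length x and the
   transit time t between the feet of the two systolic upstrokes.
2. **Signal separation** of dual-echo pCASL resting-state data into a
   BOLD-weighted series (surround averaging of the long echo) and
   perfusion-weighted series (surround subtraction / demodulation of the
   short echo), with aCompCor-style physiological denoising and 0.001-0.08 Hz
   band-pass filtering.
3. **Per-subject maps**: temporal-variance maps of the BOLD and CBF series
   (fluctuation amplitude), quantitative CBF via the single-compartment
   general kinetic model, and intrinsic-connectivity (IC) maps (per-voxel sum
   of Fisher-z correlations with all other brain voxels).
4. **Group inference**: voxelwise GLM of the map stacks on PWV with
   threshold-free cluster enhancement (TFCE) and Freedman-Lane permutation
   FWE correction; mixed-effects models of PWV on demographics; regression of
   association strength on vessel probability; bootstrap mediation of the
   PWV-BOLD relation by CBF fluctuations.

No public dataset accompanies the design, so the package ships a seeded
synthetic-cohort generator whose statistical structure matches what the
analysis assumes, making every downstream stage testable end to end.

## The synthetic cohort

`generate_covariates()` draws a two-generation cohort: parents aged 43-67 and
offspring aged 19-39, with group-wise systolic/diastolic pressure, height and
heart-rate targets taken from healthy-adult norms (parent SBP 122.5 +/- 13.2,
DBP 67.5 +/- 8.3 mmHg, so parent pulse pressure averages 55.0 mmHg by the
identity PP = SBP - DBP). True PWV follows the linear model

pwv = intercept + beta_age * age + beta_sbp * sbp + beta_height * height +
sex offset + noise,

which is exactly the fixed-effect structure that `fit_pwv_mixed_model()`
estimates, so parameter recovery is a well-posed check. Defaults
(`beta_age = 0.053` m/s/yr, `beta_sbp = 0.01` m/s/mmHg, intercept 1.63 m/s,
residual SD 0.45 m/s) put the offspring group mean near 4.17 m/s and the
parent mean near 5.74 m/s. The per-sex offset is drawn once per sex level,
mirroring a random-intercept-by-sex model; with only two levels that variance
component is fragile, so the fitter falls back to OLS with sex as a fixed
covariate whenever the REML fit degenerates, and records the fallback.

`generate_pcasl_series()` builds each subject's interleaved dual-echo series
on a small co-registered grid (default 12 x 12 x 6, 100 frames, TR 4 s,
frame 0 = control) as

s(v, e, i) = M0(v, e) [1 + beta(v) b_i] + (-1)^i (delta(v, e) / 2)
[1 + gamma(v) c_i] + noise,

where `b` (BOLD-like) and `c` (CBF-like) are independent unit-variance sums
of eight random-phase sinusoids in 0.01-0.05 Hz, `delta` is the perfusion
label amplitude (1.5% of the GM baseline at the short echo, reduced in WM,
absent in CSF, and much weaker at the long echo), and the white noise SD is
2 (0.2% of GM baseline). Two deliberate design choices:

* **Fluctuation band 0.01-0.05 Hz.** The dominant resting-state power lives
  below 0.05 Hz, and keeping the synthetic BOLD process strictly below the
  demodulation high-pass cutoff (1/(4 TR) = 0.0625 Hz) means the CBF
  envelope extracted by `demodulate_first_echo()` is free of BOLD
  contamination by construction. With content up to 0.08 Hz, the 0.0625-0.08
  Hz share of the BOLD signal would demodulate into the envelope band - a
  genuine limitation of Nyquist-carrier demodulation at TR = 4 s that the
  generator does not emulate.
* **GM-only fluctuations.** beta and gamma are nonzero only in gray matter,
  so the WM+CSF noise ROI contains baseline plus white noise, which is what
  the aCompCor model assumes; a shared global process in the noise ROI would
  make the denoiser remove signal.

The mediation chain PWV -> CBF-fluctuation amplitude -> BOLD-fluctuation
amplitude is injected in a compact 48-voxel cortical GM patch
(`default_effect_roi()`, about 10% of the brain grid - the spatial scale of a
default-mode-network-sized effect): per subject, gamma = gamma0 +
a_path (pwv - 5) + N(0, gamma_noise_sd) and beta = beta_base + b_path gamma +
N(0, beta_noise_sd), with defaults a_path = -0.15 per m/s, b_path = 0.05,
gamma0 = 0.5. Across the cohort's PWV range this yields BOLD fluctuation
amplitudes of roughly 1.5-3.5% of baseline, declining with stiffness. The
two noise terms are essential, not cosmetic: the b path of the mediation
model is identified only by mediator variation that is independent of PWV,
so `gamma_noise_sd` sets the mediation analysis's effective power, while
both terms bound the voxelwise GLM's per-voxel effect size. Defaults were
chosen so the standardized voxelwise effect is of order unity - comparable to
effects a 40-59 subject cluster study is designed to detect - and are
recorded in the `ground_truth` object alongside the seed, so any simulation
is exactly reproducible.

`generate_atlases()` partitions an ellipsoidal brain into GM/WM/CSF
(mutually exclusive, jointly exhaustive) and grows a sparse branching
random-walk "vessel tree" until exactly 10% of brain voxels carry nonzero
vessel probability, split into disjoint arterial (inferior, upward-drifting)
and venous (superior) subtrees.

`generate_flow_waveforms()` produces one cardiac cycle of arch and abdominal
flow: a flat diastolic baseline plus a raised-cosine systolic bump (default
300 ms wide, 400 mL/s peak), with the abdominal waveform delayed analytically
by path_length / pwv before sampling, so the true delay is not quantized to
the sampling step. The default step is 5 ms: finer than a scanner's ~25 ms
reconstructed resolution, chosen so that sub-sample foot detection - not grid
resolution - limits recovery accuracy. Waveform noise is additive white
Gaussian.

## Numerical choices

**Foot detection** uses the intersecting-tangent realization of
time-to-foot: the foot is where the tangent through the maximum-upslope
point meets the diastolic baseline (median flow over the 100 ms before
upstroke onset; onset = first sample whose derivative exceeds 20% of the
maximum). For a raised-cosine upstroke this foot sits systematically after
the true onset (by rise/2 - rise/pi), but the bias is identical at both
planes and cancels in the transit-time difference - which is why the
estimator recovers PWV to a few percent even though neither foot time equals
the true onset. An optional Savitzky-Golay smoother (quadratic, window
configurable) stabilizes the derivative on noisy waveforms; it is off by
default and enabled (window 21, about 100 ms) in the noisy-waveform validations.

**Surround stencils.** Surround averaging (s_i/2 + neighbors/4) and surround
subtraction (sign-corrected s_i - neighbor mean) are exact complementary
projections on a 3-frame window: for s_i = c_i + sigma_i d_i with locally
linear c and d they return c and d exactly. Endpoint frames are dropped
rather than padded.

**Filters.** Band-pass filtering is an explicit per-voxel de-mean followed
by cascaded order-4 Butterworth high-pass and low-pass stages, each applied
forward-backward (zero phase) with odd-reflection padding, in compiled code.
A single 8th-order band-pass transfer function at a normalized low cutoff of
0.008 is numerically fragile; the cascade keeps each stage well-conditioned.
The explicit de-mean makes DC rejection exact rather than asymptotic.
In-band tones are preserved within 2%; content at twice the upper edge is
attenuated by more than 90%.

**Demodulation.** The CBF-fluctuation series is high-pass (above 1/(4 TR)),
multiplied by the +1/-1 control/tag carrier (which sits exactly at the
Nyquist frequency), and low-pass filtered below 0.08 Hz. The envelope's
constant level delta/2 rides on the carrier itself, so it passes the
high-pass and survives demodulation; no DC restoration is needed.

**Variance maps** reject time points more than `outlier_k = 5` scaled-MAD
units from the voxel median before computing the unbiased variance - a
robust, scale-free realization of "variance with outlier rejection" that can
be disabled (`outlier_k = Inf`). Voxels with fewer than 3 surviving points
become NaN and are counted. The outlier-volume rejection for the perfusion
series is a greedy SNR optimizer (drop the frame whose removal most
increases GM-mean temporal SNR, stop below 1% gain or at 20% removed); the
default mode performs no removal, matching conventional quantification.

**CBF quantification** uses the single-compartment closed form
f = 6000 lambda dM exp(PLD/T1b) / (2 alpha T1b M0 (1 - exp(-tau/T1b)))
with defaults lambda = 0.9 mL/g, alpha = 0.85, T1b = 1.65 s, tau = 1.5 s,
PLD = 1.0 s. The PLD is short for full label arrival in older subjects;
fidelity here is judged by exact round-trip recovery, not physiological
accuracy, and all constants are configurable.

**Intrinsic connectivity** sums Fisher-z-transformed Pearson correlations
over all other masked voxels, including negative correlations as negative z
(the literal definition; a threshold option exists but defaults off). |r| is
clipped at 0.9999 before atanh so degenerate synthetic series stay finite;
computation is block-wise with results independent of block size to within
1e-10, verified against an O(V^2) double-loop oracle.

**TFCE** integrates extent^0.5 x height^2 over thresholds (step
max(t)/100, 26-connectivity by default - the field-standard parameters),
implemented in C++ with per-threshold connected-component labeling and
verified against a closed form (isolated voxel -> h^3/3 as dh -> 0) and a
brute-force R oracle. Inference is one-sided per requested direction
(default negative, since the stiffness hypothesis is a decline).

**Permutation correction** follows the Freedman-Lane scheme: nuisance-only
fit, seeded whole-row residual shuffles, full-model refit, TFCE, max-statistic
null. Corrected p-values use the +1 convention, so they are bounded below by
1/(n_perm + 1) and are valid (super-uniform) under the null; family
structure is ignored when permuting (no exchangeability blocks by default; a
hook exists in the design for adding them). The TFCE step size is fixed from
the observed map and reused across permutations so the null and observed
statistics are on a common scale.

**Mediation** is the product-of-coefficients estimator with case-resampling
bootstrap (percentile 95% CI, default 1000 iterations, two-sided p with the
+1 correction). The percentile CI is used rather than bias-corrected; c =
c' + ab holds exactly for the linear model, and determinism follows from the
seeded resampler.

**Three blood-pressure models** (SBP, DBP, PP) are fitted without
multiplicity correction across models, mirroring common practice for a
small family of planned comparisons.

## Pipeline and problem sizes

`run_pipeline()` executes simulate -> pwv -> separate -> maps -> icc -> glm
-> vesselreg -> mediate under a single validated configuration
(`validate_config()`: discard 4 frames, 4 aCompCor components per stream,
band 0.001-0.08 Hz, FWHM 6 mm at 3.44 x 3.44 x 6 mm voxels, 10,000
permutations, 1,000 bootstrap iterations). Identical configurations and
seeds give identical outputs; the manifest records a checksum per stage. The
two-rater averaging of PWV is emulated by running the foot detector under
two perturbed settings (baseline window 100 vs 80 ms, smoothing off vs
window 5) and averaging.

The shipped validation suite runs at deliberately compact problem sizes
chosen to exercise every code path while keeping the full suite in the
minutes range: 40-subject cohorts on 12 x 12 x 6 grids with 500 permutations
for the end-to-end checks, 6 x 6 x 3 null grids with 200 replicates x 500
permutations for the family-wise-error calibration, 100 replicate fits at
n = 2000 for mixed-model coverage, and 200 replicates for mediation
validity. The permutation default of 10,000 in the configuration reflects
the analysis prescription; the validation scripts override it explicitly.

## What passing tests do and do not show

The generator emulates the statistical structure the analysis assumes:
band-limited global fluctuation processes with tissue-specific amplitudes, a
perfusion-weighted alternating component, white thermal noise, a linear
covariate model for PWV, and a linear amplitude-mediation chain localized to
one region. It deliberately omits head motion, slice-timing effects,
cardiac/respiratory aliasing, T1 relaxation dynamics, spatial autocorrelation
of noise, nonlinear hemodynamics, and registration error. Recovery on this
cohort therefore validates the estimators and their implementation - not
robustness to the artifacts real data carry. In particular, FWE control is
demonstrated under exchangeable white noise; real spatial noise correlation
is handled by the permutation scheme in principle but is not exercised here,
and the two-level sex random intercept is structurally under-identified, so
the OLS fallback is the expected path on real-sized cohorts.

## Known limitations

* The greedy SNR outlier-volume rejection is a simplification of
  multiparametric adaptive schemes; it is labeled as such and off by default.
* Demodulation at TR = 4 s cannot separate BOLD content above 1/(4 TR) from
  the perfusion envelope; the generator's band choice sidesteps what real
  data cannot.
* The vessel atlas is a stylized branching tree, adequate for exercising
  binned regressions and overlap fractions, not for anatomical realism.
* Cortical thickness is carried as a per-subject covariate only; no surface
  analysis is implemented.
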