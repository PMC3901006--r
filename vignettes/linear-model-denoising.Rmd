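---
title: "Linear-model denoising of trial-based optical imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-model denoising of trial-based optical imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdiglm)
```

## The problem

Mesoscopic optical imaging of cortex with voltage-sensitive dyes records a
2D movie per stimulus presentation (a *trial*) at millisecond resolution.
The evoked neural component is a fractional fluorescence change of order
10⁻³ of the resting light level, while the recording is dominated by
structured nuisance components: a slow exponential decay from dye
bleaching, quasi-periodic oscillations locked to the heartbeat (acquisition
is typically triggered on the heartbeat, so their phase is similar across
trials), and broadband sensor/shot noise. `vsdiglm` implements the two
standard trial-level strategies for isolating ΔF/F, plus everything they
need around them: NIfTI session storage, noise-parameter estimation from
blank trials, session-level aggregation, and a synthetic-session generator
used throughout the validation suite.

## The blank-subtraction workflow

Each trial is first divided, pixel by pixel, by the mean of its
pre-stimulus frames (the "frames 0"), making the movie a dimensionless
ratio whose pre-stimulus mean is exactly 1. The average of all blank trials
of the session — averaged *after* frames-0 division, so that baseline
differences between trials do not bias the reference — is subtracted frame
by frame, and a linear trend is removed per pixel. The detrending line is
anchored on the two windows where the true response is known to vanish:
the pre-stimulus window and a trailing window of `end_window` frames
(default: the pre-stimulus length). Subtracting the line through the two
window means leaves both means exactly zero, which is the operational
meaning of "the response returns to baseline at the end of the trial".
Anchoring on window means rather than regressing on all frames keeps the
evoked transient from leaking into the trend estimate.

Pixels whose baseline mean is non-positive (dead or saturated sensors)
abort the computation by default; a flag converts them to `NaN` and they
are excluded, with counts reported, from all downstream averages.

## The linear-model workflow

At every pixel and for every trial the raw intensity timecourse is modeled
as

$$y = X_0\beta_0 + X_n\beta_n + X_s\beta_s + \epsilon$$

- $X_0$ is the constant regressor; $\beta_0$ is the baseline estimate. The
  GLM therefore runs on raw counts — no frames-0 division — and the final
  normalization uses $\beta_0$, which is statistically better behaved than
  the mean of a handful of pre-stimulus frames.
- $X_n$ stacks the noise regressors: $e^{-t/\tau}$ for dye bleaching and a
  sine/cosine pair per oscillation frequency and harmonic. Two harmonics of
  the heartbeat frequency are included by default, one for any further
  detected peak.
- $X_s$ spans the plausible evoked-response shapes (next section).

The fit is ordinary least squares through one QR factorization of $X$
shared by all pixels (never an explicit inverse); rank-deficient designs
are refused, not pseudo-solved. The denoised signal is
$\Delta F/F = (y - X_n\beta_n)/\beta_0$; by default the constant
contribution $X_0\beta_0$ is removed as well ("centered" mode) so that
blank-like pixels fluctuate around zero, which is how denoised timecourses
are conventionally displayed. The as-written variant is available behind a
flag.

### The response-shape family and its PCA basis

The canonical evoked shape $r(t)$ is piecewise half-cosine, parameterized
by six durations (latency, initial dip, rise, plateau, decay, undershoot)
and two depths (dip, undershoot) in $[0,1]$. Each segment interpolates
between its endpoint levels ($0 \to -d_{dip} \to 1 \to 1 \to
-d_{under} \to 0$) with a half-cosine; the cosine coefficients are fixed
by requiring continuity at every breakpoint, which determines them
uniquely. Segments of zero duration are skipped; a segment leading to a
nonzero depth therefore needs nonzero duration for the curve to stay
continuous — the validation suite draws its random shapes under that
constraint.

The user states an interval and step count per parameter; the library of
all grid combinations is evaluated on the post-onset time grid, and its
leading $L$ principal directions become $X_s$, padded with zeros before the
stimulus onset frame. Two deliberate choices:

- **Uncentered PCA.** The decomposition runs on the raw library, not on
  mean-removed shapes, so the mean shape stays inside $X_s$ rather than
  leaking into $\beta_0$. A `center` flag enables the conventional variant
  for comparison.
- **Choice of $L$.** By default $L$ is the smallest value capturing 99% of
  the library's squared singular values. For the study configuration used
  in the tests and the acceptance script we set $L = 15$ explicitly
  (of 81 library shapes): at $L=15$ the worst-case reconstruction error of
  the generator's shape prototype is below 1% of the peak, which is the
  approximation budget the noiseless-recovery checks are written against.
  $L$ is a user parameter of the method; the energy default is a fallback,
  not a recommendation, and the fitted model is insensitive to moderate
  increases of $L$ beyond this point.

### Estimating the noise parameters from blank trials

The spatially averaged blank timecourse drives two estimators:

- **τ** minimizes the least-squares error of `constant + b·exp(-t/τ)` over
  a grid of candidate values, by default 50 log-spaced points spanning
  0.1×–10× the trial duration (adjacent grid points differ by ~10%, i.e.
  ±5% worst-case quantization). The exponential then enters the design as
  a fixed regressor — the small residual from quantization is far below
  the broadband noise floor at realistic bleaching amplitudes.
- **Heartbeat frequency** is the maximum periodogram ordinate of the
  exponential-removed residual inside a physiological band (default
  0.5–15 Hz), ties broken toward the lower frequency. The resolution is one
  DFT bin, `sampling_rate / n_frames`. A flat residual spectrum returns
  `NA` with a warning rather than a silent value.
- **Additional peaks** use a robust threshold: local maxima of the
  amplitude spectrum above `median + z·MAD` (median and MAD over the full
  non-DC spectrum, default z = 8), after removing excluded bands and
  ordinates within one bin of an already accepted stronger peak. At z = 8,
  white-noise inputs yield no false peaks in ≥95 of 100 seeded runs.

### Residual diagnostics

The Durbin–Watson statistic
$DW = \sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2 \in [0,4]$ is computed per
pixel; white residuals give values near 2 and an AR(1) process gives
approximately $2(1-\rho)$. A pixel counts as "white" when its statistic
falls in the default bounds (1.5, 2.5); these are pragmatic screening
bounds, not small-sample critical values, and exact p-values are out of
scope. The whiteness fraction is an a-posteriori indicator of model
validity: dropping the heartbeat regressors on heartbeat-contaminated data
visibly drops it.

### The heartbeat-contribution map

Per pixel, the fractional heartbeat amplitude is
$\sqrt{\beta_{sin}^2 + \beta_{cos}^2} / \beta_0$ summed over the heartbeat
harmonics, i.e. normalized to baseline units. For a session-level map the
sine/cosine coefficients are averaged across trials *before* the modulus:
the modulus of noisy coefficients is biased upward (Rayleigh-type bias,
dominated by harmonics with little true power), whereas coefficient
averaging is unbiased and loses almost no true amplitude because
heartbeat-triggered acquisition keeps trial phases nearly aligned.

## The synthetic-session generator

The generator emulates the structure of the distributed awake-macaque VSDI
dataset this kind of analysis is validated on: 110 Hz acquisition,
6 stimulus conditions × 10 trials + 20 blank trials (80 trials),
heartbeat-triggered recording. Each trial is

$$F(x,y,t) = F_0(x,y)\,[1 + b\,e^{-t/\tau} + \textstyle\sum_k a_k
\sin(2\pi f_k t + \phi_{k}) + c\,A(x,y)\,r(t - t_{on})] +
F_0\,\sigma\,\eta$$

with $F_0$ a smooth positive random field (Gaussian-smoothed white noise,
rescaled to the target mean and CV), $A$ a radial raised-cosine bump, and
$\eta$ i.i.d. standard Gaussian noise. Every component is multiplicative in
$F_0$; that is the regime in which frames-0 division and $\beta_0$
normalization are exact, so ground-truth recovery tests have a closed-form
target. The heartbeat phase is drawn per trial with a small sd (default
0.1 rad) around zero, reflecting heartbeat triggering; larger jitter can be
configured to probe the failure modes of a session-wide model.

Default magnitudes are chosen as realistic for awake-primate VSDI and were
fixed before the validation suite was run: baseline 1000 a.u. with 10%
spatial CV, 3% bleaching with τ = 2 s, 2.5 Hz heartbeat at 0.2% of
baseline, evoked peaks of 0.1–0.6% ΔF/F across the six conditions over a
radial profile of radius 5 px, per-pixel noise sd 0.1% of baseline, 220
frames with stimulus onset at frame 22 (0.2 s pre-stimulus window). The
image is 16×16 by default — the native 512×512 would add nothing to the
statistical structure at vastly higher cost, and the data model's binning
covers the reduction path for real data. One master seed drives everything;
trial *k* uses a fixed-offset substream so any trial is reproducible in
isolation.

What the generator does **not** emulate: vascular structure in $F_0$,
motion, photon (Poisson) statistics, camera saturation, trial-to-trial
variation of heartbeat *frequency*, and respiration-like second
oscillations unless configured. Passing the recovery tests therefore shows
correctness of the estimators under the model's own assumptions, not
robustness to every artifact of real recordings.

## Numerical and interface choices

- Axis convention: in memory `[row, column, frame]`; on disk 4D NIfTI-1
  `(X=W, Y=H, Z=1, T)`, float32, `pixdim[4] = 1/sampling_rate`, stimulus
  onset stored in `toffset` (seconds) so files round-trip without sidecars.
  Frame indices are 0-based in all metadata; the pre-stimulus window is
  `[0, onset_frame)`.
- Binning drops remainder rows/columns/frames so every output value is an
  exact block mean; the onset frame maps to `floor(onset/k)` and is kept
  ≥ 1.
- Degenerate inputs fail loudly: non-finite movies, rank-deficient designs
  (with the dependent columns and condition number named), empty blank
  lists, overlapping detrending windows, harmonics at or beyond Nyquist.
  Masking (`NaN`) of non-positive baseline pixels is always opt-in.
- The blank average operates in fractional units (order of operations not
  fixed by convention elsewhere); leave-one-out exclusion of the processed
  blank is available for null checks.
- All-zero residuals give `DW = NaN` (flagged), never a silent 0/0.

## Problem sizes in the validation suite

The test suite and `scripts/acceptance.R` run the full study session
(16×16×220, 80 trials) for recovery, whiteness and null checks; 100 seeded
blanks-only sessions (8×8) for τ/heartbeat recovery rates; 1000 replicates
for Durbin–Watson calibration; and small analytic fixtures everywhere a
closed form exists. These sizes give all Monte-Carlo assertions ≥3-sigma
margins while keeping a full run in well under a minute.

## Known limitations

- One design matrix per session: trials with varying onset frames or
  heartbeat frequencies need per-trial models, which this package does not
  build automatically.
- The Durbin–Watson screen uses fixed bounds, not exact critical values.
- Proprietary camera formats are not read; sessions must be converted to
  NIfTI first.
- No spatial regularization or weighted least squares; pixels are fitted
  independently.
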