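---
title: "Methods: calcium transient and burst analysis for adrenal slice imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium transient and burst analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciburst)
library(dplyr)
```

## The biological setting

Zona glomerulosa (zG) cells of the adrenal cortex synthesize aldosterone
under the control of intracellular Ca²⁺. Assembled in rosettes, they behave
as conditional voltage oscillators: stimulation — angiotensin II (AngII), or
loss of TASK potassium-channel function (pharmacological TASK inhibitors,
"TI") — evokes Ca²⁺ transients that cluster into *bursts*, and burst
activity tracks steroidogenic output. Experiments image zG-specific GCaMP6f
fluorescence in acute adrenal slices at 10 Hz under different stimulation
and extracellular-osmolarity conditions (280 mOsm "permissive" vs 310 mOsm
"suppressive"), extract per-cell ROI traces with standard tools, and then
need a trace-level analysis: which deflections are real Ca²⁺ transients,
which transients form bursts, and how much of the recording each cell spends
bursting. `calciburst` implements that analysis, together with the
aldosterone-secretion normalization used to relate activity to hormone
output, and a synthetic-data generator that emulates the statistical
structure the analysis assumes.

## Pipeline stages and their parameters

The stage order is fixed: neuropil subtraction → rolling-baseline removal →
SD-ratio QC → deconvolution → detection → validation → burst segmentation →
metrics.

**Neuropil subtraction.** ROI fluorescence in widefield slice imaging is
contaminated by scattered light from surrounding tissue. Given a matched
neuropil trace, `subtract_neuropil()` computes `F − c·F_neu` elementwise.
The coefficient `c` (default 0.7) is not identifiable from a single trace
and is configuration; 0.7 is the convention of the common ROI-extraction
tools.

**Rolling baseline.** `rolling_baseline()` subtracts a running low
percentile (default: 10th percentile in a 600-frame = 1-minute window),
removing drift with period much longer than the window while preserving
transient amplitudes. For speed the percentile is evaluated on a grid of
centers spaced window/10 apart and linearly interpolated — the baseline is
by construction smooth on that scale, so the interpolation error is
negligible; when the window covers the whole trace the global percentile is
subtracted exactly.

**SD-ratio QC.** `sd_ratio_qc()` computes the trace SD in sliding windows
(1 minute, stride half a window) and the ratio max/min, flooring the minimum
at `1e-6 × sd(trace)` so a flat segment produces a large finite ratio rather
than a division by zero; this also makes the ratio scale-invariant. ROIs
with ratio above `sd_ratio_max` (default 6) are excluded as unstable or
poor signal-to-noise. Both window and threshold are configuration: the
choice of 6 passes stationary-noise traces essentially always while
rejecting traces whose variance changes an order of magnitude.

**Deconvolution.** The indicator decay is modeled as AR(1) with
`γ = exp(−1/(f_s·τ_decay))`, default `τ_decay` = 0.6 s (GCaMP6f-like).
`deconvolve()` solves

$$\min_{C}\; \tfrac12\lVert F - C\rVert^2 + \lambda \sum_t s_t
\quad\text{s.t.}\quad s_t = C_t - \gamma C_{t-1} \ge 0,\; C \ge 0$$

exactly, by a pool-adjacent-violators pass (the standard online solver for
this convex program), implemented in C++. The tests verify the solution
objective against a generic box-constrained quadratic solve on small
instances. When run from `preprocess_traces()`, the penalty is
`λ = sparsity_penalty + sparsity_n_sigma × σ̂` with `σ̂` the robust noise SD
of the trace (default `sparsity_n_sigma = 3`): tying the shrinkage to the
noise level suppresses noise-driven event candidates without biasing large
events appreciably (an isolated event is shrunk by `λ(1−γ)`, about 5% of a
unit amplitude at default settings).

**Noise estimate.** `estimate_noise()` uses the median absolute deviation
of the first differences divided by `√2·0.6745`. Differencing whitens slow
components, and the MAD ignores the sparse large differences contributed by
transients, so the estimate tracks the sensor-noise SD even on active
traces.

**Transient detection.** `detect_transients()` applies the staged rules:
(i) frames with deconvolved amplitude above `deconv_frac` (default 0.05) of
the trace maximum become candidates; (ii) contiguous candidate runs merge to
the run's maximum; (iii) each candidate moves to the local maximum of the
*denoised* trace within ±`align_halfwidth_frames` (default 5 = 0.5 s) —
the denoised trace has the same peaks as the fluorescence but its local
maxima are not perturbed frame-by-frame by sensor noise — and detections
within `dedup_radius_frames` (default 4) collapse to the one carrying the
largest deconvolved amplitude; (iv) events whose fluorescence amplitude
(the mean over peak ± 1 frame) falls below `amp_n_sigma` (default 3) noise
SDs are removed; (v) a moving filter removes events whose deconvolved
amplitude is below `movfilt_rel_amp` (default 0.15) of the largest event
within `movfilt_window_frames` (default 10). All values are configuration,
with optional per-ROI overrides, mirroring practice where detection
thresholds are tuned per cell. The defaults were chosen on synthetic traces
to keep event-level F1 above 0.9 at amplitude/noise = 5.

**Validation.** `validate_transients()` rejects events that do not look
like indicator transients. The fluorescence segment from 2 frames before to
`⌈3·τ_decay·f_s⌉` frames after the peak is fitted by least squares with the
event's own kernel template at −1/0/+1-frame shifts (absorbing alignment
jitter and sub-frame event timing) plus the templates of neighbouring
detected events whose tails reach the segment. An event validates when the
best own-template correlation against the neighbour-subtracted segment
reaches `validate_corr_min` (default 0.6) and the full-fit residual SD is at
most `validate_noise_max_sigma` (default 2) noise SDs. A single-template
correlation was tried first and rejects a large fraction of genuine
intraburst events — their segments contain neighbouring transients' rises
and tails — which is why the local model includes neighbours; events planted
on pure noise are still rejected ≈99% of the time. Unvalidated events are
flagged, not dropped, and excluded from metrics by default.

## The interval mixture and the burst threshold

Interpeak intervals pool two regimes: regular intraburst periods
(Gaussian, mean ≈ 2 s) and long interburst gaps (exponential).
`fit_interval_mixture()` fits

$$p(x) = w_g\,\mathcal{N}_{[a,\infty)}(x;\mu,\sigma^2) +
         (1-w_g)\,\lambda_e e^{-\lambda_e x}$$

by EM with 5 restarts (tol 1e-8 on the log-likelihood, max 500 iterations;
first restart split at the median, later restarts at random quantiles). The
Gaussian is truncated below at `truncate_at` (default 0): intervals are
positive, and with a broad Gaussian the truncated mass is not negligible —
ignoring it shifts every parameter and moves the derived threshold by
several tenths of a second, which is why the truncated form is the default
rather than documented as an approximation. The truncated M-step has no
closed form; the mean/SD update is a Nelder–Mead refinement of the expected
complete-data log-likelihood started at the current values, so each
iteration still cannot decrease the observed log-likelihood (a generalized
EM), and the mean is kept inside the support so the Gaussian remains a bell
around a real period instead of degenerating into a second decaying
component.

`mixture_intersection()` returns the burst-defining maximum interpeak
interval: the crossing point `x* > μ` of the weighted component densities,
bracketed on `[μ, μ + 10σ]` and solved to `|f| < 1e−10`. The crossing below
the mean is deliberately ignored — it would place the burst ceiling under
typical intraburst intervals, which is non-physical. If a component weight
is zero or no sign change exists in the bracket, a `NoIntersection` error is
raised and callers may fall back to a configured fixed threshold (the
pipeline default is the reference 5.6 s for TI-like data, 5.3 s for
AngII-like data; both reproduce as worked examples of the intersection with
the reference mixture parameters).

```{r thresholds, eval = FALSE}
mixture_intersection(interval_mixture(0.7545, 2.0, 1.5, 1/15))  # 5.5998 -> 5.6
mixture_intersection(interval_mixture(0.6644, 2.0, 1.5, 1/15))  # 5.2999 -> 5.3
```

**Segmentation and metrics.** `segment_bursts()` takes maximal runs of
consecutive events whose adjacent intervals are all strictly below the
threshold; runs with ≥3 events are bursts (both numbers configurable).
Burst duration is onset-to-offset of the event peaks; indicator decay tails
are excluded, since duration should describe the electrical event train,
not the reporter kinetics. `compute_metrics()` then reports, per ROI:
transient count, burst count, mean burst duration, fraction of time
bursting (summed burst durations over the analysis-window duration), and
intraburst period — the *median* adjacent interval inside bursts, missing
when there are none and never coerced to zero. The median is deliberate: an
exponential interburst gap occasionally falls below the burst threshold and
joins two bursts, planting a long spurious "intraburst" interval, and the
frequency of such joins differs across stimulation conditions; a mean
inherits that contamination as a condition-dependent bias of a few percent,
while the median leaves the period estimate where the biology puts it. Per
slice: active-ROI count (≥3
transients), active-cell density over the zG area, and 1-minute-binned
transient rates. Note that widening the threshold can only grow the set of
burst-assigned events, but may *merge* bursts and so reduce the burst
count; the monotone quantity is event membership, and the tests assert
exactly that.

## Secretion normalization and dose-response fits

Slice-to-slice variation in viable zG mass makes absolute aldosterone
(pg/slice/h) noisy, so `normalize_secretion()` works in fold changes: each
slice's post-treatment value over its own baseline, then, per animal, folds
divided by the mean fold of that animal's vehicle slices — making vehicle
slices average exactly 1 per animal by construction. Animals without
vehicle slices cannot be normalized and are dropped with a warning.
`summarize_secretion()` averages replicate slices per animal × condition
before group statistics. `fit_sigmoid()` fits the osmolarity response with
a four-parameter logistic by Levenberg–Marquardt with quartile-based
self-starting values, the midpoint bounded within the data range ± one
span, jittered restarts on failure, and canonicalization to `top ≥ bottom`;
a saturating Hill form is available for activity-versus-secretion curves
(both figures' "nonlinear fit" are served by one fitter; the logistic is
the default because osmolarity responses plateau at both ends). Constant
data yield a flagged degenerate fit with R² = 0. Whether the fit is done on
per-animal means (default) or per-slice values is a configuration switch.

## What the synthetic generator emulates — and what it does not

`sample_burst_train()` draws an alternating renewal process: exponential
interburst gaps (truncated below at the interval floor), bursts of
`3 + Geometric(p)` events separated by Gaussian intervals truncated at the
floor (0.2 s = 2 frames at 10 Hz, the smallest spacing the detector can
resolve). The geometric excess gives the heavy-ish tail of burst sizes that
variable burst durations require while fixing only the ≥3 rule. A trailing
burst cut by the recording keeps its realized events; its window is
recorded only if it still has ≥3 events, so every ground-truth burst obeys
the burst rule. `render_trace()` is strictly linear: unit-amplitude
peak-normalized difference-of-exponentials kernels (rise 0.08 s, decay
0.6 s) at the event times, plus a shared low-frequency background entering
each ROI with coefficient 0.7 (the neuropil ground truth), a slow sinusoidal
drift, and white sensor noise.

The presets encode the study contrasts: suppressive conditions (`TI-310`,
`AngII-310`) have a lower active-cell probability, longer interburst gaps
(45–50 s vs 15–18 s; the permissive TI gap matches the reference interval
mixture's exponential mean), and fewer events per burst than their
permissive counterparts, while the intraburst interval distribution
(2.0 ± 0.3 s, the stereotyped within-burst periodicity) is identical across
presets — the invariant the analysis must *not* break. A broad intraburst SD
was considered and rejected: it blurs the two interval classes so strongly
that threshold-based segmentation induces large selection effects, whereas
the tight SD matches both the observed regularity of within-burst
oscillations and the generator's own 0.2 s resolution floor. Defaults:
600 s recordings at 10 Hz, 10,000 µm² zG area, noise SD 0.05 ΔF/F.
Determinism: one master seed derives a sub-seed per ROI by counter, so
growing `n_roi` extends a dataset without reshuffling earlier ROIs.

One estimator property deserves emphasis. Even with *perfect* detection,
segmenting at a fixed threshold misclassifies the exponential gaps that
happen to fall below it, and the frequency of these joins differs across
conditions; the resulting per-slice period estimates carry a ~1–2%
condition-dependent bias no estimator of "intervals within bursts" can
remove. The end-to-end invariance test therefore asserts *equivalence* —
the 99% confidence interval of the between-condition period difference must
lie within ±5% of the period — rather than demanding non-significance,
which at high replication power would reject for any implementation.

What passing tests on these data do **not** show about real recordings: the
generator has white sensor noise (no photon shot noise or 1/f structure),
a single shared background (no per-ROI neuropil heterogeneity), fixed and
known indicator kinetics, no amplitude variability between events, no
photobleaching, and no motion or focal-plane artifacts. Indicator kinetics
and the noise model are stand-ins — the source experiments do not
characterize them — and are fully configurable.

## Numerical choices and problem sizes

Ties in peak alignment resolve to the earlier frame. The alignment signal
is the denoised trace when available, the fluorescence itself otherwise.
Degenerate inputs: an all-zero deconvolved trace yields zero events (not an
error); fewer than 50 intervals or all-identical intervals refuse a mixture
fit; a recording window of zero length is an error. Event scoring against
ground truth shifts true event times by the kernel peak delay (≈0.19 s at
default kinetics) because the detector reports fluorescence peak frames,
not event onsets, and then matches greedily within ±2 frames.

The test suite exercises: EM recovery and threshold consistency at 50,000
intervals; segmentation against an exhaustive scan on 10,000 random trains
(≤50 events); deconvolution against a generic constrained-QP solve on
instances of ≤40 frames; detection F1 on 10 ROIs × 600 s at
amplitude/noise = 5; and the end-to-end condition contrast on 20 seeds ×
16 ROIs × 600 s per preset. These sizes give stable Monte-Carlo margins for
every stochastic assertion while keeping the suite comfortably fast.

## Known limitations

Peak timing is frame-resolution (no sub-frame interpolation); deconvolved
amplitudes are arbitrary units, not spike counts; bursts cannot span
excluded analysis-window spans; the mixture model assumes one Gaussian
period — cells with multimodal intraburst rhythms would need a richer model;
and pooled mixture fitting (the default) assumes intervals are exchangeable
across ROIs, with per-recording fitting available through the pipeline
configuration when that assumption is doubtful.
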