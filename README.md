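# calciburst

Trace-level analysis of oscillatory calcium activity in adrenal zona
glomerulosa (zG) cells, and of the aldosterone secretion it drives.

zG cells embedded in their native rosettes are electrical oscillators: when
stimulated (by angiotensin II, or by TASK potassium-channel inhibition) they
fire intracellular Ca²⁺ transients organized into *bursts*, and the fraction
of time spent bursting tracks aldosterone output. Experiments record
GCaMP6f fluorescence movies at 10 Hz; upstream tools (motion correction,
segmentation) reduce each cell to an ROI fluorescence trace. `calciburst`
implements everything downstream of ROI extraction:

1. **Quality control & conditioning** — neuropil (background) subtraction
   `F − c·F_neu`, rolling-percentile detrending, and exclusion of ROIs whose
   moving-window SD ratio `max(SD)/min(SD)` exceeds a threshold.
2. **Deconvolution** — the indicator decay is an AR(1) kernel with
   `γ = exp(−1/(f_s·τ_decay))`; event amplitudes solve the nonnegative
   sparse program
   `min ½‖F − C‖² + λ·Σs,  s_t = C_t − γC_{t−1} ≥ 0, C ≥ 0`
   via an exact pool-adjacent-violators pass (Rcpp).
3. **Transient detection** — dual thresholds (a fraction of the maximum
   deconvolved value, and a minimum fluorescence amplitude in units of the
   baseline-noise SD), peak alignment within ±5 frames, duplicate collapse,
   a moving specificity filter, and template-correlation validation of each
   event.
4. **Burst analysis** — interpeak intervals are modeled as a mixture
   `w_g·N(μ, σ²) + w_e·Exp(λ_e)` fitted by EM; the burst-defining maximum
   interval is the crossing point `x* > μ` where
   `w_g·φ(x*; μ, σ) = w_e·λ_e·e^{−λ_e x*}`. A burst is ≥3 consecutive
   transients with all interpeak intervals below `x*`. Per-ROI and per-slice
   metrics: transient counts, burst number/duration, fraction of time
   bursting, intraburst period, active-cell density per zG area, 1-minute
   binned frequency.
5. **Secretion** — per-slice aldosterone fold change (post/baseline),
   within-animal vehicle normalization, and four-parameter logistic
   (optionally Hill) dose-response fits with R².
6. **Synthetic data** — a generator that renders ground-truth bursting
   spike trains (exponential interburst gaps, truncated-Gaussian intraburst
   intervals, geometric event counts) as noisy GCaMP6f-like traces with
   shared neuropil contamination, under condition presets
   (`TI-280`, `TI-310`, `AngII-280`, `AngII-310`) that differ in
   active-cell fraction, burst rate and burst duration but not in
   intraburst period.

With the reference mixture parameters the threshold evaluates to **5.6 s**
for the TASK-inhibitor condition (`w_g = 0.7545`) and **5.3 s** for
angiotensin II (`w_g = 0.6644`).

## Worked example

```r
library(calciburst)
library(dplyr)

ds <- generate_dataset("TI-280", n_roi = 12, seed = 1)
ds
#> <calci_dataset> condition: TI-280 | ROIs: 12 | duration: 600 s @ 10 Hz | seed: 1
#>   active ROIs: 8 | ground-truth events: 1041 | ground-truth bursts: 179

pr     <- preprocess_traces(ds$traces, fs_hz = ds$fs_hz)
events <- detect_transients(pr) |> validate_transients(pr)
ev_ok  <- filter(events, validated)

thr <- mixture_intersection(interval_mixture(0.7545, 2.0, 1.5, 1/15))
round(thr, 2)
#> [1] 5.6

bursts <- segment_bursts(ev_ok, burst_definition(thr, 3))
m <- compute_metrics(ev_ok, bursts, ds$duration_s,
                     zg_area_um2 = ds$zg_area_um2,
                     roi_ids = unique(pr$traces$roi_id))
glance(m)
#> # A tibble: 1 × 8
#>   n_rois n_active_rois active_cell_density_per_um2 total_transients n_bursts
#> 1     12             8                      0.0008              991      127
#> # mean_burst_duration_s 14.4, mean_fraction_active 0.252,
#> # mean_intraburst_period_s 2.05
```

Reading the output: 8 of 12 simulated ROIs are active (≥3 transients),
giving 8/10,000 µm² = 8 × 10⁻⁴ active cells per µm²; their bursts last
14.4 s on average and occupy 25.2% of the recording, with a 2.05 s
intraburst period — and the detected event train matches the generator's
ground truth with F1 ≈ 0.97
(`score_events(ev_ok, ds$ground_truth$spikes)`). `tidy(m)`
returns the per-ROI table; `autoplot()` methods exist for datasets, interval
mixtures, metrics and sigmoid fits.

End-to-end runs over config files (YAML) are available as
`run_simulate()`, `run_analyze()`, `run_secretion()`, or from a shell via
`inst/cli/calciburst.R <simulate|analyze|secretion> --config run.yaml`.

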