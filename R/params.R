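#' Parameters of the ground-truth bursting spike-train process
#'
#' An alternating renewal process generates per-ROI event trains: interburst
#' gaps are exponential, within-burst interpeak intervals are Gaussian
#' (truncated below at `interval_floor_s`), and the number of events in a
#' burst is `events_per_burst_min` plus a geometric excess. An ROI is active
#' at all with probability `active_prob`.
#'
#' @param interburst_mean_s Mean (s) of the exponential gap between the last
#'   event of a burst and the first event of the next. `Inf` is a sentinel for
#'   a silent ROI.
#' @param intraburst_mu_s Gaussian mean (s) of within-burst interpeak
#'   intervals; must exceed `interval_floor_s`.
#' @param intraburst_sigma_s Gaussian SD (s) of within-burst intervals.
#' @param events_per_burst_min Minimum events per burst (>= 3, the burst rule).
#' @param events_per_burst_geom_p Success probability in (0, 1] of the
#'   geometric excess-event count; `1` fixes every burst at the minimum.
#' @param active_prob Probability that an ROI is active at all.
#' @param duration_s Recording duration in seconds.
#' @param interval_floor_s Truncation floor (s) for sampled intervals;
#'   default 0.2 s (two frames at 10 Hz) so no interval falls below what the
#'   detector can resolve.
#' @return A `burst_train_params` list.
#' @export
burst_train_params <- function(interburst_mean_s = 30,
                               intraburst_mu_s = 2,
                               intraburst_sigma_s = 0.3,
                               events_per_burst_min = 3L,
                               events_per_burst_geom_p = 0.35,
                               active_prob = 1,
                               duration_s = 600,
                               interval_floor_s = 0.2) {
  stopifnot(
    interburst_mean_s > 0,
    intraburst_sigma_s > 0,
    events_per_burst_min >= 3,
    events_per_burst_geom_p > 0, events_per_burst_geom_p <= 1,
    active_prob >= 0, active_prob <= 1,
    interval_floor_s > 0
  )
  if (!is.finite(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be a positive finite number.",
          class = "calci_invalid_parameter")
  }
  if (intraburst_mu_s <= interval_floor_s) {
    abort("`intraburst_mu_s` must exceed `interval_floor_s`.",
          class = "calci_invalid_parameter")
  }
  structure(
    list(
      interburst_mean_s = interburst_mean_s,
      intraburst_mu_s = intraburst_mu_s,
      intraburst_sigma_s = intraburst_sigma_s,
      events_per_burst_min = as.integer(events_per_burst_min),
      events_per_burst_geom_p = events_per_burst_geom_p,
      active_prob = active_prob,
      duration_s = duration_s,
      interval_floor_s = interval_floor_s
    ),
    class = "burst_train_params"
  )
}

#' Indicator response parameters
#'
#' The fluorescence response to a single event is a peak-normalized
#' difference of exponentials, `k(t) = (exp(-t/decay) - exp(-t/rise)) / k_max`
#' for `t >= 0`, scaled by `unit_amplitude_dff`. Defaults are a GCaMP6f-like
#' fast indicator (80 ms rise, 600 ms decay).
#'
#' @param rise_tau_s Rise time constant (s).
#' @param decay_tau_s Decay time constant (s); must exceed `rise_tau_s`.
#' @param unit_amplitude_dff Peak dF/F of a unit event.
#' @return An `indicator_params` list.
#' @export
indicator_params <- function(rise_tau_s = 0.08, decay_tau_s = 0.6,
                             unit_amplitude_dff = 1.0) {
  stopifnot(rise_tau_s > 0, decay_tau_s > rise_tau_s, unit_amplitude_dff >= 0)
  structure(
    list(rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
         unit_amplitude_dff = unit_amplitude_dff),
    class = "indicator_params"
  )
}

#' Noise and contamination parameters for rendered traces
#'
#' @param white_sd_dff SD of per-frame white sensor noise (dF/F units).
#' @param drift_amplitude_dff Amplitude of a per-ROI slow sinusoidal drift.
#' @param drift_period_s Period (s) of the drift sinusoid.
#' @param neuropil_coeff_true Coefficient with which the shared background
#'   contaminates each ROI trace (ground truth for neuropil subtraction).
#' @param shared_bg_sd_dff SD of the low-frequency background trace shared by
#'   all ROIs of a dataset (the neuropil signal).
#' @param shared_bg_period_s Characteristic period (s) of the shared
#'   background.
#' @return A `noise_params` list.
#' @export
noise_params <- function(white_sd_dff = 0.05,
                         drift_amplitude_dff = 0.05,
                         drift_period_s = 300,
                         neuropil_coeff_true = 0.7,
                         shared_bg_sd_dff = 0.1,
                         shared_bg_period_s = 120) {
  vals <- c(white_sd_dff, drift_amplitude_dff, drift_period_s,
            neuropil_coeff_true, shared_bg_sd_dff, shared_bg_period_s)
  stopifnot(all(vals >= 0))
  structure(
    list(white_sd_dff = white_sd_dff,
         drift_amplitude_dff = drift_amplitude_dff,
         drift_period_s = drift_period_s,
         neuropil_coeff_true = neuropil_coeff_true,
         shared_bg_sd_dff = shared_bg_sd_dff,
         shared_bg_period_s = shared_bg_period_s),
    class = "noise_params"
  )
}

#' SD-ratio quality-control parameters
#'
#' ROIs are screened by computing the SD of the trace in sliding windows
#' (stride = half a window) and excluding ROIs whose maximum:minimum SD ratio
#' exceeds `sd_ratio_max` (poor or unstable signal-to-noise).
#'
#' @param window_frames Window length in frames (default 600 = 1 min at 10 Hz).
#' @param sd_ratio_max Exclusion threshold on max/min windowed SD.
#' @param sd_floor_frac The minimum SD is floored at
#'   `sd_floor_frac * sd(trace)` before the ratio, so flat segments give a
#'   large finite ratio rather than dividing by zero.
#' @return A `qc_params` list.
#' @export
qc_params <- function(window_frames = 600L, sd_ratio_max = 6,
                      sd_floor_frac = 1e-6) {
  stopifnot(window_frames >= 2, sd_ratio_max > 1, sd_floor_frac > 0)
  structure(
    list(window_frames = as.integer(window_frames),
         sd_ratio_max = sd_ratio_max,
         sd_floor_frac = sd_floor_frac),
    class = "qc_params"
  )
}

#' Deconvolution parameters
#'
#' The indicator decay is modelled as AR(1) with coefficient
#' `gamma = exp(-1 / (fs_hz * decay_tau_s))`; [deconvolve()] solves the
#' nonnegative sparse problem
#' `min 0.5*||y - C||^2 + lambda * sum(s)` with `s[t] = C[t] - gamma*C[t-1] >= 0`.
#'
#' @param decay_tau_s Indicator decay time constant (s).
#' @param sparsity_penalty Nonnegative L1 penalty `lambda` on event amplitudes.
#' @param sparsity_n_sigma When the pipeline ([preprocess_traces()])
#'   deconvolves a trace, it adds `sparsity_n_sigma` times the trace's
#'   estimated noise SD to `sparsity_penalty`, so the shrinkage adapts to the
#'   recording's noise level; [deconvolve()] itself always uses the penalty
#'   it is given.
#' @param baseline_window_frames,baseline_percentile Rolling-percentile
#'   detrending options applied by the pipeline before deconvolution.
#' @return A `deconv_params` list.
#' @export
deconv_params <- function(decay_tau_s = 0.6, sparsity_penalty = 0,
                          sparsity_n_sigma = 3,
                          baseline_window_frames = 600L,
                          baseline_percentile = 10) {
  stopifnot(decay_tau_s > 0, sparsity_penalty >= 0, sparsity_n_sigma >= 0,
            baseline_window_frames >= 2,
            baseline_percentile >= 0, baseline_percentile <= 100)
  structure(
    list(decay_tau_s = decay_tau_s,
         sparsity_penalty = sparsity_penalty,
         sparsity_n_sigma = sparsity_n_sigma,
         baseline_window_frames = as.integer(baseline_window_frames),
         baseline_percentile = baseline_percentile),
    class = "deconv_params"
  )
}

#' Transient detection and validation parameters
#'
#' Dual-threshold detection: a frame is a candidate when its deconvolved
#' amplitude exceeds `deconv_frac` of the trace-wide maximum, and survives
#' only if the aligned fluorescence peak exceeds `amp_n_sigma` baseline-noise
#' SDs. Candidates are aligned to the fluorescence maximum within
#' `align_halfwidth_frames` frames; a final moving filter drops events whose
#' deconvolved amplitude is below `movfilt_rel_amp` of the largest event
#' within `movfilt_window_frames` frames.
#'
#' @param deconv_frac Fraction of the maximum deconvolved value (threshold 1).
#' @param amp_n_sigma Fluorescence amplitude threshold in units of
#'   baseline-noise SD (threshold 2).
#' @param align_halfwidth_frames Half-width (frames) of the peak-alignment
#'   window (default 5 = 0.5 s at 10 Hz).
#' @param dedup_radius_frames Aligned peaks closer than this many frames are
#'   treated as duplicate detections of one transient and collapsed, keeping
#'   the larger amplitude (default 4; events 5 or more frames apart are
#'   never merged).
#' @param movfilt_window_frames Span (frames) of the moving specificity filter.
#' @param movfilt_rel_amp Relative deconvolved amplitude below which an event
#'   within the span of a larger event is discarded.
#' @param validate_corr_min Minimum Pearson correlation with the indicator
#'   template for an event to validate.
#' @param validate_noise_max_sigma Maximum local residual SD, in units of the
#'   ROI noise SD, for an event to validate.
#' @return A `detection_params` list.
#' @export
detection_params <- function(deconv_frac = 0.05, amp_n_sigma = 3,
                             align_halfwidth_frames = 5L,
                             dedup_radius_frames = 4L,
                             movfilt_window_frames = 10L,
                             movfilt_rel_amp = 0.15,
                             validate_corr_min = 0.6,
                             validate_noise_max_sigma = 2) {
  stopifnot(deconv_frac > 0, deconv_frac < 1, amp_n_sigma >= 0,
            align_halfwidth_frames >= 0, dedup_radius_frames >= 0,
            movfilt_window_frames >= 0,
            movfilt_rel_amp >= 0, movfilt_rel_amp <= 1,
            validate_corr_min >= -1, validate_corr_min <= 1,
            validate_noise_max_sigma > 0)
  structure(
    list(deconv_frac = deconv_frac, amp_n_sigma = amp_n_sigma,
         align_halfwidth_frames = as.integer(align_halfwidth_frames),
         dedup_radius_frames = as.integer(dedup_radius_frames),
         movfilt_window_frames = as.integer(movfilt_window_frames),
         movfilt_rel_amp = movfilt_rel_amp,
         validate_corr_min = validate_corr_min,
         validate_noise_max_sigma = validate_noise_max_sigma),
    class = "detection_params"
  )
}

#' Burst definition
#'
#' A burst is a maximal run of at least `min_events` consecutive transients
#' whose adjacent interpeak intervals are all strictly below `max_interval_s`.
#' The threshold is usually derived from the interval-mixture intersection
#' ([mixture_intersection()]); 5.6 s is the TASK-inhibitor value and 5.3 s
#' the angiotensin-II value.
#'
#' @param max_interval_s Maximum interpeak interval (s) inside a burst.
#' @param min_events Minimum number of consecutive events (>= 2; default 3).
#' @return A `burst_definition` list.
#' @export
burst_definition <- function(max_interval_s = 5.6, min_events = 3L) {
  stopifnot(max_interval_s > 0, min_events >= 2)
  structure(
    list(max_interval_s = max_interval_s, min_events = as.integer(min_events)),
    class = "burst_definition"
  )
}
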