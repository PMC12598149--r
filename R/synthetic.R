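#' Evaluate the indicator kernel
#'
#' Peak-normalized difference of exponentials:
#' `k(t) = (exp(-t/decay) - exp(-t/rise)) / k_peak` for `t >= 0`, zero before
#' the event. The continuous-time peak value is computed analytically, so
#' `max_t k(t) = 1` and the sampled kernel never exceeds 1.
#'
#' @param t Numeric vector of times (s) relative to the event.
#' @param indicator An [indicator_params()] object.
#' @return Kernel values, same length as `t`.
#' @export
indicator_kernel <- function(t, indicator = indicator_params()) {
  tr <- indicator$rise_tau_s
  td <- indicator$decay_tau_s
  t_peak <- tr * td / (td - tr) * log(td / tr)
  k_peak <- exp(-t_peak / td) - exp(-t_peak / tr)
  k <- ifelse(t >= 0, (exp(-t / td) - exp(-t / tr)) / k_peak, 0)
  pmax(k, 0)
}

#' Time (s) from event to the kernel peak
#' @param indicator An [indicator_params()] object.
#' @return Peak delay in seconds.
#' @export
indicator_peak_delay <- function(indicator = indicator_params()) {
  tr <- indicator$rise_tau_s
  td <- indicator$decay_tau_s
  tr * td / (td - tr) * log(td / tr)
}

# Gaussian truncated below at `floor`, by rejection (floor is far in the
# lower tail for all preset parameter values, so acceptance is ~1).
rnorm_trunc <- function(n, mu, sigma, floor) {
  if (n == 0L) return(numeric(0))
  out <- rnorm(n, mu, sigma)
  bad <- which(out < floor)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mu, sigma)
    bad <- bad[out[bad] < floor]
  }
  out
}

#' Sample one ground-truth bursting event train
#'
#' Alternating renewal process: exponential interburst gaps (mean
#' `interburst_mean_s`), then a burst of `events_per_burst_min` plus a
#' geometric excess of events separated by truncated-Gaussian intervals.
#' Event times are confined to `[0, duration_s]`; a trailing burst cut by the
#' end of the recording keeps its realized events, and its window is recorded
#' in the burst table only if it still has at least `events_per_burst_min`
#' events.
#'
#' Uses the current R RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param params A [burst_train_params()] object.
#' @return A list with `spike_times` (sorted numeric vector, s), `bursts`
#'   (tibble: `burst_start_s`, `burst_end_s`, `n_events`), and `active`
#'   (logical: did the ROI's activity Bernoulli draw succeed).
#' @export
sample_burst_train <- function(params = burst_train_params()) {
  stopifnot(inherits(params, "burst_train_params"))
  empty <- list(
    spike_times = numeric(0),
    bursts = tibble::tibble(burst_start_s = numeric(0),
                            burst_end_s = numeric(0),
                            n_events = integer(0)),
    active = FALSE
  )
  active <- params$active_prob > 0 && runif(1) < params$active_prob
  if (!active || !is.finite(params$interburst_mean_s)) return(empty)

  spikes <- list()
  bursts <- list()
  t_cur <- 0
  repeat {
    # exponential gap, truncated below at the interval floor so the global
    # minimum interpeak interval invariant holds across burst boundaries too
    repeat {
      gap <- rexp(1, rate = 1 / params$interburst_mean_s)
      if (gap >= params$interval_floor_s) break
    }
    t_start <- t_cur + gap
    if (t_start > params$duration_s) break
    n_ev <- params$events_per_burst_min +
      rgeom(1, params$events_per_burst_geom_p)
    gaps <- rnorm_trunc(n_ev - 1, params$intraburst_mu_s,
                        params$intraburst_sigma_s, params$interval_floor_s)
    ev <- t_start + c(0, cumsum(gaps))
    ev <- ev[ev <= params$duration_s]  # truncate trailing burst
    if (length(ev) == 0) break
    spikes[[length(spikes) + 1L]] <- ev
    if (length(ev) >= params$events_per_burst_min) {
      bursts[[length(bursts) + 1L]] <- tibble::tibble(
        burst_start_s = ev[1], burst_end_s = ev[length(ev)],
        n_events = length(ev)
      )
    }
    if (length(ev) < n_ev) break  # recording ended inside this burst
    t_cur <- ev[length(ev)]
  }
  list(
    spike_times = unlist(spikes) %||% numeric(0),
    bursts = if (length(bursts)) dplyr::bind_rows(bursts) else empty$bursts,
    active = TRUE
  )
}

# Shared low-frequency background: three random-phase sinusoids at the base
# period and its subharmonics, standardized to the requested SD.
make_shared_background <- function(n_frames, fs_hz, noise) {
  if (noise$shared_bg_sd_dff == 0 || n_frames == 0) return(numeric(n_frames))
  t <- (seq_len(n_frames) - 1) / fs_hz
  periods <- noise$shared_bg_period_s / c(1, 2.3, 4.1)
  phases <- runif(3, 0, 2 * pi)
  amps <- c(1, 0.5, 0.25)
  bg <- rowSums(vapply(
    1:3, function(i) amps[i] * sin(2 * pi * t / periods[i] + phases[i]),
    numeric(n_frames)
  ))
  s <- sd(bg)
  if (s == 0) return(numeric(n_frames))
  bg / s * noise$shared_bg_sd_dff
}

#' Render an event train as a noisy fluorescence trace
#'
#' Linear superposition (no indicator saturation): the ROI trace is the sum
#' of unit-amplitude kernels at the event times, plus
#' `neuropil_coeff_true * shared_background`, a slow sinusoidal drift, and
#' white sensor noise. The matched neuropil trace is the shared background
#' plus independent white noise.
#'
#' @param spike_times Event times (s) within `[0, duration_s]`.
#' @param fs_hz Sampling rate (Hz).
#' @param duration_s Trace duration (s); `n_frames = round(duration_s * fs_hz)`.
#' @param indicator An [indicator_params()] object.
#' @param noise A [noise_params()] object.
#' @param shared_background Optional precomputed background vector (one per
#'   dataset); generated from `noise` if `NULL`.
#' @return A list with numeric vectors `F` and `Fneu` of length `n_frames`.
#' @export
render_trace <- function(spike_times, fs_hz = 10, duration_s = 600,
                         indicator = indicator_params(),
                         noise = noise_params(),
                         shared_background = NULL) {
  if (!is.finite(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "calci_invalid_parameter")
  }
  if (length(spike_times) && (min(spike_times) < 0 ||
                              max(spike_times) > duration_s)) {
    abort("spike times must lie within [0, duration_s].",
          class = "calci_invalid_parameter")
  }
  n_frames <- round(duration_s * fs_hz)
  t <- (seq_len(n_frames) - 1) / fs_hz
  f <- numeric(n_frames)
  # kernel support: until the decay tail falls below 1e-8 of peak
  support_s <- indicator$decay_tau_s * log(1e8)
  for (ts in spike_times) {
    i0 <- max(1L, floor(ts * fs_hz) + 1L)
    i1 <- min(n_frames, ceiling((ts + support_s) * fs_hz) + 1L)
    if (i0 > n_frames) next
    idx <- i0:i1
    f[idx] <- f[idx] +
      indicator$unit_amplitude_dff * indicator_kernel(t[idx] - ts, indicator)
  }
  if (is.null(shared_background)) {
    shared_background <- make_shared_background(n_frames, fs_hz, noise)
  }
  stopifnot(length(shared_background) == n_frames)
  drift <- if (noise$drift_amplitude_dff > 0) {
    noise$drift_amplitude_dff *
      sin(2 * pi * t / noise$drift_period_s + runif(1, 0, 2 * pi))
  } else numeric(n_frames)
  wn <- function() {
    if (noise$white_sd_dff > 0) rnorm(n_frames, 0, noise$white_sd_dff)
    else numeric(n_frames)
  }
  list(
    F = f + noise$neuropil_coeff_true * shared_background + drift + wn(),
    Fneu = shared_background + wn()
  )
}

#' Condition presets for the synthetic generator
#'
#' Four presets mirror the study's stimulation-by-osmolarity contrasts:
#' TASK-inhibitor (TI) or angiotensin II (AngII) stimulation in permissive
#' (280 mOsm) or suppressive (310 mOsm) media. The intraburst interval
#' distribution (Gaussian, 2.0 +- 0.3 s — the stereotyped within-burst
#' periodicity of these oscillators) is identical across presets, the
#' periodicity invariant of the biological system; the permissive TI
#' interburst gap matches the reference interburst exponential mean of
#' 15 s. Suppressive presets have a lower active-cell fraction, longer
#' interburst gaps, and fewer events per burst (hence shorter bursts).
#'
#' @return A named list of [burst_train_params()] objects.
#' @export
condition_presets <- function() {
  base <- function(active, gap, p) {
    burst_train_params(
      interburst_mean_s = gap,
      intraburst_mu_s = 2.0, intraburst_sigma_s = 0.3,
      events_per_burst_min = 3L, events_per_burst_geom_p = p,
      active_prob = active, duration_s = 600, interval_floor_s = 0.2
    )
  }
  list(
    `TI-280`    = base(0.60, 15, 0.25),
    `TI-310`    = base(0.25, 45, 0.55),
    `AngII-280` = base(0.50, 18, 0.30),
    `AngII-310` = base(0.22, 50, 0.55)
  )
}

#' Generate a complete synthetic dataset
#'
#' Samples a ground-truth event train per ROI under a condition preset and
#' renders each as a noisy fluorescence trace with a matched neuropil trace.
#' Reproducible: the master `seed` derives one RNG substream per ROI by
#' counter, so increasing `n_roi` extends a dataset without reshuffling
#' earlier ROIs.
#'
#' @param preset A preset name (see [condition_presets()]) or a
#'   [burst_train_params()] object.
#' @param n_roi Number of ROIs.
#' @param seed Master seed (integer).
#' @param duration_s Recording duration (s); overrides the preset's.
#' @param fs_hz Sampling rate (Hz).
#' @param zg_area_um2 Imaged zona glomerulosa area (um^2), used for
#'   active-cell density.
#' @param indicator,noise Rendering parameter objects.
#' @return A `calci_dataset` list: `traces` (tibble: `roi_id`, `frame`,
#'   `time_s`, `F`, `Fneu`), `ground_truth` (list of `roi`, `spikes`,
#'   `bursts` tibbles), plus metadata (`condition`, `fs_hz`, `duration_s`,
#'   `zg_area_um2`, `seed`, parameter objects).
#' @export
generate_dataset <- function(preset, n_roi, seed,
                             duration_s = NULL, fs_hz = 10,
                             zg_area_um2 = 10000,
                             indicator = indicator_params(),
                             noise = noise_params()) {
  if (is.character(preset)) {
    presets <- condition_presets()
    if (!preset %in% names(presets)) {
      abort(paste0("unknown preset '", preset, "'; available: ",
                   paste(names(presets), collapse = ", ")),
            class = "calci_unknown_preset")
    }
    condition <- preset
    params <- presets[[preset]]
  } else if (inherits(preset, "burst_train_params")) {
    condition <- "custom"
    params <- preset
  } else {
    abort("`preset` must be a preset name or burst_train_params object.",
          class = "calci_invalid_parameter")
  }
  if (!is.null(duration_s)) {
    params$duration_s <- duration_s
  }
  duration_s <- params$duration_s
  n_frames <- round(duration_s * fs_hz)
  stopifnot(n_roi >= 0, zg_area_um2 > 0)

  # counter-derived substreams: one for the shared background, one per ROI
  set.seed(as.integer(seed))
  stream_seeds <- sample.int(.Machine$integer.max - 1L, n_roi + 1L)

  set.seed(stream_seeds[1L])
  shared_bg <- make_shared_background(n_frames, fs_hz, noise)

  roi_ids <- sprintf("roi%04d", seq_len(n_roi))
  traces <- vector("list", n_roi)
  spikes <- vector("list", n_roi)
  bursts <- vector("list", n_roi)
  active <- logical(n_roi)
  for (i in seq_len(n_roi)) {
    set.seed(stream_seeds[i + 1L])
    train <- sample_burst_train(params)
    active[i] <- train$active
    tr <- render_trace(train$spike_times, fs_hz, duration_s,
                       indicator, noise, shared_background = shared_bg)
    traces[[i]] <- tibble::tibble(
      roi_id = roi_ids[i],
      frame = seq_len(n_frames),
      time_s = (seq_len(n_frames) - 1) / fs_hz,
      F = tr$F, Fneu = tr$Fneu
    )
    spikes[[i]] <- tibble::tibble(roi_id = roi_ids[i],
                                  spike_time_s = train$spike_times)
    bursts[[i]] <- dplyr::mutate(train$bursts, roi_id = roi_ids[i],
                                 .before = 1)
  }
  structure(
    list(
      traces = if (n_roi) dplyr::bind_rows(traces) else
        tibble::tibble(roi_id = character(0), frame = integer(0),
                       time_s = numeric(0), F = numeric(0), Fneu = numeric(0)),
      ground_truth = list(
        roi = tibble::tibble(roi_id = roi_ids, active = active),
        spikes = if (n_roi) dplyr::bind_rows(spikes) else
          tibble::tibble(roi_id = character(0), spike_time_s = numeric(0)),
        bursts = if (n_roi) dplyr::bind_rows(bursts) else
          tibble::tibble(roi_id = character(0), burst_start_s = numeric(0),
                         burst_end_s = numeric(0), n_events = integer(0))
      ),
      condition = condition,
      fs_hz = fs_hz,
      duration_s = duration_s,
      zg_area_um2 = zg_area_um2,
      seed = as.integer(seed),
      train_params = params,
      indicator = indicator,
      noise = noise
    ),
    class = "calci_dataset"
  )
}

#' @export
print.calci_dataset <- function(x, ...) {
  n_roi <- nrow(x$ground_truth$roi)
  cat("<calci_dataset> condition:", x$condition,
      "| ROIs:", n_roi,
      "| duration:", x$duration_s, "s @", x$fs_hz, "Hz",
      "| seed:", x$seed, "\n")
  cat("  active ROIs:", sum(x$ground_truth$roi$active),
      "| ground-truth events:", nrow(x$ground_truth$spikes),
      "| ground-truth bursts:", nrow(x$ground_truth$bursts), "\n")
  invisible(x)
}

#' Sample interpeak intervals from a Gaussian+exponential mixture
#'
#' With probability `w_g` an interval is drawn from a Gaussian (mean `mu_s`,
#' SD `sigma_s`) truncated below at `interval_floor_s`; otherwise from an
#' exponential with rate `rate_per_s`. This is the generative counterpart of
#' the interval model fitted by [fit_interval_mixture()].
#'
#' @param n Number of intervals (>= 0).
#' @param w_g Gaussian mixing weight in `[0, 1]`.
#' @param mu_s,sigma_s Gaussian mean and SD (s).
#' @param rate_per_s Exponential rate (1/s).
#' @param interval_floor_s Truncation floor (s) of the Gaussian component.
#' @return A tibble with `interval_s` and `component`
#'   (`"gaussian"`/`"exponential"`).
#' @export
sample_interval_mixture <- function(n, w_g, mu_s, sigma_s, rate_per_s,
                                    interval_floor_s = 0.2) {
  if (length(n) != 1 || n < 0) {
    abort("`n` must be a nonnegative integer.",
          class = "calci_invalid_parameter")
  }
  stopifnot(w_g >= 0, w_g <= 1, sigma_s > 0, rate_per_s > 0)
  n <- as.integer(n)
  if (n == 0L) {
    return(tibble::tibble(interval_s = numeric(0), component = character(0)))
  }
  is_g <- runif(n) < w_g
  out <- numeric(n)
  out[is_g] <- rnorm_trunc(sum(is_g), mu_s, sigma_s, interval_floor_s)
  out[!is_g] <- rexp(sum(!is_g), rate_per_s)
  tibble::tibble(interval_s = out,
                 component = ifelse(is_g, "gaussian", "exponential"))
}
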