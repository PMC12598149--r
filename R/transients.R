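#' Robust baseline-noise SD of a fluorescence trace
#'
#' Estimated from first differences as
#' `MAD(diff(trace)) / (sqrt(2) * 0.6745)`, which is insensitive to sparse
#' transients riding on the baseline (a transient contributes few large
#' differences, which the median absolute deviation ignores).
#'
#' @param trace Numeric vector with at least 100 frames.
#' @return Noise SD (same units as the trace).
#' @export
estimate_noise <- function(trace) {
  if (length(trace) < 100) {
    abort("need at least 100 frames to estimate noise.",
          class = "calci_trace_short")
  }
  # mad() already divides by 0.6745 via its 1.4826 constant
  mad(diff(trace)) / sqrt(2)
}

# Staged detector on one trace. `s` and `fluor` are aligned vectors; `align`
# is the signal whose local maxima define peak positions (the denoised trace
# when available, else the fluorescence itself). Returns positional indices
# (1-based) with amplitudes.
detect_trace <- function(s, fluor, sigma, params, align = fluor) {
  empty <- tibble::tibble(peak_index = integer(0),
                          fluor_amplitude = numeric(0),
                          deconv_amplitude = numeric(0))
  n <- length(s)
  if (n == 0 || length(fluor) != n) {
    if (n == 0) return(empty)
    abort("deconvolved and fluorescence traces must have equal length.",
          class = "calci_length_mismatch")
  }
  smax <- max(s)
  if (smax <= 0) return(empty)

  # (i) dual threshold, part 1: fraction of the maximum deconvolved value
  cand <- which(s > params$deconv_frac * smax)
  if (length(cand) == 0) return(empty)

  # (ii) merge contiguous candidate runs, keeping the run's max (earlier
  # frame on ties)
  run_id <- cumsum(c(1L, diff(cand) > 1L))
  cand <- vapply(split(cand, run_id),
                 function(ix) ix[which.max(s[ix])], integer(1))
  damp <- s[cand]

  # (iii) align each candidate to the fluorescence maximum within the
  # +-align window (earlier frame on ties), collapse duplicates
  hw <- params$align_halfwidth_frames
  peak <- vapply(cand, function(f0) {
    lo <- max(1L, f0 - hw); hi <- min(n, f0 + hw)
    lo + which.max(align[lo:hi]) - 1L
  }, integer(1))
  # peak amplitude estimated as the local mean over peak +-1 frame, which is
  # robust to single-frame noise at the peak sample
  amp3 <- vapply(peak, function(pk) {
    mean(fluor[max(1L, pk - 1L):min(n, pk + 1L)])
  }, numeric(1))
  ev <- tibble::tibble(peak_index = peak,
                       fluor_amplitude = amp3,
                       deconv_amplitude = damp) |>
    dplyr::group_by(.data$peak_index) |>
    dplyr::summarise(
      fluor_amplitude = max(.data$fluor_amplitude),
      deconv_amplitude = max(.data$deconv_amplitude),
      .groups = "drop"
    )
  # peaks within the dedup radius are duplicate detections of one transient:
  # the detection carrying the dominant deconvolved mass wins (earlier frame
  # on ties)
  if (params$dedup_radius_frames > 0 && nrow(ev) > 1) {
    o <- order(-ev$deconv_amplitude, ev$peak_index)
    taken <- integer(0)
    keep <- logical(nrow(ev))
    for (i in o) {
      if (!length(taken) ||
          min(abs(taken - ev$peak_index[i])) > params$dedup_radius_frames) {
        keep[i] <- TRUE
        taken <- c(taken, ev$peak_index[i])
      }
    }
    ev <- ev[keep, ]
  }

  # (iv) dual threshold, part 2: minimum fluorescence amplitude relative to
  # baseline noise
  ev <- dplyr::filter(ev, .data$fluor_amplitude >= params$amp_n_sigma * sigma)
  if (nrow(ev) == 0) return(empty)

  # (v) moving filter: drop events dwarfed by a larger event within the span
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    near <- abs(ev$peak_index - ev$peak_index[i]) <= params$movfilt_window_frames
    ev$deconv_amplitude[i] >=
      params$movfilt_rel_amp * max(ev$deconv_amplitude[near])
  }, logical(1))
  dplyr::arrange(ev[keep, ], .data$peak_index)
}

#' Detect calcium transients by dual-threshold peak detection
#'
#' Per ROI, candidate frames are those whose deconvolved amplitude exceeds
#' `deconv_frac` of the ROI maximum; contiguous runs are merged; each
#' candidate is aligned to the fluorescence maximum within
#' `align_halfwidth_frames` frames; events whose fluorescence amplitude falls
#' below `amp_n_sigma` noise SDs are discarded; and a moving filter removes
#' minor fluctuations superimposed on larger transients. When the input
#' carries a `denoised` column, peak alignment uses the denoised
#' fluorescence (whose local maxima are noise-robust) while the amplitude
#' threshold is always measured on the detrended fluorescence itself, as the
#' mean over the peak and its two flanking frames.
#'
#' @param processed A `calci_processed` object from [preprocess_traces()],
#'   or a tibble with columns `roi_id`, `frame`, `fluor`, `deconv`.
#' @param params A [detection_params()] object. Per-ROI overrides may be
#'   given via `roi_overrides`, a named list `list(roi_id = detection_params)`.
#' @param fs_hz Sampling rate; taken from `processed` when available.
#' @param noise Optional tibble `roi_id`, `sigma`; estimated with
#'   [estimate_noise()] if missing.
#' @param roi_overrides Optional named list of per-ROI [detection_params()].
#' @return A `calci_transients` tibble: `roi_id`, `peak_frame`,
#'   `peak_time_s`, `fluor_amplitude`, `deconv_amplitude`, `validated`
#'   (initialized `NA`; see [validate_transients()]).
#' @export
detect_transients <- function(processed, params = detection_params(),
                              fs_hz = NULL, noise = NULL,
                              roi_overrides = NULL) {
  if (inherits(processed, "calci_processed")) {
    fs_hz <- fs_hz %||% processed$fs_hz
    data <- processed$traces
  } else {
    data <- processed
  }
  fs_hz <- fs_hz %||% 10
  stopifnot(all(c("roi_id", "frame", "fluor", "deconv") %in% names(data)))

  out <- data |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      sigma <- if (!is.null(noise)) {
        noise$sigma[match(d$roi_id[1], noise$roi_id)]
      } else {
        estimate_noise(d$fluor)
      }
      p <- roi_overrides[[d$roi_id[1]]] %||% params
      al <- if ("denoised" %in% names(d)) d$denoised else d$fluor
      ev <- detect_trace(d$deconv, d$fluor, sigma, p, align = al)
      tibble::tibble(
        roi_id = d$roi_id[1],
        peak_frame = d$frame[ev$peak_index],
        peak_time_s = (d$frame[ev$peak_index] - 1) / fs_hz,
        fluor_amplitude = ev$fluor_amplitude,
        deconv_amplitude = ev$deconv_amplitude,
        validated = NA
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble::tibble(roi_id = character(0), peak_frame = integer(0),
                          peak_time_s = numeric(0),
                          fluor_amplitude = numeric(0),
                          deconv_amplitude = numeric(0), validated = logical(0))
  }
  class(out) <- c("calci_transients", class(out))
  attr(out, "fs_hz") <- fs_hz
  out
}

#' Validate detected transients by template correlation
#'
#' Rejects low-correlation and high-noise events. For each event, the
#' fluorescence segment from 2 frames before to `ceil(3 * decay_tau * fs)`
#' frames after the peak is fitted by least squares with a local transient
#' model: the event's own indicator template at frame shifts -1, 0, +1
#' (absorbing alignment jitter and subframe event timing) plus the templates
#' of neighbouring detected events whose tails reach into the segment. The
#' event validates when (a) the best Pearson correlation between one of its
#' own shifted templates and the segment minus the fitted neighbour
#' contributions reaches `validate_corr_min`, and (b) the residual SD of the
#' full fit stays below `validate_noise_max_sigma` times the ROI noise SD.
#' Unvalidated events are retained but flagged; downstream metrics exclude
#' them by default.
#'
#' @param events A `calci_transients` tibble from [detect_transients()].
#' @param processed The `calci_processed` object (or tibble with `roi_id`,
#'   `frame`, `fluor`) the events came from.
#' @param indicator An [indicator_params()] object defining the template.
#' @param params A [detection_params()] object (validation thresholds).
#' @param fs_hz Sampling rate; taken from `processed` when available.
#' @return `events` with the `validated` column filled in.
#' @export
validate_transients <- function(events, processed,
                                indicator = indicator_params(),
                                params = detection_params(),
                                fs_hz = NULL) {
  if (inherits(processed, "calci_processed")) {
    fs_hz <- fs_hz %||% processed$fs_hz
    data <- processed$traces
  } else {
    data <- processed
  }
  fs_hz <- fs_hz %||% attr(events, "fs_hz") %||% 10
  if (nrow(events) == 0) return(events)

  n_post <- as.integer(ceiling(3 * indicator$decay_tau_s * fs_hz))
  rel <- seq(-2L, n_post)
  # align templates so the sampled kernel peak sits at the event's frame
  tgrid <- seq(0, by = 1 / fs_hz, length.out = n_post + 10L)
  j_peak <- which.max(indicator_kernel(tgrid, indicator)) - 1L
  kcol <- function(idx, pos) {
    indicator_kernel((idx - pos + j_peak) / fs_hz, indicator)
  }
  own_shifts <- c(-1L, 0L, 1L)

  validated <- logical(nrow(events))
  for (rid in unique(events$roi_id)) {
    d <- data[data$roi_id == rid, ]
    trace <- d$fluor
    sigma <- estimate_noise(trace)
    ev_rows <- which(events$roi_id == rid)
    pos_all <- match(events$peak_frame[ev_rows], d$frame)
    if (anyNA(pos_all)) {
      abort("event outside trace bounds.", class = "calci_event_bounds")
    }
    for (k in seq_along(ev_rows)) {
      pos <- pos_all[k]
      seg_idx <- pos + rel
      seg_idx <- seg_idx[seg_idx >= 1 & seg_idx <= length(trace)]
      seg <- trace[seg_idx]
      own <- vapply(own_shifts, function(dd) kcol(seg_idx, pos + dd),
                    numeric(length(seg_idx)))
      if (length(seg) < 5 || sd(seg) == 0 || all(apply(own, 2, sd) == 0)) {
        validated[ev_rows[k]] <- FALSE
        next
      }
      nb <- pos_all[pos_all != pos &
                      pos_all >= pos - 2L * n_post &
                      pos_all <= pos + n_post + 2L]
      n_own <- ncol(own)
      X <- own
      for (q in nb) X <- cbind(X, kcol(seg_idx, q))
      nonconst <- apply(X, 2, sd) > 0
      nonconst[seq_len(n_own)] <- TRUE  # keep own columns addressable
      is_own <- c(rep(TRUE, n_own), rep(FALSE, ncol(X) - n_own))[nonconst]
      X <- cbind(1, X[, nonconst, drop = FALSE])
      fit <- stats::lm.fit(X, seg)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      nb_cols <- which(!c(TRUE, is_own))
      other <- if (length(nb_cols)) {
        drop(X[, nb_cols, drop = FALSE] %*% beta[nb_cols])
      } else 0
      segc <- seg - other
      r <- if (sd(segc) == 0) 0 else {
        max(apply(own, 2, function(cl) {
          if (sd(cl) == 0) -1 else cor(segc, cl)
        }))
      }
      res_sd <- sd(drop(seg - X %*% beta))
      validated[ev_rows[k]] <- (r >= params$validate_corr_min) &&
        (res_sd <= params$validate_noise_max_sigma * sigma + 1e-12)
    }
  }
  events$validated <- validated
  events
}

#' Score detected events against ground-truth spike times
#'
#' Greedy one-to-one matching of detected peak times to ground-truth event
#' times within a frame tolerance. Because the detector reports fluorescence
#' peak frames while ground truth records event onsets, truth times are
#' shifted by the indicator peak delay (`peak_delay_s`) before matching.
#'
#' @param events A `calci_transients` tibble (optionally filtered to
#'   validated events).
#' @param truth Tibble with `roi_id`, `spike_time_s`.
#' @param fs_hz Sampling rate (Hz).
#' @param tol_frames Matching tolerance in frames (default 2).
#' @param peak_delay_s Shift (s) applied to truth times; default the kernel
#'   peak delay of the standard indicator.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
score_events <- function(events, truth, fs_hz = 10, tol_frames = 2,
                         peak_delay_s = indicator_peak_delay()) {
  tol_s <- tol_frames / fs_hz
  tp <- 0L; fp <- 0L; fn <- 0L
  rois <- union(unique(events$roi_id), unique(truth$roi_id))
  for (rid in rois) {
    det <- sort(events$peak_time_s[events$roi_id == rid])
    tru <- sort(truth$spike_time_s[truth$roi_id == rid]) + peak_delay_s
    used <- rep(FALSE, length(tru))
    for (dt in det) {
      cand <- which(!used & abs(tru - dt) <= tol_s + 1e-9)
      if (length(cand)) {
        used[cand[which.min(abs(tru[cand] - dt))]] <- TRUE
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(!used)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}
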