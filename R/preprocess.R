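#' Subtract the scaled neuropil signal from an ROI trace
#'
#' Removes background contamination: `corrected = F - coeff * Fneu`,
#' elementwise.
#'
#' @param f ROI fluorescence vector.
#' @param fneu Matched neuropil vector (same length).
#' @param coeff Contamination coefficient in `[0, 1]` (default 0.7).
#' @return Corrected vector.
#' @export
subtract_neuropil <- function(f, fneu, coeff = 0.7) {
  if (length(f) != length(fneu)) {
    abort("`f` and `fneu` must have the same length.",
          class = "calci_length_mismatch")
  }
  stopifnot(coeff >= 0, coeff <= 1)
  f - coeff * fneu
}

#' Remove slow baseline drift by a running percentile
#'
#' Subtracts a running low-percentile baseline computed in a centered window
#' (edges clamped to the trace), removing components with period much longer
#' than the window while preserving transient peak amplitudes. The percentile
#' is evaluated on a grid of window centers (stride = window/10) and linearly
#' interpolated between them; when the window covers the whole trace the
#' global percentile is subtracted exactly.
#'
#' @param trace Numeric vector.
#' @param window_frames Window length in frames (>= 2).
#' @param percentile Percentile in `[0, 100]` used as the baseline
#'   (default 10).
#' @return Detrended vector of the same length.
#' @export
rolling_baseline <- function(trace, window_frames = 600L, percentile = 10) {
  if (percentile < 0 || percentile > 100) {
    abort("`percentile` must be in [0, 100].",
          class = "calci_invalid_parameter")
  }
  stopifnot(window_frames >= 2)
  n <- length(trace)
  if (n == 0) return(trace)
  if (window_frames >= n) {
    return(trace - quantile(trace, percentile / 100, names = FALSE))
  }
  half <- window_frames %/% 2L
  stride <- max(1L, window_frames %/% 10L)
  centers <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(centers, function(ct) {
    quantile(trace[max(1L, ct - half):min(n, ct + half)],
             percentile / 100, names = FALSE)
  }, numeric(1))
  baseline <- approx(centers, q, xout = seq_len(n), rule = 2)$y
  trace - baseline
}

#' Moving-window SD-ratio quality control
#'
#' Computes the trace SD in sliding windows (stride = half a window) and the
#' ratio of the maximum to the minimum windowed SD; ROIs whose signal
#' variance is wildly nonstationary (ratio above `sd_ratio_max`) are flagged
#' for exclusion as poor signal-to-noise. The minimum SD is floored at
#' `sd_floor_frac * sd(trace)` so flat segments yield a large finite ratio.
#' The ratio is invariant to rescaling the trace.
#'
#' @param trace Numeric vector, at least `window_frames` long.
#' @param params A [qc_params()] object.
#' @return A one-row tibble: `min_sd`, `max_sd`, `ratio`, `passed`.
#' @export
sd_ratio_qc <- function(trace, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  w <- params$window_frames
  n <- length(trace)
  if (n < w) {
    abort("trace is shorter than the QC window.", class = "calci_trace_short")
  }
  starts <- seq(1L, n - w + 1L, by = max(1L, w %/% 2L))
  sds <- vapply(starts, function(s0) sd(trace[s0:(s0 + w - 1L)]), numeric(1))
  min_sd <- min(sds)
  max_sd <- max(sds)
  floor_sd <- params$sd_floor_frac * sd(trace)
  ratio <- max_sd / max(min_sd, floor_sd)
  if (!is.finite(ratio)) ratio <- 1  # all-constant trace
  tibble::tibble(min_sd = min_sd, max_sd = max_sd, ratio = ratio,
                 passed = ratio <= params$sd_ratio_max)
}

#' Nonnegative sparse AR(1) deconvolution of a fluorescence trace
#'
#' Models the indicator decay as AR(1) with coefficient
#' `gamma = exp(-1/(fs_hz * decay_tau_s))` and solves
#' `min 0.5*||trace - C||^2 + lambda * sum(s)` subject to
#' `s[t] = C[t] - gamma*C[t-1] >= 0` and `C >= 0`, by a pool-adjacent-
#' violators pass (exact for this convex program). `s` is the inferred
#' event-amplitude sequence; `C` the denoised trace.
#'
#' @param trace Numeric vector (baseline-subtracted fluorescence).
#' @param params A [deconv_params()] object.
#' @param fs_hz Sampling rate (Hz).
#' @return A `deconv_result` list with vectors `C` and `s` and the `gamma`
#'   used.
#' @export
deconvolve <- function(trace, params = deconv_params(), fs_hz = 10) {
  stopifnot(inherits(params, "deconv_params"), fs_hz > 0)
  if (any(!is.finite(trace))) {
    abort("trace contains non-finite values.", class = "calci_nonfinite")
  }
  gamma <- exp(-1 / (fs_hz * params$decay_tau_s))
  stopifnot(gamma > 0, gamma < 1)
  res <- oasis_ar1(as.numeric(trace), gamma, params$sparsity_penalty)
  structure(
    list(C = res$C, s = res$s, gamma = gamma,
         lambda = params$sparsity_penalty),
    class = "deconv_result"
  )
}

#' Objective value of the sparse deconvolution program
#'
#' `0.5 * ||y - C||^2 + lambda * sum(s)`; used to compare solvers.
#'
#' @param trace Observed trace.
#' @param C Denoised trace.
#' @param s Event-amplitude sequence.
#' @param lambda Sparsity penalty.
#' @return Scalar objective value.
#' @export
deconv_objective <- function(trace, C, s, lambda = 0) {
  0.5 * sum((trace - C)^2) + lambda * sum(s)
}

#' Preprocess a long trace table
#'
#' Runs the fixed pipeline order per ROI: neuropil subtraction, rolling
#' percentile detrending, SD-ratio QC, and sparse nonnegative deconvolution.
#' ROIs failing QC are retained in the QC report but dropped from the
#' processed traces.
#'
#' @param traces Tibble with columns `roi_id`, `frame`, `F` and optionally
#'   `Fneu` (long format, one row per ROI per frame).
#' @param fs_hz Sampling rate (Hz).
#' @param neuropil_coeff Neuropil subtraction coefficient; ignored when no
#'   `Fneu` column is present.
#' @param qc A [qc_params()] object, or `NULL` to skip QC.
#' @param deconv A [deconv_params()] object.
#' @return A `calci_processed` list: `traces` (tibble with `roi_id`, `frame`,
#'   `time_s`, `fluor` detrended fluorescence, `denoised`, `deconv`),
#'   `qc` (per-ROI QC report tibble), `fs_hz`.
#' @export
preprocess_traces <- function(traces, fs_hz = 10, neuropil_coeff = 0.7,
                              qc = qc_params(), deconv = deconv_params()) {
  stopifnot(all(c("roi_id", "frame", "F") %in% names(traces)))
  has_neu <- "Fneu" %in% names(traces)
  traces <- dplyr::arrange(traces, .data$roi_id, .data$frame)

  per_roi <- traces |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_split()

  qc_rows <- vector("list", length(per_roi))
  out_rows <- vector("list", length(per_roi))
  for (i in seq_along(per_roi)) {
    d <- per_roi[[i]]
    corrected <- if (has_neu) {
      subtract_neuropil(d$F, d$Fneu, neuropil_coeff)
    } else d$F
    fluor <- rolling_baseline(corrected, deconv$baseline_window_frames,
                              deconv$baseline_percentile)
    if (!is.null(qc)) {
      qr <- sd_ratio_qc(fluor, qc)
      qc_rows[[i]] <- dplyr::mutate(qr, roi_id = d$roi_id[1], .before = 1)
      if (!qr$passed) next
    }
    dcp <- deconv
    if (deconv$sparsity_n_sigma > 0 && length(fluor) >= 100) {
      dcp$sparsity_penalty <- deconv$sparsity_penalty +
        deconv$sparsity_n_sigma * estimate_noise(fluor)
    }
    dc <- deconvolve(fluor, dcp, fs_hz)
    out_rows[[i]] <- tibble::tibble(
      roi_id = d$roi_id[1], frame = d$frame,
      time_s = (d$frame - 1) / fs_hz,
      fluor = fluor, denoised = dc$C, deconv = dc$s
    )
  }
  empty_traces <- tibble::tibble(
    roi_id = character(0), frame = integer(0), time_s = numeric(0),
    fluor = numeric(0), denoised = numeric(0), deconv = numeric(0))
  out <- dplyr::bind_rows(out_rows)
  structure(
    list(
      traces = if (nrow(out)) out else empty_traces,
      qc = dplyr::bind_rows(qc_rows),
      fs_hz = fs_hz
    ),
    class = "calci_processed"
  )
}

#' @export
print.calci_processed <- function(x, ...) {
  n_in <- if (nrow(x$qc)) nrow(x$qc) else
    dplyr::n_distinct(x$traces$roi_id)
  cat("<calci_processed>", n_in, "ROIs in,",
      dplyr::n_distinct(x$traces$roi_id), "passing QC @", x$fs_hz, "Hz\n")
  invisible(x)
}
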