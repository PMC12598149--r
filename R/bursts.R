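#' Fit a Gaussian+exponential mixture to interpeak intervals
#'
#' Models the interval distribution as
#' `w_g * Normal(mu, sigma^2) + (1 - w_g) * Exponential(rate)`: the Gaussian
#' captures the regular within-burst periodicity, the exponential the long
#' between-burst gaps. Fitted by EM; the Gaussian component is truncated
#' below at `truncate_at` during fitting (default 0, since intervals are
#' positive — ignoring the truncation measurably biases the fit whenever the
#' Gaussian has appreciable mass below zero). E-step responsibilities come
#' from the weighted component densities; the exponential rate and the
#' mixing weight have closed-form M-steps, while the truncated-Gaussian
#' mean/SD update is a Nelder-Mead refinement of the expected complete-data
#' log-likelihood started at the current values, so the observed
#' log-likelihood never decreases. The best of `n_restarts` runs by
#' log-likelihood is returned; the first restart initializes the Gaussian
#' from intervals below the sample median and the exponential from those
#' above, later restarts use random quantile splits.
#'
#' @param intervals Positive interval vector (s), length >= 50.
#' @param tol Log-likelihood convergence gain (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param n_restarts Number of EM restarts (default 5).
#' @param truncate_at Lower truncation point of the Gaussian component
#'   (default 0; `-Inf` fits a plain Gaussian with fully closed-form
#'   M-steps).
#' @return An `interval_mixture` object with fields `w_g`, `mu_s`, `sigma_s`,
#'   `w_e`, `rate_per_s`, `loglik`, `n_intervals`, `n_iter`, `converged`;
#'   the per-iteration log-likelihood trace of the winning restart is in
#'   `attr(, "loglik_trace")`.
#' @export
fit_interval_mixture <- function(intervals, tol = 1e-8, max_iter = 500,
                                 n_restarts = 5, truncate_at = 0) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 50) {
    abort("need at least 50 intervals to fit the mixture.",
          class = "calci_too_few_intervals")
  }
  if (any(intervals <= 0)) {
    abort("all intervals must be positive.", class = "calci_invalid_parameter")
  }
  if (diff(range(intervals)) == 0) {
    abort("all intervals identical: degenerate fit.",
          class = "calci_degenerate_fit")
  }
  x <- intervals
  n <- length(x)
  a <- truncate_at
  dgauss <- function(x, mu, sigma) {
    if (is.finite(a)) {
      dnorm(x, mu, sigma) / max(1 - pnorm(a, mu, sigma), 1e-300)
    } else {
      dnorm(x, mu, sigma)
    }
  }

  run_em <- function(split_q) {
    cut <- quantile(x, split_q, names = FALSE)
    lo <- x[x <= cut]; hi <- x[x > cut]
    if (length(lo) < 2 || length(hi) < 2) {
      lo <- x[x <= median(x)]; hi <- x[x > median(x)]
    }
    w_g <- length(lo) / n
    mu <- mean(lo)
    sigma <- max(sd(lo), 1e-3)
    rate <- 1 / mean(hi)
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      dg <- w_g * dgauss(x, mu, sigma)
      de <- (1 - w_g) * dexp(x, rate)
      tot <- dg + de
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_prev) && ll - ll_prev < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_prev <- ll
      r <- dg / tot
      sw <- sum(r)
      if (!is.finite(sw) || sw < 2 || n - sw < 2) break  # component collapsed
      w_g <- sw / n
      srx <- sum(r * x)
      srx2 <- sum(r * x^2)
      mu_cf <- srx / sw
      sg_cf <- sqrt(max(srx2 / sw - mu_cf^2, 1e-12))
      if (is.finite(a)) {
        # negative expected Gaussian complete-data log-likelihood in terms
        # of the weighted sufficient statistics; mu is kept inside the
        # support (mu >= a) so the truncated Gaussian stays a bell around a
        # real period rather than degenerating into a second decaying
        # component
        nq <- function(p) {
          m <- a + exp(p[1]); sg <- exp(p[2])
          sw * log(sg) + (srx2 - 2 * m * srx + m^2 * sw) / (2 * sg^2) +
            sw * log(max(1 - pnorm(a, m, sg), .Machine$double.xmin))
        }
        o <- stats::optim(c(log(max(mu - a, 1e-6)), log(sigma)), nq)
        mu <- a + exp(o$par[1])
        sigma <- max(exp(o$par[2]), 1e-6)
      } else {
        mu <- mu_cf
        sigma <- max(sg_cf, 1e-6)
      }
      rate <- (n - sw) / sum((1 - r) * x)
    }
    list(w_g = w_g, mu = mu, sigma = sigma, rate = rate, loglik = ll,
         n_iter = iter, converged = converged, trace = trace)
  }

  splits <- c(0.5, runif(max(0, n_restarts - 1), 0.3, 0.7))
  fits <- lapply(splits[seq_len(n_restarts)], run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  structure(
    list(w_g = best$w_g, mu_s = best$mu, sigma_s = best$sigma,
         w_e = 1 - best$w_g, rate_per_s = best$rate,
         loglik = best$loglik, n_intervals = n,
         n_iter = best$n_iter, converged = best$converged),
    loglik_trace = best$trace,
    class = "interval_mixture"
  )
}

#' Construct an interval mixture from known parameters
#'
#' @param w_g Gaussian weight in `[0, 1]`.
#' @param mu_s,sigma_s Gaussian mean and SD (s).
#' @param rate_per_s Exponential rate (1/s).
#' @return An `interval_mixture` object (no fit statistics).
#' @export
interval_mixture <- function(w_g, mu_s, sigma_s, rate_per_s) {
  stopifnot(w_g >= 0, w_g <= 1, sigma_s > 0, rate_per_s > 0)
  structure(
    list(w_g = w_g, mu_s = mu_s, sigma_s = sigma_s, w_e = 1 - w_g,
         rate_per_s = rate_per_s, loglik = NA_real_,
         n_intervals = NA_integer_, n_iter = NA_integer_, converged = NA),
    class = "interval_mixture"
  )
}

#' @export
print.interval_mixture <- function(x, ...) {
  cat(sprintf(
    "<interval_mixture> w_g=%.4f N(%.3f, %.3f^2) + w_e=%.4f Exp(rate=%.4f)\n",
    x$w_g, x$mu_s, x$sigma_s, x$w_e, x$rate_per_s))
  if (!is.na(x$loglik)) {
    cat(sprintf("  logLik %.2f on %d intervals (%d EM iterations%s)\n",
                x$loglik, x$n_intervals, x$n_iter,
                if (isTRUE(x$converged)) ", converged" else ""))
  }
  invisible(x)
}

#' @export
tidy.interval_mixture <- function(x, ...) {
  tibble::tibble(
    term = c("w_g", "mu_s", "sigma_s", "w_e", "rate_per_s"),
    estimate = c(x$w_g, x$mu_s, x$sigma_s, x$w_e, x$rate_per_s)
  )
}

#' @export
glance.interval_mixture <- function(x, ...) {
  thr <- tryCatch(mixture_intersection(x), error = function(e) NA_real_)
  tibble::tibble(logLik = x$loglik, n_intervals = x$n_intervals,
                 n_iter = x$n_iter, converged = x$converged,
                 threshold_s = thr)
}

#' Burst threshold: intersection of the mixture's weighted densities
#'
#' Finds the crossing point `x* > mu_s` where
#' `w_g * dnorm(x*, mu, sigma) = w_e * dexp(x*, rate)`, i.e. where an
#' interpeak interval becomes more likely to come from the between-burst
#' exponential than from the within-burst Gaussian. Root-found by uniroot
#' bisection on `[mu_s, mu_s + 10*sigma_s]` to `|f| < 1e-10`. This value is
#' the maximum interpeak interval within a burst.
#'
#' @param mix An `interval_mixture` object (fitted or constructed).
#' @param bracket_sigmas Upper bracket in Gaussian SDs above the mean.
#' @return Threshold in seconds.
#' @export
mixture_intersection <- function(mix, bracket_sigmas = 10) {
  stopifnot(inherits(mix, "interval_mixture"))
  if (mix$w_g <= 0 || mix$w_e <= 0) {
    abort("both mixture components must have positive weight.",
          class = "calci_no_intersection")
  }
  f <- function(x) {
    mix$w_g * dnorm(x, mix$mu_s, mix$sigma_s) -
      mix$w_e * dexp(x, mix$rate_per_s)
  }
  lo <- mix$mu_s
  hi <- mix$mu_s + bracket_sigmas * mix$sigma_s
  if (!(f(lo) > 0 && f(hi) < 0)) {
    abort("no density crossing above the Gaussian mean in the bracket.",
          class = "calci_no_intersection")
  }
  r <- uniroot(f, c(lo, hi), tol = 1e-12)
  if (abs(f(r$root)) > 1e-10) {
    abort("root finding did not reach |f| < 1e-10.",
          class = "calci_no_intersection")
  }
  r$root
}

# Core segmentation on a sorted time vector; returns tibble with list-column
# of event times.
segment_times <- function(times, defn) {
  empty <- tibble::tibble(onset_s = numeric(0), offset_s = numeric(0),
                          duration_s = numeric(0), n_events = integer(0),
                          event_times_s = list())
  n <- length(times)
  if (n == 0) return(empty)
  if (is.unsorted(times, strictly = TRUE)) {
    abort("event times must be sorted and unique.",
          class = "calci_unsorted_events")
  }
  if (n < defn$min_events) return(empty)
  below <- diff(times) < defn$max_interval_s
  # maximal runs of consecutive below-threshold intervals
  grp <- cumsum(c(0L, !below))  # events joined while interval below threshold
  runs <- split(seq_len(n), grp)
  out <- purrr::map(runs, function(ix) {
    if (length(ix) < defn$min_events) return(NULL)
    tt <- times[ix]
    tibble::tibble(onset_s = tt[1], offset_s = tt[length(tt)],
                   duration_s = tt[length(tt)] - tt[1],
                   n_events = length(tt), event_times_s = list(tt))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty else out
}

#' Segment transient trains into bursts
#'
#' A burst is a maximal run of consecutive events whose adjacent interpeak
#' intervals are all strictly below `defn$max_interval_s`, containing at
#' least `defn$min_events` events. Events outside such runs stay unassigned.
#'
#' @param events A `calci_transients` tibble (or any tibble with `roi_id` and
#'   `peak_time_s`), or a sorted numeric vector of event times for a single
#'   train.
#' @param defn A [burst_definition()] object.
#' @param validated_only Drop unvalidated events first (default `TRUE`; events
#'   with `validated = NA` are kept).
#' @return A `calci_bursts` tibble: `roi_id`, `burst_id`, `onset_s`,
#'   `offset_s`, `duration_s`, `n_events`, and the list-column
#'   `event_times_s`.
#' @export
segment_bursts <- function(events, defn = burst_definition(),
                           validated_only = TRUE) {
  stopifnot(inherits(defn, "burst_definition"))
  if (is.numeric(events)) {
    events <- tibble::tibble(roi_id = "roi", peak_time_s = as.numeric(events),
                             validated = NA)
  }
  if (validated_only && "validated" %in% names(events)) {
    events <- dplyr::filter(events, is.na(.data$validated) | .data$validated)
  }
  out <- events |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      b <- segment_times(d$peak_time_s, defn)
      if (nrow(b)) dplyr::mutate(b, roi_id = d$roi_id[1],
                                 burst_id = dplyr::row_number(), .before = 1)
      else NULL
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble::tibble(roi_id = character(0), burst_id = integer(0),
                          onset_s = numeric(0), offset_s = numeric(0),
                          duration_s = numeric(0), n_events = integer(0),
                          event_times_s = list())
  }
  class(out) <- c("calci_bursts", class(out))
  attr(out, "definition") <- defn
  out
}

#' Per-ROI and per-slice activity metrics
#'
#' Summarizes a recording the way the study's activity figures do: per ROI,
#' the transient count, burst count, mean burst duration, fraction of time
#' spent bursting (summed burst durations over the recording duration), and
#' the intraburst period — the median adjacent interpeak interval inside
#' bursts. The median (rather than the mean) is deliberate: an exponential
#' interburst gap occasionally falls below the burst threshold and joins two
#' bursts, planting a long spurious "intraburst" interval whose frequency
#' differs across stimulation conditions; a mean inherits that
#' condition-dependent contamination, while the median leaves the period
#' estimate invariant, which is the quantity being measured;
#' per slice, the number of active ROIs (>= `min_transients_active`
#' transients), their density over the zG area, the total transient count,
#' and transient counts in 1-minute bins.
#'
#' @param events A `calci_transients` tibble.
#' @param bursts A `calci_bursts` tibble from the same events.
#' @param duration_s Recording (analysis-window) duration in seconds.
#' @param zg_area_um2 Imaged zG area (um^2); `NA` skips the density.
#' @param min_transients_active Transients needed for an ROI to count as
#'   active (default 3).
#' @param bin_s Bin width (s) for the binned transient frequency
#'   (default 60).
#' @param validated_only Use only validated events (default `TRUE`; `NA`
#'   flags are kept).
#' @param roi_ids Optional character vector of all ROIs in the recording;
#'   ROIs without any event still get a per-ROI row (zero transients).
#' @return An `activity_metrics` list: `per_roi` tibble, `slice` one-row
#'   tibble, `binned` tibble (`bin_start_s`, `n_events`,
#'   `rate_per_min`).
#' @export
compute_metrics <- function(events, bursts, duration_s,
                            zg_area_um2 = NA_real_,
                            min_transients_active = 3L, bin_s = 60,
                            validated_only = TRUE, roi_ids = NULL) {
  if (duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "calci_invalid_parameter")
  }
  if (validated_only && "validated" %in% names(events)) {
    events <- dplyr::filter(events, is.na(.data$validated) | .data$validated)
  }
  roi_ids <- unique(c(roi_ids, events$roi_id, bursts$roi_id))
  per_roi <- purrr::map(roi_ids, function(rid) {
    ev <- events[events$roi_id == rid, ]
    bu <- bursts[bursts$roi_id == rid, ]
    intra <- unlist(purrr::map(bu$event_times_s, diff)) %||% numeric(0)
    tibble::tibble(
      roi_id = rid,
      n_transients = nrow(ev),
      n_bursts = nrow(bu),
      mean_burst_duration_s = if (nrow(bu)) mean(bu$duration_s) else NA_real_,
      fraction_active = sum(bu$duration_s) / duration_s,
      intraburst_period_s = if (length(intra)) median(intra) else NA_real_
    )
  }) |> dplyr::bind_rows()
  if (length(roi_ids) == 0) {
    per_roi <- tibble::tibble(roi_id = character(0), n_transients = integer(0),
                              n_bursts = integer(0),
                              mean_burst_duration_s = numeric(0),
                              fraction_active = numeric(0),
                              intraburst_period_s = numeric(0))
  }
  n_active <- sum(per_roi$n_transients >= min_transients_active)
  if (!is.na(zg_area_um2) && zg_area_um2 <= 0) {
    abort("`zg_area_um2` must be positive.", class = "calci_invalid_parameter")
  }
  slice <- tibble::tibble(
    n_rois = nrow(per_roi),
    n_active_rois = n_active,
    active_cell_density_per_um2 = if (is.na(zg_area_um2)) NA_real_ else
      n_active / zg_area_um2,
    total_transients = nrow(events),
    n_bursts = sum(per_roi$n_bursts),
    mean_burst_duration_s = if (any(per_roi$n_bursts > 0)) {
      mean(per_roi$mean_burst_duration_s[per_roi$n_bursts > 0])
    } else NA_real_,
    mean_fraction_active = if (nrow(per_roi)) mean(per_roi$fraction_active)
      else NA_real_,
    mean_intraburst_period_s = if (any(!is.na(per_roi$intraburst_period_s))) {
      mean(per_roi$intraburst_period_s, na.rm = TRUE)
    } else NA_real_
  )
  breaks <- seq(0, duration_s, by = bin_s)
  if (breaks[length(breaks)] < duration_s) breaks <- c(breaks, duration_s)
  counts <- if (nrow(events)) {
    tabulate(findInterval(events$peak_time_s, breaks,
                          rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  } else integer(length(breaks) - 1)
  binned <- tibble::tibble(
    bin_start_s = breaks[-length(breaks)],
    n_events = counts,
    rate_per_min = counts / (diff(breaks) / 60)
  )
  structure(list(per_roi = per_roi, slice = slice, binned = binned,
                 duration_s = duration_s),
            class = "activity_metrics")
}

#' @export
print.activity_metrics <- function(x, ...) {
  cat("<activity_metrics>", nrow(x$per_roi), "ROIs over", x$duration_s, "s\n")
  print(x$slice)
  invisible(x)
}

#' @export
tidy.activity_metrics <- function(x, ...) x$per_roi

#' @export
glance.activity_metrics <- function(x, ...) x$slice
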