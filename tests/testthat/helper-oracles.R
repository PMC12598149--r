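# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms / code paths than R/.

# Exhaustive O(n^2) burst segmentation: enumerate all (i, j) windows, keep
# those that are valid runs, maximal, and long enough.
oracle_segment <- function(times, thr, min_events) {
  n <- length(times)
  if (n == 0) return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                                n_events = integer(0)))
  gaps_ok <- c(TRUE, diff(times) < thr)   # gaps_ok[k]: interval before event k
  bad <- cumsum(!gaps_ok)                 # run id; equal bad => joined
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_events) next
      if (bad[j] != bad[i]) next          # some internal interval >= thr
      left_max <- i == 1 || !gaps_ok[i]
      right_max <- j == n || !gaps_ok[j + 1]
      if (left_max && right_max) {
        out[[length(out) + 1]] <- data.frame(onset_s = times[i],
                                             offset_s = times[j],
                                             n_events = j - i + 1L)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               n_events = integer(0))
}

# Brute-force staged transient detector: plain-loop re-implementation of the
# detection rules (candidate threshold, run merge, alignment, duplicate
# collapse, amplitude threshold, moving filter).
oracle_detect <- function(s, fluor, sigma, p, align = fluor) {
  n <- length(s)
  empty <- data.frame(peak = integer(0), damp = numeric(0), famp = numeric(0))
  if (n == 0 || max(s) <= 0) return(empty)
  cand <- which(s > p$deconv_frac * max(s))
  if (!length(cand)) return(empty)
  reps <- integer(0)
  k <- 1
  while (k <= length(cand)) {
    j <- k
    while (j < length(cand) && cand[j + 1] == cand[j] + 1) j <- j + 1
    run <- cand[k:j]
    reps <- c(reps, run[which.max(s[run])])
    k <- j + 1
  }
  peaks <- vapply(reps, function(f) {
    w <- max(1, f - p$align_halfwidth_frames):
      min(n, f + p$align_halfwidth_frames)
    w[which.max(align[w])]
  }, integer(1))
  ev <- data.frame(peak = peaks, damp = s[reps])
  ev <- do.call(rbind, lapply(split(ev, ev$peak), function(g) {
    data.frame(peak = g$peak[1], damp = max(g$damp))
  }))
  ev$famp <- vapply(ev$peak, function(pk) {
    mean(fluor[max(1, pk - 1):min(n, pk + 1)])
  }, numeric(1))
  ev <- ev[order(ev$peak), ]
  if (p$dedup_radius_frames > 0 && nrow(ev) > 1) {
    ord <- order(-ev$damp, ev$peak)
    taken <- integer(0)
    keep <- rep(FALSE, nrow(ev))
    for (i in ord) {
      if (!length(taken) ||
          min(abs(taken - ev$peak[i])) > p$dedup_radius_frames) {
        keep[i] <- TRUE
        taken <- c(taken, ev$peak[i])
      }
    }
    ev <- ev[keep, ]
  }
  ev <- ev[ev$famp >= p$amp_n_sigma * sigma, ]
  if (nrow(ev) > 1) {
    keep <- vapply(seq_len(nrow(ev)), function(i) {
      near <- abs(ev$peak - ev$peak[i]) <= p$movfilt_window_frames
      ev$damp[i] >= p$movfilt_rel_amp * max(ev$damp[near])
    }, logical(1))
    ev <- ev[keep, ]
  }
  ev[order(ev$peak), ]
}

# Generic box-constrained quadratic solver for the deconvolution program,
# parameterized by the event amplitudes s >= 0 (C is the causal AR(1)
# filter of s, so C >= 0 is implied).
oracle_qp_deconv <- function(y, gamma, lambda) {
  n <- length(y)
  fwd <- function(s) as.numeric(stats::filter(s, gamma, "recursive"))
  obj <- function(s) {
    cc <- fwd(s)
    0.5 * sum((y - cc)^2) + lambda * sum(s)
  }
  gr <- function(s) {
    r <- fwd(s) - y
    rev(as.numeric(stats::filter(rev(r), gamma, "recursive"))) + lambda
  }
  o <- stats::optim(rep(0, n), obj, gr, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 5000, factr = 1e1))
  list(s = o$par, C = fwd(o$par), objective = o$value)
}

# Mean of a Gaussian truncated below at `a` (closed form).
tnorm_mean <- function(mu, sigma, a) {
  z <- (a - mu) / sigma
  mu + sigma * dnorm(z) / (1 - pnorm(z))
}

# Independent truncated-normal sampler (inverse CDF, unlike the package's
# rejection sampler).
rtnorm_inv <- function(n, mu, sigma, a) {
  u <- runif(n, pnorm(a, mu, sigma), 1)
  qnorm(u, mu, sigma)
}

# Dense grid-scan for the weighted-density crossing above the Gaussian mean.
oracle_intersection <- function(w_g, mu, sigma, rate, res = 1e-4) {
  xs <- seq(mu, mu + 12 * sigma, by = res)
  f <- w_g * dnorm(xs, mu, sigma) - (1 - w_g) * dexp(xs, rate)
  i <- which(f[-length(f)] > 0 & f[-1] <= 0)[1]
  mean(xs[c(i, i + 1)])
}

# Difference-of-exponentials kernel evaluated from scratch (independent of
# indicator_kernel()).
oracle_kernel <- function(t, rise, decay) {
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  kp <- exp(-tp / decay) - exp(-tp / rise)
  ifelse(t >= 0, (exp(-t / decay) - exp(-t / rise)) / kp, 0)
}

# Noiseless render of spike times on a frame grid using oracle_kernel.
oracle_render <- function(spikes, fs, duration, rise = 0.08, decay = 0.6) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  out <- numeric(length(t))
  for (ts in spikes) out <- out + oracle_kernel(t - ts, rise, decay)
  out
}

# Random event train with controllable clustering, for segmentation tests.
random_train <- function(n_max = 50) {
  n <- sample.int(n_max, 1)
  sort(cumsum(c(runif(1, 0, 5),
                sample(c(runif(n - 1, 0.3, 4), rexp(n - 1, 1 / 10)), n - 1))))
}
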