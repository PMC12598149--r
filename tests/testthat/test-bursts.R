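test_that("EM fitting recovers generating mixtures", {
  set.seed(11)
  iv <- sample_interval_mixture(50000, 0.7545, 2, 1.5, 1 / 15,
                                interval_floor_s = 0)
  f <- fit_interval_mixture(iv$interval_s)
  expect_lt(abs(f$w_g - 0.7545) / 0.7545, 0.05)
  expect_lt(abs(f$mu_s - 2) / 2, 0.05)
  expect_lt(abs(f$sigma_s - 1.5) / 1.5, 0.05)
  expect_lt(abs(f$rate_per_s - 1 / 15) * 15, 0.05)
  expect_identical(f$w_g + f$w_e, 1)

  # purely exponential intervals leave the Gaussian weight near zero
  set.seed(3)
  expect_lt(fit_interval_mixture(rexp(20000, 1 / 5))$w_g, 0.05)
  set.seed(4)
  expect_lt(fit_interval_mixture(rexp(20000, 1 / 15))$w_g, 0.05)
})

test_that("EM log-likelihood is non-decreasing and inputs are checked", {
  set.seed(12)
  for (i in 1:3) {
    iv <- sample_interval_mixture(3000, runif(1, 0.3, 0.9), 2, 1, 0.08)
    tr <- attr(fit_interval_mixture(iv$interval_s), "loglik_trace")
    expect_true(all(diff(tr) >= -1e-7))
  }
  expect_error(fit_interval_mixture(rexp(10)),
               class = "calci_too_few_intervals")
  expect_error(fit_interval_mixture(rep(2, 100)),
               class = "calci_degenerate_fit")
  expect_error(fit_interval_mixture(c(rexp(99), -1)),
               class = "calci_invalid_parameter")
})

test_that("the mixture intersection reproduces the printed burst thresholds", {
  ti <- mixture_intersection(interval_mixture(0.7545, 2, 1.5, 1 / 15))
  ang <- mixture_intersection(interval_mixture(0.6644, 2, 1.5, 1 / 15))
  expect_identical(round(ti, 1), 5.6)
  expect_identical(round(ang, 1), 5.3)
  # dense grid-scan oracle agreement
  expect_lt(abs(ti - oracle_intersection(0.7545, 2, 1.5, 1 / 15)), 1e-3)
  expect_lt(abs(ang - oracle_intersection(0.6644, 2, 1.5, 1 / 15)), 1e-3)

  expect_error(mixture_intersection(interval_mixture(1, 2, 1.5, 1 / 15)),
               class = "calci_no_intersection")
  expect_error(mixture_intersection(interval_mixture(0, 2, 1.5, 1 / 15)),
               class = "calci_no_intersection")
})

test_that("fit-then-intersect converges to the generating threshold", {
  set.seed(2)
  iv <- sample_interval_mixture(5e4, 0.7545, 2, 1.5, 1 / 15,
                                interval_floor_s = 0)
  thr <- mixture_intersection(fit_interval_mixture(iv$interval_s))
  expect_lt(abs(thr - 5.5998), 0.15)
})

test_that("burst segmentation matches the worked example and handles edge cases", {
  times <- c(0, 1, 2, 10, 11, 12, 13, 30)
  b <- segment_bursts(times, burst_definition(5.6, 3))
  expect_identical(nrow(b), 2L)
  expect_equal(b$onset_s, c(0, 10))
  expect_equal(b$offset_s, c(2, 13))
  expect_equal(b$duration_s, c(2, 3))
  expect_identical(b$n_events, c(3L, 4L))

  expect_identical(nrow(segment_bursts(c(1, 2), burst_definition(5.6, 3))), 0L)
  expect_identical(nrow(segment_bursts(c(0, 10, 20, 30),
                                       burst_definition(5.6, 3))), 0L)
  expect_error(segment_bursts(c(3, 1, 2), burst_definition()),
               class = "calci_unsorted_events")
})

test_that("burst segmentation equals the exhaustive oracle on random trains", {
  set.seed(606)
  defn <- burst_definition(5.6, 3)
  for (i in 1:2000) {
    times <- random_train(50)
    got <- segment_bursts(times, defn)
    want <- oracle_segment(times, defn$max_interval_s, defn$min_events)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$onset_s, want$onset_s)
      expect_equal(got$offset_s, want$offset_s)
      expect_identical(got$n_events, want$n_events)
    }
  }
})

test_that("segmentation conserves events and is monotone in the threshold", {
  set.seed(707)
  for (i in 1:50) {
    times <- random_train(50)
    prev <- -1L
    for (thr in c(1, 2, 4, 6, 10)) {
      b <- segment_bursts(times, burst_definition(thr, 3))
      # each event in at most one burst
      assigned <- unlist(b$event_times_s)
      expect_identical(anyDuplicated(assigned), 0L)
      expect_lte(length(assigned), length(times))
      # intervals inside a burst sum to its duration
      if (nrow(b)) {
        expect_equal(vapply(b$event_times_s, function(tt) sum(diff(tt)),
                            numeric(1)),
                     b$duration_s)
      }
      # widening the threshold can merge bursts (so the burst count may
      # drop) but can never strip an event of burst membership
      expect_gte(length(assigned), prev)
      prev <- length(assigned)
    }
  }
})

test_that("activity metrics match hand-computed values", {
  times <- c(0, 1, 2, 10, 11, 12, 13, 30)
  ev <- tibble::tibble(roi_id = "r1", peak_time_s = times,
                       peak_frame = as.integer(times * 10 + 1),
                       fluor_amplitude = 1, deconv_amplitude = 1,
                       validated = TRUE)
  bu <- segment_bursts(ev, burst_definition(5.6, 3))
  m <- compute_metrics(ev, bu, duration_s = 60)
  expect_equal(m$per_roi$fraction_active, 5 / 60)
  expect_equal(m$per_roi$intraburst_period_s, 1.0)
  expect_identical(m$per_roi$n_transients, 8L)
  expect_identical(m$per_roi$n_bursts, 2L)
  expect_equal(m$per_roi$mean_burst_duration_s, 2.5)

  # binned frequency: 8 events in the first minute of a 2-minute recording
  m2 <- compute_metrics(ev, bu, duration_s = 120)
  expect_identical(m2$binned$n_events, c(8L, 0L))
  expect_equal(m2$binned$rate_per_min, c(8, 0))

  # no bursts: missing (not zero) mean duration
  ev2 <- dplyr::filter(ev, peak_time_s > 25)
  m3 <- compute_metrics(ev2, segment_bursts(ev2, burst_definition(5.6, 3)),
                        duration_s = 60)
  expect_identical(m3$per_roi$n_bursts, 0L)
  expect_true(is.na(m3$per_roi$mean_burst_duration_s))
  expect_identical(m3$per_roi$fraction_active, 0)

  # density: 12 active ROIs over 4000 um^2
  ev12 <- dplyr::bind_rows(lapply(1:13, function(i) {
    k <- if (i <= 12) 3 else 2   # the 13th ROI stays below the cutoff
    tibble::tibble(roi_id = sprintf("r%02d", i),
                   peak_time_s = seq_len(k) * 2,
                   peak_frame = as.integer(seq_len(k) * 20),
                   fluor_amplitude = 1, deconv_amplitude = 1,
                   validated = TRUE)
  }))
  m4 <- compute_metrics(ev12, segment_bursts(ev12, burst_definition(5.6, 3)),
                        duration_s = 60, zg_area_um2 = 4000)
  expect_identical(m4$slice$n_active_rois, 12L)
  expect_equal(m4$slice$active_cell_density_per_um2, 0.003)

  expect_error(compute_metrics(ev, bu, duration_s = 0),
               class = "calci_invalid_parameter")
  expect_error(compute_metrics(ev, bu, duration_s = 60, zg_area_um2 = -1),
               class = "calci_invalid_parameter")
})

test_that("tidy and glance methods summarize fitted objects", {
  set.seed(9)
  iv <- sample_interval_mixture(2000, 0.7, 2, 0.5, 0.1)
  f <- fit_interval_mixture(iv$interval_s)
  td <- tidy(f)
  expect_identical(td$term,
                   c("w_g", "mu_s", "sigma_s", "w_e", "rate_per_s"))
  gl <- glance(f)
  expect_true(is.finite(gl$logLik))
  expect_true(is.finite(gl$threshold_s))
})
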