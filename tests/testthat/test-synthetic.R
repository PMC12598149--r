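test_that("burst-train parameters reject impossible settings", {
  expect_error(burst_train_params(duration_s = 0),
               class = "calci_invalid_parameter")
  expect_error(burst_train_params(duration_s = -5),
               class = "calci_invalid_parameter")
  expect_error(burst_train_params(intraburst_mu_s = 0.1,
                                  interval_floor_s = 0.2),
               class = "calci_invalid_parameter")
  expect_error(burst_train_params(events_per_burst_min = 2))
})

test_that("inactive ROIs and infinite interburst gaps give empty trains", {
  set.seed(1)
  tr <- sample_burst_train(burst_train_params(active_prob = 0))
  expect_length(tr$spike_times, 0)
  expect_false(tr$active)
  tr2 <- sample_burst_train(burst_train_params(interburst_mean_s = Inf,
                                               active_prob = 1))
  expect_length(tr2$spike_times, 0)
})

test_that("sampled trains satisfy the ground-truth structural invariants", {
  p <- burst_train_params()
  set.seed(42)
  for (i in 1:30) {
    tr <- sample_burst_train(p)
    ts <- tr$spike_times
    bu <- tr$bursts
    if (length(ts) > 1) {
      expect_true(all(diff(ts) > 0))
      # truncation floor applies to every interpeak interval
      expect_gte(min(diff(ts)), p$interval_floor_s)
    }
    expect_true(all(ts >= 0 & ts <= p$duration_s))
    if (nrow(bu) > 0) {
      expect_true(all(bu$n_events >= p$events_per_burst_min))
      expect_true(all(bu$burst_end_s >= bu$burst_start_s))
      if (nrow(bu) > 1) {
        # windows disjoint and ordered
        expect_true(all(bu$burst_start_s[-1] > bu$burst_end_s[-nrow(bu)]))
      }
      # spikes inside a window belong to that burst
      for (k in seq_len(nrow(bu))) {
        inside <- sum(ts >= bu$burst_start_s[k] & ts <= bu$burst_end_s[k])
        expect_identical(inside, as.integer(bu$n_events[k]))
      }
    }
  }
})

test_that("burst count matches the renewal-theory expectation", {
  # fixed 5 events per burst, mean cycle = 30 + 4 * 2 s => ~15.8 bursts/600 s
  p <- burst_train_params(interburst_mean_s = 30, intraburst_mu_s = 2,
                          intraburst_sigma_s = 0.3,
                          events_per_burst_min = 5L,
                          events_per_burst_geom_p = 1,
                          active_prob = 1, duration_s = 600)
  set.seed(99)
  counts <- replicate(400, nrow(sample_burst_train(p)$bursts))
  expect_equal(mean(counts), 600 / (30 + 4 * 2), tolerance = 0.04)
})

test_that("rendering is kernel-exact, linear, and silent without input", {
  quiet <- noise_params(white_sd_dff = 0, drift_amplitude_dff = 0,
                        shared_bg_sd_dff = 0)
  r0 <- render_trace(numeric(0), duration_s = 60, noise = quiet)
  expect_true(all(r0$F == 0))
  expect_true(all(r0$Fneu == 0))

  r1 <- render_trace(10, duration_s = 60, noise = quiet)
  expected <- oracle_render(10, fs = 10, duration = 60)
  expect_lt(max(abs(r1$F - expected)), 1e-7)
  peak_frame <- which.max(r1$F)
  expect_lte(abs(peak_frame - (round(10 * 10) + 1)), 3)
  expect_equal(max(r1$F), max(expected), tolerance = 1e-9)

  ra <- render_trace(10, duration_s = 60, noise = quiet)
  rb <- render_trace(40, duration_s = 60, noise = quiet)
  rab <- render_trace(c(10, 40), duration_s = 60, noise = quiet)
  expect_lt(max(abs(rab$F - (ra$F + rb$F))), 1e-9)

  expect_error(render_trace(70, duration_s = 60, noise = quiet),
               class = "calci_invalid_parameter")
})

test_that("dataset generation is deterministic and prefix-stable", {
  d1 <- generate_dataset("TI-310", 6, seed = 7, duration_s = 60)
  d2 <- generate_dataset("TI-310", 6, seed = 7, duration_s = 60)
  expect_identical(d1$traces, d2$traces)
  expect_identical(d1$ground_truth, d2$ground_truth)

  # growing n_roi extends the dataset without reshuffling earlier ROIs
  d3 <- generate_dataset("TI-310", 3, seed = 7, duration_s = 60)
  expect_identical(
    dplyr::filter(d1$traces, roi_id %in% d3$ground_truth$roi$roi_id),
    d3$traces)

  expect_error(generate_dataset("no-such-preset", 2, seed = 1),
               class = "calci_unknown_preset")

  d0 <- generate_dataset("TI-280", 0, seed = 1, duration_s = 60)
  expect_identical(nrow(d0$traces), 0L)
  expect_identical(d0$condition, "TI-280")
  expect_identical(d0$fs_hz, 10)
})

test_that("permissive presets activate more ROIs than suppressive ones", {
  wins <- 0L
  for (s in 1:20) {
    a <- generate_dataset("TI-280", 40, seed = s, duration_s = 30)
    b <- generate_dataset("TI-310", 40, seed = s, duration_s = 30)
    wins <- wins + (sum(a$ground_truth$roi$active) >
                      sum(b$ground_truth$roi$active))
  }
  expect_gte(wins, 19L)
})

test_that("the interval-mixture sampler matches its distributional oracles", {
  expect_identical(nrow(sample_interval_mixture(0, 0.5, 2, 1, 0.1)), 0L)
  expect_error(sample_interval_mixture(-1, 0.5, 2, 1, 0.1),
               class = "calci_invalid_parameter")

  set.seed(5)
  g <- sample_interval_mixture(30000, 1, 2, 0.3, 0.1)
  expect_true(all(g$component == "gaussian"))
  expect_lte(abs(mean(g$interval_s) - 2), 3 * 0.3 / sqrt(30000))
  expect_gte(min(g$interval_s), 0.2)

  # full mixture mean against closed form and an independent inverse-CDF
  # sampler of the same truncated mixture
  set.seed(6)
  m <- sample_interval_mixture(1e5, 0.7545, 2, 1.5, 1 / 15,
                               interval_floor_s = 0.2)
  truth <- 0.7545 * tnorm_mean(2, 1.5, 0.2) + (1 - 0.7545) * 15
  set.seed(60)
  ind <- ifelse(runif(1e5) < 0.7545, rtnorm_inv(1e5, 2, 1.5, 0.2),
                rexp(1e5, 1 / 15))
  expect_lte(abs(mean(m$interval_s) - truth) / truth, 0.01)
  expect_lte(abs(mean(m$interval_s) - mean(ind)) / truth, 0.01)
})

test_that("intraburst intervals share one distribution across presets", {
  presets <- condition_presets()
  collect <- function(p, n_target) {
    p$active_prob <- 1
    out <- numeric(0)
    set.seed(2718)
    while (length(out) < n_target) {
      tr <- sample_burst_train(p)
      for (k in seq_len(nrow(tr$bursts))) {
        inside <- tr$spike_times[tr$spike_times >= tr$bursts$burst_start_s[k] &
                                   tr$spike_times <= tr$bursts$burst_end_s[k]]
        out <- c(out, diff(inside))
      }
    }
    out[seq_len(n_target)]
  }
  a <- collect(presets[["TI-280"]], 1e4)
  b <- collect(presets[["TI-310"]], 1e4)
  expect_gt(t.test(a, b)$p.value, 0.01)
  expect_equal(mean(a), mean(b), tolerance = 0.02)
})
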