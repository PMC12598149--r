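test_that("noise estimation is calibrated and transient-insensitive", {
  expect_identical(estimate_noise(rep(5, 200)), 0)
  expect_error(estimate_noise(rnorm(50)), class = "calci_trace_short")

  set.seed(55)
  ok <- replicate(200, {
    e <- estimate_noise(rnorm(6000))
    e >= 0.9 && e <= 1.1
  })
  expect_gte(mean(ok), 0.95)

  # sparse transients barely move the estimate
  set.seed(56)
  base <- rnorm(6000, 0, 0.3)
  spiked <- base + 3 * oracle_render(sort(runif(20, 5, 590)), 10, 600)
  expect_lt(abs(estimate_noise(spiked) - estimate_noise(base)) /
              estimate_noise(base), 0.15)
})

test_that("detection returns no events for silent input", {
  d <- tibble::tibble(roi_id = "r", frame = 1:200, fluor = rnorm(200),
                      deconv = rep(0, 200))
  ev <- detect_transients(d, noise = tibble::tibble(roi_id = "r", sigma = 1))
  expect_identical(nrow(ev), 0L)
})

test_that("dual thresholds, duplicate collapse, and the moving filter stage correctly", {
  # a major transient at frame 100 plus a minor deconvolved blip
  fluor <- oracle_render(9.9, 10, 60) + 0.05 * oracle_render(11.1, 10, 60)
  n <- length(fluor)
  mk <- function(blip_at) {
    s <- numeric(n)
    s[100] <- 1
    s[blip_at] <- 0.05
    tibble::tibble(roi_id = "r", frame = seq_len(n), fluor = fluor, deconv = s)
  }
  noise <- tibble::tibble(roi_id = "r", sigma = 0.01)

  # blip fails the deconvolved-fraction threshold outright
  ev <- detect_transients(mk(103), detection_params(deconv_frac = 0.1),
                          noise = noise)
  expect_identical(nrow(ev), 1L)
  win <- 95:105
  expect_identical(ev$peak_frame, win[which.max(fluor[win])])

  # with a permissive fraction, a 3-frame blip is a duplicate of the same
  # transient and collapses onto it
  ev2 <- detect_transients(mk(103), detection_params(deconv_frac = 0.01),
                           noise = noise)
  expect_identical(nrow(ev2), 1L)

  # a 12-frame blip survives collapse but is removed by the moving filter
  ev3 <- detect_transients(mk(112), detection_params(deconv_frac = 0.01),
                           noise = noise)
  expect_identical(nrow(ev3), 1L)
  expect_identical(ev3$peak_frame, ev$peak_frame)
  # ... and is kept once the moving filter is disabled
  ev4 <- detect_transients(mk(112),
                           detection_params(deconv_frac = 0.01,
                                            movfilt_rel_amp = 0),
                           noise = noise)
  expect_identical(nrow(ev4), 2L)
})

test_that("the staged detector equals its brute-force oracle", {
  set.seed(202)
  for (i in 1:100) {
    n <- 200
    s <- numeric(n)
    spikes <- sample(n, 12)
    s[spikes] <- runif(12, 0.05, 1)
    s[sample(n, 30)] <- s[sample(n, 30)] + runif(30, 0, 0.08)
    fluor <- rnorm(n, 0, 0.3) +
      as.numeric(stats::filter(s, 0.85, "recursive"))
    p <- detection_params(
      deconv_frac = runif(1, 0.01, 0.3),
      amp_n_sigma = runif(1, 0, 2),
      align_halfwidth_frames = sample(0:6, 1),
      dedup_radius_frames = sample(0:5, 1),
      movfilt_window_frames = sample(0:15, 1),
      movfilt_rel_amp = runif(1, 0, 0.5)
    )
    use_denoised <- i %% 2 == 0
    align <- if (use_denoised) {
      as.numeric(stats::filter(s, 0.85, "recursive"))
    } else {
      fluor
    }
    d <- tibble::tibble(roi_id = "r", frame = seq_len(n), fluor = fluor,
                        deconv = s)
    if (use_denoised) d$denoised <- align
    got <- detect_transients(d, p,
                             noise = tibble::tibble(roi_id = "r", sigma = 1))
    want <- oracle_detect(s, fluor, 1, p, align = align)
    expect_identical(got$peak_frame, as.integer(want$peak))
    expect_equal(got$deconv_amplitude, want$damp)
    expect_equal(got$fluor_amplitude, want$famp)
  }
})

test_that("raising either detection threshold never adds events", {
  set.seed(301)
  spikes <- sort(runif(40, 2, 280))
  quiet <- noise_params(white_sd_dff = 0.15, drift_amplitude_dff = 0,
                        shared_bg_sd_dff = 0)
  r <- render_trace(spikes, duration_s = 300, noise = quiet)
  dc <- deconvolve(r$F, deconv_params(sparsity_penalty = 0.3), fs_hz = 10)
  d <- tibble::tibble(roi_id = "r", frame = seq_along(r$F), fluor = r$F,
                      deconv = dc$s, denoised = dc$C)
  noise <- tibble::tibble(roi_id = "r", sigma = estimate_noise(r$F))
  fracs <- c(0.02, 0.05, 0.1, 0.2)
  sigmas <- c(1, 2, 3, 4)
  counts <- matrix(0L, length(fracs), length(sigmas))
  for (i in seq_along(fracs)) {
    for (j in seq_along(sigmas)) {
      counts[i, j] <- nrow(detect_transients(
        d, detection_params(deconv_frac = fracs[i], amp_n_sigma = sigmas[j]),
        noise = noise))
    }
  }
  expect_true(all(apply(counts, 2, diff) <= 0))
  expect_true(all(apply(counts, 1, diff) <= 0))
})

test_that("noise-free renders are recovered exactly", {
  set.seed(401)
  spikes <- cumsum(runif(40, 0.6, 3))
  quiet <- noise_params(white_sd_dff = 0, drift_amplitude_dff = 0,
                        shared_bg_sd_dff = 0)
  r <- render_trace(spikes, duration_s = ceiling(max(spikes)) + 10,
                    noise = quiet)
  dc <- deconvolve(r$F)
  d <- tibble::tibble(roi_id = "r", frame = seq_along(r$F), fluor = r$F,
                      deconv = dc$s, denoised = dc$C)
  ev <- detect_transients(d, noise = tibble::tibble(roi_id = "r", sigma = 0.02))
  expect_identical(nrow(ev), length(spikes))
  delay <- indicator_peak_delay()
  expect_true(all(abs(ev$peak_time_s - (spikes + delay)) <= 0.2 + 1e-9))
})

test_that("detection quality stays high at moderate noise", {
  ds <- generate_dataset(burst_train_params(active_prob = 1), n_roi = 4,
                        seed = 17, duration_s = 300,
                        noise = noise_params(white_sd_dff = 0.2))
  pr <- preprocess_traces(ds$traces, fs_hz = 10,
                          qc = qc_params(window_frames = 300))
  ev <- validate_transients(detect_transients(pr), pr)
  sc <- score_events(dplyr::filter(ev, validated),
                     ds$ground_truth$spikes, fs_hz = 10, tol_frames = 2)
  expect_gte(sc$f1, 0.85)
})

test_that("template validation accepts clean transients and rejects noise", {
  # segment exactly equal to the template validates with correlation 1
  tr <- oracle_render(5.8, 10, 30)
  d <- tibble::tibble(roi_id = "r", frame = 1:300, fluor = tr)
  peak <- which.max(tr)
  ev <- tibble::tibble(roi_id = "r", peak_frame = peak,
                       peak_time_s = (peak - 1) / 10,
                       fluor_amplitude = 1, deconv_amplitude = 1,
                       validated = NA)
  out <- validate_transients(ev, d, fs_hz = 10)
  expect_true(out$validated)

  # empty input passes through
  e0 <- ev[0, ]
  expect_identical(nrow(validate_transients(e0, d, fs_hz = 10)), 0L)

  # events planted on pure noise are rejected nearly always
  set.seed(501)
  rejected <- replicate(200, {
    dtr <- tibble::tibble(roi_id = "r", frame = 1:2000,
                          fluor = rnorm(2000, 0, 0.2))
    pk <- sample(100:1900, 3)
    evn <- tibble::tibble(roi_id = "r", peak_frame = pk,
                          peak_time_s = (pk - 1) / 10,
                          fluor_amplitude = 1, deconv_amplitude = 1,
                          validated = NA)
    mean(!validate_transients(evn, dtr, fs_hz = 10)$validated)
  })
  expect_gte(mean(rejected), 0.95)

  # out-of-bounds events raise
  evb <- dplyr::mutate(ev, peak_frame = 5000)
  expect_error(validate_transients(evb, d, fs_hz = 10),
               class = "calci_event_bounds")
})
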