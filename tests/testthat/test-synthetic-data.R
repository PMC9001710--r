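test_that("eye-trace generation is seed-reproducible and tiles the trace", {
  a <- generate_eye_trace(3, seed = 5)
  b <- generate_eye_trace(3, seed = 5)
  expect_identical(a, b)
  # fixation onsets equal the preceding saccade offset
  sac <- a$truth$saccades
  fx <- a$truth$fixations[a$truth$fixations$post_saccadic, ]
  expect_true(all(fx$onset %in% sac$offset))
  # saccades never overlap each other
  expect_true(all(diff(as.vector(t(sac[, c("onset", "offset")]))) >= 0))
})

test_that("a zero-saccade request gives a drift-only constant trace", {
  e <- generate_eye_trace(1, max_saccades_per_trial = 0, seed = 2)
  expect_identical(nrow(e$truth$saccades), 0L)
  expect_lt(max(abs(e$gaze$x)) + max(abs(e$gaze$y)), 1)
  expect_identical(nrow(e$truth$fixations), 1L)
})

test_that("fixation durations follow the requested gamma mean", {
  # mean 250 ms (shape 6.25, scale 0.04), 100 trials of 3 s
  e <- generate_eye_trace(100, fixation_duration_dist = c(6.25, 0.04),
                          seed = 31)
  fx <- e$truth$fixations
  fx$duration <- fx$offset - fx$onset
  img_off <- e$truth$trials$img_off[fx$trial]
  img_on <- e$truth$trials$img_on[fx$trial]
  # post-saccadic viewing fixations begun after image onset and not
  # truncated by the trial end (the pre-period fixation spans 1.2 s)
  viewing <- fx[fx$post_saccadic & !is.na(fx$trial) &
                  fx$onset > img_on & fx$offset < img_off, ]
  expect_lt(abs(mean(viewing$duration) - 0.25), 0.025)
})

test_that("every generated saccade exceeds the 30 deg/s detection threshold", {
  e <- generate_eye_trace(10, seed = 8)
  v <- sqrt(diff(e$gaze$x)^2 + diff(e$gaze$y)^2) * 1000  # numerical oracle
  sac <- e$truth$saccades
  for (i in seq_len(nrow(sac))) {
    idx <- which(e$gaze$t >= sac$onset[i] & e$gaze$t <= sac$offset[i])
    expect_gt(max(v[idx[-length(idx)]]), 30)
  }
})

test_that("stimulus objects respect the pairwise separation constraint", {
  st <- generate_stimulus_image(n_objects = 5, min_separation = 4, seed = 3)
  d <- stats::dist(as.matrix(st$objects))
  expect_identical(length(d), 10L)
  expect_true(all(d > 4))
  expect_true(all(st$image >= 0 & st$image <= 1))
  one <- generate_stimulus_image(n_objects = 1, seed = 3)
  expect_identical(nrow(one$objects), 1L)
  none <- generate_stimulus_image(n_objects = 0, seed = 3)
  expect_identical(nrow(none$objects), 0L)
  expect_identical(generate_stimulus_image(seed = 9)$image,
                   generate_stimulus_image(seed = 9)$image)
  expect_error(generate_stimulus_image(background_size = c(8, 8),
                                       n_objects = 20, min_separation = 4,
                                       seed = 1),
               "infeasible|not fit")
})

test_that("gain-zero spike trains are homogeneous Poisson at the baseline", {
  tru <- unit_truth(baseline_rate = 10, img_gain = 0, fix_gain = 0)
  sp <- generate_spikes(tru, list(img_on = numeric(0)), span = c(0, 1000),
                        seed = 4)[[1]]
  # 1000 one-second windows; mean count should be 10 within 3 SE
  cnt <- avpipe:::count_in_intervals(sp, 0:999, 1:1000)
  expect_lt(abs(mean(cnt) - 10), 3 * sqrt(10 / 1000))
  # rate-integral convergence: ~10^4 expected events, relative error < 2 %
  expect_lt(abs(length(sp) - 10000) / 10000, 0.02)
})

test_that("baseline-free spikes stay within the kernel support of the event", {
  tru <- unit_truth(baseline_rate = 0, img_gain = 500, fix_gain = 0,
                    img_latency_ms = 60, kernel_sd_ms = 10)
  sp <- generate_spikes(tru, list(img_on = 5), span = c(0, 10), seed = 6)[[1]]
  expect_gt(length(sp), 0)
  expect_true(all(sp >= 5 + 0.06 - 0.05 & sp <= 5 + 0.06 + 0.05))
})

test_that("a mid-session rate step scales trial counts as constructed", {
  trials <- make_trial_table(100)
  tru <- unit_truth(baseline_rate = 5, img_gain = 0, fix_gain = 0,
                    changepoint_trial = 51L, step_factor = 4)
  sp <- generate_spikes(tru, list(img_on = trials$img_on),
                        span = c(0, max(trials$img_off) + 1),
                        trial_table = trials, seed = 7)[[1]]
  cnt <- avpipe:::count_in_intervals(sp, trials$img_on, trials$img_off)
  ratio <- mean(cnt[51:100]) / mean(cnt[1:50])
  expect_lt(abs(ratio - 4), 0.5)
})

test_that("negative instantaneous rates and out-of-span triggers error", {
  expect_error(generate_spikes(unit_truth(baseline_rate = 1, img_gain = -50),
                               list(img_on = 5), span = c(0, 10), seed = 1),
               "negative")
  expect_error(generate_spikes(unit_truth(), list(img_on = 50),
                               span = c(0, 10)),
               "within")
})

test_that("waveform banks reproduce templates, drift and noise as built", {
  tpl <- make_template()
  exact <- generate_waveforms(list(tpl), 10, noise_sd = 0,
                              amplitude_drift = 0, seed = 1)[[1]]
  expect_equal(exact, matrix(tpl, 10, length(tpl), byrow = TRUE),
               ignore_attr = TRUE)
  drifted <- generate_waveforms(list(tpl), 200, noise_sd = 0,
                                amplitude_drift = 0.5, seed = 1)[[1]]
  amp <- apply(drifted, 1, function(r) max(abs(r)))
  ratio <- mean(amp[181:200]) / mean(amp[1:20])
  # decile means of the linear 1 -> 1.5 ramp: 293.75/199 over 203.75/199
  expect_equal(ratio, 293.75 / 203.75, tolerance = 1e-10)
  expect_error(generate_waveforms(list(), 5), "non-empty")
  expect_error(generate_waveforms(list(1:3, 1:4), 5), "share")
})

test_that("noiseless laminar LFP yields the constructed sink-source pair", {
  ev <- seq(1, by = 2, length.out = 12)
  g <- generate_laminar_lfp(1.15, ev, duration = 26, noise_sd = 0, seed = 1)
  csd <- estimate_csd(g$lfp, g$fs, ev)
  prof <- csd$csd[, which.max(colSums(abs(csd$csd)))]
  sink_depth <- csd$depths_mm[which.min(prof)]
  source_depth <- csd$depths_mm[which.max(prof)]
  expect_lt(abs(sink_depth - 1.1), 0.051)
  expect_lt(abs(source_depth - 1.2), 0.051)
  expect_error(generate_laminar_lfp(0.05, ev, duration = 5), "span")
})

test_that("event-free LFP carries no trigger-locked structure", {
  g <- generate_laminar_lfp(1.15, numeric(0), duration = 10, noise_sd = 1,
                            seed = 2)
  fake_ev <- seq(1, 8, by = 1)
  csd <- suppressWarnings(estimate_csd(g$lfp, g$fs, fake_ev))
  bd <- suppressWarnings(find_granular_boundary(csd))
  # either undetermined or far weaker than a real dipole would produce
  expect_true(bd$undetermined ||
                bd$score < 10 * stats::sd(as.vector(csd$pre_csd)))
})
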