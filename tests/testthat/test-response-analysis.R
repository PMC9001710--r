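test_that("spike alignment clips to the window and recovers Poisson means", {
  a <- align_spikes(c(1.05), triggers = 1, window = c(-0.1, 0.3))
  expect_equal(a[[1]], 0.05)
  expect_identical(length(align_spikes(c(2.5), 1, c(-0.1, 0.3))[[1]]), 0L)
  expect_identical(length(align_spikes(1:3, numeric(0))), 0L)
  set.seed(31)
  sp <- cumsum(stats::rexp(6000, 10))
  trig <- seq(5, 395, by = 4)
  a <- align_spikes(sp, trig, window = c(0, 0.3))
  m <- mean(lengths(a))
  expect_lt(abs(m - 3), 0.5)
})

test_that("the smoothed PSTH recovers a flat rate and is count-normalized", {
  set.seed(32)
  trig <- seq(2, by = 2, length.out = 500)
  sp <- cumsum(stats::rexp(11000, 10))
  a <- align_spikes(sp, trig, c(-0.1, 0.3))
  ps <- smooth_psth(a)
  interior <- ps$time > -0.05 & ps$time < 0.25
  expect_true(all(abs(ps$rate[interior] - 10) < 1.5))
  # integral equals mean spikes per event (interior mass; edges excluded)
  integral <- sum(ps$rate) * 0.002
  expect_lt(abs(integral - ps$mean_count) / ps$mean_count, 0.01)
})

test_that("a point mass of spikes peaks at its time and doubling is neutral", {
  rel <- rep(0.06, 200)
  a <- structure(as.list(rel), n_events = 200)
  ps <- smooth_psth(a)
  expect_lt(abs(ps$time[which.max(ps$rate)] - 0.06), 0.0021)
  doubled <- structure(c(as.list(rel), as.list(rel)), n_events = 400)
  ps2 <- smooth_psth(doubled, bandwidth = ps$bandwidth)
  expect_equal(ps2$rate, ps$rate, tolerance = 1e-10)
})

sim_unit <- function(baseline, gain, latency_ms, n_trig = 150, seed = 1,
                     kernel_sd_ms = 10) {
  trials <- make_trial_table(n_trig)
  tru <- unit_truth(baseline_rate = baseline, img_gain = gain, fix_gain = 0,
                    img_latency_ms = latency_ms, kernel_sd_ms = kernel_sd_ms)
  sp <- generate_spikes(tru, list(img_on = trials$img_on),
                        span = c(0, max(trials$img_off) + 0.5),
                        seed = seed)[[1]]
  list(spikes = sp, trials = trials)
}

test_that("peak significance fires on injected responses and not on silence", {
  u <- sim_unit(3, 22, 70, seed = 33)
  res <- test_peak_significance(u$spikes, u$trials$img_on,
                                baseline_intervals("img_on", u$trials))
  expect_true(res$significant)
  expect_lt(abs(res$peak_time_ms - 70), 10)
  silent <- test_peak_significance(numeric(0), u$trials$img_on,
                                   baseline_intervals("img_on", u$trials))
  expect_false(silent$significant)
  expect_identical(silent$p_value, 1)
  expect_error(test_peak_significance(u$spikes, u$trials$img_on,
                                      matrix(numeric(0), 0, 2)),
               "baseline")
})

test_that("null units stay at the nominal false-positive level", {
  set.seed(34)
  n_sig <- 0L
  for (i in 1:60) {
    u <- sim_unit(5, 0, 60, n_trig = 100, seed = 1000 + i)
    res <- test_peak_significance(u$spikes, u$trials$img_on,
                                  baseline_intervals("img_on", u$trials))
    n_sig <- n_sig + res$significant
  }
  expect_lte(n_sig / 60, 0.1)
})

test_that("responsiveness labels and the 80-ms latency split are correct", {
  mk <- function(sig, lat) list(significant = sig, peak_time_ms = lat)
  expect_identical(classify_unit(mk(TRUE, 60), mk(TRUE, 50))$label,
                   "doubly_responsive")
  expect_identical(classify_unit(mk(FALSE, 60), mk(TRUE, 50))$label,
                   "fixation_only")
  expect_identical(classify_unit(mk(TRUE, 60), mk(FALSE, 50))$label,
                   "img_only")
  expect_identical(classify_unit(mk(FALSE, 60), mk(FALSE, 50))$label,
                   "non_responsive")
  expect_identical(classify_unit(mk(TRUE, 95), mk(TRUE, 50))$latency_class,
                   "long")
  expect_identical(classify_unit(mk(TRUE, 80), mk(TRUE, 50))$latency_class,
                   "short")
})

test_that("latency tables aggregate paired differences correctly", {
  units <- data.frame(unit_id = 1:40, layer = rep(c("supragranular", "granular"), 20),
                      label = "doubly_responsive",
                      img_latency_ms = rep(100, 40), fix_latency_ms = rep(100, 40),
                      latency_class = "long")
  lt <- latency_table(units)
  expect_true(all(lt$paired$latency_diff_ms == 0))
  # recovery of constructed medians
  set.seed(35)
  units2 <- data.frame(unit_id = 1:80, layer = "granular",
                       label = "doubly_responsive",
                       img_latency_ms = stats::rnorm(80, 110, 15),
                       fix_latency_ms = stats::rnorm(80, 70, 8))
  units2$latency_class <- ifelse(units2$img_latency_ms > 80, "long", "short")
  lt2 <- latency_table(units2)
  all_row <- lt2$by_layer[lt2$by_layer$layer == "all" &
                            lt2$by_layer$latency_class == "all", ]
  expect_lt(abs(all_row$median_diff - 40), 6)
  # a single unit aggregates without failure
  lt3 <- latency_table(units2[1, ])
  expect_identical(nrow(lt3$paired), 1L)
})
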