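make_record <- function(x, y = rep(0, length(x)), fs = 1000) {
  gaze_record((seq_along(x) - 1) / fs, x, y)
}

test_that("Savitzky-Golay derivatives are exact on polynomial inputs", {
  n <- 1000
  rec <- differentiate_gaze(make_record(rep(3, n)))
  interior <- 50:(n - 50)
  expect_lt(max(rec$velocity[interior]), 1e-9)
  expect_lt(max(rec$acceleration[interior]), 1e-6)
  t <- (0:(n - 1)) / 1000
  ramp <- differentiate_gaze(make_record(10 * t))
  expect_equal(ramp$velocity[interior], rep(10, length(interior)),
               tolerance = 1e-8)
})

test_that("sinusoid velocity amplitude matches the closed form", {
  fs <- 1000; f <- 2; A <- 3
  t <- (0:4999) / fs
  rec <- differentiate_gaze(make_record(A * sin(2 * pi * f * t)))
  vmax <- max(rec$velocity[100:4900])
  expect_lt(abs(vmax - 2 * pi * f * A) / (2 * pi * f * A), 0.01)
})

test_that("window/polyorder preconditions are enforced", {
  rec <- make_record(rep(0, 100))
  expect_error(differentiate_gaze(rec, window = 20), "odd")
  expect_error(differentiate_gaze(rec, polyorder = 1), "polyorder")
  expect_error(differentiate_gaze(make_record(rep(0, 10)), window = 21),
               "longer than")
})

# one minimum-jerk saccade embedded in a stable trace
one_saccade_record <- function(amp = 5, onset_i = 1001, dur_i = 32,
                               fs = 1000, noise = 0) {
  n <- 3000
  x <- numeric(n)
  x[onset_i:(onset_i + dur_i)] <-
    amp * avpipe:::minimum_jerk(seq(0, 1, length.out = dur_i + 1))
  x[(onset_i + dur_i + 1):n] <- amp
  if (noise > 0) x <- x + stats::rnorm(n, 0, noise)
  make_record(x, fs = fs)
}

test_that("a single synthetic saccade is detected with accurate onset", {
  rec <- differentiate_gaze(one_saccade_record())
  sac <- detect_saccades(rec)
  expect_identical(nrow(sac), 1L)
  expect_lt(abs(sac$onset - 1.0), 0.002)          # within 2 samples at 1 kHz
  expect_lt(abs(sac$amplitude - 5), 0.2)
  expect_gt(sac$peak_velocity, 200)
})

test_that("constant gaze and slow drift produce no saccades", {
  rec <- differentiate_gaze(make_record(rep(1, 2000)))
  expect_identical(nrow(detect_saccades(rec)), 0L)
  # 20 deg/s ramp: below the 30 deg/s threshold
  t <- (0:1999) / 1000
  drift <- differentiate_gaze(make_record(20 * t))
  expect_identical(nrow(detect_saccades(drift)), 0L)
})

test_that("detection is monotone in the velocity threshold and offset-invariant", {
  set.seed(11)
  e <- generate_eye_trace(5, seed = 21)
  rec <- differentiate_gaze(e$gaze)
  n30 <- nrow(detect_saccades(rec, v_thresh = 30))
  n60 <- nrow(detect_saccades(rec, v_thresh = 60))
  n120 <- nrow(detect_saccades(rec, v_thresh = 120))
  expect_true(n30 >= n60 && n60 >= n120)
  shifted <- gaze_record(e$gaze$t, e$gaze$x + 7, e$gaze$y - 3)
  sac0 <- detect_saccades(rec)
  sac1 <- detect_saccades(differentiate_gaze(shifted))
  expect_equal(sac0$onset, sac1$onset)
  expect_equal(sac0$amplitude, sac1$amplitude)
})

test_that("inter-saccade intervals become fixations unless gaze shifts > 1 deg", {
  # two saccades around a stable 300-ms epoch
  n <- 2400
  x <- numeric(n)
  s <- avpipe:::minimum_jerk(seq(0, 1, length.out = 33))
  x[1001:1033] <- 5 * s; x[1034:n] <- 5
  x[1334:1366] <- 5 + 4 * s; x[1367:n] <- 9
  rec <- differentiate_gaze(make_record(x))
  sac <- detect_saccades(rec)
  expect_identical(nrow(sac), 2L)
  fx <- detect_fixations(rec, sac)
  mid <- fx[fx$post_saccadic, ]
  expect_identical(nrow(mid), 2L)   # between the saccades + after the last
  expect_lt(abs(mid$duration[1] - 0.3), 0.01)
  expect_equal(mid$onset[1], sac$offset[1])

  # interval containing a slow 1.5-degree drift is discarded
  x2 <- x
  x2[1034:1333] <- 5 + seq(0, 1.5, length.out = 300)
  x2[1334:1366] <- 6.5 + 4 * s; x2[1367:n] <- 10.5
  rec2 <- differentiate_gaze(make_record(x2))
  sac2 <- detect_saccades(rec2)
  fx2 <- detect_fixations(rec2, sac2)
  in_between <- fx2$onset >= sac2$offset[1] - 1e-9 &
    fx2$offset <= sac2$onset[2] + 1e-9
  expect_false(any(in_between))
})

test_that("a saccade-free stable record yields one whole-record fixation", {
  rec <- differentiate_gaze(make_record(rep(2, 1500)))
  fx <- detect_fixations(rec, detect_saccades(rec))
  expect_identical(nrow(fx), 1L)
  expect_false(fx$post_saccadic)
  expect_equal(fx$duration, 1.499, tolerance = 1e-6)
})

test_that("benchmarking counts matches, misses and false alarms", {
  b <- benchmark_detection(c(1, 2, 3), c(1, 2, 3), tolerance = 0.01)
  expect_equal(c(b$precision, b$recall, b$f1), c(1, 1, 1))
  expect_true(all(b$onset_errors == 0))
  truth <- seq(1, 10)
  detected <- c(truth[1:9] + 0.001, 99)   # 9 correct + 1 spurious
  b2 <- benchmark_detection(detected, truth, tolerance = 0.01)
  expect_equal(b2$precision, 0.9)
  expect_equal(b2$recall, 0.9)
})
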