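# Minimum-jerk displacement profile on [0, 1]: s(0)=0, s(1)=1, zero
# velocity/acceleration at both ends; peak velocity 1.875 * A / D.
minimum_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Main-sequence saccade duration (s) for amplitude A (deg): an affine
# duration-amplitude law typical of primate saccades (~21 ms + 2.2 ms/deg).
main_sequence_duration <- function(amplitude) 0.021 + 0.0022 * amplitude

#' Generate a synthetic free-viewing gaze trace with ground truth
#'
#' Builds a continuous session of `n_trials` free-viewing trials. Each trial
#' has a pre-stimulus central-fixation period of `pre_duration` followed by
#' `trial_duration` of free viewing in which fixations (position held, with
#' small random-walk drift) alternate with saccades (minimum-jerk
#' displacement whose duration follows a main-sequence law, so peak velocity
#' grows with amplitude and exceeds 30 deg/s for amplitudes >= 1 degree).
#' After the viewing period a return saccade brings gaze back to the screen
#' center for the next trial's pre-period. Exact event intervals are
#' returned as ground truth; fixation onsets equal the preceding saccade
#' offset, so the intervals tile the trace.
#'
#' Defaults emulate macaque free viewing of large natural images: gamma
#' fixation durations with mean ~168 ms (about 15 fixations per 3-s trial)
#' and gamma saccade amplitudes with mean 5 degrees truncated to
#' [1, 20] degrees (microsaccades are not modeled).
#'
#' @param n_trials number of trials.
#' @param fixation_duration_dist `c(shape, scale)` of the gamma law for
#'   fixation durations (s).
#' @param saccade_amplitude_dist `c(shape, scale)` of the gamma law for
#'   saccade amplitudes (deg).
#' @param sampling_rate gaze sampling rate (Hz), >= 500.
#' @param trial_duration free-viewing duration per trial (s).
#' @param pre_duration pre-stimulus central fixation duration (s).
#' @param max_saccades_per_trial cap on saccades per viewing period
#'   (0 gives a saccade-free, drift-only trace).
#' @param bounds half-extent `c(x, y)` of the admissible gaze area (deg).
#' @param drift_step_sd per-sample SD of the fixational drift random walk
#'   (deg); the default keeps cumulative drift well below the 1-degree
#'   fixation criterion over a 400-ms fixation.
#' @param seed integer seed; identical seeds give identical traces.
#' @return list with elements `gaze` (a [gaze_record()]) and `truth`
#'   (list of `saccades`, `fixations`, `trials` data.frames).
#' @export
generate_eye_trace <- function(n_trials,
                               fixation_duration_dist = c(shape = 4, scale = 0.042),
                               saccade_amplitude_dist = c(shape = 2.5, scale = 2),
                               sampling_rate = 1000,
                               trial_duration = 3,
                               pre_duration = 1.2,
                               max_saccades_per_trial = Inf,
                               bounds = c(15, 11),
                               drift_step_sd = 0.1 / sqrt(0.4 * sampling_rate),
                               seed = NULL) {
  stop_if_not_positive(c(n_trials, trial_duration, pre_duration), "durations")
  stop_if_not_positive(fixation_duration_dist, "fixation_duration_dist")
  stop_if_not_positive(saccade_amplitude_dist, "saccade_amplitude_dist")
  if (sampling_rate < 500) stop("sampling_rate must be >= 500 Hz", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  fs <- sampling_rate
  dt <- 1 / fs
  trial_period <- pre_duration + trial_duration
  total <- n_trials * trial_period + 0.3
  n <- ceiling(total * fs)
  x <- numeric(n); y <- numeric(n)
  t <- (seq_len(n) - 1L) * dt

  draw_fixdur <- function() max(stats::rgamma(1, shape = fixation_duration_dist[1],
                                              scale = fixation_duration_dist[2]), 0.05)
  draw_amp <- function() {
    for (i in 1:50) {
      a <- stats::rgamma(1, shape = saccade_amplitude_dist[1],
                         scale = saccade_amplitude_dist[2])
      if (a >= 1 && a <= 20) return(a)
    }
    5
  }

  sac_rows <- list(); fix_rows <- list(); trial_rows <- list()
  cur <- c(0, 0)    # current gaze position
  i_cur <- 1L       # next sample index to fill

  fill_fixation <- function(i0, i1, start_pos) {
    L <- i1 - i0 + 1L
    dx <- cumsum(stats::rnorm(L, 0, drift_step_sd))
    dy <- cumsum(stats::rnorm(L, 0, drift_step_sd))
    x[i0:i1] <<- start_pos[1] + dx
    y[i0:i1] <<- start_pos[2] + dy
    c(x[i1], y[i1])
  }
  fill_saccade <- function(i0, i1, from, to) {
    tau <- seq(0, 1, length.out = i1 - i0 + 1L)
    s <- minimum_jerk(tau)
    x[i0:i1] <<- from[1] + (to[1] - from[1]) * s
    y[i0:i1] <<- from[2] + (to[2] - from[2]) * s
    to
  }

  for (tr in seq_len(n_trials)) {
    t_start <- (tr - 1) * trial_period
    img_on <- t_start + pre_duration
    img_off <- img_on + trial_duration
    trial_rows[[tr]] <- data.frame(trial = tr, start = t_start,
                                   img_on = img_on, img_off = img_off)
    # pre-period: hold center; the running fixation began either at the
    # session start or at the offset of the previous return saccade
    if (tr == 1L) fix_on_t <- t[i_cur]
    i_pre_end <- round(img_on * fs)
    cur <- fill_fixation(i_cur, i_pre_end, cur)
    i_cur <- i_pre_end + 1L

    # viewing period: alternate fixations and saccades
    n_sacc <- 0L
    t_now <- img_on
    # first fixation: continues the central pre-fixation until 1st saccade
    repeat {
      fixdur <- draw_fixdur()
      fix_end <- min(t_now + fixdur, img_off)
      amp <- draw_amp()
      sac_dur <- main_sequence_duration(amp)
      can_saccade <- n_sacc < max_saccades_per_trial &&
        fix_end + sac_dur < img_off - 0.05
      if (!can_saccade) fix_end <- img_off
      i_fix_end <- round(fix_end * fs)
      if (i_fix_end >= i_cur) {
        cur <- fill_fixation(i_cur, i_fix_end, cur)
        i_cur <- i_fix_end + 1L
      }
      fix_rows[[length(fix_rows) + 1L]] <- data.frame(
        onset = fix_on_t, offset = fix_end, x = cur[1], y = cur[2],
        trial = tr, post_saccadic = n_sacc > 0L || tr > 1L
      )
      if (!can_saccade) break
      # pick a target inside bounds
      target <- NULL
      for (k in 1:30) {
        ang <- stats::runif(1, 0, 2 * pi)
        cand <- cur + amp * c(cos(ang), sin(ang))
        if (abs(cand[1]) <= bounds[1] && abs(cand[2]) <= bounds[2]) {
          target <- cand; break
        }
      }
      if (is.null(target)) target <- cur + amp * (c(0, 0) - cur) / max(sqrt(sum(cur^2)), 1e-9)
      i_sac_end <- round((fix_end + sac_dur) * fs)
      from <- cur
      cur <- fill_saccade(i_cur, i_sac_end, cur, target)
      sac_rows[[length(sac_rows) + 1L]] <- data.frame(
        onset = fix_end, offset = t[i_sac_end],
        amplitude = sqrt(sum((target - from)^2)), trial = tr
      )
      fix_on_t <- t[i_sac_end]
      i_cur <- i_sac_end + 1L
      t_now <- t[i_sac_end]
      n_sacc <- n_sacc + 1L
    }
    # return saccade to screen center for the next pre-period
    if (tr <= n_trials && sqrt(sum(cur^2)) > 0.5) {
      amp <- sqrt(sum(cur^2))
      sac_dur <- main_sequence_duration(amp)
      i_sac_end <- round((img_off + sac_dur) * fs)
      from <- cur
      cur <- fill_saccade(i_cur, i_sac_end, cur, c(0, 0))
      sac_rows[[length(sac_rows) + 1L]] <- data.frame(
        onset = img_off, offset = t[i_sac_end],
        amplitude = sqrt(sum((c(0, 0) - from)^2)), trial = NA_integer_
      )
      fix_on_t <- t[i_sac_end]
      i_cur <- i_sac_end + 1L
    } else {
      fix_on_t <- t[i_cur]
    }
  }
  if (i_cur <= n) cur <- fill_fixation(i_cur, n, cur)

  saccades <- if (length(sac_rows)) do.call(rbind, sac_rows) else
    data.frame(onset = numeric(0), offset = numeric(0),
               amplitude = numeric(0), trial = integer(0))
  fixations <- do.call(rbind, fix_rows)
  list(
    gaze = gaze_record(t, x, y),
    truth = list(saccades = saccades, fixations = fixations,
                 trials = do.call(rbind, trial_rows))
  )
}
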