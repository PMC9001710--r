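#' Simulate a complete free-viewing session with ground truth
#'
#' Composes the synthetic generators into a full session: gaze trace with
#' saccade/fixation ground truth, trial table, stimulus images, per-unit
#' spike trains driven by img-on and fix-on locked response kernels, a
#' laminar LFP with a 4c/5 dipole, and RF geometry. Units are drawn from
#' responsiveness classes (doubly responsive, fixation-only, img-only,
#' non-responsive) with configurable proportions; the defaults emulate the
#' qualitative population structure of macaque V1 during free viewing
#' (roughly half doubly responsive, a third fixation-only, img-only rare).
#'
#' Injected condition effects (all switchable):
#' \itemize{
#' \item `latency_shortening`: long-latency units (img-on latency > 80 ms)
#'   respond to fix-on with substantially shorter latency; short-latency
#'   units keep similar latencies in both conditions.
#' \item `sup_sparseness`: supragranular units respond to only a fraction
#'   of fixations (per-event Bernoulli), making their fix-on responses
#'   sparser across events than their img-on responses.
#' }
#'
#' @param n_trials number of free-viewing trials.
#' @param n_units number of single-units (split evenly across sup/GL/inf).
#' @param seed integer seed; the whole session is reproducible from it.
#' @param effects list of logical flags `latency_shortening`,
#'   `sup_sparseness`.
#' @param class_probs responsiveness class proportions (doubly,
#'   fixation_only, img_only, non_responsive).
#' @param trial_duration,pre_duration trial timing (s).
#' @param fs_gaze,fs_lfp sampling rates (Hz).
#' @param n_images stimulus images cycled over trials.
#' @param ppd stimulus raster scale (pixels/degree).
#' @param changepoint_frac fraction of units given a baseline-rate change
#'   point at a random mid-session trial.
#' @param boundary_depth_mm simulated 4c/5 boundary depth.
#' @param lfp_noise_sd 1/f noise SD on the LFP.
#' @return object of class `av_session`.
#' @export
simulate_session <- function(n_trials = 60, n_units = 45, seed = 1,
                             effects = list(latency_shortening = TRUE,
                                            sup_sparseness = TRUE),
                             class_probs = c(doubly_responsive = 0.52,
                                             fixation_only = 0.34,
                                             img_only = 0.02,
                                             non_responsive = 0.12),
                             trial_duration = 3, pre_duration = 1.2,
                             fs_gaze = 1000, fs_lfp = 500,
                             n_images = 6, ppd = 16,
                             changepoint_frac = 0.2,
                             boundary_depth_mm = 1.15,
                             lfp_noise_sd = 2) {
  set.seed(seed)
  eye <- generate_eye_trace(n_trials, sampling_rate = fs_gaze,
                            trial_duration = trial_duration,
                            pre_duration = pre_duration)
  trials <- eye$truth$trials
  total_dur <- max(eye$gaze$t)

  images <- lapply(seq_len(n_images), function(i)
    generate_stimulus_image(pixels_per_degree = ppd))
  trials$image_id <- rep_len(seq_len(n_images), n_trials)

  # --- unit ground truth ---------------------------------------------------
  layer_channels <- list(supragranular = 2:8, granular = 9:12,
                         infragranular = 13:16)
  layers_true <- rep(names(layer_channels), length.out = n_units)
  channels <- vapply(layers_true, function(ly) {
    chs <- layer_channels[[ly]]
    chs[sample.int(length(chs), 1)]
  }, 1L)
  depths <- (channels - 1L) * 0.1
  labels <- sample(names(class_probs), n_units, replace = TRUE,
                   prob = class_probs)
  img_resp <- labels %in% c("doubly_responsive", "img_only")
  fix_resp <- labels %in% c("doubly_responsive", "fixation_only")
  long_lat <- stats::runif(n_units) < 0.5
  img_lat <- ifelse(long_lat, stats::rnorm(n_units, 110, 10),
                    pmax(stats::rnorm(n_units, 55, 8), 30))
  fix_lat <- if (isTRUE(effects$latency_shortening)) {
    ifelse(long_lat, pmax(stats::rnorm(n_units, 70, 8), 30),
           pmax(img_lat + stats::rnorm(n_units, 0, 4), 30))
  } else {
    pmax(img_lat + stats::rnorm(n_units, 0, 4), 30)
  }
  fix_prob <- rep(1, n_units)
  if (isTRUE(effects$sup_sparseness)) {
    sup_fix <- layers_true == "supragranular" & fix_resp
    fix_prob[sup_fix] <- 0.12
  }
  base_fix_gain <- stats::runif(n_units, 12, 20)
  truth_units <- data.frame(
    unit_id = seq_len(n_units), channel = channels, depth_mm = depths,
    layer = layers_true, label = labels,
    baseline_rate = stats::rlnorm(n_units, log(6), 0.3),
    img_gain = ifelse(img_resp, stats::runif(n_units, 15, 25), 0),
    fix_gain = ifelse(fix_resp, base_fix_gain / fix_prob, 0),
    img_latency_ms = img_lat, fix_latency_ms = fix_lat,
    kernel_sd_ms = 10, fix_response_prob = fix_prob,
    changepoint_trial = NA_integer_, step_factor = 1,
    stringsAsFactors = FALSE
  )
  has_cp <- stats::runif(n_units) < changepoint_frac
  truth_units$changepoint_trial[has_cp] <-
    sample(seq(n_trials %/% 4, 3 * n_trials %/% 4), sum(has_cp), replace = TRUE)
  truth_units$step_factor[has_cp] <- sample(c(0.4, 2.5), sum(has_cp),
                                            replace = TRUE)

  fx <- eye$truth$fixations
  fix_on_all <- fx$onset[fx$post_saccadic & !is.na(fx$trial) &
                           fx$onset > trials$img_on[fx$trial]]
  spikes <- generate_spikes(truth_units,
                            triggers = list(img_on = trials$img_on,
                                            fix_on = fix_on_all),
                            span = c(0, total_dur), trial_table = trials)

  lfp <- generate_laminar_lfp(boundary_depth_mm, trials$img_on,
                              duration = total_dur, sampling_rate = fs_lfp,
                              noise_sd = lfp_noise_sd)

  structure(list(
    gaze = eye$gaze, trials = trials, images = images, spikes = spikes,
    units = truth_units, lfp = lfp,
    rf = rf_geometry(offset = c(1.0, -0.8), diameter = 0.6,
                     pixels_per_degree = ppd),
    truth = list(eye = eye$truth, units = truth_units,
                 boundary_depth_mm = boundary_depth_mm),
    seed = seed
  ), class = "av_session")
}

#' @export
print.av_session <- function(x, ...) {
  cat(sprintf("synthetic free-viewing session: %d trials, %d units, %.0f s\n",
              nrow(x$trials), length(x$spikes), max(x$gaze$t)))
  invisible(x)
}
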