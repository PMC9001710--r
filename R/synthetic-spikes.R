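#' Default ground-truth parameters for one simulated unit
#'
#' @param baseline_rate baseline firing rate (Hz).
#' @param img_gain,fix_gain peak added rate (Hz) of the event-locked
#'   Gaussian response kernel for img-on / fix-on events; 0 disables the
#'   response. The firing rate at the response peak is
#'   `baseline_rate + gain`.
#' @param img_latency_ms,fix_latency_ms response latency (ms) from trigger
#'   to kernel peak.
#' @param kernel_sd_ms Gaussian kernel SD (ms).
#' @param fix_response_prob probability that the unit responds to any given
#'   fix-on event (per-event Bernoulli); values < 1 make fix-on responses
#'   sparser across events.
#' @param changepoint_trial trial index at which the baseline rate steps by
#'   `step_factor` (NA for a stationary unit).
#' @param step_factor multiplicative baseline step applied from
#'   `changepoint_trial` onward.
#' @export
unit_truth <- function(baseline_rate = 5, img_gain = 20, fix_gain = 15,
                       img_latency_ms = 60, fix_latency_ms = 60,
                       kernel_sd_ms = 10, fix_response_prob = 1,
                       changepoint_trial = NA_integer_, step_factor = 1) {
  stopifnot(baseline_rate >= 0, kernel_sd_ms > 0,
            img_latency_ms >= 0, fix_latency_ms >= 0,
            fix_response_prob >= 0, fix_response_prob <= 1)
  data.frame(baseline_rate = baseline_rate, img_gain = img_gain,
             fix_gain = fix_gain, img_latency_ms = img_latency_ms,
             fix_latency_ms = fix_latency_ms, kernel_sd_ms = kernel_sd_ms,
             fix_response_prob = fix_response_prob,
             changepoint_trial = changepoint_trial, step_factor = step_factor)
}

# Add an amplitude-parameterized Gaussian kernel at each event to `rate`.
add_event_kernels <- function(rate, grid_t, events, gain, latency_s, sd_s) {
  if (gain == 0 || length(events) == 0) return(rate)
  dt <- grid_t[2] - grid_t[1]
  half <- ceiling(5 * sd_s / dt)
  for (ev in events) {
    center <- ev + latency_s
    i0 <- max(1L, floor((center - 5 * sd_s - grid_t[1]) / dt) + 1L)
    i1 <- min(length(rate), i0 + 2L * half)
    if (i1 < i0) next
    idx <- i0:i1
    rate[idx] <- rate[idx] + gain * exp(-(grid_t[idx] - center)^2 / (2 * sd_s^2))
  }
  rate
}

#' Simulate spike trains from event-locked rate functions
#'
#' Draws spikes from an inhomogeneous Poisson process with rate
#' \deqn{\lambda(t) = b(t) + \sum_k g \exp\{-(t - e_k - L)^2 / 2\sigma^2\},}
#' where the baseline \eqn{b(t)} may step at a change-point trial and the
#' fix-on kernels are included per event with probability
#' `fix_response_prob`. Simulation discretizes time at `dt` and draws
#' per-bin Poisson counts (exact in expectation); spike times are uniform
#' within their bin.
#'
#' @param truth data.frame of per-unit parameters, one row per unit
#'   (see [unit_truth()]).
#' @param triggers list with numeric elements `img_on` and `fix_on`
#'   (either may be empty).
#' @param span `c(start, end)` of the simulated record (s); all triggers
#'   must lie within it.
#' @param trial_table optional data.frame with `trial` and `img_on`, used
#'   to time baseline change points (the step applies from that trial's
#'   img-on onward).
#' @param dt simulation bin width (s).
#' @param seed integer seed.
#' @return list of per-unit sorted spike-time vectors; each carries the
#'   attribute `fix_included` (logical, which fix-on events the unit
#'   responded to).
#' @export
generate_spikes <- function(truth, triggers, span, trial_table = NULL,
                            dt = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img_on <- triggers$img_on %||% numeric(0)
  fix_on <- triggers$fix_on %||% numeric(0)
  all_tr <- c(img_on, fix_on)
  if (length(all_tr) && (min(all_tr) < span[1] || max(all_tr) > span[2])) {
    stop("all trigger times must lie within `span`", call. = FALSE)
  }
  grid_t <- seq(span[1], span[2], by = dt)
  grid_t <- grid_t[-length(grid_t)] + dt / 2   # bin centers
  out <- vector("list", nrow(truth))
  for (u in seq_len(nrow(truth))) {
    p <- truth[u, ]
    rate <- rep(p$baseline_rate, length(grid_t))
    if (!is.na(p$changepoint_trial) && !is.null(trial_table)) {
      cp_time <- trial_table$img_on[trial_table$trial == p$changepoint_trial]
      if (length(cp_time) == 1) {
        rate[grid_t >= cp_time] <- rate[grid_t >= cp_time] * p$step_factor
      }
    }
    rate <- add_event_kernels(rate, grid_t, img_on, p$img_gain,
                              ms_to_s(p$img_latency_ms), ms_to_s(p$kernel_sd_ms))
    included <- rep(TRUE, length(fix_on))
    if (length(fix_on) && p$fix_response_prob < 1) {
      included <- stats::runif(length(fix_on)) < p$fix_response_prob
    }
    rate <- add_event_kernels(rate, grid_t, fix_on[included], p$fix_gain,
                              ms_to_s(p$fix_latency_ms), ms_to_s(p$kernel_sd_ms))
    if (any(rate < 0)) {
      stop("negative instantaneous rate; check gains/baseline", call. = FALSE)
    }
    counts <- stats::rpois(length(rate), rate * dt)
    nz <- which(counts > 0L)
    times <- rep(grid_t[nz] - dt / 2, counts[nz]) +
      stats::runif(sum(counts)) * dt
    st <- sort(times)
    attr(st, "fix_included") <- included
    out[[u]] <- st
  }
  out
}

#' Simulate spike waveform banks with amplitude drift
#'
#' Each event waveform is its unit's template scaled by a linear amplitude
#' drift across the session plus white noise, emulating the gradual
#' electrode-drift amplitude changes that spike-train curation must
#' tolerate.
#'
#' @param templates list of numeric template waveforms (equal length).
#' @param n_events events per template (scalar or per-template vector).
#' @param noise_sd white-noise SD in template amplitude units.
#' @param amplitude_drift fractional amplitude change from the first to the
#'   last event (0.5 means the final event is 1.5x the first).
#' @param seed integer seed.
#' @return list of event x sample waveform matrices, one per template, each
#'   with attribute `amplitudes` (the drift multipliers).
#' @export
generate_waveforms <- function(templates, n_events, noise_sd = 0,
                               amplitude_drift = 0, seed = NULL) {
  if (length(templates) == 0) stop("`templates` must be non-empty", call. = FALSE)
  len <- unique(vapply(templates, length, 1L))
  if (length(len) != 1) stop("templates must share a sample count", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_events <- rep_len(n_events, length(templates))
  lapply(seq_along(templates), function(u) {
    ne <- n_events[u]
    amp <- if (ne > 1) 1 + amplitude_drift * (seq_len(ne) - 1) / (ne - 1) else 1
    w <- outer(amp, templates[[u]]) +
      matrix(stats::rnorm(ne * len, 0, noise_sd), ne, len)
    attr(w, "amplitudes") <- amp
    w
  })
}
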