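#' Construct a gaze record
#'
#' A gaze record holds a uniformly sampled 2-D eye-position time series in
#' degrees of visual angle. Radial velocity and acceleration are populated
#' by [differentiate_gaze()].
#'
#' @param t sample times (s), uniformly spaced.
#' @param x,y gaze position (degrees).
#' @return object of class `gaze_record`: a data.frame with columns
#'   `t`, `x`, `y` (and after differentiation `velocity`, `acceleration`),
#'   with the sampling rate in attribute `fs`.
#' @export
gaze_record <- function(t, x, y) {
  stopifnot(length(t) == length(x), length(t) == length(y), length(t) >= 2)
  dt <- diff(t)
  if (diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("gaze record must be uniformly sampled", call. = FALSE)
  }
  rec <- data.frame(t = t, x = x, y = y)
  attr(rec, "fs") <- 1 / stats::median(dt)
  class(rec) <- c("gaze_record", "data.frame")
  rec
}

#' Savitzky-Golay gaze derivatives
#'
#' Estimates eye velocity and acceleration by Savitzky-Golay differentiation
#' of the horizontal and vertical position channels; the radial speed
#' \eqn{\sqrt{\dot x^2 + \dot y^2}} and the analogous second-derivative
#' magnitude are stored on the record.
#'
#' @param record a [gaze_record()].
#' @param window filter window length in samples (odd, > `polyorder`).
#' @param polyorder polynomial order (>= 2 so acceleration is defined).
#' @return the record with `velocity` (deg/s) and `acceleration` (deg/s^2)
#'   columns filled in.
#' @export
differentiate_gaze <- function(record, window = 21, polyorder = 3) {
  stopifnot(inherits(record, "gaze_record"))
  if (window %% 2 != 1 || window <= polyorder) {
    stop("`window` must be odd and greater than `polyorder`", call. = FALSE)
  }
  if (polyorder < 2) stop("`polyorder` must be >= 2", call. = FALSE)
  if (window > nrow(record)) {
    stop("`window` longer than the gaze trace", call. = FALSE)
  }
  fs <- attr(record, "fs")
  ts <- 1 / fs
  vx <- signal::sgolayfilt(record$x, p = polyorder, n = window, m = 1, ts = ts)
  vy <- signal::sgolayfilt(record$y, p = polyorder, n = window, m = 1, ts = ts)
  ax <- signal::sgolayfilt(record$x, p = polyorder, n = window, m = 2, ts = ts)
  ay <- signal::sgolayfilt(record$y, p = polyorder, n = window, m = 2, ts = ts)
  record$velocity <- sqrt(vx^2 + vy^2)
  record$acceleration <- sqrt(ax^2 + ay^2)
  record
}

#' Artifact-rejection criteria for saccade candidates
#'
#' Plausibility bounds applied to candidate saccade segments. The values are
#' package defaults (configurable): duration 6-150 ms, amplitude
#' 0.05-40 degrees, peak velocity below 1200 deg/s.
#'
#' @param duration_ms length-2 admissible duration range (ms).
#' @param amplitude_deg length-2 admissible amplitude range (degrees).
#' @param peak_velocity_max maximum plausible peak velocity (deg/s).
#' @export
saccade_artifact_criteria <- function(duration_ms = c(6, 150),
                                      amplitude_deg = c(0.05, 40),
                                      peak_velocity_max = 1200) {
  list(duration_ms = duration_ms, amplitude_deg = amplitude_deg,
       peak_velocity_max = peak_velocity_max)
}

#' Dual-threshold saccade detection
#'
#' Candidate segments are maximal runs where radial velocity exceeds
#' `v_thresh`; a candidate is kept only if the acceleration magnitude also
#' exceeds `a_thresh` within the run (the acceleration criterion at segment
#' initiation; with smoothed derivatives the acceleration peak can trail the
#' velocity crossing by a sample or two, so the test is applied over the
#' run). Segment edges are then refined outward to the flanking local
#' velocity minima, and segments failing the artifact criteria are
#' discarded. No distinction is made between microsaccades and saccades.
#'
#' @param record a differentiated [gaze_record()].
#' @param v_thresh velocity threshold (deg/s), default 30.
#' @param a_thresh acceleration threshold (deg/s^2), default 8000.
#' @param artifact_criteria see [saccade_artifact_criteria()].
#' @return data.frame of saccade events: `kind`, `onset`, `offset` (s),
#'   `duration` (s), `amplitude` (deg), `peak_velocity` (deg/s).
#' @export
detect_saccades <- function(record, v_thresh = 30, a_thresh = 8000,
                            artifact_criteria = saccade_artifact_criteria()) {
  if (is.null(record$velocity) || is.null(record$acceleration)) {
    stop("derivatives missing: call differentiate_gaze() first", call. = FALSE)
  }
  v <- record$velocity
  a <- record$acceleration
  n <- length(v)
  above <- v > v_thresh
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- list()
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    if (max(a[i0:i1]) <= a_thresh) next
    # refine edges to flanking local velocity minima
    while (i0 > 1L && v[i0 - 1L] < v[i0]) i0 <- i0 - 1L
    while (i1 < n && v[i1 + 1L] < v[i1]) i1 <- i1 + 1L
    dur <- record$t[i1] - record$t[i0]
    amp <- sqrt((record$x[i1] - record$x[i0])^2 +
                (record$y[i1] - record$y[i0])^2)
    vpk <- max(v[i0:i1])
    ac <- artifact_criteria
    if (dur < ms_to_s(ac$duration_ms[1]) || dur > ms_to_s(ac$duration_ms[2])) next
    if (amp < ac$amplitude_deg[1] || amp > ac$amplitude_deg[2]) next
    if (vpk >= ac$peak_velocity_max) next
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "saccade", onset = record$t[i0], offset = record$t[i1],
      duration = dur, amplitude = amp, peak_velocity = vpk
    )
  }
  if (length(rows) == 0) {
    return(data.frame(kind = character(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$onset), , drop = FALSE]
}

# Maximum pairwise displacement of a 2-D point cloud, via its convex hull.
max_gaze_shift <- function(x, y) {
  if (length(x) < 2) return(0)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 2) return(0)
  h <- if (nrow(pts) > 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  d <- stats::dist(h)
  max(d)
}

#' Fixation detection from inter-saccade intervals
#'
#' Each interval between two successive saccades becomes a fixation if the
#' total gaze shift within it (maximum pairwise displacement, a conservative
#' reading of the 1-degree criterion) does not exceed `max_shift`; intervals
#' with larger shifts are discarded. Fixation onset equals the preceding
#' saccade offset, and the duration runs to the next saccade onset. The
#' record edges act as virtual boundaries so a saccade-free record yields a
#' single whole-record candidate; fixations whose onset is a true saccade
#' offset are flagged `post_saccadic`.
#'
#' @param record a [gaze_record()].
#' @param saccades saccade events from [detect_saccades()], sorted by onset.
#' @param max_shift maximum tolerated gaze shift (degrees), default 1.
#' @return data.frame of fixations: `kind`, `onset`, `offset`, `duration`,
#'   `x`, `y` (mean position), `post_saccadic`.
#' @export
detect_fixations <- function(record, saccades, max_shift = 1) {
  t <- record$t
  bounds_on <- c(t[1], saccades$offset)
  bounds_off <- c(saccades$onset, t[length(t)])
  post_sacc <- c(FALSE, rep(TRUE, nrow(saccades)))
  rows <- list()
  for (i in seq_along(bounds_on)) {
    on <- bounds_on[i]; off <- bounds_off[i]
    if (off - on <= 0) next
    idx <- which(t >= on & t <= off)
    if (length(idx) < 2) next
    if (max_gaze_shift(record$x[idx], record$y[idx]) > max_shift) next
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "fixation", onset = on, offset = off, duration = off - on,
      x = mean(record$x[idx]), y = mean(record$y[idx]),
      post_saccadic = post_sacc[i]
    )
  }
  if (length(rows) == 0) {
    return(data.frame(kind = character(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      x = numeric(0), y = numeric(0),
                      post_saccadic = logical(0)))
  }
  do.call(rbind, rows)
}

#' Benchmark detected events against ground truth
#'
#' One-to-one greedy matching of detected to true event onsets within a
#' time tolerance; reports precision, recall, F1 and the signed onset
#' errors (detected minus true) of the matches.
#'
#' @param detected_onsets detected event onset times (s).
#' @param true_onsets ground-truth onset times (s).
#' @param tolerance maximum |onset error| for a match (s), default 0.01.
#' @return list: `precision`, `recall`, `f1`, `n_matched`, `onset_errors`.
#' @export
benchmark_detection <- function(detected_onsets, true_onsets,
                                tolerance = 0.01) {
  detected_onsets <- sort(detected_onsets)
  true_onsets <- sort(true_onsets)
  used <- rep(FALSE, length(detected_onsets))
  errors <- numeric(0)
  for (tt in true_onsets) {
    cand <- which(!used & abs(detected_onsets - tt) <= tolerance)
    if (length(cand) == 0) next
    j <- cand[which.min(abs(detected_onsets[cand] - tt))]
    used[j] <- TRUE
    errors <- c(errors, detected_onsets[j] - tt)
  }
  n_match <- length(errors)
  precision <- if (length(detected_onsets) > 0) n_match / length(detected_onsets) else NA_real_
  recall <- if (length(true_onsets) > 0) n_match / length(true_onsets) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = n_match, onset_errors = errors)
}
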