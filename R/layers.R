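#' Band-pass filter laminar LFP channels
#'
#' Zero-phase (forward-backward) fourth-order Butterworth band-pass,
#' 1-100 Hz by default, applied to every channel.
#'
#' @param lfp channels x samples matrix.
#' @param fs sampling rate (Hz), > 200.
#' @param band `c(low, high)` passband edges (Hz).
#' @param order filter order.
#' @return filtered matrix of the same shape.
#' @export
preprocess_lfp <- function(lfp, fs, band = c(1, 100), order = 4) {
  if (fs <= 200) stop("sampling rate must exceed 200 Hz", call. = FALSE)
  if (band[2] >= fs / 2) stop("band edge above Nyquist", call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  out <- lfp
  for (ch in seq_len(nrow(lfp))) {
    out[ch, ] <- signal::filtfilt(bf, lfp[ch, ])
  }
  out
}

#' Estimate current source density from trigger-averaged LFP
#'
#' Averages the LFP around each trigger and applies the standard
#' second-spatial-difference estimator
#' \deqn{CSD_k(t) = -[V_{k-1}(t) - 2 V_k(t) + V_{k+1}(t)] / h^2}
#' at interior channels (uniform spacing `h`). A pre-trigger window is
#' averaged alongside to provide a noise reference for boundary detection.
#'
#' @param lfp channels x samples matrix (filtered).
#' @param fs sampling rate (Hz).
#' @param triggers trigger (image onset) times (s).
#' @param window post-trigger averaging window `c(start, end)` (s).
#' @param spacing_mm electrode spacing (mm).
#' @param depths_mm channel depths (mm); default `0, h, 2h, ...`.
#' @param pre_window pre-trigger noise window (s, relative to trigger).
#' @return object of class `csd_profile`: `csd` ((channels-2) x time),
#'   `depths_mm` (interior channel depths), `time` (s post-trigger),
#'   `pre_csd`, `spacing_mm`, `n_triggers`.
#' @export
estimate_csd <- function(lfp, fs, triggers, window = c(0, 0.25),
                         spacing_mm = 0.1,
                         depths_mm = (seq_len(nrow(lfp)) - 1) * spacing_mm,
                         pre_window = c(-0.1, 0)) {
  if (length(triggers) < 10) {
    warning("fewer than 10 triggers; CSD estimate may be unreliable")
  }
  avg_window <- function(win) {
    i_rel <- round(win[1] * fs):(round(win[2] * fs) - 1L)
    acc <- matrix(0, nrow(lfp), length(i_rel))
    n_used <- 0L
    for (ev in triggers) {
      idx <- round(ev * fs) + 1L + i_rel
      if (idx[1] < 1 || idx[length(idx)] > ncol(lfp)) next
      acc <- acc + lfp[, idx]
      n_used <- n_used + 1L
    }
    list(avg = acc / max(n_used, 1L), n = n_used)
  }
  post <- avg_window(window)
  pre <- avg_window(pre_window)
  second_diff <- function(v) {
    k <- 2:(nrow(v) - 1)
    -(v[k - 1, , drop = FALSE] - 2 * v[k, , drop = FALSE] +
        v[k + 1, , drop = FALSE]) / spacing_mm^2
  }
  structure(list(csd = second_diff(post$avg),
                 pre_csd = second_diff(pre$avg),
                 lfp_scale = max(abs(post$avg)),
                 depths_mm = depths_mm[2:(length(depths_mm) - 1)],
                 time = seq(window[1], window[2] - 1 / fs, by = 1 / fs),
                 spacing_mm = spacing_mm, n_triggers = post$n),
            class = "csd_profile")
}

#' Locate the layer 4c/5 sink-source boundary in a CSD profile
#'
#' Scans depth-adjacent channel pairs for the configuration sink (negative
#' CSD) above / source (positive CSD) below at a common latency, scores
#' each pair by |sink| + |source| maximized over the search window, and
#' places the boundary at the midpoint depth of the best pair. Pairs must
#' exceed `z_thresh` times the pre-trigger CSD variability to count. A
#' second qualifying pair located more than 1 mm deeper is reported as a
#' putative V2 boundary (activity beyond the white matter).
#'
#' @param profile a [estimate_csd()] result.
#' @param search_window latency window (s) searched for the pair; default
#'   the full profile window.
#' @param z_thresh detection threshold in pre-trigger SD units.
#' @return list: `boundary_depth_mm` (NA if undetermined), `score`,
#'   `latency_s`, `v2_boundary_depth_mm` (NA if absent), `undetermined`.
#' @export
find_granular_boundary <- function(profile, search_window = NULL,
                                   z_thresh = 3) {
  stopifnot(inherits(profile, "csd_profile"))
  csd <- profile$csd
  tsel <- if (is.null(search_window)) rep(TRUE, ncol(csd)) else
    profile$time >= search_window[1] & profile$time <= search_window[2]
  csd <- csd[, tsel, drop = FALSE]
  # floor the noise estimate at numerical roundoff of the averaged LFP so
  # that an (analytically) flat CSD never yields a spurious boundary
  floor_sd <- 1e-9 * (profile$lfp_scale %||% 0) / profile$spacing_mm^2
  noise_sd <- max(stats::sd(as.vector(profile$pre_csd)), floor_sd,
                  .Machine$double.xmin)
  # sink/source channels either adjacent or straddling one near-zero
  # channel (the boundary can fall exactly on a channel)
  pairs <- rbind(cbind(seq_len(nrow(csd) - 1L), seq_len(nrow(csd) - 1L) + 1L),
                 cbind(seq_len(nrow(csd) - 2L), seq_len(nrow(csd) - 2L) + 2L))
  scores <- rep(-Inf, nrow(pairs))
  lat_idx <- rep(NA_integer_, nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    sink <- csd[pairs[j, 1], ]      # shallower channel of the pair
    source <- csd[pairs[j, 2], ]
    ok <- sink < -z_thresh * noise_sd & source > z_thresh * noise_sd
    if (!any(ok)) next
    val <- (-sink + source) * ok
    scores[j] <- max(val)
    lat_idx[j] <- which.max(val)
  }
  if (!any(is.finite(scores))) {
    warning("no sink-source pair exceeds the detection threshold; ",
            "boundary undetermined")
    return(list(boundary_depth_mm = NA_real_, score = NA_real_,
                latency_s = NA_real_, v2_boundary_depth_mm = NA_real_,
                undetermined = TRUE))
  }
  best <- which.max(scores)
  mid <- function(j) mean(profile$depths_mm[pairs[j, ]])
  boundary <- mid(best)
  v2 <- NA_real_
  deeper <- which(is.finite(scores) &
                    vapply(seq_len(nrow(pairs)), mid, 1) > boundary + 1)
  if (length(deeper) > 0) {
    v2 <- mid(deeper[which.max(scores[deeper])])
  }
  list(boundary_depth_mm = boundary, score = scores[best],
       latency_s = profile$time[tsel][lat_idx[best]],
       v2_boundary_depth_mm = v2, undetermined = FALSE)
}

#' Assign a cortical layer label from depth relative to the 4c/5 boundary
#'
#' Depth is measured positive above (more superficial than) the boundary:
#' above 0.4 mm -> supragranular; 0 to 0.4 mm above -> granular; 0 to
#' 0.4 mm below -> infragranular (depth exactly 0 falls here); more than
#' 1 mm below -> excluded as V2 (beyond the white matter); the band 0.4 to
#' 1 mm below carries no published assignment and is returned `unassigned`.
#'
#' @param depth_rel_boundary_mm numeric vector, mm above the boundary.
#' @return character vector of labels in `{supragranular, granular,
#'   infragranular, unassigned, v2_excluded}`.
#' @export
assign_layer <- function(depth_rel_boundary_mm) {
  vapply(depth_rel_boundary_mm, function(d) {
    if (is.na(d)) return(NA_character_)
    if (d > 0.4) "supragranular"
    else if (d > 0) "granular"
    else if (d >= -0.4) "infragranular"
    else if (d >= -1.0) "unassigned"
    else "v2_excluded"
  }, character(1))
}
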