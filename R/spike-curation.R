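#' Extract, up-sample and minimum-align spike waveforms
#'
#' Cuts a window around each spike time from a high-pass-filtered signal
#' (> 500 Hz, fourth-order Butterworth; see [highpass_spikes()]), cubic-
#' interpolates it to `upsample_fs` (200 kHz by default) and aligns all
#' waveforms on their minima. Spikes whose window does not fit inside the
#' signal are dropped with a warning.
#'
#' @param x high-pass-filtered signal (numeric vector).
#' @param fs sampling rate of `x` (Hz).
#' @param spike_times spike times (s) relative to the start of `x`.
#' @param window `c(pre, post)` cut window around each spike (s).
#' @param upsample_fs target sampling rate after cubic interpolation (Hz).
#' @return object of class `waveform_set`: list with `waveforms` (events x
#'   samples matrix, minima at a common column), `spike_times`, `fs`,
#'   `align_sample`.
#' @export
extract_and_align <- function(x, fs, spike_times,
                              window = c(-0.0006, 0.001),
                              upsample_fs = 200000) {
  half_lo <- window[1]; half_hi <- window[2]
  n <- length(x)
  t_sig <- (seq_len(n) - 1L) / fs
  keep <- spike_times + half_lo >= 0 & spike_times + half_hi <= t_sig[n]
  if (any(!keep)) {
    warning(sprintf("%d spike(s) too close to the signal edge dropped",
                    sum(!keep)))
  }
  spike_times <- spike_times[keep]
  if (length(spike_times) == 0) stop("no extractable spikes", call. = FALSE)
  up_dt <- 1 / upsample_fs
  grid_rel <- seq(half_lo, half_hi, by = up_dt)
  # search for the minimum only in the central third to avoid edge noise
  ctr <- which(grid_rel >= half_lo / 2 & grid_rel <= half_hi / 2)
  mats <- lapply(spike_times, function(ts) {
    i0 <- max(1L, floor((ts + half_lo) * fs) - 2L)
    i1 <- min(n, ceiling((ts + half_hi) * fs) + 3L)
    stats::spline(t_sig[i0:i1], x[i0:i1], xout = ts + grid_rel,
                  method = "natural")$y
  })
  w <- do.call(rbind, mats)
  min_idx <- apply(w[, ctr, drop = FALSE], 1, which.min) + ctr[1] - 1L
  target <- round(stats::median(min_idx))
  max_abs <- max(abs(min_idx - target))
  lo <- 1L + max_abs
  hi <- ncol(w) - max_abs
  aligned <- t(vapply(seq_len(nrow(w)), function(i) {
    off <- min_idx[i] - target
    w[i, (lo + off):(hi + off)]
  }, numeric(hi - lo + 1L)))
  structure(list(waveforms = aligned, spike_times = spike_times,
                 fs = upsample_fs, align_sample = target - lo + 1L),
            class = "waveform_set")
}

#' High-pass filter a wideband signal for spike extraction
#'
#' Fourth-order Butterworth high-pass above `cutoff` (500 Hz default),
#' applied forward-backward for zero phase.
#'
#' @param x signal vector; @param fs sampling rate (Hz);
#' @param cutoff high-pass edge (Hz); @param order filter order.
#' @export
highpass_spikes <- function(x, fs, cutoff = 500, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff above Nyquist", call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Fraction of inter-spike intervals violating the refractory period
#'
#' @param spike_times spike times (s).
#' @param threshold refractory period (s), default 1.2 ms.
#' @export
isi_violation_fraction <- function(spike_times, threshold = 0.0012) {
  if (length(spike_times) < 2) return(0)
  isi <- diff(sort(spike_times))
  mean(isi < threshold)
}

new_unit_cluster <- function(members, mean_waveform, spike_times) {
  structure(list(members = members, mean_waveform = mean_waveform,
                 spike_times = spike_times,
                 isi_violation_fraction = isi_violation_fraction(spike_times)),
            class = "unit_cluster")
}

#' Re-cluster spike waveforms in principal-component space
#'
#' Projects the waveforms onto their first `n_components` principal
#' components, fits Gaussian mixture models with 1 to `max_clusters`
#' components (model chosen by BIC), and returns the resulting clusters as
#' single-unit candidates. Clusters whose inter-spike-interval refractory
#' violation fraction (< 1.2 ms) exceeds `violation_limit` (0.1% of all
#' ISIs by default) are rejected as multi-unit contamination and not
#' returned.
#'
#' @param ws a [extract_and_align()] `waveform_set`, or any list with
#'   `waveforms` (events x samples) and `spike_times`.
#' @param max_clusters maximum mixture components (default 3).
#' @param n_components PCs retained (default 3).
#' @param violation_limit maximal tolerated ISI-violation fraction.
#' @param min_events minimum event count required for a fit.
#' @return list of `unit_cluster` objects (possibly empty).
#' @export
recluster <- function(ws, max_clusters = 3, n_components = 3,
                      violation_limit = 0.001, min_events = 50) {
  w <- ws$waveforms
  if (nrow(w) < min_events) {
    stop(sprintf("need at least %d events to re-cluster", min_events),
         call. = FALSE)
  }
  pcs <- stats::prcomp(w, center = TRUE, scale. = FALSE)$x
  pcs <- pcs[, seq_len(min(n_components, ncol(pcs))), drop = FALSE]
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(pcs, G = seq_len(max_clusters), verbose = FALSE)
  cl <- fit$classification
  out <- list()
  for (g in sort(unique(cl))) {
    idx <- which(cl == g)
    uc <- new_unit_cluster(idx, colMeans(w[idx, , drop = FALSE]),
                           sort(ws$spike_times[idx]))
    if (uc$isi_violation_fraction > violation_limit) next
    out[[length(out) + 1L]] <- uc
  }
  out
}

#' Best-lag squared correlation between two waveforms
#'
#' Pearson correlation squared, maximized over integer shifts up to
#' `max_lag` samples (minimum-alignment leaves residual jitter).
#'
#' @param w1,w2 numeric waveforms of equal length.
#' @param max_lag maximum |shift| in samples.
#' @export
waveform_r2 <- function(w1, w2, max_lag = 10) {
  n <- length(w1)
  best <- 0
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      a <- w1[(1 + lag):n]; b <- w2[1:(n - lag)]
    } else {
      a <- w1[1:(n + lag)]; b <- w2[(1 - lag):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    best <- max(best, stats::cor(a, b)^2)
  }
  best
}

#' Merge near-duplicate waveform clusters
#'
#' Computes pairwise best-lag squared correlations between cluster-mean
#' waveforms and merges every connected component of the graph whose edges
#' have R^2 above `r2_threshold` (so merging is symmetric and transitive);
#' no events are lost.
#'
#' @param clusters list of `unit_cluster` objects sharing a sample count.
#' @param r2_threshold merge threshold on R^2 (default 0.95).
#' @param max_lag see [waveform_r2()].
#' @return list of merged `unit_cluster` objects.
#' @export
merge_clusters <- function(clusters, r2_threshold = 0.95, max_lag = 10) {
  k <- length(clusters)
  if (k <= 1) return(clusters)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      r2 <- waveform_r2(clusters[[i]]$mean_waveform,
                        clusters[[j]]$mean_waveform, max_lag)
      if (r2 > r2_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  lapply(unique(roots), function(r) {
    grp <- clusters[roots == r]
    members <- sort(unlist(lapply(grp, `[[`, "members")))
    sizes <- vapply(grp, function(g) length(g$members), 1L)
    mw <- Reduce(`+`, Map(function(g, s) g$mean_waveform * s, grp, sizes)) /
      sum(sizes)
    new_unit_cluster(members, mw, sort(unlist(lapply(grp, `[[`, "spike_times"))))
  })
}
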