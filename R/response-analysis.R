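#' Align spike times to trigger events
#'
#' @param spikes spike times (s), need not be sorted.
#' @param triggers trigger event times (s).
#' @param window `c(pre, post)` window around each trigger (s); spikes
#'   outside it are excluded.
#' @return list (one element per trigger) of trigger-relative spike times;
#'   attribute `n_events` = number of triggers.
#' @export
align_spikes <- function(spikes, triggers, window = c(-0.1, 0.3)) {
  spikes <- sort(spikes)
  out <- lapply(triggers, function(tr) {
    i0 <- findInterval(tr + window[1], spikes) + 1L
    i1 <- findInterval(tr + window[2], spikes)
    if (i1 < i0) numeric(0) else spikes[i0:i1] - tr
  })
  attr(out, "n_events") <- length(triggers)
  out
}

# Integrated-squared-error cost for a fixed Gaussian kernel bandwidth,
# evaluated on binned spike counts (Shimazaki-Shinomoto style): the
# convolution term uses the self-convolved kernel (SD w*sqrt(2)) and the
# leave-one-out cross term subtracts the zero-lag contribution.
kernel_cost <- function(counts, binwidth, w) {
  nb <- length(counts)
  lags <- (0:(nb - 1)) * binwidth
  k2 <- stats::dnorm(lags, 0, sqrt(2) * w)
  k1 <- stats::dnorm(lags, 0, w)
  # sum_{i,j} f(|ti - tj|) via count cross-products per lag
  cc <- numeric(nb)
  cc[1] <- sum(counts^2)
  for (l in seq_len(nb - 1)) {
    cc[l + 1] <- 2 * sum(counts[1:(nb - l)] * counts[(1 + l):nb])
  }
  n_sp <- sum(counts)
  sum(cc * k2) - 2 * (sum(cc * k1) - n_sp * stats::dnorm(0, 0, w))
}

#' Optimal fixed Gaussian bandwidth for a PSTH
#'
#' Selects the kernel width minimizing an integrated-squared-error cost
#' estimated from the data (fixed-kernel bandwidth optimization), searched
#' on a log-spaced grid. Spike times are pre-binned at `binwidth` for the
#' cost evaluation.
#'
#' @param rel_times pooled trigger-relative spike times (s).
#' @param window analysis window `c(pre, post)` (s).
#' @param binwidth pre-binning resolution (s).
#' @param grid candidate bandwidths (s).
#' @return bandwidth (s).
#' @export
optimize_bandwidth <- function(rel_times, window, binwidth = 0.002,
                               grid = exp(seq(log(0.003), log(0.1),
                                              length.out = 18))) {
  edges <- seq(window[1], window[2], by = binwidth)
  counts <- as.integer(table(cut(rel_times, edges)))
  if (sum(counts) < 2) return(grid[length(grid) %/% 2])
  costs <- vapply(grid, function(w) kernel_cost(counts, binwidth, w),
                  numeric(1))
  grid[which.min(costs)]
}

#' Kernel-smoothed PSTH
#'
#' Gaussian-kernel firing-rate estimate at `resolution` (2 ms default),
#' normalized per trigger event so that the integral of the curve over the
#' window equals the mean spike count per event. The bandwidth is selected
#' by [optimize_bandwidth()] unless supplied.
#'
#' @param aligned output of [align_spikes()] (or a list of relative spike
#'   time vectors with attribute `n_events`).
#' @param window analysis window `c(pre, post)` (s).
#' @param resolution sample step of the rate curve (s).
#' @param bandwidth optional fixed kernel SD (s).
#' @return object of class `psth`: list with `time` (s), `rate` (Hz),
#'   `bandwidth`, `n_events`, `mean_count`.
#' @export
smooth_psth <- function(aligned, window = c(-0.1, 0.3), resolution = 0.002,
                        bandwidth = NULL) {
  n_events <- attr(aligned, "n_events") %||% length(aligned)
  rel <- unlist(aligned)
  rel <- rel[rel >= window[1] & rel <= window[2]]
  tgrid <- seq(window[1], window[2], by = resolution)
  if (length(rel) == 0) {
    return(structure(list(time = tgrid, rate = numeric(length(tgrid)),
                          bandwidth = NA_real_, n_events = n_events,
                          mean_count = 0), class = "psth"))
  }
  if (is.null(bandwidth)) {
    bandwidth <- optimize_bandwidth(rel, window, binwidth = resolution)
  }
  # bin at the output resolution, renormalize each source bin by the kernel
  # mass falling inside the window (boundary-corrected KDE, so the curve
  # integrates to the mean count per event), then convolve
  edges <- c(tgrid - resolution / 2, tgrid[length(tgrid)] + resolution / 2)
  counts <- as.integer(table(cut(rel, edges)))
  inside_mass <- stats::pnorm(window[2], tgrid, bandwidth) -
    stats::pnorm(window[1], tgrid, bandwidth)
  weights <- counts / pmax(inside_mass, 1e-12)
  half <- ceiling(4 * bandwidth / resolution)
  kern <- stats::dnorm((-half:half) * resolution, 0, bandwidth)
  padded <- c(numeric(half), weights, numeric(half))
  sm <- vapply(seq_along(tgrid), function(i) sum(padded[i:(i + 2 * half)] * kern),
               numeric(1))
  rate <- sm / n_events
  structure(list(time = tgrid, rate = rate, bandwidth = bandwidth,
                 n_events = n_events, mean_count = length(rel) / n_events),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d events, bandwidth %.1f ms, peak %.2f Hz at %.0f ms\n",
              x$n_events, s_to_ms(x$bandwidth), max(x$rate),
              s_to_ms(x$time[which.max(x$rate)])))
  invisible(x)
}

#' Test PSTH peak significance against a condition-specific baseline
#'
#' Computes the smoothed PSTH, finds the peak within `search_window`
#' ([0, 300) ms by default), counts spikes per trigger in a 20-ms bin
#' centered at the peak (shifted inward if it overlaps the analysis-window
#' edge), builds the baseline spike-count distribution from exclusive 20-ms
#' bins tiling `baseline_intervals` (passive condition: the second before
#' each image onset; active condition: from 1 s after image onset to image
#' offset), and compares the two count distributions with a two-sample
#' Kolmogorov-Smirnov test. The peak is significant iff `p < alpha` and
#' the mean peak count exceeds the mean baseline count (the test itself is
#' sign-blind; responsiveness counts rate increases only).
#'
#' @param spikes spike times (s).
#' @param triggers trigger times (s).
#' @param baseline_intervals two-column matrix (start, end) of baseline
#'   intervals (s).
#' @param condition label stored on the result (`"img_on"` or `"fix_on"`).
#' @param alpha significance level.
#' @param window PSTH window (s).
#' @param search_window peak search window (s).
#' @param peak_bin peak-counting bin width (s).
#' @param resolution PSTH resolution (s).
#' @param bandwidth optional fixed kernel SD (s).
#' @return object of class `psth_result`: the `psth` fields plus
#'   `condition`, `peak_time_ms`, `peak_rate`, `peak_counts`,
#'   `baseline_counts`, `baseline_rate`, `p_value`, `significant`.
#' @export
test_peak_significance <- function(spikes, triggers, baseline_intervals,
                                   condition = c("img_on", "fix_on"),
                                   alpha = 0.05, window = c(-0.1, 0.3),
                                   search_window = c(0, 0.3),
                                   peak_bin = 0.02, resolution = 0.002,
                                   bandwidth = NULL) {
  condition <- match.arg(condition)
  if (nrow(baseline_intervals) == 0 ||
      all(baseline_intervals[, 2] - baseline_intervals[, 1] < peak_bin)) {
    stop("baseline shorter than one bin", call. = FALSE)
  }
  aligned <- align_spikes(spikes, triggers, window)
  ps <- smooth_psth(aligned, window, resolution, bandwidth)
  in_search <- ps$time >= search_window[1] & ps$time < search_window[2]
  idx <- which(in_search)[which.max(ps$rate[in_search])]
  peak_time <- ps$time[idx]
  peak_rate <- ps$rate[idx]
  # center the 20-ms bin on the peak, shifting inward at window edges
  lo <- peak_time - peak_bin / 2
  lo <- min(max(lo, window[1]), window[2] - peak_bin)
  peak_counts <- as.integer(count_in_intervals(spikes, triggers + lo,
                                               triggers + lo + peak_bin))
  baseline_counts <- count_in_tiled_bins(spikes, baseline_intervals[, 1],
                                         baseline_intervals[, 2], peak_bin)
  if (length(baseline_counts) == 0) stop("empty baseline", call. = FALSE)
  if (sum(peak_counts) + sum(baseline_counts) == 0) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::ks.test(peak_counts, baseline_counts, exact = FALSE)$p.value)
  }
  significant <- p < alpha && mean(peak_counts) > mean(baseline_counts)
  structure(c(ps, list(condition = condition,
                       peak_time_ms = s_to_ms(peak_time),
                       peak_rate = peak_rate,
                       peak_counts = peak_counts,
                       baseline_counts = baseline_counts,
                       baseline_rate = mean(baseline_counts) / peak_bin,
                       p_value = p, significant = significant)),
            class = c("psth_result", "psth"))
}

#' Baseline intervals for the two viewing conditions
#'
#' Passive (`img_on`): the interval from 1 s before to each image onset.
#' Active (`fix_on`): from 1 s after image onset to image offset of every
#' trial, excluding the early post-onset transient.
#'
#' @param condition `"img_on"` or `"fix_on"`.
#' @param trials data.frame with `img_on` and `img_off` times (s).
#' @return two-column matrix of interval (start, end) times.
#' @export
baseline_intervals <- function(condition = c("img_on", "fix_on"), trials) {
  condition <- match.arg(condition)
  if (condition == "img_on") {
    cbind(trials$img_on - 1, trials$img_on)
  } else {
    cbind(trials$img_on + 1, trials$img_off)
  }
}

#' Classify a unit's responsiveness from both conditions
#'
#' Deterministic function of the two significance verdicts:
#' both -> `doubly_responsive`; fix-on only -> `fixation_only`;
#' img-on only -> `img_only`; neither -> `non_responsive`. The latency
#' class splits units at 80 ms of img-on peak latency (`long` strictly
#' above 80 ms).
#'
#' @param img_result,fix_result [test_peak_significance()] results.
#' @return list: `label`, `latency_class`, `img_latency_ms`,
#'   `fix_latency_ms`.
#' @export
classify_unit <- function(img_result, fix_result) {
  si <- isTRUE(img_result$significant)
  sf <- isTRUE(fix_result$significant)
  label <- if (si && sf) "doubly_responsive"
  else if (!si && sf) "fixation_only"
  else if (si && !sf) "img_only"
  else "non_responsive"
  list(label = label,
       latency_class = if (img_result$peak_time_ms > 80) "long" else "short",
       img_latency_ms = img_result$peak_time_ms,
       fix_latency_ms = fix_result$peak_time_ms)
}

#' Latency summaries per layer and latency class
#'
#' Paired img-on minus fix-on latency differences for doubly responsive
#' units, with medians and interquartile ranges per layer, overall and
#' split at the 80-ms img-on latency boundary into short- and long-latency
#' units.
#'
#' @param units data.frame with columns `unit_id`, `layer`, `label`,
#'   `latency_class`, `img_latency_ms`, `fix_latency_ms`.
#' @return list: `paired` (data.frame of per-unit differences for doubly
#'   responsive units), `by_layer` (summary data.frame).
#' @export
latency_table <- function(units) {
  dbl <- units[units$label == "doubly_responsive", , drop = FALSE]
  dbl$latency_diff_ms <- dbl$img_latency_ms - dbl$fix_latency_ms
  summarize <- function(sub, layer, cls) {
    if (nrow(sub) == 0) return(NULL)
    data.frame(layer = layer, latency_class = cls, n = nrow(sub),
               median_img = stats::median(sub$img_latency_ms),
               median_fix = stats::median(sub$fix_latency_ms),
               median_diff = stats::median(sub$latency_diff_ms),
               iqr_diff = stats::IQR(sub$latency_diff_ms))
  }
  rows <- list()
  for (ly in unique(dbl$layer)) {
    sub <- dbl[dbl$layer == ly, , drop = FALSE]
    rows <- c(rows, list(summarize(sub, ly, "all")),
              list(summarize(sub[sub$latency_class == "short", ], ly, "short")),
              list(summarize(sub[sub$latency_class == "long", ], ly, "long")))
  }
  rows <- c(rows, list(summarize(dbl, "all", "all")),
            list(summarize(dbl[dbl$latency_class == "short", ], "all", "short")),
            list(summarize(dbl[dbl$latency_class == "long", ], "all", "long")))
  list(paired = dbl, by_layer = do.call(rbind, Filter(Negate(is.null), rows)))
}
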