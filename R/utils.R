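# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

# Count spikes falling in [start, end) for each interval, using a sorted
# spike-time vector. Returns an integer vector of length nrow(intervals).
count_in_intervals <- function(spikes, starts, ends) {
  spikes <- sort(spikes)
  findInterval(ends, spikes, left.open = FALSE) -
    findInterval(starts, spikes, left.open = FALSE)
}

# Tile each interval [starts[i], ends[i]] with exclusive bins of width
# `binwidth` (partial trailing bins dropped) and count spikes per bin.
count_in_tiled_bins <- function(spikes, starts, ends, binwidth) {
  spikes <- sort(spikes)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    n_bins <- floor((ends[i] - starts[i]) / binwidth + 1e-9)
    if (n_bins < 1L) {
      out[[i]] <- integer(0)
      next
    }
    edges <- starts[i] + binwidth * (0:n_bins)
    out[[i]] <- as.integer(diff(findInterval(edges, spikes)))
  }
  unlist(out)
}

# Seconds <-> milliseconds, kept explicit to avoid unit slips.
ms_to_s <- function(x) x / 1000
s_to_ms <- function(x) x * 1000
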