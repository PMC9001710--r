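#' Detect firing-rate change points in per-trial spike counts
#'
#' Slides a `block`-trial window (step `step`, 1 by default so each and
#' every successive block is tested) over the trial spike counts, compares
#' the first `half` and last `half` counts of every block with a two-sample
#' Kolmogorov-Smirnov test, applies Benjamini-Hochberg false-discovery-rate
#' control at `alpha` across all block p-values, and consolidates each
#' maximal run of significant consecutive blocks into one change point at
#' the middle of the run's minimum-p block (the border between the two
#' block halves). Segments between consecutive change points (and the
#' record ends) are returned; analyses downstream use only the longest.
#'
#' KS p-values on tied integer counts use the asymptotic statistic, which
#' is conservative under ties.
#'
#' @param trial_counts integer vector of per-trial spike counts.
#' @param block sliding block length in trials (default 30).
#' @param half trials per half (default `block / 2`).
#' @param alpha BH false-discovery level.
#' @param step slide step in trials.
#' @return object of class `segmentation_result`: list with `changepoints`
#'   (trial indices; a change point at `k` splits trials `1..k` and
#'   `k+1..n`), `segments` (data.frame `first`,`last`), `longest_segment`,
#'   `block_pvalues`, `block_starts`, `n_trials`.
#' @export
detect_rate_changepoints <- function(trial_counts, block = 30,
                                     half = block %/% 2, alpha = 0.05,
                                     step = 1) {
  n <- length(trial_counts)
  if (n < block) {
    warning("fewer trials than one block; whole record returned as one segment")
    return(new_segmentation(integer(0), n, numeric(0), integer(0)))
  }
  starts <- seq(1L, n - block + 1L, by = step)
  pvals <- vapply(starts, function(s) {
    a <- trial_counts[s:(s + half - 1L)]
    b <- trial_counts[(s + half):(s + block - 1L)]
    suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  padj <- stats::p.adjust(pvals, method = "BH")
  sig <- padj <= alpha
  cps <- integer(0)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  run_starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    run_idx <- run_starts[k]:ends[k]
    best <- run_idx[which.min(pvals[run_idx])]
    cps <- c(cps, starts[best] + half - 1L)   # border between the halves
  }
  new_segmentation(sort(unique(cps)), n, pvals, starts)
}

new_segmentation <- function(changepoints, n_trials, pvals, starts) {
  edges <- c(0L, changepoints, n_trials)
  segments <- data.frame(first = head(edges, -1) + 1L, last = edges[-1])
  lens <- segments$last - segments$first + 1L
  # ties broken toward the later segment: late-session data follow
  # stabilization
  best <- max(which(lens == max(lens)))
  structure(list(changepoints = changepoints, segments = segments,
                 longest_segment = c(segments$first[best], segments$last[best]),
                 block_pvalues = pvals, block_starts = starts,
                 n_trials = n_trials),
            class = "segmentation_result")
}

#' Longest stationary trial segment
#'
#' Returns the `(first, last)` trial interval of the longest segment
#' between detected change points; ties are broken toward the later
#' segment.
#'
#' @param result a [detect_rate_changepoints()] result.
#' @export
select_stationary_segment <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  result$longest_segment
}
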