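#' Lifetime sparseness of a spike-count vector
#'
#' Quantifies how unevenly a unit's response is distributed across trigger
#' events (image onsets or fixation onsets). With per-event spike counts
#' \eqn{r_i}, \eqn{i = 1..N}, the activity ratio is
#' \deqn{a = \left(\sum_i r_i / N\right)^2 / \left(\sum_i r_i^2 / N\right)}
#' and the lifetime sparseness
#' \deqn{S = (1 - a) / (1 - 1/N).}
#' \eqn{S = 0} when the unit responds identically to every event (least
#' sparse) and \eqn{S = 1} when it responds to exactly one event (maximally
#' sparse).
#'
#' An all-zero count vector makes \eqn{a} a 0/0 form; it is returned as
#' \eqn{S = 0} with attribute \code{degenerate = TRUE}, on the reasoning that
#' a silent unit carries no sparseness information. Such units should be
#' excluded from condition comparisons (see [layer_resolved_report()]).
#'
#' @param r numeric vector of non-negative per-event spike counts
#'   (real values are accepted so rate-based inputs also work).
#' @param N number of events; defaults to `length(r)` and must equal it.
#' @return scalar sparseness in `[0, 1]`; attributes `a` (activity ratio)
#'   and `degenerate`.
#' @examples
#' lifetime_sparseness(c(5, 5, 5, 5))   # 0
#' lifetime_sparseness(c(10, 0, 0, 0))  # 1
#' lifetime_sparseness(c(2, 0, 2, 0))   # 2/3
#' @export
lifetime_sparseness <- function(r, N = length(r)) {
  if (!is.numeric(r) || any(!is.finite(r))) {
    stop("`r` must be a finite numeric vector", call. = FALSE)
  }
  if (any(r < 0)) stop("spike counts must be non-negative", call. = FALSE)
  if (N != length(r)) stop("`N` must equal length(r)", call. = FALSE)
  if (N < 2) stop("sparseness requires N >= 2 events", call. = FALSE)
  if (all(r == 0)) {
    return(structure(0, a = NA_real_, degenerate = TRUE))
  }
  a <- (sum(r) / N)^2 / (sum(r^2) / N)
  s <- (1 - a) / (1 - 1 / N)
  structure(s, a = a, degenerate = FALSE)
}

#' Per-event spike counts in the peak-centered response window
#'
#' Counts spikes in a window (100 ms by default) centered at the PSTH peak
#' time of the unit, per trigger event. If the peak lies closer to the
#' trigger than half the window, the window is shifted to start at the
#' trigger so that it never extends into pre-trigger time.
#'
#' @param spikes numeric vector of spike times (s).
#' @param triggers trigger event times (s).
#' @param peak_time_ms PSTH peak time, ms post-trigger.
#' @param window_ms counting window width, ms.
#' @return integer vector of counts, one per trigger; attribute
#'   `window_ms` records the (possibly shifted) window actually used.
#' @export
count_response_spikes <- function(spikes, triggers, peak_time_ms,
                                  window_ms = 100) {
  stopifnot(is.numeric(triggers), length(triggers) >= 1)
  stop_if_not_positive(window_ms, "window_ms")
  half <- window_ms / 2
  lo <- peak_time_ms - half
  if (lo < 0) {
    lo <- 0
  }
  hi <- lo + window_ms
  counts <- count_in_intervals(spikes, triggers + ms_to_s(lo),
                               triggers + ms_to_s(hi))
  structure(as.integer(counts), window_ms = c(lo, hi))
}

#' Compare sparseness between viewing conditions
#'
#' Paired comparison (Wilcoxon signed-rank) of per-unit sparseness between
#' the passive (img-on) and active (fix-on) condition, or an unpaired
#' Mann-Whitney U fallback when the unit sets differ.
#'
#' @param img_values per-unit sparseness, passive condition.
#' @param fix_values per-unit sparseness, active condition.
#' @param paired logical; paired signed-rank (default) or unpaired U test.
#' @return list with `statistic`, `p_value`, `median_img`, `median_fix`,
#'   `n`, `flag` (e.g. "all_differences_zero").
#' @export
compare_sparseness <- function(img_values, fix_values, paired = TRUE) {
  if (paired && length(img_values) != length(fix_values)) {
    stop("paired comparison needs aligned vectors of equal length",
         call. = FALSE)
  }
  n <- if (paired) length(img_values) else min(length(img_values), length(fix_values))
  if (paired && n < 2) {
    warning("signed-rank test undefined for fewer than 2 pairs")
    return(list(statistic = NA_real_, p_value = NA_real_,
                median_img = stats::median(img_values),
                median_fix = stats::median(fix_values),
                n = n, flag = "too_few_pairs"))
  }
  flag <- NULL
  if (paired && all(fix_values - img_values == 0)) {
    return(list(statistic = NA_real_, p_value = 1,
                median_img = stats::median(img_values),
                median_fix = stats::median(fix_values),
                n = n, flag = "all_differences_zero"))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(fix_values, img_values, paired = paired, exact = FALSE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       median_img = stats::median(img_values),
       median_fix = stats::median(fix_values),
       n = n, flag = flag)
}

#' Layer-resolved sparseness report
#'
#' Groups per-unit sparseness by cortical layer and condition, excludes
#' degenerate (zero-spike) units, and runs the paired condition comparison
#' within each layer. Columns `S_img` and `S_fix` are required;
#' `S_fix_matched` (contrast-matched fix-on sparseness) is used when present.
#'
#' @param sparseness data.frame with columns `unit_id`, `layer`, `S_img`,
#'   `S_fix`, optionally `S_fix_matched`, and optionally logical
#'   `degenerate` marking zero-spike units.
#' @return list per layer with medians, `n`, the paired test, and (when the
#'   matched column exists) the contrast-matched comparison; layers with no
#'   units are omitted with a warning.
#' @export
layer_resolved_report <- function(sparseness) {
  stopifnot(all(c("unit_id", "layer", "S_img", "S_fix") %in% names(sparseness)))
  if (!is.null(sparseness$degenerate)) {
    n_drop <- sum(sparseness$degenerate)
    if (n_drop > 0) {
      message(sprintf("excluding %d zero-spike unit(s) from comparisons", n_drop))
    }
    sparseness <- sparseness[!sparseness$degenerate, , drop = FALSE]
  }
  layers <- c("supragranular", "granular", "infragranular")
  out <- list()
  for (ly in layers) {
    sub <- sparseness[sparseness$layer == ly, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("no units in layer '%s'; group omitted", ly))
      next
    }
    entry <- list(
      n = nrow(sub),
      median_img = stats::median(sub$S_img),
      median_fix = stats::median(sub$S_fix),
      test = compare_sparseness(sub$S_img, sub$S_fix, paired = TRUE)
    )
    if (!is.null(sub$S_fix_matched)) {
      ok <- !is.na(sub$S_fix_matched)
      entry$median_fix_matched <- stats::median(sub$S_fix_matched[ok])
      if (sum(ok) >= 2) {
        entry$test_matched <- compare_sparseness(sub$S_img[ok],
                                                 sub$S_fix_matched[ok],
                                                 paired = TRUE)
      }
    }
    out[[ly]] <- entry
  }
  out
}
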