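#' Default end-to-end study configuration
#'
#' One nested list mirroring every stage default; pass a modified copy to
#' [run_study()] to change any of them.
#'
#' @export
default_config <- function() {
  list(
    eye = list(window = 21, polyorder = 3, v_thresh = 30, a_thresh = 8000,
               max_shift = 1,
               artifact_criteria = saccade_artifact_criteria()),
    curation = list(block = 30, alpha = 0.05, recluster = FALSE),
    response = list(alpha = 0.05, window = c(-0.1, 0.3),
                    search_window = c(0, 0.3), peak_bin = 0.02,
                    resolution = 0.002,
                    min_fix_duration = 0.1,     # peak bin must fit
                    min_post_imgon = 0.2,       # skip the 1st post-onset fixation
                    fix_margin = 0.35),         # full window inside the trial
    sparseness = list(window_ms = 100, min_events_matched = 10),
    features = list(n_bins = 10, patch_factor = 2),
    layers = list(band = c(1, 100), z_thresh = 3, csd_window = c(0, 0.25))
  )
}

#' Responsiveness contingency table
#'
#' 2 x 2 counts of img-on significance by fix-on significance, with
#' percentages of the total, overall and (when layers are supplied) per
#' layer. Marginals always sum to the unit count.
#'
#' @param labels per-unit responsiveness labels from [classify_unit()].
#' @param layers optional per-unit layer labels.
#' @return list: `counts` (2 x 2 matrix, rows img-on sig/not, columns
#'   fix-on sig/not), `percent`, `total`, and `by_layer` if layers given.
#' @export
make_contingency <- function(labels, layers = NULL) {
  tab <- function(lab) {
    m <- matrix(c(sum(lab == "doubly_responsive"), sum(lab == "fixation_only"),
                  sum(lab == "img_only"), sum(lab == "non_responsive")),
                2, 2,
                dimnames = list(img_on = c("sig", "ns"),
                                fix_on = c("sig", "ns")))
    list(counts = m, percent = 100 * m / max(length(lab), 1L),
         total = length(lab))
  }
  out <- tab(labels)
  if (!is.null(layers)) {
    out$by_layer <- lapply(split(labels, layers), tab)
  }
  out
}

# Gaze position at given times (nearest sample).
gaze_at <- function(gaze, times) {
  idx <- pmin(pmax(round(times * attr(gaze, "fs")) + 1L, 1L), nrow(gaze))
  cbind(gaze$x[idx], gaze$y[idx])
}

#' Run the full passive-versus-active study on one session
#'
#' Orchestrates all stages on an `av_session` (from [simulate_session()] or
#' [read_session()]): eye-event detection, per-unit firing-rate
#' change-point segmentation (only the longest stationary segment of each
#' unit is analyzed), CSD-based layer assignment, img-on and fix-on PSTH
#' peak/latency/significance analysis, gaze-contingent patch contrast and
#' orientedness with contrast matching, contrast-matched fix-on reanalysis,
#' and lifetime sparseness with layer-resolved paired comparisons.
#'
#' @param session an `av_session`.
#' @param config see [default_config()].
#' @param seed seed for the (only) stochastic stage, the contrast-matching
#'   subsample; fixed seed + fixed session gives an identical report.
#' @return object of class `study_report`.
#' @export
run_study <- function(session, config = default_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  trials <- session$trials
  dropped <- list()

  # --- 1. eye events -------------------------------------------------------
  rec <- differentiate_gaze(session$gaze, cfg$eye$window, cfg$eye$polyorder)
  saccades <- detect_saccades(rec, cfg$eye$v_thresh, cfg$eye$a_thresh,
                              cfg$eye$artifact_criteria)
  fixations <- detect_fixations(rec, saccades, cfg$eye$max_shift)

  # fix-on trigger events: post-saccadic fixations inside a trial, long
  # enough for the peak bin, past the image-onset transient, and with the
  # full analysis window inside the viewing period
  tr_idx <- findInterval(fixations$onset, trials$img_on)
  ok <- tr_idx >= 1 & tr_idx <= nrow(trials)
  ok[ok] <- fixations$onset[ok] <= trials$img_off[tr_idx[ok]] - cfg$response$fix_margin &
    fixations$onset[ok] >= trials$img_on[tr_idx[ok]] + cfg$response$min_post_imgon
  keep <- ok & fixations$post_saccadic &
    fixations$duration >= cfg$response$min_fix_duration
  fix_events <- data.frame(onset = fixations$onset[keep],
                           x = fixations$x[keep], y = fixations$y[keep],
                           trial = tr_idx[keep])
  dropped$fixations_excluded <- sum(!keep)

  # --- 2. stationary-segment selection per unit ----------------------------
  n_units <- length(session$spikes)
  segments <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    counts <- count_in_intervals(session$spikes[[u]], trials$img_on,
                                 trials$img_off)
    seg <- suppressWarnings(
      detect_rate_changepoints(counts, block = cfg$curation$block,
                               alpha = cfg$curation$alpha))
    segments[[u]] <- select_stationary_segment(seg)
  }

  # --- 3. layer assignment -------------------------------------------------
  lfp_f <- preprocess_lfp(session$lfp$lfp, session$lfp$fs, cfg$layers$band)
  csd <- estimate_csd(lfp_f, session$lfp$fs, trials$img_on,
                      window = cfg$layers$csd_window)
  bnd <- find_granular_boundary(csd, z_thresh = cfg$layers$z_thresh)
  unit_layer <- assign_layer(bnd$boundary_depth_mm - session$units$depth_mm)

  # --- 4. response analysis, both conditions -------------------------------
  # --- 5. image features + contrast matching -------------------------------
  rf <- session$rf
  img_gaze <- gaze_at(session$gaze, trials$img_on)
  feat_of <- function(gxy, trial) {
    img <- session$images[[trials$image_id[trial]]]
    patch_features(img, gxy, rf, cfg$features$patch_factor)
  }
  img_feat <- lapply(seq_len(nrow(trials)), function(i)
    feat_of(img_gaze[i, ], i))
  fix_feat <- lapply(seq_len(nrow(fix_events)), function(i)
    feat_of(c(fix_events$x[i], fix_events$y[i]), fix_events$trial[i]))
  img_ok <- !vapply(img_feat, is.null, TRUE)
  fix_ok <- !vapply(fix_feat, is.null, TRUE)
  dropped$patches_out_of_bounds <- sum(!img_ok) + sum(!fix_ok)
  img_contrast <- vapply(img_feat[img_ok], `[[`, 1, "contrast")
  fix_contrast <- vapply(fix_feat[fix_ok], `[[`, 1, "contrast")
  img_orient <- vapply(img_feat[img_ok], `[[`, 1, "orientedness")
  fix_orient <- vapply(fix_feat[fix_ok], `[[`, 1, "orientedness")
  matched_rel <- match_contrast(fix_contrast, img_contrast,
                                n_bins = cfg$features$n_bins)
  matched_idx <- which(fix_ok)[matched_rel]   # rows of fix_events
  feature_summary <- list(
    contrast = compare_feature_distributions(img_contrast, fix_contrast),
    orientedness = compare_feature_distributions(img_orient, fix_orient),
    contrast_matched = if (length(matched_rel) >= 2)
      compare_feature_distributions(img_contrast, fix_contrast[matched_rel])
    else NULL,
    n_img = sum(img_ok), n_fix = sum(fix_ok),
    n_matched = length(matched_rel)
  )

  unit_rows <- list()
  sparse_rows <- list()
  rcfg <- cfg$response
  for (u in seq_len(n_units)) {
    sp <- session$spikes[[u]]
    seg <- segments[[u]]
    seg_trials <- trials[trials$trial >= seg[1] & trials$trial <= seg[2], ]
    img_trig <- seg_trials$img_on
    in_seg <- fix_events$trial >= seg[1] & fix_events$trial <= seg[2]
    fix_trig <- fix_events$onset[in_seg]
    if (length(img_trig) < 2 || length(fix_trig) < 2) next
    img_res <- test_peak_significance(sp, img_trig,
                                      baseline_intervals("img_on", seg_trials),
                                      "img_on", rcfg$alpha, rcfg$window,
                                      rcfg$search_window, rcfg$peak_bin,
                                      rcfg$resolution)
    fix_res <- test_peak_significance(sp, fix_trig,
                                      baseline_intervals("fix_on", seg_trials),
                                      "fix_on", rcfg$alpha, rcfg$window,
                                      rcfg$search_window, rcfg$peak_bin,
                                      rcfg$resolution)
    cls <- classify_unit(img_res, fix_res)

    # sparseness, 100-ms peak-centered counting windows
    r_img <- count_response_spikes(sp, img_trig, img_res$peak_time_ms,
                                   cfg$sparseness$window_ms)
    r_fix <- count_response_spikes(sp, fix_trig, fix_res$peak_time_ms,
                                   cfg$sparseness$window_ms)
    s_img <- lifetime_sparseness(r_img)
    s_fix <- lifetime_sparseness(r_fix)

    # contrast-matched fix-on reanalysis (latency + sparseness)
    m_onsets <- fix_events$onset[intersect(matched_idx, which(in_seg))]
    s_fix_m <- NA_real_; fix_lat_m <- NA_real_
    if (length(m_onsets) >= cfg$sparseness$min_events_matched) {
      fix_res_m <- test_peak_significance(sp, m_onsets,
                                          baseline_intervals("fix_on", seg_trials),
                                          "fix_on", rcfg$alpha, rcfg$window,
                                          rcfg$search_window, rcfg$peak_bin,
                                          rcfg$resolution)
      fix_lat_m <- fix_res_m$peak_time_ms
      s_fix_m <- as.numeric(lifetime_sparseness(
        count_response_spikes(sp, m_onsets, fix_res_m$peak_time_ms,
                              cfg$sparseness$window_ms)))
    }

    unit_rows[[length(unit_rows) + 1L]] <- data.frame(
      unit_id = session$units$unit_id[u], layer = unit_layer[u],
      label = cls$label, latency_class = cls$latency_class,
      img_latency_ms = cls$img_latency_ms, fix_latency_ms = cls$fix_latency_ms,
      fix_latency_matched_ms = fix_lat_m,
      img_peak_rate = img_res$peak_rate, fix_peak_rate = fix_res$peak_rate,
      img_p = img_res$p_value, fix_p = fix_res$p_value,
      segment_first = seg[1], segment_last = seg[2],
      stringsAsFactors = FALSE
    )
    sparse_rows[[length(sparse_rows) + 1L]] <- data.frame(
      unit_id = session$units$unit_id[u], layer = unit_layer[u],
      S_img = as.numeric(s_img), S_fix = as.numeric(s_fix),
      S_fix_matched = s_fix_m,
      degenerate = isTRUE(attr(s_img, "degenerate")) ||
        isTRUE(attr(s_fix, "degenerate")),
      stringsAsFactors = FALSE
    )
  }
  units_df <- do.call(rbind, unit_rows)
  sparse_df <- do.call(rbind, sparse_rows)
  dropped$units_skipped <- n_units - nrow(units_df)

  v1 <- units_df$layer %in% c("supragranular", "granular", "infragranular")
  dropped$units_not_v1 <- sum(!v1)
  structure(list(
    responsiveness = make_contingency(units_df$label[v1],
                                      units_df$layer[v1]),
    latency = latency_table(units_df[v1, , drop = FALSE]),
    sparseness = suppressWarnings(
      layer_resolved_report(sparse_df[v1, , drop = FALSE])),
    features = feature_summary,
    units = units_df, sparseness_by_unit = sparse_df,
    eye = list(n_saccades = nrow(saccades), n_fix_events = nrow(fix_events)),
    boundary = bnd, dropped = dropped, config = cfg, seed = seed
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  ct <- x$responsiveness
  cat("Passive vs active vision study report\n")
  cat(sprintf("  units analyzed (V1): %d\n", ct$total))
  cat(sprintf("  doubly responsive:   %d (%.0f%%)\n",
              ct$counts["sig", "sig"], ct$percent["sig", "sig"]))
  cat(sprintf("  fixation-only:       %d (%.0f%%)\n",
              ct$counts["ns", "sig"], ct$percent["ns", "sig"]))
  cat(sprintf("  img-only:            %d (%.0f%%)\n",
              ct$counts["sig", "ns"], ct$percent["sig", "ns"]))
  cat(sprintf("  non-responsive:      %d (%.0f%%)\n",
              ct$counts["ns", "ns"], ct$percent["ns", "ns"]))
  for (ly in names(x$sparseness)) {
    s <- x$sparseness[[ly]]
    cat(sprintf("  sparseness %-13s med img %.3f / fix %.3f (p = %.4g, n = %d)\n",
                paste0(ly, ":"), s$median_img, s$median_fix,
                s$test$p_value, s$n))
  }
  cat(sprintf("  4c/5 boundary: %.2f mm\n", x$boundary$boundary_depth_mm))
  invisible(x)
}

#' Write a study report to JSON
#'
#' @param report a [run_study()] result.
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
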