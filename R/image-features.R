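#' Receptive-field geometry
#'
#' @param offset RF center `c(x, y)` relative to gaze (deg, x right / y up).
#' @param diameter RF diameter (deg), > 0.
#' @param pixels_per_degree raster scale of the stimulus images.
#' @export
rf_geometry <- function(offset = c(0, 0), diameter = 0.6,
                        pixels_per_degree = 12) {
  stop_if_not_positive(diameter, "diameter")
  stop_if_not_positive(pixels_per_degree, "pixels_per_degree")
  list(offset = offset, diameter = diameter, ppd = pixels_per_degree)
}

#' Extract and preprocess the RF-windowed image patch
#'
#' Cuts a square patch centered on the receptive field (gaze position plus
#' RF offset), zeroes everything outside the inscribed circle, subtracts
#' the circle's mean luminance, and multiplies by a 2-D Gaussian window
#' with SD equal to 0.25 times the RF diameter so that luminance decays
#' smoothly to the mean toward the patch edge. Patches that do not fit in
#' the image return `NULL` with a warning (the event is excluded).
#'
#' @param image numeric luminance matrix in `[0, 1]` (row 1 = top) or a
#'   `stimulus_image`.
#' @param gaze gaze position `c(x, y)` (deg, origin at image center).
#' @param rf an [rf_geometry()].
#' @param patch_factor patch side length as a multiple of the RF diameter.
#' @return square numeric matrix (odd side), or `NULL` if out of bounds.
#' @export
extract_patch <- function(image, gaze, rf, patch_factor = 2) {
  if (inherits(image, "stimulus_image")) image <- image$image
  ppd <- rf$ppd
  nr <- nrow(image); nc <- ncol(image)
  side <- round(rf$diameter * patch_factor * ppd)
  if (side %% 2 == 0) side <- side + 1L
  half <- (side - 1L) %/% 2L
  cx <- gaze[1] + rf$offset[1]
  cy <- gaze[2] + rf$offset[2]
  cc <- round((nc + 1) / 2 + cx * ppd)
  rr <- round((nr + 1) / 2 - cy * ppd)
  if (rr - half < 1 || rr + half > nr || cc - half < 1 || cc + half > nc) {
    warning("patch out of image bounds; event excluded")
    return(NULL)
  }
  patch <- image[(rr - half):(rr + half), (cc - half):(cc + half)]
  ax <- -half:half
  d2 <- outer(ax^2, ax^2, `+`)
  circle <- d2 <= half^2
  patch[!circle] <- mean(patch[circle])
  patch <- patch - mean(patch[circle])
  gauss_sd <- 0.25 * rf$diameter * ppd
  win <- exp(-d2 / (2 * gauss_sd^2))
  patch * win
}

#' Two-dimensional power spectrum with physical frequency axes
#'
#' Squared modulus of the 2-D discrete Fourier transform of a square patch,
#' with frequency axes in cycles/degree.
#'
#' @param patch square numeric matrix.
#' @param ppd pixels per degree of the patch raster.
#' @return list: `power` (matrix), `fx` (cycles/deg along columns), `fy`
#'   (cycles/deg along rows), `df` (native frequency resolution).
#' @export
power_spectrum <- function(patch, ppd) {
  if (nrow(patch) != ncol(patch)) {
    stop("patch must be square", call. = FALSE)
  }
  n <- nrow(patch)
  p <- Mod(stats::fft(patch))^2
  f <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1))[seq_len(n)] * ppd / n
  list(power = p, fx = f, fy = f, df = ppd / n)
}

#' CSF-weighted spectral contrast of a patch
#'
#' Collapses the 2-D power spectrum to a radial marginal by integer-ring
#' binning at the DFT's native frequency resolution, weights it with a
#' Gaussian spatial-frequency sensitivity profile (mean 3.0 cycles/deg,
#' FWHM 1.5 cycles/deg, after the contrast sensitivity of macaque V1
#' neurons) and sums over frequency. The DC bin is excluded, which together
#' with mean subtraction makes the measure invariant to additive luminance.
#'
#' @param ps a [power_spectrum()].
#' @param csf_mean CSF peak frequency (cycles/deg).
#' @param csf_fwhm CSF full width at half maximum (cycles/deg).
#' @return non-negative contrast (arbitrary units).
#' @export
compute_contrast <- function(ps, csf_mean = 3.0, csf_fwhm = 1.5) {
  fr <- sqrt(outer(ps$fy^2, ps$fx^2, `+`))
  ring <- round(fr / ps$df)
  f_ring <- ring * ps$df
  sd <- csf_fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-(f_ring - csf_mean)^2 / (2 * sd^2))
  w[ring == 0] <- 0
  sum(ps$power * w)
}

#' Orientedness of a patch's power spectrum
#'
#' Magnitude of the orientation resultant of the spectral power with angle
#' doubling, the circular-statistics convention for axial data:
#' \deqn{\left| \sum P(f_x, f_y) e^{i 2\theta} \right| / \sum P(f_x, f_y),}
#' \eqn{\theta = \mathrm{atan2}(f_y, f_x)}, DC excluded. (Without angle
#' doubling the resultant vanishes identically for any real image, because
#' the power spectrum of a real signal satisfies
#' \eqn{P(\theta) = P(\theta + \pi)}.) Ranges from 0 (isotropic) to 1
#' (single orientation); an all-zero spectrum returns 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param ps a [power_spectrum()].
#' @return orientedness in `[0, 1]`.
#' @export
compute_orientedness <- function(ps) {
  theta <- atan2(outer(ps$fy, rep(1, length(ps$fx))),
                 outer(rep(1, length(ps$fy)), ps$fx))
  p <- ps$power
  dc <- which(ps$fx == 0)
  p[dc, dc] <- 0
  tot <- sum(p)
  if (tot == 0) return(structure(0, degenerate = TRUE))
  res <- Mod(sum(p * exp(2i * theta))) / tot
  structure(res, degenerate = FALSE)
}

#' Contrast and orientedness of one gaze-contingent patch
#'
#' Convenience wrapper: extract the RF-windowed patch and score it.
#'
#' @inheritParams extract_patch
#' @return list `contrast`, `orientedness`, or `NULL` if out of bounds.
#' @export
patch_features <- function(image, gaze, rf, patch_factor = 2) {
  patch <- extract_patch(image, gaze, rf, patch_factor)
  if (is.null(patch)) return(NULL)
  ps <- power_spectrum(patch, rf$ppd)
  list(contrast = compute_contrast(ps),
       orientedness = as.numeric(compute_orientedness(ps)))
}

#' Subsample fixation events to match the img-on contrast distribution
#'
#' Decile histogram matching: img-on contrasts are binned into deciles and
#' fix-on events are randomly subsampled so that each decile holds an equal
#' share of the retained events, i.e. the retained fix-on contrast
#' distribution matches the img-on distribution at decile resolution.
#' Fix-on events outside the img-on support are never retained. If the
#' supports do not overlap the result is empty, with a warning.
#'
#' @param fix_contrast contrasts at fix-on events.
#' @param img_contrast contrasts at img-on events.
#' @param n_bins quantile bins (default deciles).
#' @param seed optional seed for the subsample.
#' @return integer indices into `fix_contrast` of the retained events.
#' @export
match_contrast <- function(fix_contrast, img_contrast, n_bins = 10,
                           seed = NULL) {
  if (length(fix_contrast) == 0 || length(img_contrast) == 0) {
    stop("both contrast vectors must be non-empty", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  breaks <- unique(stats::quantile(img_contrast, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2 ||
      max(fix_contrast) < breaks[1] || min(fix_contrast) > breaks[length(breaks)]) {
    warning("no overlap between fix-on and img-on contrast supports")
    return(integer(0))
  }
  nb <- length(breaks) - 1L
  bin <- findInterval(fix_contrast, breaks, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= nb
  counts <- tabulate(bin[inside], nbins = nb)
  if (min(counts) == 0) {
    warning("an img-on contrast decile holds no fix-on events; empty match")
    return(integer(0))
  }
  per_bin <- min(counts)
  idx <- integer(0)
  for (b in seq_len(nb)) {
    members <- which(inside & bin == b)
    idx <- c(idx, sample(members, per_bin))
  }
  sort(idx)
}

#' Two-sided Mann-Whitney U comparison of feature distributions
#'
#' @param a,b numeric samples (>= 2 values each).
#' @return list: `statistic` (U), `p_value`, `median_a`, `median_b`,
#'   `flag` (`"degenerate"` when both samples are a single shared constant).
#' @export
compare_feature_distributions <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = NA_real_, p_value = 1,
                median_a = stats::median(a), median_b = stats::median(b),
                flag = "degenerate"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       median_a = stats::median(a), median_b = stats::median(b),
       flag = NULL)
}
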