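# Pink (1/f-amplitude) noise of length n, unit SD.
pink_noise <- function(n) {
  f <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1))[seq_len(n)]
  amp <- 1 / pmax(abs(f), 1)
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * amp, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Depth profile of the target CSD for a dipole at `boundary`: a sink
# (negative CSD) centered half a channel spacing above and a source
# (positive) half a spacing below.
dipole_csd_profile <- function(depths, boundary, spacing, width = 0.12) {
  -exp(-((depths - (boundary - spacing / 2)) / width)^2) +
    exp(-((depths - (boundary + spacing / 2)) / width)^2)
}

# Solve the discrete Poisson problem so that the second-spatial-difference
# estimator -(V[k-1]-2V[k]+V[k+1])/h^2 applied to the returned potential
# reproduces `csd` exactly at interior channels (V pinned to 0 at the ends).
potential_from_csd <- function(csd, spacing) {
  n <- length(csd)
  m <- n - 2L
  A <- diag(-2, m)
  if (m > 1) {
    A[cbind(1:(m - 1), 2:m)] <- 1
    A[cbind(2:m, 1:(m - 1))] <- 1
  }
  v_int <- solve(A, -spacing^2 * csd[2:(n - 1)])
  c(0, v_int, 0)
}

#' Generate a laminar LFP array with an image-onset-evoked dipole
#'
#' Builds a 24-channel (by default) laminar local field potential in which
#' every image onset evokes a transient dipolar potential whose second
#' spatial difference (the CSD estimator) shows a current sink immediately
#' above and a source immediately below `boundary_depth_mm` — the synthetic
#' analogue of the layer 4c/5 sink-source signature. Optionally a second,
#' deeper dipole emulates V2 activity beyond the white matter. Channels
#' carry independent 1/f noise.
#'
#' @param boundary_depth_mm depth of the simulated 4c/5 boundary (mm from
#'   the most superficial channel); must lie strictly inside the span of
#'   interior channels.
#' @param img_on_times image-onset times (s).
#' @param duration record duration (s).
#' @param n_channels,spacing_mm electrode geometry (defaults 24 x 0.1 mm).
#' @param sampling_rate LFP sampling rate (Hz).
#' @param noise_sd SD of the additive 1/f noise, in the same units as
#'   `amplitude`.
#' @param amplitude dipole potential scale.
#' @param tau time-to-peak of the evoked alpha-function transient (s).
#' @param v2_boundary_depth_mm optional second (deeper) dipole depth.
#' @param seed integer seed.
#' @return list: `lfp` (channels x samples matrix), `fs`, `depths_mm`,
#'   `t`, `boundary_depth_mm`.
#' @export
generate_laminar_lfp <- function(boundary_depth_mm, img_on_times, duration,
                                 n_channels = 24, spacing_mm = 0.1,
                                 sampling_rate = 1000, noise_sd = 0,
                                 amplitude = 50, tau = 0.04,
                                 v2_boundary_depth_mm = NULL, seed = NULL) {
  depths <- (seq_len(n_channels) - 1L) * spacing_mm
  if (boundary_depth_mm <= depths[2] || boundary_depth_mm >= depths[n_channels - 1]) {
    stop("boundary depth outside the interior electrode span", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- sampling_rate
  n_t <- ceiling(duration * fs)
  t <- (seq_len(n_t) - 1L) / fs

  profile <- potential_from_csd(
    dipole_csd_profile(depths, boundary_depth_mm, spacing_mm), spacing_mm)
  if (!is.null(v2_boundary_depth_mm)) {
    profile2 <- potential_from_csd(
      dipole_csd_profile(depths, v2_boundary_depth_mm, spacing_mm), spacing_mm)
  }

  timecourse <- numeric(n_t)
  for (ev in img_on_times) {
    rel <- t - ev
    w <- rel > 0 & rel < 8 * tau
    timecourse[w] <- timecourse[w] + (rel[w] / tau) * exp(1 - rel[w] / tau)
  }
  lfp <- amplitude * outer(profile, timecourse)
  if (!is.null(v2_boundary_depth_mm)) {
    lfp <- lfp + 0.7 * amplitude * outer(profile2, timecourse)
  }
  if (noise_sd > 0) {
    # 1/f in time, Gaussian-correlated across contacts (0.1-mm-spaced
    # channels see nearly the same volume-conducted noise)
    raw <- t(vapply(seq_len(n_channels), function(ch) pink_noise(n_t),
                    numeric(n_t)))
    ker <- stats::dnorm(-4:4, 0, 1.5)
    sm <- apply(raw, 2, function(col) {
      padded <- c(rep(col[1], 4), col, rep(col[n_channels], 4))
      stats::filter(padded, ker, sides = 2)[5:(4 + n_channels)]
    })
    sm <- sm / stats::sd(sm)
    lfp <- lfp + noise_sd * sm
  }
  list(lfp = lfp, fs = fs, depths_mm = depths, t = t,
       boundary_depth_mm = boundary_depth_mm)
}
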