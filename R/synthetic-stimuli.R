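# Radial spatial-frequency grid (cycles/image-side units) for an n x m array.
fft_radial_freq <- function(nr, nc) {
  fy <- c(0:floor(nr / 2), -((ceiling(nr / 2) - 1):1))[seq_len(nr)]
  fx <- c(0:floor(nc / 2), -((ceiling(nc / 2) - 1):1))[seq_len(nc)]
  sqrt(outer(fy^2, fx^2, `+`))
}

# Isotropic 1/f-amplitude noise field, zero mean, unit SD.
one_over_f_noise <- function(nr, nc) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  fr <- fft_radial_freq(nr, nc)
  amp <- 1 / pmax(fr, 1)
  field <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (nr * nc)
  (field - mean(field)) / stats::sd(field)
}

# Gabor patch: oriented grating under a Gaussian envelope, values in [-1, 1].
gabor_patch <- function(side_px, ppd, sf_cpd = 1.5, theta = 0, phase = 0,
                        envelope_sd_px = side_px / 5) {
  ax <- (seq_len(side_px) - (side_px + 1) / 2)
  xx <- matrix(ax, side_px, side_px, byrow = TRUE)
  yy <- matrix(ax, side_px, side_px)
  u <- xx * cos(theta) + yy * sin(theta)
  env <- exp(-(xx^2 + yy^2) / (2 * envelope_sd_px^2))
  env * cos(2 * pi * sf_cpd * u / ppd + phase)
}

#' Generate a synthetic stimulus image with embedded objects
#'
#' Composes a naturalistic background (isotropic 1/f-amplitude noise, the
#' canonical spectral stand-in for natural scenes) with `n_objects`
#' Gabor-like objects placed at pseudo-random positions whose pairwise
#' distances all exceed `min_separation`, so the objects never overlap.
#' Placement is by bounded rejection sampling; an infeasible packing raises
#' an error.
#'
#' @param background_size `c(width, height)` in degrees.
#' @param n_objects number of objects to embed.
#' @param object_diameter object diameter (deg).
#' @param min_separation minimum pairwise center distance (deg).
#' @param pixels_per_degree raster scale.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget for placement.
#' @return object of class `stimulus_image`: list with `image` (numeric
#'   matrix in `[0, 1]`, rows = top to bottom), `objects` (data.frame of
#'   center positions in degrees relative to the image center, x right /
#'   y up), `ppd`, `width_deg`, `height_deg`.
#' @export
generate_stimulus_image <- function(background_size = c(34.8, 26.1),
                                    n_objects = 5,
                                    object_diameter = 2,
                                    min_separation = 4,
                                    pixels_per_degree = 12,
                                    seed = NULL,
                                    max_attempts = 5000) {
  stop_if_not_positive(background_size, "background_size")
  stop_if_not_positive(pixels_per_degree, "pixels_per_degree")
  if (n_objects < 0) stop("n_objects must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ppd <- pixels_per_degree
  nc <- round(background_size[1] * ppd)
  nr <- round(background_size[2] * ppd)
  img <- 0.5 + 0.12 * one_over_f_noise(nr, nc)

  objects <- data.frame(x = numeric(0), y = numeric(0))
  if (n_objects > 0) {
    half_w <- background_size[1] / 2 - object_diameter
    half_h <- background_size[2] / 2 - object_diameter
    if (half_w <= 0 || half_h <= 0) {
      stop("objects do not fit inside the background", call. = FALSE)
    }
    pos <- matrix(NA_real_, n_objects, 2)
    placed <- 0L
    attempts <- 0L
    while (placed < n_objects) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("object placement infeasible at the requested separation",
             call. = FALSE)
      }
      cand <- c(stats::runif(1, -half_w, half_w), stats::runif(1, -half_h, half_h))
      if (placed > 0) {
        d <- sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                             matrix(cand, placed, 2, byrow = TRUE))^2))
        if (any(d <= min_separation)) next
      }
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
    side <- round(object_diameter * ppd)
    for (k in seq_len(n_objects)) {
      g <- gabor_patch(side, ppd, theta = stats::runif(1, 0, pi),
                       phase = stats::runif(1, 0, 2 * pi))
      # degree coords -> pixel indices (row 1 = top)
      cc <- round((nc + 1) / 2 + pos[k, 1] * ppd)
      rr <- round((nr + 1) / 2 - pos[k, 2] * ppd)
      r0 <- rr - floor(side / 2); c0 <- cc - floor(side / 2)
      ri <- r0:(r0 + side - 1L); ci <- c0:(c0 + side - 1L)
      img[ri, ci] <- img[ri, ci] + 0.35 * g
    }
    objects <- data.frame(x = pos[, 1], y = pos[, 2])
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, objects = objects, ppd = ppd,
                 width_deg = background_size[1],
                 height_deg = background_size[2]),
            class = "stimulus_image")
}
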