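# Seeded generator of curvilinear vessel phantoms: smooth random spline
# strokes dilated to a sampled width give an exact binary mask; the image is
# the mask painted at a vessel intensity over a uniform background, optionally
# Gaussian-blurred and corrupted with Gaussian noise.  The mask is exact by
# construction, so phantoms provide paired oracles for every metric.

#' Specification of a synthetic vessel phantom
#'
#' Presets: `"cta"` emulates an angiography slice (bright vessels, moderate
#' noise); `"fundus"` a retinal patch (96 x 96, dark background, low
#' contrast).
#'
#' @param size c(H, W) of the generated pair.
#' @param n_vessels number of vessel strokes.
#' @param width_range c(min, max) stroke width in pixels (must not exceed a
#'   quarter of the smaller image side).
#' @param tortuosity waypoint jitter amplitude (>= 0); 0 gives straight
#'   chords.
#' @param vessel_intensity,background_intensity intensities in \[0, 1\].
#' @param noise_sigma Gaussian pixel noise standard deviation.
#' @param blur_sigma Gaussian blur standard deviation (0 = none).
#' @param seed integer seed; generation is fully deterministic given it.
#' @param preset `"cta"` (default) or `"fundus"`; explicit arguments
#'   override preset values.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = NULL, n_vessels = 3L, width_range = c(2, 4),
                         tortuosity = 1, vessel_intensity = NULL,
                         background_intensity = NULL, noise_sigma = 0.18,
                         blur_sigma = 0.8, seed = 1L,
                         preset = c("cta", "fundus")) {
  preset <- match.arg(preset)
  if (is.null(size)) size <- if (preset == "fundus") c(96L, 96L) else c(64L, 64L)
  if (is.null(vessel_intensity))
    vessel_intensity <- if (preset == "fundus") 0.45 else 0.65
  if (is.null(background_intensity))
    background_intensity <- if (preset == "fundus") 0.15 else 0.35
  stopifnot(length(size) == 2L, all(size >= 8L), n_vessels >= 1,
            tortuosity >= 0, noise_sigma >= 0, blur_sigma >= 0)
  if (max(width_range) > min(size) / 4)
    stop("width_range max (", max(width_range),
         ") exceeds min(H, W)/4 = ", min(size) / 4)
  structure(list(size = as.integer(size), n_vessels = as.integer(n_vessels),
                 width_range = width_range, tortuosity = tortuosity,
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed), preset = preset),
            class = "phantom_spec")
}

# rasterise one smooth stroke into the mask (in place value-wise)
stamp_stroke <- function(mask, H, W, tortuosity, width) {
  # endpoints on opposite borders, orientation chosen at random
  horiz <- stats::runif(1) < 0.5
  if (horiz) {
    p0 <- c(stats::runif(1, 1, H), 1)
    p1 <- c(stats::runif(1, 1, H), W)
  } else {
    p0 <- c(1, stats::runif(1, 1, W))
    p1 <- c(H, stats::runif(1, 1, W))
  }
  nway <- 5L
  t0 <- seq(0, 1, length.out = nway)
  jit <- tortuosity * min(H, W) / 12
  wy <- p0[1] + t0 * (p1[1] - p0[1]) + c(0, stats::rnorm(nway - 2L, 0, jit), 0)
  wx <- p0[2] + t0 * (p1[2] - p0[2]) + c(0, stats::rnorm(nway - 2L, 0, jit), 0)
  dense <- 4L * max(H, W)
  sy <- stats::spline(t0, wy, n = dense)$y
  sx <- stats::spline(t0, wx, n = dense)$y
  r <- width / 2
  ri <- ceiling(r)
  off <- expand.grid(dh = -ri:ri, dw = -ri:ri)
  off <- off[off$dh^2 + off$dw^2 <= r^2, , drop = FALSE]
  hh <- outer(round(sy), off$dh, "+")
  ww <- outer(round(sx), off$dw, "+")
  ok <- hh >= 1 & hh <= H & ww >= 1 & ww <= W
  mask[cbind(hh[ok], ww[ok])] <- 1
  mask
}

#' Generate one vessel phantom with its exact mask
#'
#' Each vessel is a smooth random spline through jittered waypoints, dilated
#' to a width sampled from `width_range`; the mask is the exact union of the
#' strokes.  Strokes are added while the mask stays within a 25% foreground
#' budget (at least one vessel is always drawn), so the foreground fraction is
#' bounded by construction.  The image paints the vessel intensity over the
#' background, then applies Gaussian blur and Gaussian noise (clamped to
#' \[0, 1\]).
#'
#' @param spec a [phantom_spec()].
#' @return a list with `image` (H, W matrix in \[0, 1\]), `mask` (binary
#'   H, W matrix), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  with_seed(spec$seed, {
    mask <- matrix(0, H, W)
    for (v in seq_len(spec$n_vessels)) {
      wdt <- stats::runif(1, spec$width_range[1], spec$width_range[2])
      cand <- stamp_stroke(mask, H, W, spec$tortuosity, wdt)
      if (mean(cand) <= 0.25) {
        mask <- cand
      } else if (v == 1L) {
        # keep at least one vessel: retry the first stroke at minimum width
        cand <- stamp_stroke(mask, H, W, spec$tortuosity, spec$width_range[1])
        if (mean(cand) > 0.25)
          stop("a single minimum-width stroke exceeds the 25% foreground ",
               "budget; enlarge the image or narrow width_range")
        mask <- cand
      } else break   # foreground budget used up; stop adding vessels
    }
    frac <- mean(mask)
    stopifnot(frac > 0, frac <= 0.25)
    img <- matrix(spec$background_intensity, H, W)
    img[mask == 1] <- spec$vessel_intensity
    if (spec$blur_sigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = spec$blur_sigma))
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask, spec = spec)
  })
}

#' Generate a corpus of independent phantoms
#'
#' Item seeds are derived deterministically from `seed`, so the corpus is
#' identical across machines.
#'
#' @param n number of phantoms (`n <= 0` gives an empty list).
#' @param spec a [phantom_spec()] template (its own seed is ignored).
#' @param seed corpus seed.
#' @return a list of `n` phantom lists (`image`, `mask`, `spec`).
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1L) {
  if (n <= 0) return(list())
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- (as.integer(seed) %% 100000L) * 20011L + i * 104729L
    generate_phantom(s)
  })
}

#' Classical threshold-plus-filter baseline segmentation
#'
#' Otsu's threshold on the image intensity followed by
#' [remove_small_components()].  On noiseless phantoms this recovers the mask
#' nearly exactly; on noisy phantoms it sets the floor a trained network must
#' beat.
#'
#' @param image (H, W) intensity matrix in \[0, 1\].
#' @param fraction small-component threshold fraction.
#' @param connectivity component connectivity (8 or 4).
#' @return a binary (H, W) mask.
#' @export
baseline_segment <- function(image, fraction = 0.0003, connectivity = 8L) {
  th <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  remove_small_components((image > th) * 1, fraction, connectivity)
}
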