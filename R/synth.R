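# Synthetic NIR spectra generator.  Spectra are Gaussian absorption-band
# mixtures whose band amplitudes and centres drift with maturity level,
# corrupted by the scatter model (per-spot multiplicative gain, additive
# offset, linear baseline) that SNV/MSC/derivative pretreatments are
# designed to invert, plus i.i.d. point noise.  No claim of chemical
# realism is made; the generator exists to exercise the pipeline.

#' Synthetic absorption band
#'
#' One Gaussian band of the generative model.  The band's centre shifts
#' and its amplitude scales with maturity level (five-element vectors in
#' the canonical [maturity_levels()] order).
#'
#' @param center_nm band centre (nm).
#' @param width_nm Gaussian standard deviation (nm), > 0.
#' @param base_amplitude peak amplitude (reflectance units).
#' @param maturity_shift_nm length-5 per-level centre drift (nm).
#' @param maturity_gain length-5 per-level amplitude multiplier.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(center_nm, width_nm, base_amplitude,
                      maturity_shift_nm = rep(0, 5),
                      maturity_gain = rep(1, 5)) {
  check(width_nm > 0, "width_nm must be positive")
  check(length(maturity_shift_nm) == 5 && length(maturity_gain) == 5,
        "maturity_shift_nm and maturity_gain must have length 5")
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 base_amplitude = base_amplitude,
                 maturity_shift_nm = maturity_shift_nm,
                 maturity_gain = maturity_gain),
            class = "band_spec")
}

# Default band library: broad features loosely placed at the classic NIR
# water/C-H overtone regions on a slowly varying continuum, with
# monotone maturity trends of mixed sign and size.
default_bands <- function(position = "upper") {
  pos_scale <- switch(position, upper = 1, middle = 0.9, lower = 0.8)
  list(
    band_spec(1700, 2000, 0.45 * pos_scale),                      # continuum
    band_spec(970, 45, 0.18, maturity_shift_nm = c(-8, -4, 0, 4, 8),
              maturity_gain = c(1.3, 1.15, 1.0, 0.85, 0.7)),
    band_spec(1200, 60, 0.14, maturity_gain = c(0.7, 0.85, 1.0, 1.15, 1.3)),
    band_spec(1450, 55, 0.30, maturity_shift_nm = c(10, 5, 0, -5, -10),
              maturity_gain = c(1.2, 1.1, 1.0, 0.9, 0.8)),
    band_spec(1720, 40, 0.10, maturity_gain = c(0.6, 0.8, 1.0, 1.2, 1.4)),
    band_spec(1940, 70, 0.35, maturity_gain = c(1.25, 1.12, 1.0, 0.88, 0.75)),
    band_spec(2310, 50, 0.12, maturity_shift_nm = c(-12, -6, 0, 6, 12),
              maturity_gain = c(0.8, 0.9, 1.0, 1.1, 1.2)))
}

#' Synthetic dataset configuration
#'
#' @param grid wavelength grid (default the 512-point acquisition grid).
#' @param bands named list (per position) of lists of [band_spec()]s, or
#'   a single list of bands used for every position.
#' @param positions which positions to simulate.
#' @param n_per_class leaves per (position, maturity) cell.
#' @param n_spots replicate spot spectra per leaf (default 6).
#' @param scatter_mult_range range of the per-spot multiplicative gain
#'   (uniform; default 0.8-1.2).
#' @param scatter_add_sd sd of the per-spot additive offset.
#' @param baseline_slope_sd sd of the per-spot linear-baseline slope; the
#'   baseline term is `c * s` with `s` the wavelength rescaled to [0, 1]
#'   across the grid.
#' @param noise_sd sd of the i.i.d. per-point noise.
#' @param seed integer seed; identical config + seed gives an identical
#'   dataset.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(grid = default_grid(), bands = NULL,
                         positions = leaf_positions(), n_per_class = 56,
                         n_spots = 6, scatter_mult_range = c(0.8, 1.2),
                         scatter_add_sd = 0.05, baseline_slope_sd = 0.02,
                         noise_sd = 0.005, seed = 1) {
  check(n_per_class >= 1 && n_spots >= 1, "n_per_class and n_spots must be >= 1")
  check(length(scatter_mult_range) == 2 &&
          scatter_mult_range[1] <= scatter_mult_range[2] &&
          scatter_mult_range[1] > 0, "invalid scatter_mult_range")
  check(scatter_add_sd >= 0 && baseline_slope_sd >= 0 && noise_sd >= 0,
        "noise/scatter sds must be non-negative")
  check(all(positions %in% leaf_positions()), "unknown position in 'positions'")
  if (is.null(bands)) {
    bands <- stats::setNames(lapply(positions, default_bands), positions)
  } else if (length(bands) == 0 ||
             inherits(bands[[1]], "band_spec")) {
    # one band list (possibly empty) shared by every position
    bands <- stats::setNames(rep(list(bands), length(positions)), positions)
  }
  structure(list(grid = grid, bands = bands, positions = positions,
                 n_per_class = as.integer(n_per_class),
                 n_spots = as.integer(n_spots),
                 scatter_mult_range = scatter_mult_range,
                 scatter_add_sd = scatter_add_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Noise-free class spectrum of the generative model
#'
#' The deterministic pure spectrum for one (position, maturity) cell: the
#' sum over bands of `gain * amplitude * exp(-(lambda - center - shift)^2
#' / (2 width^2))` evaluated on the grid.
#'
#' @param config a [synth_config()].
#' @param position one of the config's positions.
#' @param maturity one of [maturity_levels()].
#' @return numeric vector of length `grid$n_points`.
#' @export
pure_spectrum <- function(config, position, maturity) {
  stopifnot(inherits(config, "synth_config"))
  check(position %in% names(config$bands), "no bands for position '%s'", position)
  mi <- match(maturity, maturity_levels())
  check(!is.na(mi), "unknown maturity '%s'", maturity)
  wl <- wavelengths(config$grid)
  s <- numeric(length(wl))
  for (b in config$bands[[position]]) {
    ctr <- b$center_nm + b$maturity_shift_nm[mi]
    s <- s + b$maturity_gain[mi] * b$base_amplitude *
      exp(-(wl - ctr)^2 / (2 * b$width_nm^2))
  }
  s
}

#' Simulate a labelled synthetic dataset
#'
#' Each leaf gets `n_spots` spot spectra, each generated as
#' `b * pure + a + c * s + eps` with per-spot gain `b ~ U(mult_range)`,
#' offset `a ~ N(0, add_sd)`, baseline slope `c ~ N(0, slope_sd)` (times
#' the [0,1]-rescaled wavelength `s`), and per-point noise
#' `eps ~ N(0, noise_sd)`.  Exactly `n_per_class` leaves are produced for
#' every (position, maturity) cell.
#'
#' @param config a [synth_config()].
#' @return a [spectra_set()].
#' @examples
#' cfg <- synth_config(grid = make_grid(900, 2500, 25), positions = "upper",
#'                     n_per_class = 3, seed = 7)
#' simulate_dataset(cfg)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  wl <- wavelengths(config$grid)
  s01 <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
  p <- length(wl)
  records <- list()
  with_seed(config$seed, {
    for (pos in config$positions) {
      for (mat in maturity_levels()) {
        pure <- pure_spectrum(config, pos, mat)
        for (i in seq_len(config$n_per_class)) {
          spots <- matrix(0, config$n_spots, p)
          for (j in seq_len(config$n_spots)) {
            b <- stats::runif(1, config$scatter_mult_range[1],
                              config$scatter_mult_range[2])
            a <- stats::rnorm(1, 0, config$scatter_add_sd)
            cc <- stats::rnorm(1, 0, config$baseline_slope_sd)
            eps <- stats::rnorm(p, 0, config$noise_sd)
            spots[j, ] <- b * pure + a + cc * s01 + eps
          }
          records[[length(records) + 1]] <-
            spectrum_record(sprintf("%s_%s_%03d", pos, mat, i),
                            pos, mat, spots)
        }
      }
    }
  })
  spectra_set(config$grid, records)
}

#' Canonical well-separated benchmark dataset
#'
#' A five-class synthetic dataset with large between-class band contrasts
#' and high signal-to-noise, sized like a roughly four-fold scaled-down
#' version of one position's field dataset (5 x 56 = 280 leaves, six
#' spots each, on the 512-point grid).  Scatter (multiplicative gain and
#' additive offset) is on, the linear baseline is off, so SNV/MSC remove
#' the corruption exactly up to noise.  Used as the acceptance fixture on
#' which every classifier should perform near-perfectly.
#'
#' @param seed integer seed.
#' @param n_per_class leaves per class (default 56).
#' @return a [spectra_set()] with 5 classes of upper-position leaves.
#' @export
easy_benchmark <- function(seed = 1, n_per_class = 56) {
  bands <- list(
    band_spec(1700, 2000, 0.45),
    band_spec(1000, 50, 0.25, maturity_shift_nm = c(-30, -15, 0, 15, 30),
              maturity_gain = c(1.6, 1.3, 1.0, 0.7, 0.4)),
    band_spec(1450, 60, 0.35, maturity_gain = c(0.4, 0.7, 1.0, 1.3, 1.6)),
    band_spec(1940, 70, 0.30, maturity_shift_nm = c(24, 12, 0, -12, -24),
              maturity_gain = c(1.5, 1.25, 1.0, 0.8, 0.6)),
    band_spec(2200, 55, 0.20, maturity_gain = c(0.3, 0.65, 1.0, 1.35, 1.7)))
  cfg <- synth_config(bands = bands, positions = "upper",
                      n_per_class = n_per_class, n_spots = 6,
                      scatter_mult_range = c(0.8, 1.2),
                      scatter_add_sd = 0.05, baseline_slope_sd = 0,
                      noise_sd = 0.002, seed = seed)
  simulate_dataset(cfg)
}
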