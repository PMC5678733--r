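# Synthetic orientation maps with known structure, used as fixtures for the
# analysis suite (known pinwheel content, known dominant wavelength).

#' Synthetic single-pinwheel map
#'
#' `z(x, y) = ((x - cx) + i (y - cy)) / |.|` around the grid centre: one
#' pinwheel of charge `charge` (+1 default; -1 conjugates the field).
#'
#' @param n Grid side.
#' @param charge +1 or -1.
#' @return An `orientation_map` (selectivity 1 away from the centre).
#' @export
synthetic_pinwheel_map <- function(n = 64, charge = 1) {
  c0 <- (n + 1) / 2
  dx <- outer(seq_len(n) - c0, rep(1, n))
  dy <- outer(rep(1, n), seq_len(n) - c0)
  z <- matrix(complex(real = dx, imaginary = dy), n, n)
  r <- Mod(z)
  z <- ifelse(r > 0, z / r, 0)
  if (charge < 0) z <- Conj(z)
  synthetic_map_from_z(z)
}

#' Synthetic periodic map with a known pinwheel lattice
#'
#' `z = cos(2 pi fx x) + i cos(2 pi fy y)`: the zero lines of the real and
#' imaginary parts form a rectangular grid whose `2 fx * 2 fy` intersections
#' are pinwheels of alternating charge (net charge 0).
#'
#' @param n Grid side.
#' @param fx,fy Cycles across the map for the two quadratures.
#' @return An `orientation_map`; attribute `n_pinwheels` holds the planted
#'   count `4 * fx * fy`.
#' @export
synthetic_crossing_map <- function(n = 64, fx = 1, fy = 2) {
  u <- (seq_len(n) - 0.5) / n
  re <- outer(cos(2 * pi * fx * u), rep(1, n))
  im <- outer(rep(1, n), cos(2 * pi * fy * u))
  m <- synthetic_map_from_z(matrix(complex(real = re, imaginary = im), n, n))
  attr(m, "n_pinwheels") <- 4L * fx * fy
  m
}

#' Synthetic band-pass orientation map with a planted wavelength
#'
#' Complex Gaussian white noise filtered by a narrow annulus at radial
#' frequency `cycles` (cycles per map extent): the classic pinwheel-rich
#' random orientation map with a known dominant wavelength.
#'
#' @param n Grid side.
#' @param cycles Planted dominant frequency, cycles per map extent.
#' @param bandwidth Annulus half-width, cycles.
#' @param seed Seed for the noise draw.
#' @return An `orientation_map` (extent assumed 3 mm at density `n/1`).
#' @export
synthetic_bandpass_map <- function(n = 64, cycles = 6, bandwidth = 1,
                                   seed = 1) {
  stream <- rng_stream(seed, "bandpass-map")
  wn <- with_stream(stream,
    matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n))
  kk <- freq_grid(n, n)
  mask <- exp(-(kk - cycles)^2 / (2 * bandwidth^2))
  z <- fft(mask * fft(wn), inverse = TRUE) / n^2
  synthetic_map_from_z(z)
}

#' Uniform-random (salt-and-pepper) orientation map
#'
#' @param n Grid side.
#' @param seed Seed.
#' @return An `orientation_map` with independent uniform preferences.
#' @export
synthetic_random_map <- function(n = 48, seed = 1) {
  stream <- rng_stream(seed, "random-map")
  pref <- with_stream(stream, matrix(runif(n * n, 0, pi), n, n))
  structure(list(preference = pref,
                 selectivity = matrix(1, n, n),
                 responses = NULL, angles = NULL,
                 layer = "synthetic", iteration = NA_integer_,
                 extent_mm = 3, density = n / 1, mm_per_unit = 3),
            class = "orientation_map")
}

# build an orientation_map (plus cos-model responses) from a complex field
synthetic_map_from_z <- function(z, extent_mm = 3) {
  n <- nrow(z)
  pref <- (Arg(z) / 2) %% pi
  sel <- Mod(z)
  if (max(sel) > 0) sel <- sel / max(sel)
  angles <- (0:3) * pi / 4
  responses <- array(0, c(n, n, 4))
  for (k in 1:4)   # cos(2 dphi) tuning model, non-negative
    responses[, , k] <- 1 + sel * cos(2 * (pref - angles[k]))
  structure(list(preference = pref, selectivity = sel,
                 responses = responses, angles = angles,
                 layer = "synthetic", iteration = NA_integer_,
                 extent_mm = extent_mm, density = n / 1,
                 mm_per_unit = extent_mm),
            class = "orientation_map")
}
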