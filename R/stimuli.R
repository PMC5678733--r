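#' Training-stimulus parameters
#'
#' The training ensemble consists of elongated two-dimensional Gaussians with
#' centres and orientations drawn uniformly at random, rendered on the
#' retinal sheet. Elongation (3:1 by default) at roughly the afferent
#' receptive-field scale is what carries the orientation signal.
#'
#' @param sigma_major,sigma_minor Gaussian axes in sheet units
#'   (`sigma_major >= sigma_minor > 0`).
#' @param amplitude Peak luminance of the Gaussian.
#' @param margin Extra border (sheet units) around the retinal sheet from
#'   which centres may be drawn, so stimuli can straddle edges.
#' @return A list of class `stimulus_params`.
#' @export
stimulus_params <- function(sigma_major = 0.3, sigma_minor = 0.1,
                            amplitude = 1, margin = sigma_major) {
  if (!(sigma_major >= sigma_minor && sigma_minor > 0))
    stop("need sigma_major >= sigma_minor > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(sigma_major = sigma_major, sigma_minor = sigma_minor,
                 amplitude = amplitude, margin = margin),
            class = "stimulus_params")
}

#' Draw one random training stimulus
#'
#' Centre uniform over the retinal extent (plus margin), orientation uniform
#' on `[0, pi)`. Deterministic given the stream state.
#'
#' @param stream An [rng_stream()].
#' @param geometry Retinal [sheet_geometry()].
#' @param params A [stimulus_params()].
#' @return A list of class `training_stimulus` with fields `center`
#'   (sheet coords), `orientation` (radians in `[0, pi)`), `sigma_major`,
#'   `sigma_minor`, `amplitude`.
#' @export
sample_training_stimulus <- function(stream, geometry, params) {
  lo <- geometry$origin - params$margin
  hi <- geometry$origin + geometry$extent + params$margin
  draw <- with_stream(stream, runif(3))
  structure(list(
    center = lo + draw[1:2] * (hi - lo),
    orientation = (draw[3] * pi) %% pi,
    sigma_major = params$sigma_major, sigma_minor = params$sigma_minor,
    amplitude = params$amplitude), class = "training_stimulus")
}

#' Rasterize a training stimulus onto a sheet
#'
#' Value at node u is
#' `amplitude * exp(-(d_major^2/(2*sigma_major^2) + d_minor^2/(2*sigma_minor^2)))`
#' where `(d_major, d_minor)` are the coordinates of `u - center` rotated by
#' `-orientation`.
#'
#' @param stim A `training_stimulus`.
#' @param geometry Retinal [sheet_geometry()].
#' @return An `n x n` non-negative matrix of retinal activity.
#' @export
render_stimulus <- function(stim, geometry) {
  co <- sheet_coords(geometry)
  dx <- outer(co - stim$center[1], rep(1, geometry$n))   # row axis
  dy <- outer(rep(1, geometry$n), co - stim$center[2])   # column axis
  ct <- cos(stim$orientation); st <- sin(stim$orientation)
  dmaj <- ct * dx + st * dy
  dmin <- -st * dx + ct * dy
  stim$amplitude *
    exp(-(dmaj^2 / (2 * stim$sigma_major^2) + dmin^2 / (2 * stim$sigma_minor^2)))
}

#' Render a full-field sine grating probe
#'
#' Luminance `0.5 * amplitude * (1 + cos(2*pi*freq*proj + phase))` where
#' `proj` is the coordinate along the grating's modulation direction
#' (perpendicular to the bar orientation).
#'
#' @param geometry Retinal [sheet_geometry()].
#' @param orientation Bar orientation in radians.
#' @param freq Spatial frequency in cycles per sheet unit.
#' @param phase Phase in radians.
#' @param amplitude Peak-to-trough contrast.
#' @return An `n x n` non-negative matrix.
#' @export
render_grating <- function(geometry, orientation, freq, phase = 0,
                           amplitude = 1) {
  co <- sheet_coords(geometry)
  dx <- outer(co, rep(1, geometry$n))
  dy <- outer(rep(1, geometry$n), co)
  # modulation direction is perpendicular to the bars
  proj <- -sin(orientation) * dx + cos(orientation) * dy
  0.5 * amplitude * (1 + cos(2 * pi * freq * proj + phase))
}
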