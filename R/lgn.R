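#' Difference-of-Gaussians LGN receptive-field kernel
#'
#' Centre and surround Gaussians are each normalized to unit mass over the
#' discrete square support (normalizers `Z_c`, `Z_s` are the discrete sums),
#' so the kernel sums to zero and ignores uniform luminance. The OFF kernel
#' is the exact negation of the ON kernel.
#'
#' @param sigma_c,sigma_s Centre/surround widths in sheet units
#'   (`sigma_s > sigma_c > 0`).
#' @param support_radius Square half-support in sheet units; values below
#'   `3 * sigma_s` trigger a truncation warning.
#' @param polarity `"ON"` or `"OFF"`.
#' @param density Nodes per sheet unit of the sheet the kernel acts on.
#' @return Object of class `dog_kernel`: fields `weights` (square matrix),
#'   `sigma_c`, `sigma_s`, `support_radius`, `polarity`, `half` (pixels).
#' @export
make_dog_kernel <- function(sigma_c, sigma_s, support_radius = 3 * sigma_s,
                            polarity = c("ON", "OFF"), density = 48) {
  polarity <- match.arg(polarity)
  if (!(sigma_s > sigma_c && sigma_c > 0))
    stop("need sigma_s > sigma_c > 0")
  if (support_radius < 3 * sigma_s)
    warning("support_radius < 3*sigma_s: DoG truncation error may be large")
  half <- max(1L, as.integer(round(support_radius * density)))
  d <- (-half:half) / density
  r2 <- outer(d^2, d^2, "+")
  gc <- exp(-r2 / (2 * sigma_c^2)); gc <- gc / sum(gc)
  gs <- exp(-r2 / (2 * sigma_s^2)); gs <- gs / sum(gs)
  w <- gc - gs
  if (polarity == "OFF") w <- -w
  structure(list(weights = w, sigma_c = sigma_c, sigma_s = sigma_s,
                 support_radius = support_radius, polarity = polarity,
                 half = half, density = density),
            class = "dog_kernel")
}

#' Unit-mass Gaussian pooling kernel (LGN suppressive pool)
#'
#' @param sigma Width in sheet units.
#' @param support_radius Half-support in sheet units.
#' @param density Nodes per sheet unit.
#' @return Square matrix summing to 1.
#' @export
make_gaussian_kernel <- function(sigma, support_radius = 3 * sigma,
                                 density = 48) {
  half <- max(1L, as.integer(round(support_radius * density)))
  d <- (-half:half) / density
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  g / sum(g)
}

#' Analytic DoG transfer function and its peak frequency
#'
#' For unit-mass Gaussians the Fourier transfer of the ON kernel is
#' `exp(-2*pi^2*sigma_c^2*k^2) - exp(-2*pi^2*sigma_s^2*k^2)` with k in cycles
#' per sheet unit; its argmax is
#' `sqrt(log(sigma_s^2/sigma_c^2) / (2*pi^2*(sigma_s^2 - sigma_c^2)))`.
#'
#' @param sigma_c,sigma_s Centre/surround widths, sheet units.
#' @param k Spatial frequency (cycles per sheet unit).
#' @return Transfer value(s) / peak frequency.
#' @export
dog_transfer <- function(sigma_c, sigma_s, k) {
  exp(-2 * pi^2 * sigma_c^2 * k^2) - exp(-2 * pi^2 * sigma_s^2 * k^2)
}

#' @rdname dog_transfer
#' @export
dog_peak_frequency <- function(sigma_c, sigma_s) {
  sqrt(log(sigma_s^2 / sigma_c^2) / (2 * pi^2 * (sigma_s^2 - sigma_c^2)))
}

# --- zero-padded FFT convolution --------------------------------------------

# Precompute a linear same-size convolution plan for a fixed kernel and
# field dimension.
make_conv_plan <- function(kernel, n_field) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  m <- stats::nextn(n_field + 2L * kh, c(2L, 3L, 5L))
  kp <- matrix(0, m, m)
  kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  list(kfft = fft(kp), m = m, kh = kh, n = n_field)
}

conv_same <- function(field, plan) {
  fp <- matrix(0, plan$m, plan$m)
  fp[seq_len(plan$n), seq_len(plan$n)] <- field
  full <- Re(fft(fft(fp) * plan$kfft, inverse = TRUE)) / plan$m^2
  idx <- plan$kh + seq_len(plan$n)
  full[idx, idx]
}

# --- LGN sheet ---------------------------------------------------------------

#' Build an LGN stage for a retinal geometry
#'
#' Packages the DoG receptive-field kernel, the suppressive-pool kernel and
#' their convolution plans, plus the gain parameters.
#'
#' @param geometry Retinal [sheet_geometry()].
#' @param sigma_c,sigma_s DoG widths, sheet units.
#' @param sigma_pool Width of the suppressive pool (defaults to `sigma_c`,
#'   as the pool reuses the centre width; override to decouple them).
#' @param k Offset of the divisive denominator (semisaturation constant).
#' @param gamma_o Overall afferent gain.
#' @param gamma_s Strength of the recurrent suppressive pool.
#' @param gain `"divisive"` (default) rescales the afferent drive by
#'   `k + gamma_s * pool`, giving contrast saturation; `"subtractive"`
#'   subtracts `gamma_s * pool` as the recurrence is printed.
#' @param settle_steps Settling recursion length per stimulus (>= 1).
#' @param alpha Relaxation weight per settling step in (0, 1]: the new
#'   activity is `(1 - alpha) * L_prev + alpha * f(...)`. The divisive
#'   recurrence has the same fixed point for any alpha, but alpha < 1 damps
#'   its two-cycle oscillation so a handful of steps settle it.
#' @return Object of class `lgn_stage`.
#' @export
lgn_stage <- function(geometry, sigma_c = 0.0375, sigma_s = 4 * sigma_c,
                      sigma_pool = 0.25, k = 0.11, gamma_o = 1, gamma_s = 0.6,
                      gain = c("divisive", "subtractive"), settle_steps = 5,
                      alpha = 0.5) {
  gain <- match.arg(gain)
  dog <- make_dog_kernel(sigma_c, sigma_s, density = geometry$density)
  sup <- make_gaussian_kernel(sigma_pool, density = geometry$density)
  structure(list(
    geometry = geometry, dog = dog,
    plan_dog = make_conv_plan(dog$weights, geometry$n),
    plan_sup = make_conv_plan(sup, geometry$n),
    k = k, gamma_o = gamma_o, gamma_s = gamma_s, gain = gain,
    settle_steps = settle_steps, alpha = alpha), class = "lgn_stage")
}

#' One step of the ON/OFF LGN recurrence
#'
#' The ON drive is the DoG-filtered retinal image; the OFF drive its
#' negation. Each channel is suppressed by a Gaussian pool of its own
#' previous activity (divisive by default) and half-wave rectified.
#'
#' @param x Retinal activity matrix (non-negative).
#' @param L_prev List `(on, off)` of previous LGN activity (zeros at onset).
#' @param lgn An [lgn_stage()].
#' @param drive Optional precomputed DoG response to `x` (internal reuse).
#' @return List `(on, off)` of non-negative activity matrices.
#' @export
lgn_step <- function(x, L_prev, lgn, drive = NULL) {
  if (!all(dim(x) == c(lgn$geometry$n, lgn$geometry$n)))
    stop("retinal field does not match the LGN geometry")
  if (is.null(drive)) drive <- conv_same(x, lgn$plan_dog)
  step1 <- function(d, Lp) {
    pool <- conv_same(Lp, lgn$plan_sup)
    v <- if (lgn$gain == "divisive") lgn$gamma_o * d / (lgn$k + lgn$gamma_s * pool)
         else lgn$gamma_o * d - lgn$gamma_s * pool
    (1 - lgn$alpha) * Lp + lgn$alpha * pmax(v, 0)
  }
  list(on = step1(drive, L_prev$on), off = step1(-drive, L_prev$off))
}

#' Settled LGN response to a stimulus
#'
#' Initializes each channel to the rectified pure afferent response and runs
#' a short settling recursion so the gain control takes effect.
#'
#' @inheritParams lgn_step
#' @return List `(on, off)`.
#' @export
lgn_settle <- function(x, lgn) {
  drive <- conv_same(x, lgn$plan_dog)
  L <- list(on = pmax(lgn$gamma_o * drive, 0),
            off = pmax(-lgn$gamma_o * drive, 0))
  for (i in seq_len(lgn$settle_steps)) L <- lgn_step(x, L, lgn, drive = drive)
  L
}
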