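# Projection fields: per-target-unit weight kernels stored as K x N matrices
# (K = square window entries, column-major over (di fastest, dj); N cortical
# units, u = uj*nc + ui). Entries outside the circular support are
# structurally zero and the update rules never touch them.

# logical mask of length (2*half+1)^2 marking offsets within radius_px
mask_offsets <- function(half, radius_px) {
  d <- -half:half
  as.vector(outer(d^2, d^2, "+") <= radius_px^2)
}

# one initial kernel column: normalized Gaussian of the support radius plus
# uniform noise, zero off-mask, unit sum
init_kernel_column <- function(half, mask, sigma_px, noise, stream) {
  d <- -half:half
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma_px^2))
  g <- as.vector(g / max(g))
  if (noise > 0) g <- g + noise * with_stream(stream, runif(length(g)))
  g[!mask] <- 0
  g / sum(g)
}

#' Initialize the afferent and lateral projection fields
#'
#' Each unit's kernel is a normalized Gaussian profile over its circular
#' support plus uniform noise (the symmetry-breaking the Hebbian rules need),
#' normalized to unit sum. The lateral excitatory support is capped at the
#' inhibitory radius `rad_I`: excitatory mass beyond the astrocyte radius is
#' pruned by the BCM rule during training, so the cap only bounds memory.
#'
#' @param config An [model_config()].
#' @param stream [rng_stream()] for the initialization noise.
#' @return List with weight banks `A_on`, `A_off`, `E`, `I`, masks
#'   `mask_a`, `mask_i`, window half-widths `half_a`, `half_i`, and the
#'   retina padding `pad` (pixels).
#' @export
init_projections <- function(config, stream = rng_stream(config$seed, "weights")) {
  nc <- as.integer(round(config$extent * config$density))
  rad_e <- if (is.null(config$rad_E)) config$rad_I else config$rad_E
  half_a <- as.integer(round(config$rad_A * config$density))
  half_i <- as.integer(round(config$rad_I * config$density))
  half_e <- max(1L, as.integer(round(rad_e * config$density)))
  if (2 * config$rad_I >= config$extent)
    stop("lateral radius exceeds the sheet extent")
  ra_px <- config$rad_A * config$density
  ri_px <- config$rad_I * config$density
  re_px <- max(1, rad_e * config$density)
  mask_a <- mask_offsets(half_a, ra_px)
  mask_i <- mask_offsets(half_i, ri_px)
  mask_e <- mask_offsets(half_e, re_px)
  N <- nc * nc
  bank <- function(half, mask, radius_px) {
    K <- (2 * half + 1)^2
    W <- matrix(0, K, N)
    for (u in seq_len(N))
      W[, u] <- init_kernel_column(half, mask, radius_px / 2,
                                   config$init_noise, stream)
    W
  }
  A_on <- bank(half_a, mask_a, ra_px)
  A_off <- bank(half_a, mask_a, ra_px)
  # joint afferent normalization across ON/OFF: halve each bank
  A_on <- A_on / 2; A_off <- A_off / 2
  E <- bank(half_e, mask_e, re_px)
  I <- bank(half_i, mask_i, ri_px)
  # zero entries whose presynaptic pixel falls off the cortical sheet, then
  # renormalize, so edge-unit kernels sum to 1 over their valid support
  fix_edges <- function(W, half) {
    d <- -half:half
    for (uj in 0:(nc - 1)) for (ui in 0:(nc - 1)) {
      ok <- as.vector(outer(ui + d >= 0 & ui + d < nc,
                            uj + d >= 0 & uj + d < nc, "&"))
      u <- uj * nc + ui + 1
      if (!all(ok)) {
        W[!ok, u] <- 0
        s <- sum(W[, u]); if (s > 0) W[, u] <- W[, u] / s
      }
    }
    W
  }
  E <- fix_edges(E, half_e)
  I <- fix_edges(I, half_i)
  list(A_on = A_on, A_off = A_off, E = E, I = I,
       mask_a = mask_a, mask_i = mask_i, mask_e = mask_e,
       half_a = half_a, half_i = half_i, half_e = half_e, pad = half_a)
}

#' Normalized Hebbian weight update
#'
#' `w' = (w + eta * y_post * P) / sum(w + eta * y_post * P)`: Hebbian growth
#' with divisive postsynaptic normalization, applied to the afferent and
#' lateral inhibitory projections. If the denominator is zero (all-zero
#' weights and activity) the weights are returned unchanged.
#'
#' @param w Weight vector/matrix (non-negative, unit sum).
#' @param y_post Postsynaptic rate (scalar, >= 0).
#' @param P_pre Presynaptic activity, same shape as `w`.
#' @param eta Learning rate.
#' @return Updated weights, summing to 1.
#' @export
hebbian_update <- function(w, y_post, P_pre, eta) {
  w2 <- w + eta * y_post * P_pre
  s <- sum(w2)
  if (s <= 0) {
    message("hebbian_update: zero normalizer, weights left unchanged")
    return(w)
  }
  w2 / s
}

#' Astrocyte-thresholded BCM update of excitatory weights
#'
#' `E' = max(0, E + eta * y_post * (y_post - theta) * y_pre)` with
#' `theta = 1 - S`: postsynaptic rates above the astrocyte-set threshold
#' potentiate coactive synapses, rates below depress them, and weights
#' driven to zero are pruned. No renormalization is applied — the sliding
#' threshold self-limits growth (an optional per-entry cap guards the
#' trainer against runaway).
#'
#' @param E Excitatory weights (>= 0).
#' @param y_post Postsynaptic rate (scalar, >= 0).
#' @param S Astrocyte activation at the postsynaptic unit, in [0, 1].
#' @param y_pre Presynaptic rates, same shape as `E`.
#' @param eta Learning rate.
#' @param e_max Optional per-entry upper cap.
#' @return Updated weights.
#' @export
bcm_update <- function(E, y_post, S, y_pre, eta, e_max = Inf) {
  theta <- 1 - S
  pmin(pmax(E + eta * y_post * (y_post - theta) * y_pre, 0), e_max)
}
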