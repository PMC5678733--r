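#' Build the full cortical model
#'
#' Assembles the retinal/cortical geometries (the retina is padded by
#' `rad_A` on each side so edge cortical units keep complete receptive
#' fields), the LGN stage, the projection fields, the homeostatic state and
#' the astrocyte layer from a configuration.
#'
#' @param config An [model_config()].
#' @return An environment of class `astro_model` with fields `config`,
#'   `cortex`/`retina` geometries, `lgn`, weight banks `W`, state fields
#'   `y`, `gs`, `rho`, `ybar`, `S`, `s_max`, the gap-junction kernel (if
#'   enabled), the RNG `streams`, and the `iteration` counter.
#' @export
astro_model <- function(config) {
  m <- new.env(parent = emptyenv())
  m$config <- config
  nc <- as.integer(round(config$extent * config$density))
  m$cortex <- sheet_geometry(config$extent, config$density, config$mm_per_unit)
  streams <- list(stimuli = rng_stream(config$seed, "stimuli"),
                  weights = rng_stream(config$seed, "weights"),
                  gap = rng_stream(config$seed, "gap-junction"))
  m$streams <- streams
  proj <- init_projections(config, streams$weights)
  m$W <- proj[c("A_on", "A_off", "E", "I")]
  m$mask_a <- proj$mask_a; m$mask_i <- proj$mask_i; m$mask_e <- proj$mask_e
  m$half_a <- proj$half_a; m$half_i <- proj$half_i; m$half_e <- proj$half_e
  m$pad <- proj$pad
  nr <- nc + 2L * proj$pad
  m$retina <- sheet_geometry(nr / config$density, config$density,
                             config$mm_per_unit,
                             origin = -proj$pad / config$density)
  stopifnot(m$retina$n == nr)
  m$lgn <- lgn_stage(m$retina, sigma_c = config$sigma_c,
                     sigma_s = config$sigma_s, sigma_pool = config$sigma_pool,
                     k = config$lgn_k,
                     gamma_o = config$gamma_o, gamma_s = config$gamma_s,
                     gain = config$lgn_gain,
                     settle_steps = config$lgn_settle_steps,
                     alpha = config$lgn_alpha)
  m$stim_params <- stimulus_params(config$sigma_major, config$sigma_minor,
                                   config$amplitude, config$stim_margin)
  m$nc <- nc
  m$y <- matrix(0, nc, nc)
  m$gs <- matrix(0, nc, nc)
  m$rho <- matrix(config$rho0, nc, nc)
  m$ybar <- matrix(config$mu, nc, nc)
  m$S <- matrix(0, nc, nc)
  m$s_max <- NA_real_   # set from the first presentation
  m$e_max <- if (is.null(config$e_max)) 4 / sum(proj$mask_e) else config$e_max
  m$gj_kernel <- if (config$gap_junctions)
    make_gap_junction_kernel(streams$gap, config$gj_strength, config$gj_sigma)
  else NULL
  m$iteration <- 0L
  m$degenerate_redraws <- 0L
  class(m) <- "astro_model"
  m
}

#' @export
print.astro_model <- function(x, ...) {
  cat(sprintf("<astro_model> %dx%d cortex, retina %dx%d, iteration %d\n",
              x$nc, x$nc, x$retina$n, x$retina$n, x$iteration))
  print(x$config)
  invisible(x)
}

#' Settle the V1 rate dynamics for one stimulus
#'
#' Iterates
#' `y(t) = f(p * A.L + q * E.y(t-1) - r * I.y(t-1))` with the
#' piecewise-linear transfer `f(v) = min(y_max, max(0, v - rho))`,
#' from `y = 0` for `steps` settling steps with the LGN input held fixed.
#'
#' @param L List `(on, off)` of settled LGN activity.
#' @param model An [astro_model()].
#' @param steps Number of settling steps.
#' @param rho Threshold field (defaults to the model's adapted threshold).
#' @return List with `y` (settled rates), `gs` (pre-rectification synaptic
#'   drive of the last step), `y_prev` (rates entering the last step), and
#'   the last step's drive components `aff`, `exc`, `inh` (vectors).
#' @export
v1_settle <- function(L, model, steps = model$config$settling_steps,
                      rho = model$rho) {
  cfg <- model$config; nc <- model$nc
  aff <- cfg$p * (proj_drive(L$on, model$W$A_on, nc, model$half_a, model$pad) +
                  proj_drive(L$off, model$W$A_off, nc, model$half_a, model$pad))
  rho_v <- as.vector(rho)
  y <- numeric(nc * nc)
  v <- aff
  e <- i <- numeric(nc * nc)
  y_prev <- y
  for (t in seq_len(steps)) {
    y_prev <- y
    if (any(y > 0)) {
      ymat <- matrix(y, nc, nc)
      e <- proj_drive(ymat, model$W$E, nc, model$half_e, 0L)
      i <- proj_drive(ymat, model$W$I, nc, model$half_i, 0L)
    } else {
      e <- i <- numeric(nc * nc)
    }
    v <- aff + cfg$q * e - cfg$r * i
    y <- (1 - cfg$v1_alpha) * y +
      cfg$v1_alpha * pmin(pmax(cfg$y_gain * (v - rho_v), 0), cfg$y_max)
  }
  if (!all(is.finite(y)))
    stop(sprintf(
      "V1 activity diverged (p=%.3g, q=%.3g, r=%.3g); reduce the recurrent strengths",
      cfg$p, cfg$q, cfg$r))
  list(y = matrix(y, nc, nc), gs = matrix(v, nc, nc),
       y_prev = matrix(y_prev, nc, nc), aff = aff, exc = e, inh = i)
}

#' Synaptic drive seen by the astrocyte layer
#'
#' The full variant is the three-term drive
#' `p * A.L + q * E.y - r * I.y`; the `no_gaba` variant drops the
#' inhibitory term (no GABA-induced gliotransmission).
#'
#' @param L List `(on, off)` of LGN activity.
#' @param y Cortical rate field the lateral terms are evaluated at.
#' @param model An [astro_model()].
#' @param variant `"full"` or `"no_gaba"` (defaults to the config's).
#' @return Matrix of synaptic drive.
#' @export
synaptic_drive <- function(L, y, model, variant = model$config$variant) {
  cfg <- model$config; nc <- model$nc
  aff <- cfg$p * (proj_drive(L$on, model$W$A_on, nc, model$half_a, model$pad) +
                  proj_drive(L$off, model$W$A_off, nc, model$half_a, model$pad))
  ymat <- if (is.matrix(y)) y else matrix(y, nc, nc)
  e <- proj_drive(ymat, model$W$E, nc, model$half_e, 0L)
  i <- proj_drive(ymat, model$W$I, nc, model$half_i, 0L)
  v <- switch(variant,
              full = aff + cfg$q * e - cfg$r * i,
              no_gaba = aff + cfg$q * e,
              stop("unknown variant: ", variant))
  matrix(v, nc, nc)
}

#' Astrocyte activation by disc pooling of synaptic drive
#'
#' Each astrocyte sums the synaptic drive over all nodes within Euclidean
#' distance `gfap_scale * radius_mm` (the anatomical GFAP radius scaled to
#' the full arbor) of its node, then the field is rescaled into [0, 1] by a
#' running maximum so the BCM threshold `theta = 1 - S` stays on the unit
#' interval. The pooling disc always contains the centre node, so radii
#' below one node spacing degrade gracefully to identity pooling (the
#' salt-and-pepper regime).
#'
#' @param gs Synaptic-drive matrix.
#' @param radius_mm Anatomical astrocyte radius, mm.
#' @param geometry Cortical [sheet_geometry()].
#' @param gfap_scale Anatomical-to-effective radius multiplier.
#' @param s_max Normalizing maximum; `NULL` uses the current field's maximum.
#' @return List of class `astro_state`: `S` (normalized, in [0, 1]),
#'   `S_raw`, `s_max`, `radius_mm`, `radius_px` (effective, pixels).
#' @export
astrocyte_activation <- function(gs, radius_mm, geometry, gfap_scale = 2,
                                 s_max = NULL) {
  if (radius_mm <= 0) stop("astrocyte radius must be > 0")
  r_px <- mm_to_px(geometry, gfap_scale * radius_mm)
  S_raw <- pool_disc(gs, r_px)
  if (is.null(s_max) || !is.finite(s_max)) s_max <- max(S_raw)
  if (s_max <= 0) s_max <- 1
  S <- pmin(pmax(S_raw / s_max, 0), 1)
  structure(list(S = S, S_raw = S_raw, s_max = s_max,
                 radius_mm = radius_mm, radius_px = r_px),
            class = "astro_state")
}

#' Fixed random gap-junction kernel
#'
#' Positive weights to the 8 nearest neighbours with half-normal magnitudes
#' `|N(0, sigma)|`, scaled so the total neighbour contribution equals
#' `strength`. Drawn once at model initialization and fixed thereafter.
#'
#' @param stream [rng_stream()].
#' @param strength Total neighbour contribution (0 disables coupling).
#' @param sigma Scale of the magnitudes.
#' @return A 3 x 3 matrix with zero centre.
#' @export
make_gap_junction_kernel <- function(stream, strength = 0.1, sigma = 1) {
  k <- matrix(0, 3, 3)
  mag <- abs(with_stream(stream, rnorm(8, 0, sigma)))
  k[-5] <- mag
  s <- sum(k)
  if (s > 0 && strength > 0) k <- k * (strength / s) else k[] <- 0
  k
}

#' Gap-junction coupling of the astrocyte layer
#'
#' `S' = (S + kernel (*) S) / (1 + sum(kernel))`, clipped to [0, 1]: each
#' astrocyte receives a weak fixed random contribution from its 8
#' neighbours; the normalization keeps a uniform field uniform and reduces
#' to the identity when the kernel is zero.
#'
#' @param S Astrocyte activation matrix.
#' @param kernel 3 x 3 gap-junction kernel (zero centre).
#' @return Updated activation matrix.
#' @export
gap_junction_update <- function(S, kernel) {
  if (!all(dim(kernel) == c(3, 3)) || kernel[2, 2] != 0)
    stop("gap-junction kernel must be 3x3 with a zero centre")
  n1 <- nrow(S); n2 <- ncol(S)
  acc <- matrix(0, n1, n2)
  for (dj in -1:1) for (di in -1:1) {
    w <- kernel[di + 2, dj + 2]
    if (w == 0) next
    src_i <- (1 + max(0, -di)):(n1 - max(0, di))
    src_j <- (1 + max(0, -dj)):(n2 - max(0, dj))
    acc[src_i + di, src_j + dj] <- acc[src_i + di, src_j + dj] +
      w * S[src_i, src_j]
  }
  pmin(pmax((S + acc) / (1 + sum(kernel)), 0), 1)
}

#' Homeostatic adaptation of the firing threshold
#'
#' Smooths the activity trace, `ybar' = (1 - beta) * y + beta * ybar`, and
#' slides the rectification threshold toward the target mean activity:
#' `rho' = rho + lambda * (ybar' - mu)` (balanced form) or
#' `rho' = rho + lambda * ybar' - mu` (the recurrence as printed).
#'
#' @param y Current activity.
#' @param ybar Smoothed activity trace.
#' @param rho Current threshold.
#' @param beta Smoothing parameter in (0, 1).
#' @param lambda Homeostatic learning rate.
#' @param mu Target mean activity.
#' @param form `"balanced"` or `"printed"`.
#' @return List `(ybar, rho)`.
#' @export
homeostatic_update <- function(y, ybar, rho, beta, lambda, mu,
                               form = c("balanced", "printed")) {
  form <- match.arg(form)
  ybar2 <- (1 - beta) * y + beta * ybar
  rho2 <- if (form == "balanced") rho + lambda * (ybar2 - mu)
          else rho + lambda * ybar2 - mu
  list(ybar = ybar2, rho = rho2)
}
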