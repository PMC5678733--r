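#' Model configuration
#'
#' Collects every tunable constant of the cortical model, the astrocyte
#' layer, the LGN stage and the training stimuli. Connection strengths,
#' learning rates and connection radii default to the values in the model's
#' reference parameter table (p = 1.5, q = 2.1, r = 1.4, eta_A = 0.1,
#' eta_E = 0.3, eta_I = 0.3, rad_A = 0.27, rad_I = 0.22 sheet units).
#'
#' @param density Cortical nodes per sheet unit per axis (the retina uses
#'   the same density and is padded by `rad_A` on each side so edge units
#'   keep full receptive fields).
#' @param extent Cortical sheet side, sheet units; 1 sheet unit corresponds
#'   to `mm_per_unit` mm of tissue (3 mm by default, i.e. a 3 x 3 mm patch).
#' @param mm_per_unit Millimetres per sheet unit.
#' @param p,q,r Afferent / lateral-excitatory / lateral-inhibitory strengths.
#' @param eta_A,eta_E,eta_I Learning rates in (0, 1].
#' @param rad_A,rad_I Afferent and lateral-inhibitory radii, sheet units.
#' @param rad_E Support radius of the lateral excitatory kernels, sheet
#'   units. `NULL` (default) caps the support at `rad_I`: the excitatory
#'   range is then set dynamically by the astrocyte-gated BCM rule, which
#'   prunes mass beyond the astrocyte reach.
#' @param bcm_scope How far an astrocyte's threshold modulation reaches:
#'   `"synapse"` (default) applies the astrocyte-lowered threshold
#'   `theta = 1 - S` only to synapses whose presynaptic partner lies within
#'   the effective astrocyte radius of the target unit; synapses from
#'   beyond that radius see no astrocytic coverage (`theta = 1`), so
#'   coactivity depresses them and they are pruned. `"node"` applies
#'   `theta = 1 - S` to every synapse of the unit (the single-threshold
#'   reading, which leaves the excitatory range unconstrained).
#' @param learning_scale `"per_unit"` (default) divides each projection's
#'   learning rate by the number of connections in its support, so `eta`
#'   sets the per-receptive-field rate (the Topographica convention the
#'   reference parameter values assume); `"raw"` applies `eta` per synapse.
#' @param e_rule Plasticity rule for the lateral excitatory projection:
#'   `"bcm"` (default) is the astrocyte-thresholded BCM rule; `"hebbian"`
#'   trains E with the same normalized Hebbian rule as A and I (the classic
#'   fixed-radius configuration, useful as a baseline).
#' @param R_astro_mm Anatomical (GFAP-stained) astrocyte radius in mm. GFAP
#'   labels only ~15% of the arbor volume, so the pooling radius used
#'   internally is `gfap_scale` times this value.
#' @param gfap_scale Multiplier from GFAP radius to effective radius.
#' @param settling_steps Joint V1 settling steps per presentation.
#' @param v1_alpha Relaxation weight per V1 settling step in (0, 1]:
#'   `y <- (1 - v1_alpha) * y + v1_alpha * f(...)`. Fixed points are
#'   unchanged; values below 1 suppress the synchronous-update two-cycle
#'   that otherwise appears when lateral excitation is weak.
#' @param beta Homeostatic smoothing parameter in (0, 1).
#' @param lambda Homeostatic learning rate.
#' @param mu Target mean V1 activity (also initializes the smoothed trace).
#' @param homeostasis_form `"balanced"` uses
#'   `rho <- rho + lambda * (ybar - mu)`; `"printed"` uses
#'   `rho <- rho + lambda * ybar - mu` (the recurrence as printed, which is
#'   dimensionally unbalanced; see the methods vignette).
#' @param rho0 Initial threshold.
#' @param variant `"full"` includes the inhibitory (GABAergic) term in the
#'   synaptic drive seen by astrocytes; `"no_gaba"` drops it.
#' @param gap_junctions Couple neighbouring astrocytes through a fixed
#'   random 8-neighbour kernel.
#' @param gj_strength Total neighbour contribution of the gap-junction
#'   kernel (its entries are scaled to sum to this).
#' @param gj_sigma Scale of the half-normal magnitudes of the kernel.
#' @param s_max_tau Time constant (presentations) of the tracked scale used
#'   to rescale astrocyte activation into [0, 1]: the scale relaxes toward
#'   each presentation's maximum pooled drive, and S is clipped to [0, 1],
#'   so near-peak regions saturate at 1.
#' @param sigma_c,sigma_s,sigma_pool,lgn_k,gamma_o,gamma_s,lgn_gain,lgn_settle_steps,lgn_alpha
#'   LGN stage parameters, see [lgn_stage()].
#' @param sigma_major,sigma_minor,amplitude,stim_margin Training stimulus
#'   parameters, see [stimulus_params()].
#' @param init_noise Relative uniform noise added to the initial Gaussian
#'   weight profiles (0 gives the pure profile).
#' @param e_max Per-entry cap on lateral excitatory weights; default
#'   `4 / n_support` where `n_support` is the number of entries in the
#'   excitatory kernel support.
#' @param e_mass_max Ceiling on each unit's total excitatory mass: after a
#'   BCM update, units whose kernel sum exceeds it are rescaled to it
#'   (below the ceiling the BCM update is unmodified). Matches the unit
#'   mass the normalized projections carry and gives the excitatory bank a
#'   stable operating point.
#' @param y_max Saturation ceiling of the piecewise-linear V1 transfer
#'   `f(v) = min(y_max, max(0, y_gain * (v - rho)))`; `Inf` gives a pure
#'   half-wave rectifier (which is not settling-stable once the BCM rule
#'   has grown the unnormalized excitatory mass).
#' @param y_gain Slope of the linear segment of the transfer. Slopes above
#'   1 sharpen settled activity into compact saturated blobs (the classic
#'   LISSOM piecewise-linear sigmoid), which is what lets coactive
#'   neighbours imprint the same stimulus and the map become smooth.
#' @param learn_per Apply plasticity once per `"presentation"` (default) or
#'   after every settling `"step"`.
#' @param seed Master seed; independent substreams are derived for stimuli,
#'   weight initialization and the gap-junction kernel.
#' @return A list of class `astromap_config`.
#' @export
model_config <- function(density = 48, extent = 1, mm_per_unit = 3,
                         p = 1.5, q = 2.1, r = 1.4,
                         eta_A = 0.1, eta_E = 0.3, eta_I = 0.3,
                         rad_A = 0.27, rad_I = 0.22, rad_E = NULL,
                         R_astro_mm = 0.1125, gfap_scale = 2,
                         settling_steps = 16, v1_alpha = 0.5,
                         beta = 0.991, lambda = 0.01, mu = 0.024,
                         homeostasis_form = c("balanced", "printed"),
                         rho0 = 0,
                         variant = c("full", "no_gaba"),
                         gap_junctions = FALSE, gj_strength = 0.1,
                         gj_sigma = 1, s_max_tau = 20,
                         sigma_c = 0.0375, sigma_s = 4 * sigma_c,
                         sigma_pool = 0.25, lgn_k = 0.11,
                         gamma_o = 1, gamma_s = 0.6,
                         lgn_gain = c("divisive", "subtractive"),
                         lgn_settle_steps = 5, lgn_alpha = 0.5,
                         sigma_major = 0.4, sigma_minor = 0.09,
                         amplitude = 1, stim_margin = sigma_minor,
                         init_noise = 0.5, e_max = NULL, e_mass_max = 1,
                         y_max = 1, y_gain = 3,
                         e_rule = c("bcm", "hebbian"),
                         bcm_scope = c("synapse", "node"),
                         learning_scale = c("per_unit", "raw"),
                         learn_per = c("presentation", "step"),
                         seed = 1) {
  stopifnot(p > 0, q > 0, r > 0)
  if (!all(c(eta_A, eta_E, eta_I) > 0 & c(eta_A, eta_E, eta_I) <= 1))
    stop("learning rates must lie in (0, 1]")
  stopifnot(rad_A > 0, rad_I > 0)
  if (R_astro_mm <= 0) stop("R_astro_mm must be > 0")
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)")
  if (settling_steps < 1) stop("settling_steps must be >= 1")
  cfg <- list(
    density = density, extent = extent, mm_per_unit = mm_per_unit,
    p = p, q = q, r = r, eta_A = eta_A, eta_E = eta_E, eta_I = eta_I,
    rad_A = rad_A, rad_I = rad_I,
    rad_E = if (is.null(rad_E)) rad_I else rad_E,
    R_astro_mm = R_astro_mm, gfap_scale = gfap_scale,
    settling_steps = as.integer(settling_steps),
    v1_alpha = v1_alpha,
    beta = beta, lambda = lambda, mu = mu,
    homeostasis_form = match.arg(homeostasis_form), rho0 = rho0,
    variant = match.arg(variant),
    gap_junctions = isTRUE(gap_junctions), gj_strength = gj_strength,
    gj_sigma = gj_sigma, s_max_tau = s_max_tau,
    sigma_c = sigma_c, sigma_s = sigma_s, sigma_pool = sigma_pool,
    lgn_k = lgn_k,
    gamma_o = gamma_o, gamma_s = gamma_s, lgn_gain = match.arg(lgn_gain),
    lgn_settle_steps = as.integer(lgn_settle_steps), lgn_alpha = lgn_alpha,
    sigma_major = sigma_major, sigma_minor = sigma_minor,
    amplitude = amplitude, stim_margin = stim_margin,
    init_noise = init_noise, e_max = e_max, e_mass_max = e_mass_max,
    y_max = y_max, y_gain = y_gain, e_rule = match.arg(e_rule),
    bcm_scope = match.arg(bcm_scope),
    learning_scale = match.arg(learning_scale),
    learn_per = match.arg(learn_per), seed = as.integer(seed))
  class(cfg) <- "astromap_config"
  cfg
}

#' @export
print.astromap_config <- function(x, ...) {
  cat(sprintf(
    "<astromap_config> %dx%d cortex, R_astro %.4g mm (x%g), variant %s%s, seed %d\n",
    round(x$extent * x$density), round(x$extent * x$density),
    x$R_astro_mm, x$gfap_scale, x$variant,
    if (x$gap_junctions) " + gap junctions" else "", x$seed))
  invisible(x)
}

#' Read a model configuration from a YAML file
#'
#' The file may group keys into blocks named `stimuli`, `lgn`, `model`,
#' `astrocyte` and `homeostasis`; all keys are [model_config()] argument
#' names and the blocks are flattened before the call.
#'
#' @param path YAML file path.
#' @return An `astromap_config`.
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  blocks <- c("stimuli", "lgn", "model", "astrocyte", "homeostasis")
  flat <- list()
  for (nm in names(raw)) {
    if (nm %in% blocks) flat <- c(flat, raw[[nm]]) else flat[[nm]] <- raw[[nm]]
  }
  keep <- intersect(names(flat), names(formals(model_config)))
  do.call(model_config, flat[keep])
}
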