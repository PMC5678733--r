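#' Training / probing schedule
#'
#' @param total_iterations Number of stimulus presentations.
#' @param probe_iterations Iterations at which orientation maps are
#'   measured (sorted, all `<= total_iterations`).
#' @param sweep_radii_mm Anatomical astrocyte radii for [run_sweep()], mm.
#' @param seeds Seeds per radius for [run_sweep()].
#' @return A list of class `run_schedule`.
#' @export
run_schedule <- function(total_iterations = 10000,
                         probe_iterations = c(250, 500, 750, 1000, 2500,
                                              5000, 7500, 10000),
                         sweep_radii_mm = c(0.015, 0.0375, 0.075, 0.1125,
                                            0.15, 0.1875),
                         seeds = 1:3) {
  probe_iterations <- as.integer(probe_iterations)
  if (is.unsorted(probe_iterations))
    stop("probe_iterations must be sorted")
  if (any(probe_iterations > total_iterations))
    stop("probe iterations must not exceed total_iterations")
  if (any(sweep_radii_mm <= 0)) stop("sweep radii must be > 0")
  structure(list(total_iterations = as.integer(total_iterations),
                 probe_iterations = probe_iterations,
                 sweep_radii_mm = sweep_radii_mm,
                 seeds = as.integer(seeds)),
            class = "run_schedule")
}

# advance the model by one stimulus presentation (draw, settle, learn)
present_one <- function(m) {
  cfg <- m$config
  repeat {
    stim <- sample_training_stimulus(m$streams$stimuli, m$retina, m$stim_params)
    x <- render_stimulus(stim, m$retina)
    if (max(x) > 1e-9) break
    m$degenerate_redraws <- m$degenerate_redraws + 1L
  }
  L <- lgn_settle(x, m$lgn)
  if (cfg$learn_per == "presentation") {
    st <- v1_settle(L, m)
    learn_step(m, L, st)
  } else {
    # per-step plasticity: settle one step at a time, learning after each
    st <- NULL
    y <- matrix(0, m$nc, m$nc)
    for (k in seq_len(cfg$settling_steps)) {
      st <- v1_settle_from(L, m, y)
      learn_step(m, L, st)
      y <- st$y
    }
  }
  m$iteration <- m$iteration + 1L
  invisible(st)
}

# one settling step starting from a given y (used by per-step learning)
v1_settle_from <- function(L, m, y) {
  cfg <- m$config; nc <- m$nc
  aff <- cfg$p * (proj_drive(L$on, m$W$A_on, nc, m$half_a, m$pad) +
                  proj_drive(L$off, m$W$A_off, nc, m$half_a, m$pad))
  e <- proj_drive(y, m$W$E, nc, m$half_e, 0L)
  i <- proj_drive(y, m$W$I, nc, m$half_i, 0L)
  v <- aff + cfg$q * e - cfg$r * i
  ynew <- (1 - cfg$v1_alpha) * as.vector(y) +
    cfg$v1_alpha * pmin(pmax(cfg$y_gain * (v - as.vector(m$rho)), 0), cfg$y_max)
  list(y = matrix(ynew, nc, nc), gs = matrix(v, nc, nc),
       y_prev = y, aff = aff, exc = e, inh = i)
}

# apply astrocyte update, plasticity and homeostasis for one settled state
learn_step <- function(m, L, st) {
  cfg <- m$config; nc <- m$nc
  gs <- if (cfg$variant == "full") st$gs
        else matrix(st$aff + cfg$q * st$exc, nc, nc)
  r_px <- mm_to_px(m$cortex, cfg$gfap_scale * cfg$R_astro_mm)
  S_raw <- pool_disc(gs, r_px)
  mx <- max(S_raw)
  m$s_max <- if (!is.finite(m$s_max)) mx
             else m$s_max + (mx - m$s_max) / cfg$s_max_tau
  if (m$s_max <= 0) m$s_max <- 1
  S <- pmin(pmax(S_raw / m$s_max, 0), 1)
  if (!is.null(m$gj_kernel)) S <- gap_junction_update(S, m$gj_kernel)
  m$S <- S
  yv <- as.vector(st$y)
  sc <- cfg$learning_scale == "per_unit"
  eta_a <- if (sc) cfg$eta_A / sum(m$mask_a) else cfg$eta_A
  eta_i <- if (sc) cfg$eta_I / sum(m$mask_i) else cfg$eta_I
  eta_e <- if (sc) cfg$eta_E / sum(m$mask_e) else cfg$eta_E
  hebbian_window_pair(m$W$A_on, m$W$A_off, m$mask_a, yv, L$on, L$off,
                      nc, m$half_a, m$pad, eta_a)
  hebbian_window(m$W$I, m$mask_i, yv, st$y, nc, m$half_i, 0L, eta_i)
  if (cfg$e_rule == "hebbian") {
    hebbian_window(m$W$E, m$mask_e, yv, st$y, nc, m$half_e, 0L, eta_e)
  } else {
    r2_near <- if (cfg$bcm_scope == "synapse") r_px^2 else Inf
    bcm_window(m$W$E, m$mask_e, yv, as.vector(1 - S), st$y, nc, m$half_e,
               eta_e, m$e_max, r2_near, 1.0)
  }
  if (cfg$e_rule == "bcm" && is.finite(cfg$e_mass_max)) {
    ms <- .colSums(m$W$E, nrow(m$W$E), ncol(m$W$E))
    over <- which(ms > cfg$e_mass_max)
    if (length(over))
      m$W$E[, over] <- m$W$E[, over] %*%
        diag(cfg$e_mass_max / ms[over], length(over))
  }
  if (!all(is.finite(m$W$E)))
    stop(sprintf("excitatory weights diverged at iteration %d", m$iteration))
  hu <- homeostatic_update(st$y, m$ybar, m$rho, cfg$beta, cfg$lambda, cfg$mu,
                           cfg$homeostasis_form)
  m$ybar <- hu$ybar
  m$rho <- hu$rho
  m$y <- st$y
  m$gs <- st$gs
  invisible(m)
}

#' Train the model
#'
#' Runs the full developmental loop: per presentation, a random elongated
#' Gaussian stimulus is drawn and rendered, the LGN and V1 settle, the
#' astrocyte layer pools the synaptic drive, and the plasticity rules are
#' applied (normalized Hebbian for afferent and lateral inhibitory weights,
#' astrocyte-thresholded BCM for lateral excitatory weights) together with
#' homeostatic threshold adaptation. Orientation maps of both layers are
#' measured at the scheduled probe iterations with plasticity frozen.
#' Fully deterministic given the config seed.
#'
#' @param config An [model_config()].
#' @param schedule A [run_schedule()] (its sweep fields are ignored here).
#' @param model Optionally, an existing [astro_model()] to continue.
#' @param probe_layers Layers to probe, subset of
#'   `c("neuronal", "astrocyte")`.
#' @param n_orientations,n_phases Probing protocol, see
#'   [probe_orientation_map()].
#' @param log_every Record run diagnostics every this many iterations.
#' @param quiet Suppress progress messages.
#' @return A list of class `astro_run`: the trained `model`, `maps` (per
#'   probe iteration, per layer), a diagnostics data frame `log`, the
#'   `config` and `schedule`.
#' @export
train <- function(config, schedule = run_schedule(), model = NULL,
                  probe_layers = c("neuronal", "astrocyte"),
                  n_orientations = 8, n_phases = 4,
                  log_every = 50, quiet = TRUE) {
  m <- if (is.null(model)) astro_model(config) else model
  probe_layers <- match.arg(probe_layers, several.ok = TRUE)
  maps <- list()
  logs <- list()
  probe_set <- schedule$probe_iterations
  r_px <- mm_to_px(m$cortex, config$gfap_scale * config$R_astro_mm)
  if (schedule$total_iterations == 0L || 0L %in% probe_set)
    maps[["0"]] <- lapply(stats::setNames(probe_layers, probe_layers),
      function(l) probe_orientation_map(m, n_orientations, n_phases, layer = l))
  for (it in seq_len(schedule$total_iterations)) {
    st <- present_one(m)
    if (it %% log_every == 0 || it == schedule$total_iterations)
      logs[[length(logs) + 1L]] <- data.frame(
        iteration = it, mean_y = mean(m$y), mean_rho = mean(m$rho),
        s_max = m$s_max,
        e_mass_beyond = mass_beyond(m$W$E, m$half_e, r_px))
    if (it %in% probe_set) {
      if (!quiet) message("probing at iteration ", it)
      maps[[as.character(it)]] <- lapply(
        stats::setNames(probe_layers, probe_layers),
        function(l) {
          om <- probe_orientation_map(m, n_orientations, n_phases, layer = l)
          om$iteration <- it
          om
        })
    }
  }
  structure(list(model = m, maps = maps,
                 log = do.call(rbind, logs),
                 config = config, schedule = schedule),
            class = "astro_run")
}

#' Measure an orientation preference map
#'
#' Probes the model with full-field sine gratings at the afferent spatial
#' scale (the analytic peak of the DoG transfer function by default):
#' `n_orientations` evenly spaced orientations, each at `n_phases` phases.
#' The per-node response to an orientation is the maximum over phases of
#' the settled activity (`y` for the neuronal layer, normalized `S` for the
#' astrocyte layer). Preference and selectivity are the argument and
#' normalized magnitude of the orientation vector sum
#' `sum_k r(phi_k) exp(2i phi_k)`. Probing never mutates the model.
#'
#' @param model An [astro_model()].
#' @param n_orientations Number of probe orientations (>= 4).
#' @param n_phases Phases per orientation (>= 2).
#' @param layer `"neuronal"` or `"astrocyte"`.
#' @param freq Grating frequency, cycles per sheet unit (default: DoG peak).
#' @param stimulus `"grating"` (default) or `"gaussian"` (elongated Gaussian
#'   sweep, an alternative probe family for sensitivity checks).
#' @param contrast Probe contrast.
#' @return Object of class `orientation_map`: `preference` (radians in
#'   `[0, pi)`), `selectivity`, per-orientation `responses`
#'   (n x n x n_orientations), `angles`, `layer`, `iteration`, and the
#'   cortical geometry (`extent_mm`, `density`).
#' @export
probe_orientation_map <- function(model, n_orientations = 8, n_phases = 4,
                                  layer = c("neuronal", "astrocyte"),
                                  freq = NULL,
                                  stimulus = c("grating", "gaussian"),
                                  contrast = 1) {
  layer <- match.arg(layer)
  stimulus <- match.arg(stimulus)
  if (n_orientations < 4) stop("need n_orientations >= 4")
  if (n_phases < 2) stop("need n_phases >= 2")
  cfg <- model$config; nc <- model$nc
  if (is.null(freq)) freq <- dog_peak_frequency(cfg$sigma_c, cfg$sigma_s)
  angles <- (seq_len(n_orientations) - 1) * pi / n_orientations
  responses <- array(0, c(nc, nc, n_orientations))
  s_max <- if (is.finite(model$s_max)) model$s_max else NULL
  for (k in seq_len(n_orientations)) {
    resp <- matrix(0, nc, nc)
    for (ph in (seq_len(n_phases) - 1) * 2 * pi / n_phases) {
      x <- if (stimulus == "grating")
        render_grating(model$retina, angles[k], freq, ph, contrast)
      else {
        ctr <- model$retina$origin + model$retina$extent / 2 +
          (ph / (2 * pi) - 0.5) * model$retina$extent / 2 *
            c(-sin(angles[k]), cos(angles[k]))
        render_stimulus(structure(list(
          center = ctr, orientation = angles[k],
          sigma_major = cfg$sigma_major, sigma_minor = cfg$sigma_minor,
          amplitude = contrast), class = "training_stimulus"), model$retina)
      }
      L <- lgn_settle(x, model$lgn)
      st <- v1_settle(L, model)
      act <- if (layer == "neuronal") st$y else {
        gs <- if (cfg$variant == "full") st$gs
              else matrix(st$aff + cfg$q * st$exc, nc, nc)
        as_state <- astrocyte_activation(gs, cfg$R_astro_mm, model$cortex,
                                         cfg$gfap_scale, s_max = s_max)
        S <- as_state$S
        if (!is.null(model$gj_kernel)) S <- gap_junction_update(S, model$gj_kernel)
        S
      }
      resp <- pmax(resp, act)
    }
    responses[, , k] <- resp
  }
  if (all(responses == 0))
    stop("dead map: all probe responses are zero at every node")
  vs <- matrix(0i, nc, nc)
  tot <- matrix(0, nc, nc)
  for (k in seq_len(n_orientations)) {
    vs <- vs + responses[, , k] * exp(2i * angles[k])
    tot <- tot + responses[, , k]
  }
  pref <- (Arg(vs) / 2) %% pi
  sel <- ifelse(tot > 0, Mod(vs) / tot, 0)
  pref[tot == 0] <- 0
  structure(list(preference = pref, selectivity = sel,
                 responses = responses, angles = angles,
                 layer = layer, iteration = model$iteration,
                 freq = freq,
                 extent_mm = model$cortex$extent * model$cortex$mm_per_unit,
                 density = model$cortex$density,
                 mm_per_unit = model$cortex$mm_per_unit),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf(
    "<orientation_map> %s layer, %dx%d nodes (%.3g mm), iteration %d, mean selectivity %.3f\n",
    x$layer, nrow(x$preference), ncol(x$preference), x$extent_mm,
    x$iteration, mean(x$selectivity)))
  invisible(x)
}

#' Sweep the astrocyte radius
#'
#' Trains one model per (radius, seed) cell, probes the final neuronal and
#' astrocyte maps, and analyzes each cell: hypercolumn width, pinwheel
#' count and density per hypercolumn, neuronal-astrocyte stability index,
#' and local orientation similarity. Failed cells are recorded in the
#' `error` column and the sweep continues.
#'
#' @param config Base [model_config()]; radius and seed are overridden per
#'   cell.
#' @param schedule A [run_schedule()] supplying `total_iterations`,
#'   `sweep_radii_mm` and `seeds`.
#' @param local_radius_mm Radius of interest for the local-similarity
#'   statistic.
#' @param keep_maps Attach the probed maps as the `maps` attribute.
#' @param quiet Suppress progress messages.
#' @return A data frame with one row per radius x seed: `radius_mm`,
#'   `seed`, `lambda_mm`, `zeta`, `n_pinwheels`, `pw_per_hc`,
#'   `si_neuro_astro`, `mean_local_angle_deg`, `mean_selectivity`, `error`.
#' @export
run_sweep <- function(config, schedule = run_schedule(),
                      local_radius_mm = 0.25, keep_maps = FALSE,
                      quiet = TRUE) {
  if (length(schedule$sweep_radii_mm) < 1 || length(schedule$seeds) < 1)
    stop("need at least one radius and one seed")
  rows <- list(); kept <- list()
  sched1 <- run_schedule(schedule$total_iterations,
                         probe_iterations = schedule$total_iterations,
                         sweep_radii_mm = schedule$sweep_radii_mm,
                         seeds = schedule$seeds)
  for (rad in schedule$sweep_radii_mm) for (sd in schedule$seeds) {
    if (!quiet) message(sprintf("sweep cell: R_astro %.4g mm, seed %d", rad, sd))
    row <- data.frame(radius_mm = rad, seed = sd, lambda_mm = NA_real_,
                      zeta = NA_real_, n_pinwheels = NA_integer_,
                      pw_per_hc = NA_real_, si_neuro_astro = NA_real_,
                      mean_local_angle_deg = NA_real_,
                      mean_selectivity = NA_real_, error = NA_character_)
    res <- tryCatch({
      cfg <- config
      cfg$R_astro_mm <- rad
      cfg$seed <- as.integer(sd)
      run <- train(cfg, sched1)
      mn <- run$maps[[as.character(sched1$total_iterations)]]$neuronal
      ma <- run$maps[[as.character(sched1$total_iterations)]]$astrocyte
      an <- analyze_map(mn)
      row$lambda_mm <- an$lambda_mm
      row$zeta <- an$zeta
      row$n_pinwheels <- an$n_pinwheels
      row$pw_per_hc <- an$pw_per_hc
      row$si_neuro_astro <- stability_index(mn$preference, ma$preference)
      row$mean_local_angle_deg <-
        local_orientation_similarity(mn, local_radius_mm)
      row$mean_selectivity <- mean(mn$selectivity)
      if (keep_maps)
        kept[[sprintf("r%g_s%d", rad, sd)]] <- list(neuronal = mn,
                                                    astrocyte = ma)
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  if (keep_maps) attr(out, "maps") <- kept
  out
}

#' @export
print.astro_run <- function(x, ...) {
  cat(sprintf(
    "<astro_run> %d iterations, %d probed map set(s), R_astro %.4g mm\n",
    x$schedule$total_iterations, length(x$maps), x$config$R_astro_mm))
  invisible(x)
}
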