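test_that("run schedules are validated", {
  expect_error(run_schedule(100, probe_iterations = c(50, 200)), "exceed")
  expect_error(run_schedule(100, probe_iterations = c(50, 20)), "sorted")
  expect_error(run_schedule(100, probe_iterations = 50,
                            sweep_radii_mm = c(-1, 2)), "radii")
  s <- run_schedule(100, probe_iterations = c(10, 100))
  expect_s3_class(s, "run_schedule")
})

test_that("probing a fresh model reflects the random initial weights", {
  cfg <- tiny_config()
  sch0 <- run_schedule(0, probe_iterations = integer(0))
  r <- train(cfg, sch0)
  m0 <- r$maps[["0"]]$neuronal
  m_direct <- probe_orientation_map(astro_model(cfg), layer = "neuronal")
  expect_identical(m0$preference, m_direct$preference)
  expect_identical(m0$selectivity, m_direct$selectivity)
})

test_that("probing never mutates the model state", {
  cfg <- tiny_config()
  r <- train(cfg, run_schedule(20, probe_iterations = integer(0)))
  m <- r$model
  before <- astromap:::model_state_image(m)
  probe_orientation_map(m, layer = "neuronal")
  probe_orientation_map(m, layer = "astrocyte")
  after <- astromap:::model_state_image(m)
  expect_identical(before, after)
})

test_that("probe orientation maps obey the vector-sum construction", {
  cfg <- tiny_config()
  m <- astro_model(cfg)
  om <- probe_orientation_map(m, n_orientations = 8, n_phases = 2)
  expect_true(all(om$preference >= 0 & om$preference < pi))
  expect_true(all(om$selectivity >= 0 & om$selectivity <= 1 + 1e-12))
  # single-orientation responder: preference at that angle, selectivity 1
  resp <- om$responses * 0
  resp[2, 2, 3] <- 1    # responds only at angles[3] = 45 deg
  vs <- matrix(0i, m$nc, m$nc); tot <- matrix(0, m$nc, m$nc)
  for (k in 1:8) {
    vs <- vs + resp[, , k] * exp(2i * om$angles[k])
    tot <- tot + resp[, , k]
  }
  pref <- (Arg(vs) / 2) %% pi
  expect_equal(pref[2, 2], pi / 4, tolerance = 1e-12)
  expect_equal((Mod(vs) / tot)[2, 2], 1)
  # equal response at all orientations: selectivity 0, preference set to 0
  resp[3, 3, ] <- 1
  vs2 <- Reduce(`+`, lapply(1:8, function(k)
    resp[, , k] * exp(2i * om$angles[k])))
  expect_lt(Mod(vs2[3, 3]), 1e-12)
  expect_error(probe_orientation_map(m, n_orientations = 2), "orientations")
  expect_error(probe_orientation_map(m, n_phases = 1), "phases")
})

test_that("vector-sum preference agrees with the argmax for unimodal tuning", {
  angles <- (0:7) * pi / 8
  for (a0 in c(0.2, 1.0, 2.8)) {
    r <- 1 + 0.8 * cos(2 * (angles - a0))   # unimodal tuning curve
    pref <- (Arg(sum(r * exp(2i * angles))) / 2) %% pi
    am <- angles[which.max(r)]
    d <- abs(pref - am); d <- min(d, pi - d)
    expect_lt(d, pi / 8 / 2 + 1e-9)
  }
})

test_that("training logs diagnostics and honours probe schedules", {
  cfg <- tiny_config()
  sch <- run_schedule(40, probe_iterations = c(20, 40))
  r <- train(cfg, sch, log_every = 10)
  expect_s3_class(r, "astro_run")
  expect_named(r$maps, c("20", "40"))
  expect_named(r$maps[["40"]], c("neuronal", "astrocyte"))
  expect_equal(r$maps[["40"]]$neuronal$iteration, 40)
  expect_true(all(c("iteration", "mean_y", "mean_rho", "e_mass_beyond") %in%
                    names(r$log)))
  expect_equal(max(r$log$iteration), 40)
})

test_that("checkpoints round-trip through disk", {
  cfg <- tiny_config()
  r <- train(cfg, run_schedule(15, probe_iterations = integer(0)))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(r$model, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$W, r$model$W)
  expect_identical(m2$rho, r$model$rho)
  expect_identical(m2$iteration, r$model$iteration)
  # restored models continue identically to an uninterrupted run
  sch <- run_schedule(10, probe_iterations = integer(0))
  cont <- train(cfg, sch, model = m2)
  full <- train(cfg, run_schedule(25, probe_iterations = integer(0)))
  expect_identical(cont$model$W, full$model$W)
  unlink(path)
})

test_that("a single-cell sweep fills every analysis column", {
  cfg <- tiny_config(density = 18)
  sch <- run_schedule(60, probe_iterations = 60,
                      sweep_radii_mm = 0.1125, seeds = 1L)
  sw <- run_sweep(cfg, sch)
  expect_equal(nrow(sw), 1L)
  expect_true(all(c("radius_mm", "seed", "lambda_mm", "n_pinwheels",
                    "pw_per_hc", "si_neuro_astro",
                    "mean_local_angle_deg") %in% names(sw)))
  if (is.na(sw$error)) {
    expect_true(is.finite(sw$lambda_mm))
    expect_true(is.finite(sw$si_neuro_astro))
  }
  # sweeps are a pure function of config and schedule
  sw2 <- run_sweep(cfg, sch)
  expect_identical(sw, sw2)
})

test_that("dropping the GABA term preserves the map qualitatively", {
  sch <- run_schedule(400, probe_iterations = 400)
  m_full <- train(tiny_config(density = 18, variant = "full"),
                  sch)$maps[["400"]]$neuronal
  m_ng <- train(tiny_config(density = 18, variant = "no_gaba"),
                sch)$maps[["400"]]$neuronal
  rnd <- synthetic_random_map(nrow(m_full$preference), seed = 99)
  si_pair <- stability_index(m_full, m_ng)
  expect_gt(si_pair, stability_index(m_full, rnd))
  expect_gt(si_pair, stability_index(m_ng, rnd))
})

test_that("small astrocyte radii prune distal excitatory mass during training", {
  cfg <- small_config(R_astro_mm = 0.015)
  r <- train(cfg, run_schedule(1200, probe_iterations = integer(0)),
             log_every = 100)
  beyond <- r$log$e_mass_beyond
  expect_lt(beyond[5], beyond[1])          # already decaying by 500
  expect_lt(tail(beyond, 1), 0.6 * head(beyond, 1))
})
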